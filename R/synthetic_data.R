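# Seeded synthetic-EHR generator: longitudinal visit sequences with an
# untreated hypertensive baseline, a persistent initial treatment, an
# endpoint-calibrated final reading, and planted subgroup-treatment effects
# that the local engine should recover.

#' Generator configuration for synthetic training data and vignette panels
#'
#' The generator emulates the structure of a routine-care hypertension
#' database: each patient contributes 2-5 visits (an untreated baseline V0
#' followed by V1-V4 under a single persistent first-line treatment), with
#' blood pressure drawn so that the 140/90 endpoint is reached with a
#' configured probability depending on the patient's subgroup and treatment.
#' Subgroups are defined by gender/age predicates (first match wins; an empty
#' predicate matches everyone). The endpoint Bernoulli is sampled first and
#' the final systolic/diastolic reading is then drawn from the matching side
#' of 140/90, so the planted effect probabilities are exactly calibrated.
#'
#' @param n_patients number of patients J
#' @param visits_range integer range of visits per patient (including the
#'   untreated baseline)
#' @param p_female proportion of female patients
#' @param age_range,bmi_range attribute ranges (uniform draws)
#' @param subgroups named list of predicates, each a list with optional
#'   `gender`, `age_min` (inclusive), `age_max` (exclusive)
#' @param treatments treatment vocabulary
#' @param effect subgroup x treatment matrix of endpoint probabilities
#' @param assignment subgroup x treatment matrix of treatment assignment
#'   probabilities (rows sum to 1)
#' @param adverse_event_rates named list per treatment of named event-code
#'   rates
#' @param contraindications data frame of planted contraindication triples:
#'   `subgroup`, `treatment`, `level`, `trigger_type`, `trigger_code`,
#'   `rate` (probability a member of the subgroup carries the trigger code)
#' @param seed integer seed; every generated artifact is reproducible per
#'   seed
#' @return a `generator_config` list
#' @export
generator_config <- function(n_patients = 1000,
                             visits_range = c(2, 5),
                             p_female = 0.5,
                             age_range = c(35, 85),
                             bmi_range = c(19, 36),
                             subgroups = NULL,
                             treatments = treatment_vocabulary(),
                             effect = NULL,
                             assignment = NULL,
                             adverse_event_rates = NULL,
                             contraindications = NULL,
                             seed = 1L) {
  if (n_patients < 1) stop("generator_config(): n_patients must be >= 1", call. = FALSE)
  if (visits_range[1] < 2)
    stop("generator_config(): need at least 2 visits (baseline + treated)",
         call. = FALSE)
  if (is.null(subgroups)) {
    subgroups <- list(
      S1 = list(gender = "F", age_min = age_range[1], age_max = 60),
      S2 = list()
    )
  }
  ns <- length(subgroups)
  if (is.null(effect)) {
    # per subgroup: one best treatment (0.8), one second-line (0.3), and a
    # low background rate for the rest
    effect <- rbind(
      S1 = c(0.05, 0.80, 0.05, 0.30, 0.05),
      S2 = c(0.80, 0.05, 0.05, 0.05, 0.30)
    )
    colnames(effect) <- treatments
    effect <- effect[names(subgroups)[seq_len(min(2, ns))], , drop = FALSE]
  }
  if (is.null(assignment)) {
    assignment <- matrix(1 / length(treatments), nrow = ns,
                         ncol = length(treatments),
                         dimnames = list(names(subgroups), treatments))
  }
  if (any(effect < 0 | effect > 1) || any(assignment < 0 | assignment > 1))
    stop("generator_config(): probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(assignment) - 1) > 1e-8))
    stop("generator_config(): assignment rows must sum to 1", call. = FALSE)
  if (is.null(adverse_event_rates)) {
    adverse_event_rates <- list(
      ACE_INHIBITOR = c(COUGH = 0.12),
      ARB = c(DIZZINESS = 0.05),
      BETA_BLOCKER = c(FATIGUE = 0.10),
      CALCIUM_CHANNEL_BLOCKER = c(ANKLE_EDEMA = 0.10),
      DIURETIC = c(HYPOKALEMIA = 0.08)
    )
  }
  if (is.null(contraindications)) {
    contraindications <- data.frame(
      subgroup = c("S1", "S2"),
      treatment = c("ARB", "ACE_INHIBITOR"),
      level = c("absolute", "absolute"),
      trigger_type = c("condition", "comorbidity"),
      trigger_code = c("PREGNANCY", "ANGIOEDEMA_HISTORY"),
      rate = c(0.3, 0.3),
      stringsAsFactors = FALSE
    )
    contraindications <-
      contraindications[contraindications$subgroup %in% names(subgroups), ,
                        drop = FALSE]
  }
  if (any(contraindications$rate < 0 | contraindications$rate > 1))
    stop("generator_config(): contraindication rates must lie in [0, 1]",
         call. = FALSE)
  cfg <- list(
    n_patients = as.integer(n_patients), visits_range = as.integer(visits_range),
    p_female = p_female, age_range = age_range, bmi_range = bmi_range,
    subgroups = subgroups, treatments = treatments, effect = effect,
    assignment = assignment, adverse_event_rates = adverse_event_rates,
    contraindications = contraindications, seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Assign a subgroup from gender and age
#'
#' @param gender,age attribute values
#' @param subgroups subgroup predicate list (see [generator_config()])
#' @return the name of the first matching subgroup
#' @export
assign_subgroup <- function(gender, age, subgroups) {
  for (nm in names(subgroups)) {
    p <- subgroups[[nm]]
    ok <- TRUE
    if (!is.null(p$gender)) ok <- ok && gender == p$gender
    if (!is.null(p$age_min)) ok <- ok && age >= p$age_min
    if (!is.null(p$age_max)) ok <- ok && age < p$age_max
    if (ok) return(nm)
  }
  stop("no subgroup matches gender=", gender, ", age=", age, call. = FALSE)
}

draw_context <- function(subgroup, cfg) {
  ctx <- list(comorbidity = character(0), condition = character(0),
              comedication = character(0))
  ci <- cfg$contraindications
  for (i in seq_len(nrow(ci))) {
    if (ci$subgroup[i] == subgroup && stats::runif(1) < ci$rate[i]) {
      tt <- ci$trigger_type[i]
      ctx[[tt]] <- c(ctx[[tt]], ci$trigger_code[i])
    }
  }
  ctx
}

draw_final_bp <- function(reached) {
  if (reached) {
    c(sys = round(stats::runif(1, 118, 140)), dia = round(stats::runif(1, 72, 90)))
  } else {
    c(sys = round(stats::runif(1, 142, 180)), dia = round(stats::runif(1, 80, 104)))
  }
}

#' Generate a synthetic training database
#'
#' Draws J patients with gender, age and BMI from the configured
#' distributions, assigns each to its subgroup and a treatment from the
#' assignment policy, samples the endpoint Bernoulli from the planted effect
#' table and emits a full visit sequence: untreated hypertensive baseline at
#' V0, the treatment starting at V1 and persisting, blood pressure
#' interpolating toward a final reading drawn on the sampled side of 140/90.
#' Fully reproducible for a given seed.
#'
#' @param cfg a [generator_config()]
#' @return list with `patients`, `visits` (data frames in the CSV dialects
#'   consumed by [build_training_db()]) and `ground_truth` (subgroup
#'   membership, per-subgroup best/second-best treatment, planted
#'   contraindications)
#' @export
generate_training_db <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  J <- cfg$n_patients
  start_date <- as.Date("2018-01-15")

  patients <- vector("list", J)
  all_visits <- vector("list", J)
  subgroup <- character(J)

  for (j in seq_len(J)) {
    pid <- sprintf("P%04d", j)
    gender <- if (stats::runif(1) < cfg$p_female) "F" else "M"
    age <- as.integer(round(stats::runif(1, cfg$age_range[1], cfg$age_range[2])))
    bmi <- stats::runif(1, cfg$bmi_range[1], cfg$bmi_range[2])
    height <- round(stats::runif(1, 155, 190))
    weight <- round(bmi * (height / 100)^2, 1)
    sg <- assign_subgroup(gender, age, cfg$subgroups)
    subgroup[j] <- sg

    n_visits <- sample(seq(cfg$visits_range[1], cfg$visits_range[2]), 1)
    dates <- start_date + ((j - 1) %% 365) + seq(0, by = 30,
                                                 length.out = n_visits)
    # date of birth chosen so completed-year age at V1 equals the drawn age
    dob <- dates[2] - round(age * 365.25) - 40

    treatment <- sample(cfg$treatments, 1, prob = cfg$assignment[sg, ])
    reached <- stats::runif(1) < cfg$effect[sg, treatment]
    base <- c(sys = round(stats::runif(1, 145, 185)),
              dia = round(stats::runif(1, 92, 110)))
    final <- draw_final_bp(reached)
    ctx <- draw_context(sg, cfg)

    rates <- cfg$adverse_event_rates[[treatment]]
    events <- names(rates)[stats::runif(length(rates)) < rates]

    n_treated <- n_visits - 1L
    frac <- if (n_treated == 1) 1 else seq_len(n_treated) / n_treated
    vs <- data.frame(
      visit_id = sprintf("%s-V%d", pid, seq_len(n_visits) - 1L),
      patient_id = pid,
      visit_date = dates,
      height_cm = height,
      weight_kg = weight,
      bmi = round(bmi, 1),
      comorbidities = join_codes(ctx$comorbidity),
      living_conditions = join_codes(ctx$condition),
      comedication = join_codes(ctx$comedication),
      bp_sys = c(base["sys"], round(base["sys"] + frac * (final["sys"] - base["sys"]))),
      bp_dia = c(base["dia"], round(base["dia"] + frac * (final["dia"] - base["dia"]))),
      treatment = c(NO_TREATMENT, rep(treatment, n_treated)),
      adverse_events = c("", rep("", n_treated - 1L),
                         join_codes(events)),
      stringsAsFactors = FALSE
    )
    all_visits[[j]] <- vs
    patients[[j]] <- data.frame(patient_id = pid, gender = gender,
                                date_of_birth = dob, stringsAsFactors = FALSE)
  }

  effect <- cfg$effect
  best <- apply(effect, 1, function(r) colnames(effect)[which.max(r)])
  second <- apply(effect, 1, function(r) {
    colnames(effect)[order(-r)][2]
  })
  gt <- list(
    subgroup = setNames(subgroup, vapply(patients, `[[`, "", "patient_id")),
    best_treatment = best,
    second_best_treatment = second,
    contraindications = cfg$contraindications,
    effect = effect,
    seed = cfg$seed
  )
  class(gt) <- "ground_truth"

  list(
    patients = do.call(rbind, c(patients, list(make.row.names = FALSE))),
    visits = do.call(rbind, c(all_visits, list(make.row.names = FALSE))),
    ground_truth = gt
  )
}

oracle_choice <- function(subgroup, ctx, cfg) {
  eff <- cfg$effect[subgroup, ]
  ci <- cfg$contraindications
  blocked <- vapply(seq_len(nrow(ci)), function(i) {
    ci$level[i] == "absolute" &&
      ci$trigger_code[i] %in% ctx[[ci$trigger_type[i]]]
  }, logical(1))
  blocked_tx <- unique(ci$treatment[blocked])
  allowed <- setdiff(names(eff), blocked_tx)
  if (length(allowed) == 0) allowed <- names(eff)
  allowed[which.max(eff[allowed])]
}

#' Generate a case-vignette panel with simulated expert labels
#'
#' Vignettes are drawn from the same attribute distributions as the training
#' data, with planted contraindication trigger codes in the clinical context
#' and non-consumed extras (24-h blood pressure, smoking status, height,
#' weight). Each simulated expert recommends exactly one treatment per
#' vignette: under the `"oracle"` policy the subgroup-best treatment that is
#' not absolutely contraindicated by the vignette's planted context; under
#' `"noisy"` the oracle choice with probability `1 - epsilon`, otherwise a
#' uniform draw among the other M - 1 treatments.
#'
#' @param cfg a [generator_config()]
#' @param n_vignettes,n_experts panel dimensions
#' @param expert_policy `"oracle"` or `"noisy"`
#' @param epsilon error rate of the noisy policy
#' @param seed seed for the panel draw (defaults to `cfg$seed + 1` so a panel
#'   differs from the training draw under the same config)
#' @return list with `vignettes` (data frame), `labels` (vignette x expert
#'   character matrix), `subgroup`, and `oracle` (per-vignette oracle choice)
#' @export
generate_vignette_panel <- function(cfg, n_vignettes = 100, n_experts = 5,
                                    expert_policy = c("oracle", "noisy"),
                                    epsilon = 0.1, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  expert_policy <- match.arg(expert_policy)
  set.seed(seed)
  M <- length(cfg$treatments)

  rows <- vector("list", n_vignettes)
  subgroup <- character(n_vignettes)
  oracle <- character(n_vignettes)
  labels <- matrix("", nrow = n_vignettes, ncol = n_experts,
                   dimnames = list(NULL, paste0("expert_", seq_len(n_experts))))

  # vignettes are classic mid-range cases: ages are drawn from the interior
  # of the population age range so every vignette's similarity window is
  # fully supported by the training population
  age_lo <- cfg$age_range[1] + 5
  age_hi <- cfg$age_range[2] - 5

  for (i in seq_len(n_vignettes)) {
    gender <- if (stats::runif(1) < cfg$p_female) "F" else "M"
    age <- as.integer(round(stats::runif(1, age_lo, age_hi)))
    bmi <- round(stats::runif(1, cfg$bmi_range[1], cfg$bmi_range[2]), 1)
    sg <- assign_subgroup(gender, age, cfg$subgroups)
    subgroup[i] <- sg
    ctx <- draw_context(sg, cfg)
    height <- round(stats::runif(1, 155, 190))
    rows[[i]] <- data.frame(
      vignette_id = sprintf("VIG%03d", i),
      gender = gender, age = age, bmi = bmi,
      comorbidities = join_codes(ctx$comorbidity),
      living_conditions = join_codes(ctx$condition),
      comedication = join_codes(ctx$comedication),
      bp_sys = round(stats::runif(1, 145, 185)),
      bp_dia = round(stats::runif(1, 92, 110)),
      smoking_status = sample(c("never", "former", "current"), 1),
      height_cm = height,
      weight_kg = round(bmi * (height / 100)^2, 1),
      stringsAsFactors = FALSE
    )
    oc <- oracle_choice(sg, ctx, cfg)
    oracle[i] <- oc
    for (p in seq_len(n_experts)) {
      labels[i, p] <- if (expert_policy == "oracle" || stats::runif(1) >= epsilon) {
        oc
      } else {
        sample(setdiff(cfg$treatments, oc), 1)
      }
    }
  }

  list(
    vignettes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    labels = labels,
    subgroup = subgroup,
    oracle = oracle
  )
}
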