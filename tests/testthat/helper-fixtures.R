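# Fixture builders used across the suite. Everything is constructed in code;
# no data files.

# one patient's visit sequence from a compact spec:
# list(treatment, sys, dia) per visit; first visit is the untreated baseline
make_visits <- function(pid, specs, start = as.Date("2020-01-01")) {
  n <- length(specs)
  data.frame(
    visit_id = sprintf("%s-V%d", pid, seq_len(n) - 1L),
    patient_id = pid,
    visit_date = start + 30 * (seq_len(n) - 1L),
    height_cm = NA_real_,
    weight_kg = NA_real_,
    bmi = 25,
    comorbidities = "",
    living_conditions = "",
    comedication = "",
    bp_sys = vapply(specs, function(s) s[[2]], numeric(1)),
    bp_dia = vapply(specs, function(s) s[[3]], numeric(1)),
    treatment = vapply(specs, function(s) s[[1]], character(1)),
    adverse_events = vapply(specs, function(s) s[["events"]] %||% "",
                            character(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_patient <- function(pid, gender = "F", dob = as.Date("1970-06-15")) {
  data.frame(patient_id = pid, gender = gender, date_of_birth = dob,
             stringsAsFactors = FALSE)
}

# a hand-built training db: features + outcomes, no extraction involved
make_db <- function(treatment, endpoint,
                    gender = rep("F", length(treatment)),
                    age = rep(50, length(treatment)),
                    bmi = rep(25, length(treatment)),
                    adverse_events = rep("", length(treatment))) {
  db <- data.frame(
    patient_id = sprintf("P%03d", seq_along(treatment)),
    gender = gender, age = age, bmi = bmi,
    comorbidities = "", living_conditions = "", comedication = "",
    treatment = treatment,
    delta_sys = -10, delta_dia = -5,
    endpoint_reached = endpoint,
    adverse_events = adverse_events,
    stringsAsFactors = FALSE
  )
  class(db) <- c("training_db", "data.frame")
  db
}

# independent brute-force SMC: per-attribute loop, scalar arithmetic only
brute_force_smc <- function(target, row, schema) {
  s <- 0
  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]
    a <- target[[nm]]; b <- row[[nm]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) next
    if (schema$kind[k] == "categorical") {
      if (a == b) s <- s + 1
    } else {
      d <- schema$half_width[k]
      if (b - d <= a && a <= b + d) s <- s + 1
    }
  }
  s / nrow(schema)
}

# random mixed-attribute schema + database for oracle tests
random_similarity_case <- function(J = 200, K = 10) {
  kinds <- sample(c("categorical", "numeric"), K, replace = TRUE)
  entries <- lapply(seq_len(K), function(k) {
    nm <- paste0("attr", k)
    if (kinds[k] == "categorical") attr_categorical(nm)
    else attr_numeric(nm, half_width = round(stats::runif(1, 0, 3), 2))
  })
  schema <- do.call(attribute_schema, entries)
  db <- as.data.frame(setNames(lapply(seq_len(K), function(k) {
    if (kinds[k] == "categorical") sample(LETTERS[1:4], J, replace = TRUE)
    else round(stats::runif(J, 0, 10), 1)
  }), schema$name), stringsAsFactors = FALSE)
  target <- setNames(lapply(seq_len(K), function(k) {
    if (kinds[k] == "categorical") sample(LETTERS[1:4], 1)
    else round(stats::runif(1, 0, 10), 1)
  }), schema$name)
  list(schema = schema, db = db, target = target)
}

benchmark_schema <- function() {
  attribute_schema(attr_categorical("gender"), attr_numeric("age", 5))
}
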