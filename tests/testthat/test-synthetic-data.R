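test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_patients = 60, seed = 42)
  a <- generate_training_db(cfg)
  b <- generate_training_db(cfg)
  expect_identical(a, b)
  pa <- generate_vignette_panel(cfg, n_vignettes = 15, n_experts = 3)
  pb <- generate_vignette_panel(cfg, n_vignettes = 15, n_experts = 3)
  expect_identical(pa, pb)
  # a different seed produces different data
  c_ <- generate_training_db(generator_config(n_patients = 60, seed = 43))
  expect_false(identical(a$visits, c_$visits))
})

test_that("generated records satisfy the visit-sequence invariants", {
  cfg <- generator_config(n_patients = 120, seed = 7)
  sim <- generate_training_db(cfg)
  for (pid in sim$patients$patient_id) {
    pv <- sim$visits[sim$visits$patient_id == pid, ]
    expect_equal(pv$treatment[1], "NONE")
    expect_true(all(diff(as.numeric(pv$visit_date)) > 0))
    expect_true(all(pv$bp_sys > pv$bp_dia & pv$bp_dia > 0))
    # baseline drawn hypertensive
    expect_true(pv$bp_sys[1] > 140 || pv$bp_dia[1] > 90)
    # the treatment persists once started
    expect_length(unique(pv$treatment[-1]), 1L)
  }
  expect_true(all(table(sim$visits$patient_id) >= 2))
  expect_true(all(table(sim$visits$patient_id) <= 5))
  # extraction consumes every generated patient
  db <- build_training_db(sim$patients, sim$visits)
  expect_equal(nrow(db), 120L)
})

test_that("a degenerate effect probability of 1 makes every patient reach the endpoint", {
  cfg <- generator_config(
    n_patients = 50, seed = 3,
    effect = matrix(1, 2, 5, dimnames = list(c("S1", "S2"),
                                             treatment_vocabulary()))
  )
  db <- build_training_db(generate_training_db(cfg)$patients,
                          generate_training_db(cfg)$visits)
  expect_true(all(db$endpoint_reached))
})

test_that("empirical endpoint rates are binomially consistent with the effect table", {
  p <- 0.8
  cfg <- generator_config(
    n_patients = 600, seed = 11,
    effect = matrix(p, 2, 5, dimnames = list(c("S1", "S2"),
                                             treatment_vocabulary()))
  )
  sim <- generate_training_db(cfg)
  db <- build_training_db(sim$patients, sim$visits)
  se <- sqrt(p * (1 - p) / nrow(db))
  expect_lt(abs(mean(db$endpoint_reached) - p), 3 * se)
})

test_that("subgroup assignment follows the predicates, first match wins", {
  sgs <- list(S1 = list(gender = "F", age_min = 35, age_max = 60),
              S2 = list())
  expect_equal(assign_subgroup("F", 45, sgs), "S1")
  expect_equal(assign_subgroup("F", 60, sgs), "S2")  # age_max exclusive
  expect_equal(assign_subgroup("M", 45, sgs), "S2")
  expect_error(assign_subgroup("F", 45, list(A = list(gender = "M"))),
               "no subgroup")
})

test_that("the ground truth names the argmax of the planted effect table", {
  cfg <- generator_config(n_patients = 10, seed = 5)
  gt <- generate_training_db(cfg)$ground_truth
  expect_equal(gt$best_treatment[["S1"]], "ARB")
  expect_equal(gt$best_treatment[["S2"]], "ACE_INHIBITOR")
  expect_equal(gt$second_best_treatment[["S1"]], "CALCIUM_CHANNEL_BLOCKER")
  expect_equal(gt$second_best_treatment[["S2"]], "DIURETIC")
  expect_setequal(unique(gt$subgroup), c("S1", "S2"))
})

test_that("oracle experts are unanimous and respect planted absolute contraindications", {
  cfg <- generator_config(n_patients = 10, seed = 9)
  panel <- generate_vignette_panel(cfg, n_vignettes = 23, n_experts = 5,
                                   expert_policy = "oracle")
  expect_true(all(inter_rater(panel$labels) == 1))
  # pregnant minority vignettes: ARB (subgroup best) must never be chosen
  pregnant <- grepl("PREGNANCY", panel$vignettes$living_conditions)
  if (any(pregnant))
    expect_false(any(panel$labels[pregnant, ] == "ARB"))
  # without contraindication the oracle picks the subgroup best
  clean <- !pregnant & !grepl("ANGIOEDEMA", panel$vignettes$comorbidities)
  best <- c(S1 = "ARB", S2 = "ACE_INHIBITOR")[panel$subgroup]
  expect_equal(panel$labels[clean, 1], unname(best[clean]))
})

test_that("a zero noise rate reproduces the oracle panel exactly", {
  cfg <- generator_config(n_patients = 10, seed = 13)
  noisy0 <- generate_vignette_panel(cfg, n_vignettes = 20, n_experts = 4,
                                    expert_policy = "noisy", epsilon = 0)
  expect_equal(unname(noisy0$labels[, 1]), noisy0$oracle)
  expect_true(all(noisy0$labels == noisy0$labels[, 1]))
})

test_that("noisy panels hit the closed-form pairwise agreement", {
  eps <- 0.3; M <- 5
  cfg <- generator_config(n_patients = 10, seed = 17)
  panel <- generate_vignette_panel(cfg, n_vignettes = 1200, n_experts = 4,
                                   expert_policy = "noisy", epsilon = eps)
  m <- inter_rater(panel$labels)
  expected <- (1 - eps)^2 + eps^2 / (M - 1)
  observed <- mean(m[upper.tri(m)])
  se <- sqrt(expected * (1 - expected) / 1200)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(visits_range = c(1, 3)), "at least 2")
  expect_error(
    generator_config(effect = matrix(1.5, 2, 5,
                                     dimnames = list(c("S1", "S2"),
                                                     treatment_vocabulary()))),
    "\\[0, 1\\]")
  bad_assign <- matrix(0.5, 2, 5, dimnames = list(c("S1", "S2"),
                                                  treatment_vocabulary()))
  expect_error(generator_config(assignment = bad_assign), "sum to 1")
})
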