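test_that("therapy matrix cells follow the pop/mean definitions", {
  db <- make_db(c("ACE_INHIBITOR", "ACE_INHIBITOR"), c(TRUE, FALSE))
  A_pop <- build_therapy_matrix(db, "pop")
  A_mean <- build_therapy_matrix(db, "mean")
  expect_equal(unname(A_pop[, "ACE_INHIBITOR"]), c(1L, 1L))
  expect_equal(unname(A_mean[, "ACE_INHIBITOR"]), c(1L, 0L))
  # one treatment per row
  expect_true(all(rowSums(attr(A_pop, "applied")) == 1))
  expect_error(build_therapy_matrix(make_db("XYZ", TRUE), "pop"),
               "unknown treatment")
})

test_that("predictions follow the l1-normalized projection (worked example)", {
  db <- make_db(c("ACE_INHIBITOR", "ACE_INHIBITOR", "CALCIUM_CHANNEL_BLOCKER",
                  "DIURETIC"),
                c(TRUE, FALSE, TRUE, FALSE))
  eta <- rep(1, 4)
  pred_mean <- predict_outcomes(eta, build_therapy_matrix(db, "mean"))
  expect_equal(pred_mean$h[["ACE_INHIBITOR"]], 0.25)
  expect_equal(pred_mean$h[["CALCIUM_CHANNEL_BLOCKER"]], 0.25)
  expect_equal(pred_mean$h[["DIURETIC"]], 0)
  expect_setequal(pred_mean$eligible,
                  c("ACE_INHIBITOR", "CALCIUM_CHANNEL_BLOCKER", "DIURETIC"))
  pred_pop <- predict_outcomes(eta, build_therapy_matrix(db, "pop"))
  expect_equal(pred_pop$h[["ACE_INHIBITOR"]], 0.5)
  expect_equal(sum(pred_pop$h), 1)
})

test_that("prediction equals an explicit double sum on random binary matrices", {
  set.seed(77)
  for (rep in 1:20) {
    J <- sample(50:500, 1); M <- 5
    treatments <- treatment_vocabulary()
    db <- make_db(sample(treatments, J, TRUE), sample(c(TRUE, FALSE), J, TRUE))
    A <- build_therapy_matrix(db, sample(c("pop", "mean"), 1),
                              treatments = treatments)
    eta <- round(runif(J), 3)
    eta[sample(J, 5)] <- 1  # ensure a nonempty neighborhood and ||eta|| > 0
    pred <- predict_outcomes(eta, A)
    # independent oracle: explicit elementwise double summation
    norm1 <- 0
    for (j in seq_len(J)) norm1 <- norm1 + abs(eta[j])
    for (m in pred$eligible) {
      acc <- 0
      for (j in seq_len(J)) acc <- acc + eta[j] * unclass(A)[j, m]
      expect_equal(pred$h[[m]], unname(acc) / norm1, tolerance = 1e-12)
    }
  }
})

test_that("pop scores sum to 1 and mean scores never exceed pop scores", {
  set.seed(88)
  for (rep in 1:10) {
    J <- sample(20:200, 1)
    db <- make_db(sample(treatment_vocabulary(), J, TRUE),
                  sample(c(TRUE, FALSE), J, TRUE))
    eta <- as.numeric(runif(J) < 0.5)
    if (sum(eta) == 0) eta[1] <- 1
    p_pop <- predict_outcomes(eta, build_therapy_matrix(db, "pop"))
    p_mean <- predict_outcomes(eta, build_therapy_matrix(db, "mean"))
    expect_equal(sum(p_pop$h), 1, tolerance = 1e-12)
    expect_true(all(p_mean$h[p_pop$eligible] <= p_pop$h[p_pop$eligible] + 1e-12))
  }
})

test_that("ranking breaks score ties by support then code, deterministically", {
  h <- c(ACE_INHIBITOR = 0.25, CALCIUM_CHANNEL_BLOCKER = 0.25)
  support <- c(ACE_INHIBITOR = 2L, CALCIUM_CHANNEL_BLOCKER = 1L)
  top <- rank_top_n(h, 1, support = support)
  expect_equal(top$treatment, "ACE_INHIBITOR")
  # equal support: lexicographic code order decides
  support2 <- c(ACE_INHIBITOR = 1L, CALCIUM_CHANNEL_BLOCKER = 1L)
  expect_equal(rank_top_n(h, 2, support = support2)$treatment,
               c("ACE_INHIBITOR", "CALCIUM_CHANNEL_BLOCKER"))
  # identical inputs give identical output
  expect_identical(rank_top_n(h, 2, support = support),
                   rank_top_n(h, 2, support = support))
  # n beyond the eligible set returns everything, ranks consecutive
  expect_equal(rank_top_n(c(BETA_BLOCKER = 1), 3)$treatment, "BETA_BLOCKER")
})

test_that("local mean-mode scores equal subgroup joint frequencies", {
  db <- make_db(
    treatment = c(rep("ARB", 4), rep("DIURETIC", 2), rep("ACE_INHIBITOR", 4)),
    endpoint = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, rep(TRUE, 4)),
    gender = c(rep("F", 6), rep("M", 4)),
    age = c(rep(50, 6), rep(50, 4))
  )
  target <- list(features = list(gender = "F", age = 50))
  cfg <- engine_config(scope = "local", mode = "mean", top_n = 5,
                       schema = benchmark_schema())
  rec <- recommend(target, db, cfg)
  expect_equal(rec$diagnostics$neighborhood_size, 6L)
  opts <- rec$options
  expect_equal(opts$score[opts$treatment == "ARB"], 3 / 6)
  expect_equal(opts$score[opts$treatment == "DIURETIC"], 1 / 6)
  # ACE was applied only outside the neighborhood (male patients)
  expect_false("ACE_INHIBITOR" %in% opts$treatment)
})

test_that("global scope reports the full database as neighborhood", {
  db <- make_db(rep("ARB", 7), rep(TRUE, 7))
  rec <- recommend(list(features = list(gender = "Z", age = 1)), db,
                   engine_config(scope = "global", schema = benchmark_schema()))
  expect_equal(rec$diagnostics$neighborhood_size, 7L)
})

test_that("empty neighborhood refuses by default and falls back when asked", {
  db <- make_db(rep("ARB", 5), rep(TRUE, 5))
  target <- list(features = list(gender = "M", age = 200))
  rec <- recommend(target, db, engine_config(schema = benchmark_schema()))
  expect_equal(rec$status, "no_recommendation")
  expect_match(rec$reason, "empty neighborhood")
  expect_equal(nrow(rec$options), 0L)
  rec2 <- recommend(target, db,
                    engine_config(schema = benchmark_schema(),
                                  fallback_on_empty = TRUE))
  expect_equal(rec2$status, "ok")
  expect_true(rec2$diagnostics$fallback)
  expect_equal(rec2$diagnostics$neighborhood_size, 5L)
})

test_that("a zero-attribute schema makes the local engine equal the global one", {
  set.seed(99)
  db <- make_db(sample(treatment_vocabulary(), 60, TRUE),
                sample(c(TRUE, FALSE), 60, TRUE))
  target <- list(features = list())
  r_loc <- recommend(target, db,
                     engine_config(scope = "local", schema = attribute_schema(),
                                   top_n = 5))
  r_glob <- recommend(target, db,
                      engine_config(scope = "global", schema = attribute_schema(),
                                    top_n = 5))
  expect_equal(r_loc$options, r_glob$options)
  expect_equal(r_loc$diagnostics$neighborhood_size,
               r_glob$diagnostics$neighborhood_size)
})

test_that("treatments never observed in the neighborhood are not offered", {
  db <- make_db(c("ARB", "ARB", "BETA_BLOCKER"), c(TRUE, FALSE, TRUE),
                gender = c("F", "F", "M"))
  rec <- recommend(list(features = list(gender = "F", age = 50)), db,
                   engine_config(schema = benchmark_schema(), top_n = 5))
  expect_setequal(rec$options$treatment, "ARB")
})

test_that("conditional scoring divides successes by applications", {
  db <- make_db(c(rep("ARB", 4), rep("DIURETIC", 2)),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cfg <- engine_config(scope = "global", mode = "mean", conditional = TRUE,
                       top_n = 5, schema = attribute_schema())
  rec <- recommend(list(features = list()), db, cfg)
  opts <- rec$options
  expect_equal(opts$score[opts$treatment == "ARB"], 3 / 4)
  expect_equal(opts$score[opts$treatment == "DIURETIC"], 0)
})

test_that("current treatment at target is flagged for continuation", {
  db <- make_db(rep("ARB", 5), rep(TRUE, 5))
  target <- list(features = list(gender = "F", age = 50),
                 current_treatment = "ARB", bp_sys = 135, bp_dia = 85)
  rec <- recommend(target, db, engine_config(schema = benchmark_schema()))
  expect_true(rec$options$is_current_and_at_target[rec$options$treatment == "ARB"])
  target$bp_sys <- 150
  rec2 <- recommend(target, db, engine_config(schema = benchmark_schema()))
  expect_false(any(rec2$options$is_current_and_at_target))
})

test_that("outcome summaries count event frequencies and bin mean deltas", {
  db <- make_db(rep("ACE_INHIBITOR", 3), c(TRUE, TRUE, FALSE),
                adverse_events = c("COUGH", "", ""))
  db$delta_sys <- c(-30, -20, -16)  # mean -22
  db$delta_dia <- c(-5, -5, -5)
  s <- outcome_summaries(db)
  expect_equal(s$ACE_INHIBITOR$event_distribution[["COUGH"]], 1 / 3)
  expect_equal(s$ACE_INHIBITOR$event_distribution[["none"]], 2 / 3)
  expect_equal(sum(s$ACE_INHIBITOR$event_distribution), 1)
  expect_equal(s$ACE_INHIBITOR$delta_sys_bin, "(-30,-15]")
  # single neighbor: degenerate distribution
  s1 <- outcome_summaries(db[1, ])
  expect_equal(s1$ACE_INHIBITOR$event_distribution[["COUGH"]], 1)
  # treatments absent from the neighborhood are omitted
  expect_named(s, "ACE_INHIBITOR")
})
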