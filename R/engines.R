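# Recommendation engines: patient-therapy matrix, outcome prediction,
# top-N ranking, and the end-to-end recommend() pipeline.

#' Engine configuration
#'
#' The four evaluated engine variants are spanned by `scope` and
#' `post_filter`: `RE-glob` (global scope), `RE-loc` (local neighborhood),
#' with the `-eb` suffix when evidence-based post-filtering is on. `mode`
#' selects how the patient-therapy matrix is filled: `"pop"` ranks by
#' treatment popularity in the neighborhood, `"mean"` by achievement of the
#' 140/90 blood-pressure endpoint.
#'
#' @param scope `"local"` or `"global"` neighborhood scope
#' @param mode `"mean"` (endpoint-driven, the evaluated default) or `"pop"`
#'   (popularity)
#' @param top_n number of ranked options to present (N >= 1)
#' @param post_filter `"off"`, `"absolute"` (hide absolutely contraindicated
#'   options) or `"absolute_relative"` (hide both levels)
#' @param schema similarity [attribute_schema()]
#' @param fallback_on_empty if `TRUE`, an empty local neighborhood falls back
#'   to the global engine (flagged in diagnostics); default `FALSE`, i.e. an
#'   explicit no-recommendation result, because silently widening the scope
#'   changes the clinical meaning of the recommendation
#' @param conditional if `TRUE`, `"mean"`-mode scores are conditioned on
#'   treatment application (successes among neighbors treated with m) rather
#'   than the joint frequency over the neighborhood; off by default
#' @param missing_policy see [smc()]
#' @param treatments treatment class vocabulary
#' @return an `engine_config` list; `engine_id(config)` gives the engine name
#' @export
engine_config <- function(scope = c("local", "global"),
                          mode = c("mean", "pop"),
                          top_n = 3,
                          post_filter = c("off", "absolute", "absolute_relative"),
                          schema = default_schema(),
                          fallback_on_empty = FALSE,
                          conditional = FALSE,
                          missing_policy = c("mismatch", "renormalize"),
                          treatments = treatment_vocabulary()) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  post_filter <- match.arg(post_filter)
  missing_policy <- match.arg(missing_policy)
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1)
    stop("engine_config(): top_n must be >= 1", call. = FALSE)
  if (length(treatments) < 2 || anyDuplicated(treatments))
    stop("engine_config(): need >= 2 distinct treatment codes", call. = FALSE)
  cfg <- list(scope = scope, mode = mode, top_n = as.integer(top_n),
              post_filter = post_filter, schema = schema,
              fallback_on_empty = isTRUE(fallback_on_empty),
              conditional = isTRUE(conditional),
              missing_policy = missing_policy,
              treatments = treatments)
  class(cfg) <- "engine_config"
  cfg
}

#' Engine identifier string, e.g. "RE-loc-eb"
#' @param config an [engine_config()]
#' @return character scalar
#' @export
engine_id <- function(config) {
  paste0("RE-", if (config$scope == "global") "glob" else "loc",
         if (config$post_filter != "off") "-eb" else "")
}

#' Build the binary patient-therapy matrix
#'
#' A J x M binary matrix over the training database. In `"pop"` mode a cell
#' (j, m) is 1 iff patient j received treatment m (the initial-treatment
#' episode); in `"mean"` mode it additionally requires that the 140/90
#' blood-pressure endpoint was reached under that treatment. Each row has at
#' most one nonzero column because only the initial treatment forms a data
#' point.
#'
#' @param db a `training_db` data frame
#' @param mode `"pop"` or `"mean"`
#' @param treatments treatment vocabulary defining the columns
#' @return a `therapy_matrix`: binary matrix with treatment-code column
#'   names; the application pattern (pop cells) is attached as attribute
#'   `"applied"` so neighborhood support can be counted in either mode
#' @export
build_therapy_matrix <- function(db, mode = c("pop", "mean"),
                                 treatments = treatment_vocabulary()) {
  mode <- match.arg(mode)
  if (nrow(db) == 0) stop("build_therapy_matrix(): empty database", call. = FALSE)
  unknown <- setdiff(unique(db$treatment), treatments)
  if (length(unknown) > 0)
    stop("unknown treatment code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  J <- nrow(db); M <- length(treatments)
  applied <- matrix(0L, nrow = J, ncol = M, dimnames = list(NULL, treatments))
  applied[cbind(seq_len(J), match(db$treatment, treatments))] <- 1L
  A <- applied
  if (mode == "mean") A <- A * as.integer(db$endpoint_reached)
  structure(A, applied = applied, mode = mode, class = c("therapy_matrix", class(A)))
}

#' Predict treatment outcomes from a neighborhood
#'
#' Normalizes the similarity vector by its l1 norm and projects it through
#' the patient-therapy matrix: `h = eta / ||eta||_1 %*% A`. Under a binary
#' similarity vector this is, per treatment, the fraction of neighbors whose
#' matrix cell is 1 — in `"mean"` mode the joint frequency of (treated with m
#' AND endpoint reached) over the neighborhood. Predictions exist only for
#' treatments applied at least once in the neighborhood (the eligible set).
#'
#' @param eta a `similarity_vector` from [select_neighborhood()], or a bare
#'   numeric vector of per-patient similarities
#' @param A a `therapy_matrix` from [build_therapy_matrix()]
#' @param conditional if `TRUE`, return instead the per-treatment success
#'   fraction among neighbors treated with m (prose reading of the score as a
#'   success probability); only meaningful for `"mean"`-mode matrices
#' @return an `outcome_prediction`: list with `h` (named scores over eligible
#'   treatments), `support` (neighbors that received each eligible
#'   treatment), `eligible`, and `neighborhood_size`
#' @export
predict_outcomes <- function(eta, A, conditional = FALSE) {
  ev <- if (inherits(eta, "similarity_vector")) eta$eta else eta
  if (length(ev) != nrow(A))
    stop("predict_outcomes(): eta length does not match matrix rows", call. = FALSE)
  norm1 <- sum(abs(ev))
  if (norm1 == 0)
    stop("predict_outcomes(): empty neighborhood (||eta||_1 = 0)", call. = FALSE)
  applied <- attr(A, "applied")
  in_nb <- ev >= 1            # binary neighborhood membership
  support <- as.integer(colSums(applied[in_nb, , drop = FALSE]))
  names(support) <- colnames(A)
  h <- as.vector((ev / norm1) %*% unclass(A))
  names(h) <- colnames(A)
  if (isTRUE(conditional)) {
    hits <- as.vector(ev %*% unclass(A))
    treated <- as.vector(ev %*% applied)
    h <- ifelse(treated > 0, hits / treated, 0)
    names(h) <- colnames(A)
  }
  eligible <- names(support)[support >= 1]
  out <- list(h = h[eligible], support = support[eligible],
              eligible = eligible, neighborhood_size = sum(in_nb))
  class(out) <- "outcome_prediction"
  out
}

#' Rank treatment options and keep the top N
#'
#' Options are sorted by score descending; ties are broken by larger support
#' count, then lexicographically by treatment code, so the ranking is fully
#' deterministic. Ranks are assigned after sorting, 1-based and consecutive.
#'
#' @param pred an `outcome_prediction`, or a named numeric score vector
#' @param n number of options to keep (the list is truncated to
#'   `min(n, number of eligible options)`)
#' @param support optional named support counts when `pred` is a bare vector
#' @return data frame with columns `treatment`, `score`, `support`, `rank`
#' @export
rank_top_n <- function(pred, n, support = NULL) {
  if (inherits(pred, "outcome_prediction")) {
    h <- pred$h; support <- pred$support
  } else {
    h <- pred
    if (is.null(support)) support <- setNames(rep(0L, length(h)), names(h))
  }
  if (length(h) == 0)
    return(data.frame(treatment = character(0), score = numeric(0),
                      support = integer(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  ord <- order(-h, -support[names(h)], names(h), method = "radix")
  keep <- ord[seq_len(min(as.integer(n), length(h)))]
  data.frame(
    treatment = names(h)[keep],
    score = as.numeric(h[keep]),
    support = as.integer(support[names(h)[keep]]),
    rank = seq_along(keep),
    stringsAsFactors = FALSE
  )
}

no_recommendation <- function(engine, reason, diagnostics) {
  out <- list(status = "no_recommendation", engine = engine, reason = reason,
              options = data.frame(treatment = character(0), score = numeric(0),
                                   support = integer(0), rank = integer(0),
                                   contraindication = character(0),
                                   is_current_and_at_target = logical(0),
                                   stringsAsFactors = FALSE),
              evidence = NULL, summaries = NULL, diagnostics = diagnostics)
  class(out) <- "recommendation"
  out
}

#' Generate a treatment recommendation for a target patient
#'
#' Runs the full pipeline: neighborhood selection (or global bypass) over the
#' training database, patient-therapy matrix construction, outcome
#' prediction, contraindication labeling against the target's clinical
#' context, optional evidence-based post-filtering (applied before top-N
#' truncation so the list still presents up to N viable options), and
#' deterministic top-N ranking. Neighborhood outcome summaries (adverse-event
#' distributions and binned mean blood-pressure changes) are attached for
#' display. When the target's current treatment already meets the 140/90
#' target, that option is flagged `is_current_and_at_target` to support
#' recommending its continuation.
#'
#' @param target list describing the target patient: `features` (named list
#'   matching the schema attributes), optional `context` (list with
#'   `comorbidities`, `conditions`, `comedication` code vectors), optional
#'   `current_treatment`, `bp_sys`, `bp_dia`
#' @param db a `training_db`
#' @param config an [engine_config()]
#' @param rules optional contraindication rule list from [load_rules()] /
#'   [demo_rules()]; required when `post_filter != "off"`
#' @return a `recommendation` object: `status` (`"ok"` or
#'   `"no_recommendation"`), ranked `options` (with contraindication labels),
#'   matched rule `evidence`, neighborhood `summaries`, and `diagnostics`
#'   (engine id, neighborhood size, fallback flag)
#' @export
recommend <- function(target, db, config = engine_config(), rules = NULL) {
  if (nrow(db) == 0) stop("recommend(): empty training database", call. = FALSE)
  if (config$post_filter != "off" && is.null(rules))
    stop("recommend(): post-filtering requested but no rule base given",
         call. = FALSE)
  eng <- engine_id(config)

  sv <- select_neighborhood(target$features, db, config$schema,
                            scope = config$scope,
                            missing_policy = config$missing_policy)
  fallback <- FALSE
  if (length(sv$neighborhood) == 0) {
    diag <- list(engine = eng, scope = config$scope, mode = config$mode,
                 neighborhood_size = 0L, n_db = nrow(db), fallback = FALSE)
    if (!config$fallback_on_empty)
      return(no_recommendation(eng, "empty neighborhood", diag))
    sv <- select_neighborhood(target$features, db, config$schema,
                              scope = "global")
    fallback <- TRUE
  }

  A <- build_therapy_matrix(db, mode = config$mode,
                            treatments = config$treatments)
  # the neighborhood engine weights members only: eta is binarized to the
  # membership indicator (patients with eta_j < 1 carry no weight)
  eta_members <- as.numeric(seq_len(nrow(db)) %in% sv$neighborhood)
  pred <- predict_outcomes(eta_members, A, conditional = config$conditional)

  ctx <- patient_context(
    comorbidities = target$context$comorbidities,
    conditions = target$context$conditions,
    comedication = target$context$comedication
  )
  matches <- if (is.null(rules)) NULL else applicable_rules(ctx, rules)

  # full ranked list first, filter, then truncate to N
  ranked <- rank_top_n(pred, n = length(pred$h))
  ranked <- label_and_filter(ranked, matches, level = config$post_filter)
  options <- utils::head(ranked, config$top_n)
  options$rank <- seq_len(nrow(options))

  at_target <- !is.null(target$current_treatment) &&
    is_treated(target$current_treatment) &&
    !is.null(target$bp_sys) && !is.null(target$bp_dia) &&
    endpoint_reached(target$bp_sys, target$bp_dia)
  options$is_current_and_at_target <-
    at_target & options$treatment == (target$current_treatment %||% "")

  nb_db <- db[sv$neighborhood, , drop = FALSE]
  out <- list(
    status = "ok",
    engine = eng,
    reason = NULL,
    options = options,
    evidence = if (is.null(matches)) NULL else matches$matches,
    summaries = outcome_summaries(nb_db),
    diagnostics = list(engine = eng, scope = config$scope, mode = config$mode,
                       neighborhood_size = length(sv$neighborhood),
                       n_db = nrow(db), fallback = fallback)
  )
  class(out) <- "recommendation"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> ", x$engine, " — ", x$status, "\n", sep = "")
  cat("  neighborhood: ", x$diagnostics$neighborhood_size, " of ",
      x$diagnostics$n_db,
      if (isTRUE(x$diagnostics$fallback)) " (global fallback)" else "",
      "\n", sep = "")
  if (x$status == "ok" && nrow(x$options) > 0) {
    for (i in seq_len(nrow(x$options))) {
      o <- x$options[i, ]
      cat(sprintf("  %d. %-24s score=%.3f support=%d%s%s\n", o$rank,
                  o$treatment, o$score, o$support,
                  if (o$contraindication != "none")
                    paste0(" [", o$contraindication, " contraindication]") else "",
                  if (isTRUE(o$is_current_and_at_target))
                    " [current, at target]" else ""))
    }
  } else if (x$status != "ok") {
    cat("  reason: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Default bin edges for blood-pressure change summaries (mmHg)
#'
#' Bins of width 15 mmHg centered at 0, open-ended at both extremes. Purely
#' presentational and overridable.
#' @return numeric vector of bin edges
#' @export
default_delta_bins <- function() c(-Inf, seq(-45, 45, by = 15), Inf)

#' Summarize outcomes observed in a neighborhood, per treatment
#'
#' For each treatment applied in the neighborhood: the relative frequency
#' distribution of adverse events (a patient with no recorded event counts
#' as `"none"`; a patient with several events contributes one count per
#' event), and the mean systolic/diastolic blood-pressure change assigned to
#' a value-range bin. Treatments with zero neighbors are omitted.
#'
#' @param nb_db the neighborhood subset of a `training_db`
#' @param bin_edges bin edges for the mean delta values
#' @return named list (per treatment) of lists with `n`, `event_distribution`
#'   (named numeric summing to 1), `mean_delta_sys`, `mean_delta_dia`,
#'   `delta_sys_bin`, `delta_dia_bin`
#' @export
outcome_summaries <- function(nb_db, bin_edges = default_delta_bins()) {
  if (nrow(nb_db) == 0) stop("outcome_summaries(): empty neighborhood", call. = FALSE)
  out <- list()
  for (tx in sort(unique(nb_db$treatment))) {
    sub <- nb_db[nb_db$treatment == tx, , drop = FALSE]
    events <- unlist(lapply(sub$adverse_events, function(s) {
      cs <- split_codes(s)
      if (length(cs) == 0) "none" else cs
    }))
    dist <- table(events) / length(events)
    ms <- mean(sub$delta_sys); md <- mean(sub$delta_dia)
    out[[tx]] <- list(
      n = nrow(sub),
      event_distribution = setNames(as.numeric(dist), names(dist)),
      mean_delta_sys = ms,
      mean_delta_dia = md,
      delta_sys_bin = as.character(cut(ms, breaks = bin_edges)),
      delta_dia_bin = as.character(cut(md, breaks = bin_edges))
    )
  }
  out
}
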