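# Vignette-panel evaluation: one-hot ground truths, top-N agreement
# statistics (per expert, union-of-experts, majority vote) and inter-rater
# agreement.

one_hot <- function(code, treatments) {
  v <- integer(length(treatments))
  names(v) <- treatments
  if (!code %in% treatments)
    stop("unknown treatment code '", code, "'", call. = FALSE)
  v[code] <- 1L
  v
}

#' Top-N indicator vector for one recommendation
#'
#' Binary vector over the treatment vocabulary with ones at the engine's
#' top-N options.
#'
#' @param rec a `recommendation` (or a character vector of the top-N
#'   treatment codes)
#' @param treatments treatment vocabulary
#' @param n keep the first `n` ranked options (default all)
#' @return named binary integer vector of length M
#' @export
top_n_indicator <- function(rec, treatments = treatment_vocabulary(), n = Inf) {
  codes <- if (inherits(rec, "recommendation")) rec$options$treatment else rec
  codes <- utils::head(codes, n)
  v <- integer(length(treatments))
  names(v) <- treatments
  v[match(codes, treatments)] <- 1L
  v
}

#' Agreement between a top-N list and one expert's choice
#'
#' The inner product of the top-N indicator with the expert's one-hot
#' ground-truth vector: 1 iff the expert's chosen treatment appears in the
#' top-N list.
#'
#' @param h0 binary indicator vector over the treatment vocabulary
#' @param t one-hot ground-truth vector over the same vocabulary
#' @return 0 or 1
#' @export
agreement <- function(h0, t) {
  if (length(h0) != length(t))
    stop("agreement(): vector length mismatch", call. = FALSE)
  as.integer(sum(h0 * t) > 0)
}

#' Panel agreement metrics over a set of case vignettes
#'
#' For each expert p, `r_p` is the fraction of vignettes whose expert choice
#' appears in the engine's top-N list; `agree_all` averages `r_p` over the
#' panel (its dispersion across experts is reported alongside). `agree_any`
#' scores against the elementwise union of the experts' one-hot vectors (a
#' hit iff ANY expert's choice is in the list) and `agree_majority` against
#' the majority vote, where all treatments tied at the maximal vote count
#' form the ground-truth set.
#'
#' @param indicators I x M binary matrix of top-N indicators (rows =
#'   vignettes, columns = treatment vocabulary)
#' @param labels I x P character matrix of expert choices (columns =
#'   experts); every expert must label every vignette
#' @param treatments treatment vocabulary (must match indicator columns)
#' @param engine,n optional identifiers carried into the report
#' @return an `agreement_report`: list with `r_p`, `agree_all`,
#'   `agree_all_sd`, `agree_any`, `agree_majority`, `n`, `engine`,
#'   `n_vignettes`, `n_experts`
#' @export
panel_metrics <- function(indicators, labels,
                          treatments = treatment_vocabulary(),
                          engine = NA_character_, n = NA_integer_) {
  indicators <- as.matrix(indicators)
  labels <- as.matrix(labels)
  if (nrow(indicators) != nrow(labels))
    stop("panel_metrics(): vignette count mismatch", call. = FALSE)
  if (ncol(indicators) != length(treatments))
    stop("panel_metrics(): indicator columns must match vocabulary", call. = FALSE)
  if (any(is.na(labels)) || any(!nzchar(labels)))
    stop("panel_metrics(): incomplete expert label matrix", call. = FALSE)
  I <- nrow(labels); P <- ncol(labels)

  r_p <- vapply(seq_len(P), function(p) {
    mean(vapply(seq_len(I), function(i) {
      agreement(indicators[i, ], one_hot(labels[i, p], treatments))
    }, integer(1)))
  }, numeric(1))

  r_any <- mean(vapply(seq_len(I), function(i) {
    u <- as.integer(treatments %in% labels[i, ])
    agreement(indicators[i, ], u)
  }, integer(1)))

  r_majority <- mean(vapply(seq_len(I), function(i) {
    votes <- table(factor(labels[i, ], levels = treatments))
    gt <- as.integer(votes == max(votes) & votes > 0)
    agreement(indicators[i, ], gt)
  }, integer(1)))

  out <- list(
    r_p = r_p,
    agree_all = mean(r_p),
    agree_all_sd = if (P > 1) stats::sd(r_p) else 0,
    agree_any = r_any,
    agree_majority = r_majority,
    n = n,
    engine = engine,
    n_vignettes = I,
    n_experts = P
  )
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s top-%s on %d vignettes x %d experts\n",
              x$engine, as.character(x$n), x$n_vignettes, x$n_experts))
  cat(sprintf("  agree_all = %.2f (%.2f)  agree_any = %.2f  agree_majority = %.2f\n",
              x$agree_all, x$agree_all_sd, x$agree_any, x$agree_majority))
  invisible(x)
}

#' Inter-rater agreement matrix of an expert panel
#'
#' Entry (p, q) is the fraction of vignettes on which experts p and q chose
#' the identical treatment. The matrix is symmetric with a unit diagonal.
#'
#' @param labels I x P character matrix of expert choices
#' @return P x P numeric matrix
#' @export
inter_rater <- function(labels) {
  labels <- as.matrix(labels)
  P <- ncol(labels)
  if (P < 2) stop("inter_rater(): need at least two experts", call. = FALSE)
  m <- diag(1, P)
  for (p in seq_len(P - 1)) {
    for (q in (p + 1):P) {
      a <- mean(labels[, p] == labels[, q])
      m[p, q] <- a
      m[q, p] <- a
    }
  }
  dimnames(m) <- list(colnames(labels), colnames(labels))
  m
}

#' Run the vignette benchmark over the four engine variants
#'
#' Evaluates `RE-glob`, `RE-loc`, `RE-glob-eb` and `RE-loc-eb` (outcome-driven
#' `"mean"` mode by default) for each requested top-N against the expert
#' panel, producing one agreement report per engine x N. Post-filtering of
#' absolute contraindications is applied on the full ranked list before
#' truncation, so top-N indicators for the `-eb` engines are prefixes of the
#' filtered list.
#'
#' @param vignettes data frame of case vignettes (columns: `vignette_id`,
#'   the schema feature columns, and semicolon code lists `comorbidities`,
#'   `living_conditions`, `comedication`)
#' @param labels I x P character matrix (or data frame) of expert choices
#' @param db a `training_db`
#' @param rules contraindication `rule_base` for the `-eb` variants
#' @param schema similarity [attribute_schema()]
#' @param n_values top-N values to evaluate
#' @param mode therapy-matrix mode, `"mean"` or `"pop"`
#' @param treatments treatment vocabulary
#' @param fallback_on_empty passed to [engine_config()]
#' @return a `benchmark_result`: list with `table` (one row per engine x N
#'   with the three agreement metrics), `reports` (the underlying
#'   `agreement_report`s), `inter_rater` (expert matrix), and
#'   `neighborhood_sizes` (local-engine diagnostics: per-vignette sizes plus
#'   mean, sd and IQR)
#' @export
run_benchmark <- function(vignettes, labels, db, rules,
                          schema = attribute_schema(attr_categorical("gender"),
                                                    attr_numeric("age", 5)),
                          n_values = 1:3, mode = "mean",
                          treatments = treatment_vocabulary(),
                          fallback_on_empty = TRUE) {
  labels <- as.matrix(labels)
  engines <- c("RE-glob", "RE-loc", "RE-glob-eb", "RE-loc-eb")
  I <- nrow(vignettes)
  M <- length(treatments)

  nb_sizes <- rep(NA_integer_, I)
  reports <- list()
  rows <- list()

  for (eng in engines) {
    scope <- if (grepl("glob", eng)) "global" else "local"
    pf <- if (grepl("-eb$", eng)) "absolute" else "off"
    cfg <- engine_config(scope = scope, mode = mode, top_n = M,
                         post_filter = pf, schema = schema,
                         fallback_on_empty = fallback_on_empty,
                         treatments = treatments)
    # ranked (and, for -eb, filtered) full lists, one per vignette
    lists <- vector("list", I)
    for (i in seq_len(I)) {
      tgt <- vignette_target(vignettes[i, , drop = FALSE], schema)
      rec <- recommend(tgt, db, cfg, rules = rules)
      lists[[i]] <- rec$options$treatment
      if (eng == "RE-loc")
        nb_sizes[i] <- if (isTRUE(rec$diagnostics$fallback)) 0L
                       else rec$diagnostics$neighborhood_size
    }
    for (N in n_values) {
      ind <- t(vapply(lists, function(l) top_n_indicator(l, treatments, n = N),
                      integer(M)))
      rep_ <- panel_metrics(ind, labels, treatments, engine = eng, n = N)
      reports[[paste0(eng, "-top", N)]] <- rep_
      rows[[paste0(eng, "-top", N)]] <- data.frame(
        engine = eng, n = N,
        agree_all = rep_$agree_all, agree_all_sd = rep_$agree_all_sd,
        agree_any = rep_$agree_any, agree_majority = rep_$agree_majority,
        stringsAsFactors = FALSE
      )
    }
  }

  out <- list(
    table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    reports = reports,
    inter_rater = inter_rater(labels),
    neighborhood_sizes = list(
      sizes = nb_sizes,
      mean = mean(nb_sizes), sd = stats::sd(nb_sizes),
      iqr = stats::IQR(nb_sizes)
    )
  )
  class(out) <- "benchmark_result"
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  cat(format_benchmark_table(x), sep = "\n")
  cat(sprintf("mean neighborhood size (RE-loc): %.2f (sd %.2f, IQR %.2f)\n",
              x$neighborhood_sizes$mean, x$neighborhood_sizes$sd,
              x$neighborhood_sizes$iqr))
  invisible(x)
}

#' Format a benchmark table as fixed-width text
#'
#' One block per engine, one line per top-N, with agree_all (and its
#' dispersion across experts), agree_any and agree_majority.
#'
#' @param result a `benchmark_result`
#' @return character vector of lines
#' @export
format_benchmark_table <- function(result) {
  tab <- result$table
  lines <- sprintf("%-12s %-6s %-12s %-10s %-14s",
                   "engine", "top-N", "agree_all", "agree_any", "agree_majority")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("%-12s %-6d %.2f (%.2f)  %-10.2f %-14.2f",
                              tab$engine[i], tab$n[i], tab$agree_all[i],
                              tab$agree_all_sd[i], tab$agree_any[i],
                              tab$agree_majority[i]))
  }
  lines
}

#' Build a recommendation target from one vignette row
#'
#' Picks the schema feature columns and the clinical context code lists out
#' of a vignette record; any other columns (24-h blood pressure, smoking
#' status, laboratory flags, ...) are carried by the vignette but not
#' consumed by the engine.
#'
#' @param row one-row data frame (a vignette)
#' @param schema the active [attribute_schema()]
#' @return a target list for [recommend()]
#' @export
vignette_target <- function(row, schema = default_schema()) {
  feats <- lapply(schema$name, function(nm) {
    if (nm %in% names(row)) row[[nm]] else NA
  })
  names(feats) <- schema$name
  list(
    features = feats,
    context = list(
      comorbidities = split_codes(row$comorbidities %||% ""),
      conditions = split_codes(row$living_conditions %||% ""),
      comedication = split_codes(row$comedication %||% "")
    ),
    current_treatment = row$current_treatment %||% NULL,
    bp_sys = row$bp_sys %||% NULL,
    bp_dia = row$bp_dia %||% NULL
  )
}
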