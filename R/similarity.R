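# Patient similarity: simple matching coefficient (SMC) over a configured
# attribute schema, and neighborhood selection as the set of database
# patients matching on all K attributes.

#' Declare a categorical similarity attribute
#'
#' @param name attribute name; must match a column of the training database
#' @return a one-row schema entry
#' @export
attr_categorical <- function(name) {
  data.frame(name = name, kind = "categorical", half_width = NA_real_,
             stringsAsFactors = FALSE)
}

#' Declare a numeric (interval-matched) similarity attribute
#'
#' @param name attribute name; must match a column of the training database
#' @param half_width interval half-width in attribute units (e.g. 5 years);
#'   two values match when they differ by at most `half_width`
#' @return a one-row schema entry
#' @export
attr_numeric <- function(name, half_width) {
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      is.na(half_width) || half_width < 0)
    stop("attr_numeric(): half_width must be a single non-negative number",
         call. = FALSE)
  data.frame(name = name, kind = "numeric", half_width = as.numeric(half_width),
             stringsAsFactors = FALSE)
}

#' Assemble an attribute schema for patient similarity
#'
#' The schema lists the K attributes over which the simple matching
#' coefficient is computed, in order, with the interval half-width for each
#' numeric attribute. A schema with zero attributes is allowed and makes
#' every pair of patients similar (the local engine then degenerates to the
#' global one).
#'
#' @param ... schema entries from [attr_categorical()] / [attr_numeric()]
#' @return an `attribute_schema` data frame with columns `name`, `kind`,
#'   `half_width`
#' @examples
#' attribute_schema(attr_categorical("gender"), attr_numeric("age", 5))
#' @export
attribute_schema <- function(...) {
  entries <- list(...)
  schema <- if (length(entries) == 0) {
    data.frame(name = character(0), kind = character(0),
               half_width = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, entries)
  }
  if (anyDuplicated(schema$name))
    stop("attribute_schema(): duplicate attribute names", call. = FALSE)
  class(schema) <- c("attribute_schema", "data.frame")
  schema
}

#' Default similarity schema: gender, age +/- 5 years, BMI +/- 2.5 kg/m2
#'
#' The BMI half-width of 2.5 kg/m2 is half the width of a standard WHO BMI
#' class; age and gender follow the usual demographic matching for
#' hypertension cohorts. All three are configurable.
#'
#' @return an `attribute_schema`
#' @export
default_schema <- function() {
  attribute_schema(
    attr_categorical("gender"),
    attr_numeric("age", 5),
    attr_numeric("bmi", 2.5)
  )
}

#' Match two categorical observations
#'
#' Codes are opaque, case-sensitive tokens; a match requires exact equality.
#'
#' @param x,x_j categorical codes
#' @return 1 if identical, else 0
#' @export
match_categorical <- function(x, x_j) {
  as.integer(!is.na(x) & !is.na(x_j) & x == x_j)
}

#' Match two numeric observations against a closed interval
#'
#' The database patient's value `x_j` spans the closed interval
#' `[x_j - delta, x_j + delta]`; the target value `x` matches when it falls
#' inside. With a symmetric closed interval this is equivalent to centering
#' the interval on the target.
#'
#' @param x target value
#' @param x_j database patient value
#' @param delta interval half-width (non-negative)
#' @return 1 if `x` falls in the interval, else 0
#' @export
match_numeric <- function(x, x_j, delta) {
  if (is.na(delta) || delta < 0)
    stop("match_numeric(): delta must be non-negative", call. = FALSE)
  as.integer(!is.na(x) & !is.na(x_j) & x_j - delta <= x & x <= x_j + delta)
}

match_counts <- function(target, db, schema, missing_policy) {
  J <- nrow(db)
  matches <- matrix(0L, nrow = J, ncol = nrow(schema))
  observed <- matrix(TRUE, nrow = J, ncol = nrow(schema))
  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]
    if (!nm %in% names(db))
      stop("schema attribute '", nm, "' not present in database", call. = FALSE)
    tv <- target[[nm]]
    if (is.null(tv)) tv <- NA
    col <- db[[nm]]
    miss <- is.na(col) | is.na(tv)
    m <- if (schema$kind[k] == "categorical") {
      !miss & col == tv
    } else {
      d <- schema$half_width[k]
      if (is.na(d) || d < 0)
        stop("invalid half_width for attribute '", nm, "'", call. = FALSE)
      !miss & (col - d <= tv) & (tv <= col + d)
    }
    matches[, k] <- as.integer(m)
    observed[, k] <- !miss
  }
  list(matches = matches, observed = observed)
}

#' Simple matching coefficient between a target and one database patient
#'
#' The SMC is the fraction of schema attributes on which the two feature
#' vectors match (exact equality for categorical attributes, closed-interval
#' inclusion for numeric ones). With `missing_policy = "mismatch"` (default)
#' an attribute missing on either side counts as a mismatch, conservatively
#' keeping incompletely observed patients out of neighborhoods;
#' `"renormalize"` instead averages over the attributes observed on both
#' sides.
#'
#' @param x,x_j named lists or one-row data frames holding the attribute
#'   values
#' @param schema an [attribute_schema()]
#' @param missing_policy `"mismatch"` or `"renormalize"`
#' @return similarity in `[0, 1]`; 1 means similar on all K attributes
#' @export
smc <- function(x, x_j, schema, missing_policy = c("mismatch", "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  db <- as.data.frame(x_j, stringsAsFactors = FALSE)
  mc <- match_counts(as.list(x), db, schema, missing_policy)
  K <- nrow(schema)
  if (K == 0) return(1)
  if (missing_policy == "renormalize") {
    k_obs <- sum(mc$observed[1, ])
    if (k_obs == 0) return(0)
    sum(mc$matches[1, ]) / k_obs
  } else {
    sum(mc$matches[1, ]) / K
  }
}

#' Select a target patient's neighborhood in the training database
#'
#' Computes the similarity `eta_j = smc(target, x_j)` against every database
#' patient and returns the neighborhood: patients similar on all schema
#' attributes (`eta_j = 1`). With `scope = "global"` the similarity
#' computation is bypassed and the entire database is the neighborhood
#' (`eta_j = 1` for all j), which is the non-personalized baseline. A schema
#' with zero attributes is treated as a universal match.
#'
#' @param target named list (or one-row data frame) of target attribute
#'   values
#' @param db a `training_db` data frame (any data frame with the schema
#'   columns works)
#' @param schema an [attribute_schema()]
#' @param scope `"local"` (similarity-based) or `"global"` (bypass)
#' @param missing_policy see [smc()]
#' @return a `similarity_vector`: list with `eta` (numeric, length
#'   `nrow(db)`) and `neighborhood` (integer indices with `eta_j = 1`)
#' @export
select_neighborhood <- function(target, db, schema,
                                scope = c("local", "global"),
                                missing_policy = c("mismatch", "renormalize")) {
  scope <- match.arg(scope)
  missing_policy <- match.arg(missing_policy)
  J <- nrow(db)
  if (J == 0) stop("select_neighborhood(): empty training database", call. = FALSE)
  K <- nrow(schema)
  if (scope == "global" || K == 0) {
    out <- list(eta = rep(1, J), neighborhood = seq_len(J))
    class(out) <- "similarity_vector"
    return(out)
  }
  mc <- match_counts(as.list(target), db, schema, missing_policy)
  n_match <- rowSums(mc$matches)
  if (missing_policy == "renormalize") {
    k_obs <- rowSums(mc$observed)
    eta <- ifelse(k_obs == 0, 0, n_match / k_obs)
    full <- which(k_obs > 0 & n_match == k_obs)
  } else {
    eta <- n_match / K
    full <- which(n_match == K)
  }
  out <- list(eta = eta, neighborhood = full)
  class(out) <- "similarity_vector"
  out
}

#' @export
print.similarity_vector <- function(x, ...) {
  cat("<similarity_vector> J=", length(x$eta),
      ", neighborhood size=", length(x$neighborhood), "\n", sep = "")
  invisible(x)
}
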