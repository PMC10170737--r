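#' @keywords internal
"_PACKAGE"

# Code-set fields (comorbidities, comedication, living conditions, adverse
# events) travel through CSV as semicolon-separated opaque tokens. Codes are
# case-sensitive; the empty string is the empty set.

#' Split a semicolon-separated code list into a character vector
#'
#' @param x character scalar (possibly `NA` or `""`)
#' @return character vector of codes (length 0 for the empty set)
#' @export
split_codes <- function(x) {
  if (length(x) != 1L) stop("split_codes() expects a single string", call. = FALSE)
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Join a character vector of codes into a semicolon-separated list
#'
#' @param x character vector of codes
#' @return character scalar
#' @export
join_codes <- function(x) {
  if (length(x) == 0) return("")
  paste(x, collapse = ";")
}

#' Default antihypertensive treatment class vocabulary
#'
#' The five main first-line antihypertensive substance groups. The vocabulary
#' is configurable everywhere it is consumed; this is the default ordering
#' used for matrices and one-hot encodings.
#'
#' @return character vector of treatment class codes
#' @export
treatment_vocabulary <- function() {
  c("ACE_INHIBITOR", "ARB", "BETA_BLOCKER", "CALCIUM_CHANNEL_BLOCKER",
    "DIURETIC")
}

# sentinel for "no antihypertensive prescribed at this visit"
NO_TREATMENT <- "NONE"

is_treated <- function(treatment) {
  !is.na(treatment) & nzchar(treatment) & treatment != NO_TREATMENT
}

#' Whole-year age at a reference date
#'
#' Floor of elapsed whole years between date of birth and a reference date.
#'
#' @param date_of_birth,at `Date` vectors
#' @return integer vector of ages in completed years
#' @export
age_at <- function(date_of_birth, at) {
  if (any(is.na(date_of_birth)) || any(is.na(at)))
    stop("age_at(): missing dates", call. = FALSE)
  as.integer(floor(as.numeric(difftime(at, date_of_birth, units = "days")) / 365.25))
}

#' Has the blood-pressure treatment endpoint been reached?
#'
#' Hypertension is defined as systolic pressure above 140 mmHg and/or
#' diastolic pressure above 90 mmHg, so a reading of exactly 140/90 counts as
#' at target: the bound is closed (`<=`) by default. Vectorized.
#'
#' @param bp_sys,bp_dia blood pressure readings in mmHg (positive)
#' @param bound numeric length-2 vector `c(sys, dia)` defining the endpoint
#' @param closed logical; if `FALSE` use a strict `<` bound instead
#' @return logical vector
#' @examples
#' endpoint_reached(141, 89) # FALSE
#' endpoint_reached(140, 90) # TRUE
#' @export
endpoint_reached <- function(bp_sys, bp_dia, bound = c(140, 90), closed = TRUE) {
  if (any(is.na(bp_sys)) || any(is.na(bp_dia)))
    stop("endpoint_reached(): missing blood pressure reading", call. = FALSE)
  if (any(bp_sys <= 0) || any(bp_dia <= 0))
    stop("endpoint_reached(): blood pressure readings must be positive", call. = FALSE)
  if (closed) bp_sys <= bound[1] & bp_dia <= bound[2]
  else        bp_sys <  bound[1] & bp_dia <  bound[2]
}

validate_visit_sequence <- function(visits) {
  if (nrow(visits) == 0) stop("empty visit sequence", call. = FALSE)
  if (length(unique(visits$patient_id)) != 1L)
    stop("visit sequence spans multiple patients", call. = FALSE)
  d <- as.Date(visits$visit_date)
  if (is.unsorted(d, strictly = TRUE))
    stop("visits must be strictly ordered by date", call. = FALSE)
  if (is_treated(visits$treatment[1]))
    stop("baseline visit (index 0) must be untreated", call. = FALSE)
  bad <- !is.na(visits$bp_sys) & !is.na(visits$bp_dia) &
    !(visits$bp_sys > visits$bp_dia & visits$bp_dia > 0)
  if (any(bad))
    stop("invalid blood pressure reading (need sys > dia > 0)", call. = FALSE)
  invisible(visits)
}

#' Extract a patient's initial-treatment episode
#'
#' From one patient's date-ordered visit sequence (untreated baseline first),
#' finds the first visit with a prescribed antihypertensive and follows the
#' maximal contiguous run of visits sharing that treatment. A treatment
#' switch truncates the episode; only the initial treatment yields a data
#' point, so outcomes can be attributed to a single drug class without
#' wash-out modeling. The outcome compares the baseline reading with the
#' reading at the last visit of the episode (`delta = last - baseline`;
#' negative values are improvements), and collects the union of adverse
#' events observed during the episode.
#'
#' @param visits data frame of one patient's visits, ordered by `visit_date`,
#'   with columns `patient_id`, `visit_date`, `bp_sys`, `bp_dia`, `treatment`,
#'   `adverse_events` (semicolon code list)
#' @return a one-row data frame with columns `patient_id`, `treatment`,
#'   `delta_sys`, `delta_dia`, `endpoint_reached`, `adverse_events`, and
#'   `first_treated_index` (1-based row index into `visits`), or `NULL` when
#'   the patient has no treated visit or the episode lacks a usable
#'   blood-pressure reading
#' @export
extract_training_point <- function(visits) {
  validate_visit_sequence(visits)
  treated <- which(is_treated(visits$treatment))
  if (length(treated) == 0) return(NULL)
  first <- treated[1]
  tx <- visits$treatment[first]
  last <- first
  while (last + 1L <= nrow(visits) &&
         is_treated(visits$treatment[last + 1L]) &&
         visits$treatment[last + 1L] == tx) {
    last <- last + 1L
  }
  base_sys <- visits$bp_sys[1]; base_dia <- visits$bp_dia[1]
  end_sys <- visits$bp_sys[last]; end_dia <- visits$bp_dia[last]
  if (is.na(base_sys) || is.na(base_dia) || is.na(end_sys) || is.na(end_dia))
    return(NULL)
  events <- unique(unlist(lapply(visits$adverse_events[first:last], split_codes)))
  data.frame(
    patient_id = visits$patient_id[1],
    treatment = tx,
    delta_sys = end_sys - base_sys,
    delta_dia = end_dia - base_dia,
    endpoint_reached = endpoint_reached(end_sys, end_dia),
    adverse_events = join_codes(events),
    first_treated_index = first,
    stringsAsFactors = FALSE
  )
}

#' Build the training database of initial-treatment episodes
#'
#' Assembles at most one training point per patient: the initial-treatment
#' episode extracted by [extract_training_point()], joined with the
#' similarity features in effect at the episode's first treated visit (age in
#' completed years from date of birth; BMI recomputed from height and weight
#' when both are present, else taken as recorded) and the clinical context
#' (comorbidities, living conditions, comedication) recorded at that visit.
#'
#' @param patients data frame with columns `patient_id`, `gender`,
#'   `date_of_birth`
#' @param visits data frame of visits (all patients) with the columns
#'   documented in [read_visits()]
#' @return a `training_db` data frame, one row per usable patient, with
#'   columns `patient_id`, `gender`, `age`, `bmi`, `comorbidities`,
#'   `living_conditions`, `comedication`, `treatment`, `delta_sys`,
#'   `delta_dia`, `endpoint_reached`, `adverse_events`
#' @export
build_training_db <- function(patients, visits) {
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patient table", call. = FALSE)
  if (!all(visits$patient_id %in% patients$patient_id))
    stop("visit references unknown patient_id", call. = FALSE)
  visits$visit_date <- as.Date(visits$visit_date)
  patients$date_of_birth <- as.Date(patients$date_of_birth)

  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    pv <- visits[visits$patient_id == pid, , drop = FALSE]
    if (nrow(pv) == 0) return(NULL)
    pv <- pv[order(pv$visit_date), , drop = FALSE]
    if (any(pv$visit_date <= patients$date_of_birth[i]))
      stop("visit before date of birth for patient ", pid, call. = FALSE)
    tp <- extract_training_point(pv)
    if (is.null(tp)) return(NULL)
    at <- tp$first_treated_index
    h <- pv$height_cm[at]; w <- pv$weight_kg[at]
    bmi <- if (!is.na(h) && !is.na(w) && h > 0) w / (h / 100)^2 else pv$bmi[at]
    data.frame(
      patient_id = pid,
      gender = patients$gender[i],
      age = age_at(patients$date_of_birth[i], pv$visit_date[at]),
      bmi = bmi,
      comorbidities = pv$comorbidities[at],
      living_conditions = pv$living_conditions[at],
      comedication = pv$comedication[at],
      treatment = tp$treatment,
      delta_sys = tp$delta_sys,
      delta_dia = tp$delta_dia,
      endpoint_reached = tp$endpoint_reached,
      adverse_events = tp$adverse_events,
      stringsAsFactors = FALSE
    )
  })
  db <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(db)) {
    db <- data.frame(
      patient_id = character(0), gender = character(0), age = integer(0),
      bmi = numeric(0), comorbidities = character(0),
      living_conditions = character(0), comedication = character(0),
      treatment = character(0), delta_sys = numeric(0), delta_dia = numeric(0),
      endpoint_reached = logical(0), adverse_events = character(0),
      stringsAsFactors = FALSE
    )
  }
  class(db) <- c("training_db", "data.frame")
  db
}

#' @export
print.training_db <- function(x, ...) {
  cat("<training_db> ", nrow(x), " initial-treatment episodes\n", sep = "")
  if (nrow(x) > 0) {
    tab <- table(x$treatment)
    cat("  treatments: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
    cat("  endpoint reached: ", sum(x$endpoint_reached), "/", nrow(x),
        "\n", sep = "")
  }
  invisible(x)
}
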