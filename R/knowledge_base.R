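# Evidence-based contraindication rule engine: structured rule records,
# patient-conditional retrieval, option labeling and post-filtering.

RULE_LEVELS <- c("relative", "absolute")
TRIGGER_TYPES <- c("comorbidity", "condition", "comedication")
RULE_FIELDS <- c("rule_id", "treatment", "trigger_type", "trigger_code",
                 "level", "description", "source_type", "source_name",
                 "source_date")

validate_rules <- function(rules) {
  missing_cols <- setdiff(RULE_FIELDS, names(rules))
  if (length(missing_cols) > 0)
    stop("rule base missing field(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    empty <- vapply(RULE_FIELDS, function(f) is.na(r[[f]]) || !nzchar(r[[f]]),
                    logical(1))
    if (any(empty))
      stop("rule '", r$rule_id, "': empty field(s): ",
           paste(RULE_FIELDS[empty], collapse = ", "), call. = FALSE)
    if (!r$level %in% RULE_LEVELS)
      stop("rule '", r$rule_id, "': unknown contraindication level '",
           r$level, "'", call. = FALSE)
    if (!r$trigger_type %in% TRIGGER_TYPES)
      stop("rule '", r$rule_id, "': unknown trigger type '", r$trigger_type,
           "'", call. = FALSE)
  }
  dup <- rules$rule_id[duplicated(rules$rule_id)]
  if (length(dup) > 0)
    stop("duplicate rule_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  class(rules) <- c("rule_base", "data.frame")
  rules
}

#' Load a contraindication rule base from a JSON file
#'
#' One record per rule with the fields `rule_id`, `treatment`,
#' `trigger_type` (`comorbidity` / `condition` / `comedication`),
#' `trigger_code` (matched against the corresponding patient context set),
#' `level` (`absolute` / `relative`), `description`, `source_type`
#' (`professional_information` / `clinical_guideline`), `source_name`,
#' `source_date`. The record schema ships at
#' `system.file("schema", "contraindication-rule.schema.json", package = "htnrec")`.
#' Malformed records and duplicate rule ids are rejected with an error naming
#' the offending record.
#'
#' @param path path to a JSON array of rule records
#' @return a validated `rule_base` data frame
#' @export
load_rules <- function(path) {
  rules <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(rules) || nrow(rules) == 0)
    stop("rule base must be a non-empty JSON array of rule records",
         call. = FALSE)
  validate_rules(rules)
}

#' The synthetic demonstration rule base
#'
#' A small, SYNTHETIC set of contraindication rules used for tests, the
#' benchmark and examples. The rules mimic the structure of real
#' professional-information and guideline content but their clinical content
#' is illustrative only — do not use for clinical decisions. The same rules
#' ship as JSON at
#' `system.file("extdata", "demo_rules_synthetic.json", package = "htnrec")`.
#'
#' @return a `rule_base` data frame
#' @export
demo_rules <- function() {
  rules <- data.frame(
    rule_id = c("R1", "R2", "R3", "R4", "R5", "R6"),
    treatment = c("ARB", "ACE_INHIBITOR", "ACE_INHIBITOR", "BETA_BLOCKER",
                  "DIURETIC", "BETA_BLOCKER"),
    trigger_type = c("condition", "comorbidity", "condition", "comorbidity",
                     "comorbidity", "comedication"),
    trigger_code = c("PREGNANCY", "ANGIOEDEMA_HISTORY", "PREGNANCY",
                     "ASTHMA", "GOUT", "VERAPAMIL"),
    level = c("absolute", "absolute", "absolute", "relative", "relative",
              "absolute"),
    description = c(
      "Angiotensin receptor blockers must not be used in pregnancy",
      "History of angioedema under ACE inhibition",
      "ACE inhibitors must not be used in pregnancy",
      "Beta blockade may aggravate bronchial obstruction",
      "Thiazide diuretics may precipitate gout attacks",
      "Combined beta blockade and verapamil risks AV block"),
    source_type = c("clinical_guideline", "professional_information",
                    "clinical_guideline", "professional_information",
                    "professional_information", "professional_information"),
    source_name = rep("synthetic demo source", 6),
    source_date = rep("2020-01-01", 6),
    stringsAsFactors = FALSE
  )
  validate_rules(rules)
}

#' Build a patient context for rule retrieval
#'
#' @param comorbidities,conditions,comedication character vectors of codes
#'   (comorbidity diagnoses, life-situation conditions such as pregnancy, and
#'   concomitant medication); each may be empty
#' @return a `patient_context` list
#' @export
patient_context <- function(comorbidities = character(0),
                            conditions = character(0),
                            comedication = character(0)) {
  ctx <- list(
    comorbidity = as.character(comorbidities %||% character(0)),
    condition = as.character(conditions %||% character(0)),
    comedication = as.character(comedication %||% character(0))
  )
  class(ctx) <- "patient_context"
  ctx
}

#' Retrieve the rules applicable to a patient context
#'
#' A rule matches when its `trigger_code` is contained in the patient context
#' set named by its `trigger_type`. Matches are grouped per treatment; a
#' treatment's effective contraindication level is the most severe level
#' among its matched rules (absolute > relative), with all matched evidence
#' retained for display.
#'
#' @param ctx a [patient_context()]
#' @param rules a `rule_base`
#' @return list with `matches` (data frame of matched rules) and `levels`
#'   (named character vector: effective level per affected treatment)
#' @export
applicable_rules <- function(ctx, rules) {
  hit <- vapply(seq_len(nrow(rules)), function(i) {
    rules$trigger_code[i] %in% ctx[[rules$trigger_type[i]]]
  }, logical(1))
  matches <- rules[hit, , drop = FALSE]
  levels <- character(0)
  if (nrow(matches) > 0) {
    levels <- vapply(split(matches$level, matches$treatment), function(lv) {
      RULE_LEVELS[max(match(lv, RULE_LEVELS))]
    }, character(1))
  }
  list(matches = matches, levels = levels)
}

#' Label ranked options with contraindications and optionally post-filter
#'
#' Every option is labeled with its effective contraindication level
#' (`"none"`, `"relative"`, `"absolute"`). With `level = "absolute"` the
#' absolutely contraindicated options are removed; with
#' `level = "absolute_relative"` relatively contraindicated ones are removed
#' too. Filtering happens on the full ranked list, i.e. before top-N
#' truncation, and surviving ranks are reassigned consecutively; scores and
#' the relative order of survivors are never altered.
#'
#' @param options ranked options data frame from [rank_top_n()]
#' @param matches result of [applicable_rules()], or `NULL` for no rule base
#' @param level `"off"`, `"absolute"` or `"absolute_relative"`
#' @return the options data frame with a `contraindication` column, filtered
#'   per `level`, ranks reassigned
#' @export
label_and_filter <- function(options, matches,
                             level = c("off", "absolute", "absolute_relative")) {
  level <- match.arg(level)
  labels <- rep("none", nrow(options))
  if (!is.null(matches) && length(matches$levels) > 0) {
    idx <- match(options$treatment, names(matches$levels))
    labels[!is.na(idx)] <- matches$levels[idx[!is.na(idx)]]
  }
  options$contraindication <- labels
  keep <- switch(level,
    off = rep(TRUE, nrow(options)),
    absolute = labels != "absolute",
    absolute_relative = labels == "none"
  )
  out <- options[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
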