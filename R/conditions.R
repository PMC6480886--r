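#' Conditions listed on the pre-operative questionnaire
#'
#' The pre-operative PROMs instrument asks patients whether a doctor has ever
#' told them that they have any of twelve chronic conditions. Arthritis is on
#' the questionnaire but is excluded from agreement analyses by default
#' because it is the indication for joint arthroplasty itself.
#'
#' @param include_arthritis Keep arthritis in the returned set (default
#'   `TRUE`; analyses typically drop it via their own `exclude` argument).
#' @return A tibble with columns `condition` (machine-readable identifier
#'   used as a column name throughout the package) and `label` (display
#'   name).
#' @examples
#' proms_conditions()
#' @export
proms_conditions <- function(include_arthritis = TRUE) {
  out <- tibble::tribble(
    ~condition,             ~label,
    "heart_disease",        "Heart disease",
    "high_blood_pressure",  "High blood pressure",
    "stroke",               "Stroke",
    "leg_pain_circulation", "Leg pain due to poor circulation",
    "lung_disease",         "Lung disease",
    "diabetes",             "Diabetes",
    "kidney_disease",       "Kidney disease",
    "nervous_system",       "Diseases of the nervous system",
    "liver_disease",        "Liver disease",
    "cancer",               "Cancer",
    "depression",           "Depression",
    "arthritis",            "Arthritis"
  )
  if (!include_arthritis) out <- out[out$condition != "arthritis", ]
  out
}

# Non-condition key columns of the questionnaire schema.
QUESTIONNAIRE_KEYS <- c("row_id", "patient_id", "procedure_link_id", "completion_day")

# Condition columns of a questionnaire-shaped table: everything that is not a
# key column. Keeps the package usable with arbitrary condition subsets.
condition_cols <- function(questionnaire) {
  setdiff(names(questionnaire), QUESTIONNAIRE_KEYS)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

diag_cols <- function() sprintf("diag_%02d", 1:20)
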