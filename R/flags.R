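#' Look-back window specification
#'
#' Defines which admissions count towards the administrative reference
#' standard: the index admission itself (when `include_index`) plus any
#' admission dated within `window_days` before the index day. The early
#' boundary is closed (an admission exactly `window_days` before the index
#' counts) and non-index admissions on the index day itself also count;
#' admissions after the index never do, because the reference standard is
#' pre-operative status.
#'
#' @param window_days Positive integer; 365 for a 12-month look-back
#'   (default) and 1826 for five years.
#' @param include_index Include the index admission's own codes (default
#'   `TRUE`).
#' @return A `lookback_spec` list.
#' @export
lookback_spec <- function(window_days = 365L, include_index = TRUE) {
  if (length(window_days) != 1 || is.na(window_days) || window_days < 1 ||
      window_days != floor(window_days)) {
    stop("window_days must be a positive integer", call. = FALSE)
  }
  structure(list(window_days = as.integer(window_days),
                 include_index = isTRUE(include_index)),
            class = "lookback_spec")
}

# Long table of (patient_id, code) pairs for admissions inside the look-back
# window. One row per distinct patient-code pair.
inwindow_codes <- function(cohort, spec) {
  cohort <- as_cohort(cohort)
  adm <- cohort$admissions
  idx <- adm[which(adm$is_index_procedure), c("patient_id", "admission_day")]
  if (anyDuplicated(idx$patient_id) > 0) {
    stop("contract violation: cohort has a patient with multiple index admissions",
         call. = FALSE)
  }
  missing_idx <- setdiff(cohort$questionnaire$patient_id, idx$patient_id)
  if (length(missing_idx) > 0) {
    stop("contract violation: cohort patient(s) without an index admission: ",
         paste(utils::head(missing_idx, 5), collapse = ", "), call. = FALSE)
  }
  names(idx)[2] <- "index_day"

  a <- dplyr::inner_join(adm, idx, by = "patient_id")
  in_window <- (a$is_index_procedure & spec$include_index) |
    (!a$is_index_procedure &
       a$admission_day >= a$index_day - spec$window_days &
       a$admission_day <= a$index_day)
  a <- a[in_window, c("patient_id", diag_cols())]
  long <- tidyr::pivot_longer(a, cols = dplyr::all_of(diag_cols()),
                              values_to = "code", values_drop_na = TRUE)
  dplyr::distinct(long[, c("patient_id", "code")])
}

#' Derive administrative disease flags over a look-back window
#'
#' For every cohort patient and mapped condition, the flag is true iff any
#' diagnosis code on an in-window admission (see [lookback_spec()]) matches
#' the condition's code set under the prefix semantics of [match_code()].
#' Diagnosis position (primary vs 20th) is irrelevant.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param map A [code_map()].
#' @param spec A [lookback_spec()].
#' @param conditions Conditions to flag (default: all conditions in the map).
#' @return An `admin_flags` tibble: `patient_id` plus one logical column per
#'   condition, with the look-back spec attached as attribute `lookback`.
#' @export
derive_admin_flags <- function(cohort, map, spec = lookback_spec(),
                               conditions = NULL) {
  cohort <- as_cohort(cohort)
  if (is.null(conditions)) conditions <- map_conditions(map)
  long <- inwindow_codes(cohort, spec)
  patients <- unique(cohort$questionnaire$patient_id)
  flags <- tibble::tibble(patient_id = patients)
  for (cond in conditions) {
    hit <- unique(long$patient_id[match_code(map, cond, long$code)])
    flags[[cond]] <- patients %in% hit
  }
  structure(flags, lookback = spec, class = c("admin_flags", class(flags)))
}

#' Prevalence of administrative flags
#'
#' @param flags An `admin_flags` table (or any table of `patient_id` plus
#'   logical condition columns).
#' @return Tibble with `condition`, `n` (patients flagged) and `pct`
#'   (percentage of the cohort).
#' @export
flag_prevalence <- function(flags) {
  if (nrow(flags) == 0) stop("empty flag table", call. = FALSE)
  conds <- setdiff(names(flags), "patient_id")
  tibble::tibble(
    condition = conds,
    n = vapply(flags[conds], sum, integer(1), USE.NAMES = FALSE),
    pct = 100 * vapply(flags[conds], mean, numeric(1), USE.NAMES = FALSE)
  )
}
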