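# Backward coding: two-stage, data-driven augmentation of a condition's
# ICD-10 code set, driven by patients who report the condition but carry no
# mapped code in their look-back window.

reporters_of <- function(cohort, condition) {
  q <- cohort$questionnaire
  check_columns(q, c("patient_id", condition), "questionnaire table")
  q$patient_id[q[[condition]]]
}

#' Reporters with no mapped administrative record
#'
#' Patients who answered "yes" to a condition but whose admissions within
#' the look-back window carry no code currently mapped to it. These are the
#' patients whose records seed backward coding.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param map A [code_map()].
#' @param condition Condition identifier.
#' @param spec A [lookback_spec()].
#' @return Character vector of patient ids.
#' @export
find_unexplained_reporters <- function(cohort, map, condition,
                                       spec = lookback_spec()) {
  cohort <- as_cohort(cohort)
  flags <- derive_admin_flags(cohort, map, spec, conditions = condition)
  reporters <- reporters_of(cohort, condition)
  explained <- flags$patient_id[flags[[condition]]]
  setdiff(reporters, explained)
}

#' Screen three-character categories for backward coding
#'
#' First stage: among the in-window admissions of unexplained reporters,
#' find ICD-10 three-character categories that (a) lie in the condition's
#' allowed chapters — the reproducible proxy for "clinically relevant" —
#' (b) occur in strictly more than `min_fraction` of all condition
#' reporters, and (c) are not already mapped at the category level.
#'
#' @inheritParams find_unexplained_reporters
#' @param chapters Allowed ICD-10 chapter letters; defaults to the map's
#'   per-condition chapter allowlist.
#' @param min_fraction Strict frequency threshold over reporters (default
#'   0.01, i.e. "> 1%").
#' @return Tibble with `category`, `n_reporters_with_category`,
#'   `n_reporters` and `fraction`, one row per retained category.
#' @export
screen_three_char <- function(cohort, map, condition, chapters = NULL,
                              min_fraction = 0.01, spec = lookback_spec()) {
  cohort <- as_cohort(cohort)
  if (is.null(chapters)) chapters <- chapters_for(map, condition)
  if (length(chapters) == 0) {
    stop("configuration error: empty chapter allowlist for condition ", condition,
         call. = FALSE)
  }
  reporters <- reporters_of(cohort, condition)
  if (length(reporters) == 0) {
    return(tibble::tibble(category = character(0),
                          n_reporters_with_category = integer(0),
                          n_reporters = integer(0), fraction = numeric(0)))
  }
  unexplained <- find_unexplained_reporters(cohort, map, condition, spec)
  long <- inwindow_codes(cohort, spec)
  long$category <- substr(long$code, 1L, 3L)

  candidates <- unique(long$category[long$patient_id %in% unexplained])
  candidates <- candidates[substr(candidates, 1L, 1L) %in% chapters]
  mapped3 <- codes_for(map, condition)$code
  candidates <- setdiff(candidates, mapped3[nchar(mapped3) == 3L])
  if (length(candidates) == 0) {
    return(tibble::tibble(category = character(0),
                          n_reporters_with_category = integer(0),
                          n_reporters = integer(0), fraction = numeric(0)))
  }

  rep_long <- dplyr::distinct(
    long[long$patient_id %in% reporters & long$category %in% candidates,
         c("patient_id", "category")]
  )
  counts <- dplyr::count(rep_long, .data$category, name = "n_with")
  out <- tibble::tibble(
    category = counts$category,
    n_reporters_with_category = counts$n_with,
    n_reporters = length(reporters),
    fraction = counts$n_with / length(reporters)
  )
  out <- out[out$fraction > min_fraction, ]
  out[order(out$category), ]
}

#' Evaluate four-character codes under a screened category
#'
#' Second stage: for every four-character code observed in the data under a
#' screened three-character category, compare its prevalence (at least one
#' in-window admission carrying the code) between condition reporters and
#' non-reporters. The code is accepted when the reporter prevalence is at
#' least `ratio_threshold` times the non-reporter prevalence; a ratio of
#' exactly the threshold is accepted ("at least twice"), and a code absent
#' among non-reporters but present among reporters has infinite ratio and
#' is accepted (flagged in `zero_nonreporter`).
#'
#' @inheritParams find_unexplained_reporters
#' @param category A screened three-character category.
#' @param ratio_threshold Acceptance threshold on the prevalence ratio
#'   (default 2).
#' @return Tibble of candidates: `condition`, `category`, `code`, reporter
#'   and non-reporter counts and denominators, `prevalence_ratio`,
#'   `accepted`, `zero_nonreporter`.
#' @export
evaluate_four_char <- function(cohort, map, condition, category,
                               ratio_threshold = 2, spec = lookback_spec()) {
  cohort <- as_cohort(cohort)
  patients <- unique(cohort$questionnaire$patient_id)
  reporters <- reporters_of(cohort, condition)
  nonreporters <- setdiff(patients, reporters)
  if (length(reporters) == 0 || length(nonreporters) == 0) {
    stop(sprintf(
      "cannot evaluate backward-coding candidates for %s: zero %s",
      condition,
      if (length(reporters) == 0) "reporters" else "non-reporters"
    ), call. = FALSE)
  }
  long <- inwindow_codes(cohort, spec)
  under <- long[substr(long$code, 1L, 3L) == category & nchar(long$code) == 4L, ]
  codes <- sort(unique(under$code))
  if (length(codes) == 0) {
    return(tibble::tibble(
      condition = character(0), category = character(0), code = character(0),
      n_reporters_with_code = integer(0), n_reporters = integer(0),
      n_nonreporters_with_code = integer(0), n_nonreporters = integer(0),
      prevalence_ratio = numeric(0), accepted = logical(0),
      zero_nonreporter = logical(0)
    ))
  }
  n_rep_with <- vapply(codes, function(cd) {
    length(unique(under$patient_id[under$code == cd & under$patient_id %in% reporters]))
  }, integer(1), USE.NAMES = FALSE)
  n_non_with <- vapply(codes, function(cd) {
    length(unique(under$patient_id[under$code == cd & under$patient_id %in% nonreporters]))
  }, integer(1), USE.NAMES = FALSE)
  p_rep <- n_rep_with / length(reporters)
  p_non <- n_non_with / length(nonreporters)
  ratio <- ifelse(p_non == 0, ifelse(p_rep > 0, Inf, NaN), p_rep / p_non)
  tibble::tibble(
    condition = condition,
    category = category,
    code = codes,
    n_reporters_with_code = n_rep_with,
    n_reporters = length(reporters),
    n_nonreporters_with_code = n_non_with,
    n_nonreporters = length(nonreporters),
    prevalence_ratio = ratio,
    accepted = !is.nan(ratio) & ratio >= ratio_threshold,
    zero_nonreporter = p_non == 0
  )
}

#' Backward-code a condition map against a cohort
#'
#' Runs the full two-stage augmentation for one or more conditions:
#' [find_unexplained_reporters()], [screen_three_char()] over the allowed
#' chapters, [evaluate_four_char()] per screened category, and addition of
#' the accepted codes to the map with provenance `"backward-coded"`. Codes
#' are only ever added, never removed, and conditions are processed
#' independently (a code may belong to several conditions).
#'
#' @inheritParams find_unexplained_reporters
#' @param conditions Conditions to augment (default: every condition that
#'   has a chapter allowlist in the map).
#' @param min_fraction,ratio_threshold Stage thresholds (see
#'   [screen_three_char()] and [evaluate_four_char()]).
#' @return List with `map` (augmented [code_map()]) and `audit` (tibble of
#'   every evaluated candidate, accepted or not).
#' @export
backward_code <- function(cohort, map, conditions = NULL,
                          spec = lookback_spec(), min_fraction = 0.01,
                          ratio_threshold = 2) {
  cohort <- as_cohort(cohort)
  if (is.null(conditions)) {
    chapters <- attr(map, "chapters")
    conditions <- intersect(map_conditions(map), names(chapters))
    conditions <- intersect(conditions, condition_cols(cohort$questionnaire))
  }
  audit <- purrr::map_dfr(conditions, function(cond) {
    unexplained <- find_unexplained_reporters(cohort, map, cond, spec)
    if (length(unexplained) == 0) return(NULL)
    screened <- screen_three_char(cohort, map, cond, min_fraction = min_fraction,
                                  spec = spec)
    purrr::map_dfr(screened$category, function(cat) {
      evaluate_four_char(cohort, map, cond, cat,
                         ratio_threshold = ratio_threshold, spec = spec)
    })
  })
  if (nrow(audit) == 0) {
    audit <- tibble::tibble(
      condition = character(0), category = character(0), code = character(0),
      n_reporters_with_code = integer(0), n_reporters = integer(0),
      n_nonreporters_with_code = integer(0), n_nonreporters = integer(0),
      prevalence_ratio = numeric(0), accepted = logical(0),
      zero_nonreporter = logical(0)
    )
    return(list(map = map, audit = audit))
  }
  added <- audit[audit$accepted, c("condition", "code")]
  existing <- tibble::as_tibble(map)[, c("condition", "code", "subcategory", "provenance")]
  new_rows <- dplyr::anti_join(added, existing, by = c("condition", "code"))
  if (nrow(new_rows) > 0) {
    new_rows$subcategory <- NA_character_
    new_rows$provenance <- "backward-coded"
    augmented <- code_map(dplyr::bind_rows(existing, new_rows),
                          chapters = attr(map, "chapters"))
  } else {
    augmented <- map
  }
  list(map = augmented, audit = audit)
}
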