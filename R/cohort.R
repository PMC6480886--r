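#' Exclusion accounting for cohort construction
#'
#' One row of bookkeeping for the record-flow of [build_cohort()]: how many
#' linked questionnaire records came in, how many were removed by each
#' exclusion rule, and how many remain. The constructor enforces the
#' conservation identity
#' `n_final = n_input - n_duplicate_questionnaires - n_duplicate_procedures -
#' n_subsequent_procedures - n_high_count_responders`.
#'
#' @param n_input Linked questionnaire records before exclusions.
#' @param n_duplicate_questionnaires Removed because more than one
#'   questionnaire was linked to one procedure.
#' @param n_duplicate_procedures Removed because more than one index
#'   procedure was linked to one questionnaire.
#' @param n_subsequent_procedures Removed because they were linked to a
#'   procedure later than the patient's first.
#' @param n_high_count_responders Removed for reporting at or above the
#'   comorbidity-count threshold.
#' @param n_final Remaining records; if omitted it is computed, if supplied
#'   it is checked against the identity.
#' @return A one-row tibble of class `exclusion_report`.
#' @examples
#' exclusion_report(791369, 10762, 140, 103395, 644, 676428)
#' @export
exclusion_report <- function(n_input,
                             n_duplicate_questionnaires = 0,
                             n_duplicate_procedures = 0,
                             n_subsequent_procedures = 0,
                             n_high_count_responders = 0,
                             n_final = NULL) {
  counts <- c(n_input, n_duplicate_questionnaires, n_duplicate_procedures,
              n_subsequent_procedures, n_high_count_responders)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("exclusion counts must be non-negative integers", call. = FALSE)
  }
  implied <- n_input - n_duplicate_questionnaires - n_duplicate_procedures -
    n_subsequent_procedures - n_high_count_responders
  if (is.null(n_final)) {
    n_final <- implied
  } else if (n_final != implied) {
    stop(sprintf(
      "exclusion report does not balance: n_input %d minus exclusions gives %d, not %d",
      n_input, implied, n_final
    ), call. = FALSE)
  }
  if (n_final < 0) stop("exclusions exceed the number of input records", call. = FALSE)
  out <- tibble::tibble(
    n_input = as.integer(n_input),
    n_duplicate_questionnaires = as.integer(n_duplicate_questionnaires),
    n_duplicate_procedures = as.integer(n_duplicate_procedures),
    n_subsequent_procedures = as.integer(n_subsequent_procedures),
    n_high_count_responders = as.integer(n_high_count_responders),
    n_final = as.integer(n_final)
  )
  class(out) <- c("exclusion_report", class(out))
  out
}

#' Remove duplicate questionnaire-procedure links
#'
#' Applies the two duplicate rules of study-sample construction: a
#' procedure linked to more than one questionnaire, and a questionnaire
#' linked to more than one index procedure. In the default `"drop-all"`
#' mode every row of an offending group is removed (no keep-rule is
#' defensible when the duplicates are indistinguishable); `"keep-first"`
#' keeps the first row by id and is provided for sensitivity checks.
#'
#' @param questionnaire,admissions Tables in the fixture schema (see
#'   [simulate_cohort()]).
#' @param mode `"drop-all"` (default) or `"keep-first"`.
#' @return List with the reduced `questionnaire` and `admissions`, and
#'   counts `n_duplicate_questionnaires` and `n_duplicate_procedures`
#'   (questionnaire rows removed by each rule).
#' @export
drop_duplicates <- function(questionnaire, admissions,
                            mode = c("drop-all", "keep-first")) {
  mode <- match.arg(mode)
  check_columns(questionnaire, QUESTIONNAIRE_KEYS, "questionnaire table")
  check_columns(admissions,
                c("admission_id", "patient_id", "procedure_link_id",
                  "admission_day", "is_index_procedure"),
                "admissions table")

  # rule 1: >1 questionnaire linked to one procedure
  q <- questionnaire[order(questionnaire$row_id), ]
  grp_n <- table(q$procedure_link_id)
  dup_links <- names(grp_n)[grp_n > 1]
  in_dup <- q$procedure_link_id %in% dup_links
  if (mode == "keep-first") {
    keep_first <- !duplicated(q$procedure_link_id)
    drop_q <- in_dup & !keep_first
  } else {
    drop_q <- in_dup
  }
  n_dup_q <- sum(drop_q)
  q <- q[!drop_q, ]

  # rule 2: >1 index procedure linked to one questionnaire (same link id)
  idx <- admissions[which(admissions$is_index_procedure), ]
  idx <- idx[order(idx$admission_id), ]
  idx_n <- table(idx$procedure_link_id)
  dup_proc_links <- names(idx_n)[idx_n > 1]
  if (mode == "keep-first") {
    extra <- idx$procedure_link_id %in% dup_proc_links &
      duplicated(idx$procedure_link_id)
    admissions <- admissions[!admissions$admission_id %in% idx$admission_id[extra], ]
    drop_q2 <- rep(FALSE, nrow(q))
  } else {
    admissions <- admissions[
      !(admissions$is_index_procedure %in% TRUE &
          admissions$procedure_link_id %in% dup_proc_links), ]
    drop_q2 <- q$procedure_link_id %in% dup_proc_links
  }
  n_dup_p <- sum(drop_q2)
  q <- q[!drop_q2, ]

  list(
    questionnaire = q,
    admissions = admissions,
    n_duplicate_questionnaires = n_dup_q,
    n_duplicate_procedures = n_dup_p
  )
}

#' Keep each patient's first index procedure
#'
#' Among a patient's index admissions, keeps the one with the smallest
#' admission day (ties broken by admission id) and removes the later ones.
#' Non-index (history) admissions are untouched.
#'
#' @param admissions Admissions table.
#' @return List with the reduced `admissions`, the number of index
#'   admissions removed (`n_removed`), and the link ids of the removed
#'   procedures (`removed_links`).
#' @export
keep_first_procedure <- function(admissions) {
  check_columns(admissions, c("admission_id", "patient_id", "admission_day",
                              "is_index_procedure"), "admissions table")
  idx <- admissions[which(admissions$is_index_procedure), ]
  idx <- idx[order(idx$patient_id, idx$admission_day, idx$admission_id), ]
  later <- duplicated(idx$patient_id)
  removed <- idx[later, ]
  list(
    admissions = admissions[!admissions$admission_id %in% removed$admission_id, ],
    n_removed = nrow(removed),
    removed_links = removed$procedure_link_id
  )
}

#' Exclude high-count responders
#'
#' Removes questionnaire rows reporting at least `threshold` of the listed
#' conditions; such response patterns were judged unreliable (patients
#' appearing to mark absence rather than presence).
#'
#' @param questionnaire Questionnaire table.
#' @param threshold Inclusive count threshold (default 7: "seven or more").
#' @param conditions Conditions counted towards the threshold; defaults to
#'   every condition column present (including arthritis).
#' @return List with the reduced `questionnaire` and `n_removed`.
#' @export
exclude_high_count <- function(questionnaire, threshold = 7L, conditions = NULL) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 1) {
    stop("configuration error: threshold must be a positive integer", call. = FALSE)
  }
  if (is.null(conditions)) conditions <- condition_cols(questionnaire)
  check_columns(questionnaire, conditions, "questionnaire table")
  n_yes <- rowSums(as.matrix(questionnaire[, conditions, drop = FALSE]))
  drop <- n_yes >= threshold
  list(questionnaire = questionnaire[!drop, ], n_removed = sum(drop))
}

#' Build the analysis cohort
#'
#' Applies the study-sample rules in a fixed, documented order — duplicate
#' removal, then first-procedure selection, then high-count exclusion — and
#' returns the cohort with a conserving [exclusion_report()]. The order
#' matters for the attribution of a row to an exclusion category, so it is
#' part of the contract.
#'
#' @inheritParams drop_duplicates
#' @inheritParams exclude_high_count
#' @param dedup Duplicate-handling mode, passed to [drop_duplicates()].
#' @return A `cohort` object: list with `questionnaire` (one row per
#'   retained linked record), `admissions` (the retained patients' index
#'   and history admissions), and `exclusions` (an [exclusion_report()]).
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 200, seed = 3,
#'                                   conditions = c("diabetes", "stroke")))
#' coh <- build_cohort(sim$questionnaire, sim$admissions)
#' coh$exclusions
#' @export
build_cohort <- function(questionnaire, admissions, threshold = 7L,
                         dedup = c("drop-all", "keep-first"),
                         conditions = NULL) {
  dedup <- match.arg(dedup)
  n_input <- nrow(questionnaire)

  step1 <- drop_duplicates(questionnaire, admissions, mode = dedup)
  q <- step1$questionnaire
  a <- step1$admissions

  step2 <- keep_first_procedure(a)
  a <- step2$admissions
  kept_links <- a$procedure_link_id[which(a$is_index_procedure)]
  orphan <- !q$procedure_link_id %in% kept_links
  unmatched <- orphan & !q$procedure_link_id %in% step2$removed_links
  if (any(unmatched)) {
    warning(sprintf(
      "%d questionnaire row(s) have no linked index admission and were excluded",
      sum(unmatched)
    ), call. = FALSE)
  }
  n_subsequent <- sum(orphan)
  q <- q[!orphan, ]

  step3 <- exclude_high_count(q, threshold = threshold, conditions = conditions)
  q <- step3$questionnaire

  a <- a[a$patient_id %in% q$patient_id, ]
  report <- exclusion_report(
    n_input = n_input,
    n_duplicate_questionnaires = step1$n_duplicate_questionnaires,
    n_duplicate_procedures = step1$n_duplicate_procedures,
    n_subsequent_procedures = n_subsequent,
    n_high_count_responders = step3$n_removed,
    n_final = nrow(q)
  )
  structure(
    list(questionnaire = q, admissions = a, exclusions = report,
         threshold = threshold, dedup = dedup),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (from %d linked records)\n",
              x$exclusions$n_final, x$exclusions$n_input))
  print(x$exclusions)
  invisible(x)
}

as_cohort <- function(x) {
  if (inherits(x, "cohort")) return(x)
  if (is.list(x) && all(c("questionnaire", "admissions") %in% names(x))) {
    return(build_cohort(x$questionnaire, x$admissions))
  }
  stop("expected a cohort (see build_cohort())", call. = FALSE)
}
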