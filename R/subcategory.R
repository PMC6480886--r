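#' Sensitivity of patient report against administrative subcategories
#'
#' Splits each condition's code set by its subcategory labels (codes
#' without a label fall into `"other"`) and, for each subcategory, computes
#' the sensitivity of the patient report among patients flagged positive
#' through any code of that subcategory within the look-back window.
#' Subcategories are overlapping patient sets, not a partition: a patient
#' carrying codes from two subcategories contributes to both denominators.
#'
#' @param cohort A `cohort` from [build_cohort()].
#' @param map A [code_map()] carrying subcategory labels.
#' @param spec A [lookback_spec()].
#' @param conditions Conditions to analyse (default: all mapped conditions
#'   present on the questionnaire).
#' @param exclude Conditions to drop (default `"arthritis"`).
#' @param ci_level,ci_method Interval settings as in [sens_spec()].
#' @return A `subcategory_sensitivity` tibble: `condition`, `subcategory`,
#'   `n_admin_positive`, `n_also_reported`, `sensitivity`, `ci_low`,
#'   `ci_high`.
#' @export
subcategory_sensitivity <- function(cohort, map, spec = lookback_spec(),
                                    conditions = NULL, exclude = "arthritis",
                                    ci_level = 0.95,
                                    ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  cohort <- as_cohort(cohort)
  if (is.null(conditions)) {
    conditions <- intersect(map_conditions(map),
                            condition_cols(cohort$questionnaire))
  }
  conditions <- setdiff(conditions, exclude)
  long <- inwindow_codes(cohort, spec)
  q <- cohort$questionnaire

  out <- purrr::map_dfr(conditions, function(cond) {
    rows <- codes_for(map, cond)
    rows$subcategory[is.na(rows$subcategory)] <- "other"
    if (all(rows$subcategory == "other")) {
      warning("condition ", cond,
              " has no labelled codes; only an 'other' row is produced",
              call. = FALSE)
    }
    reporters <- q$patient_id[q[[cond]]]
    purrr::map_dfr(sort(unique(rows$subcategory)), function(sub) {
      sub_map <- code_map(rows[rows$subcategory == sub, c("condition", "code")])
      pos <- unique(long$patient_id[match_code(sub_map, cond, long$code)])
      n_pos <- length(pos)
      n_rep <- length(intersect(pos, reporters))
      est <- if (n_pos > 0) n_rep / n_pos else NA_real_
      ci <- if (n_pos > 0) prop_ci(n_rep, n_pos, ci_level, ci_method) else
        list(lower = NA_real_, upper = NA_real_)
      tibble::tibble(
        condition = cond, subcategory = sub,
        n_admin_positive = n_pos, n_also_reported = n_rep,
        sensitivity = est, ci_low = ci$lower, ci_high = ci$upper
      )
    })
  })
  structure(out, lookback = spec, ci_level = ci_level, ci_method = ci_method,
            class = c("subcategory_sensitivity", class(out)))
}

#' Forest-plot-ready table of subcategory sensitivities
#'
#' Orders results by condition then subcategory and exposes
#' `estimate`/`lower`/`upper` columns (fractions truncated to `[0, 1]`)
#' suitable for any plotting layer.
#'
#' @param results A `subcategory_sensitivity` tibble.
#' @return Tibble with `condition`, `subcategory`, `n`, `estimate`,
#'   `lower`, `upper`.
#' @export
forest_table <- function(results) {
  check_columns(results, c("condition", "subcategory", "n_admin_positive",
                           "sensitivity", "ci_low", "ci_high"),
                "subcategory results")
  if (nrow(results) == 0) stop("no subcategory results to tabulate", call. = FALSE)
  out <- tibble::tibble(
    condition = results$condition,
    subcategory = results$subcategory,
    n = results$n_admin_positive,
    estimate = results$sensitivity,
    lower = pmax(0, results$ci_low),
    upper = pmin(1, results$ci_high)
  )
  out[order(out$condition, out$subcategory), ]
}

#' Forest plot of subcategory sensitivities
#'
#' @param object A `subcategory_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subcategory_sensitivity <- function(object, ...) {
  tab <- forest_table(object)
  tab$row <- factor(paste(tab$condition, tab$subcategory, sep = ": "),
                    levels = rev(paste(tab$condition, tab$subcategory, sep = ": ")))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$row)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2
    ) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Sensitivity of patient report (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
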