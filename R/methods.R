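#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an agreement table into one row per statistic
#'
#' @param x A `disease_agreement` tibble from [agreement()] or
#'   [agreement_from_counts()].
#' @param ... Unused.
#' @return Tibble with `condition`, `statistic` (sensitivity, specificity,
#'   kappa), `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.disease_agreement <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(condition = x$condition, statistic = "sensitivity",
                   estimate = x$sensitivity,
                   conf.low = x$sens_low, conf.high = x$sens_high),
    tibble::tibble(condition = x$condition, statistic = "specificity",
                   estimate = x$specificity,
                   conf.low = x$spec_low, conf.high = x$spec_high),
    tibble::tibble(condition = x$condition, statistic = "kappa",
                   estimate = x$kappa,
                   conf.low = x$kappa_low, conf.high = x$kappa_high)
  ) |>
    dplyr::arrange(.data$condition, .data$statistic)
}

#' One-row summary of an agreement analysis
#'
#' @inheritParams tidy.disease_agreement
#' @return Tibble with the cohort size, number of conditions, CI settings
#'   and the kappa range.
#' @export
glance.disease_agreement <- function(x, ...) {
  tibble::tibble(
    n = if (nrow(x) > 0) max(x$n) else NA_integer_,
    n_conditions = nrow(x),
    ci_level = attr(x, "ci_level"),
    ci_method = attr(x, "ci_method"),
    min_kappa = if (nrow(x) > 0) min(x$kappa, na.rm = TRUE) else NA_real_,
    max_kappa = if (nrow(x) > 0) max(x$kappa, na.rm = TRUE) else NA_real_
  )
}

#' Plot agreement statistics per condition
#'
#' Point estimates with confidence intervals, one panel per statistic.
#'
#' @param object A `disease_agreement` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disease_agreement <- function(object, ...) {
  long <- tidy(object)
  long$condition <- factor(long$condition, levels = rev(sort(unique(long$condition))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy subcategory sensitivities
#'
#' @param x A `subcategory_sensitivity` tibble.
#' @param ... Unused.
#' @return Tibble with `condition`, `subcategory`, `estimate`, `conf.low`,
#'   `conf.high`, `n`.
#' @export
tidy.subcategory_sensitivity <- function(x, ...) {
  tab <- forest_table(x)
  tibble::tibble(
    condition = tab$condition, subcategory = tab$subcategory,
    estimate = tab$estimate, conf.low = tab$lower, conf.high = tab$upper,
    n = tab$n
  )
}
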