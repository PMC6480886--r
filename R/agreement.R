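#' Cross-tabulate patient report against administrative flags
#'
#' Produces the four agreement counts for one condition: both sources
#' positive, administrative only, patient-reported only, neither. The two
#' tables must cover the same patients.
#'
#' @param responses Table with `patient_id` and one logical column per
#'   condition (e.g. a cohort questionnaire).
#' @param flags An `admin_flags` table from [derive_admin_flags()].
#' @param condition Condition to tabulate.
#' @return One-row tibble with columns `condition`, `both`, `admin_only`,
#'   `patient_only`, `neither`.
#' @export
crosstab <- function(responses, flags, condition) {
  check_columns(responses, c("patient_id", condition), "responses table")
  check_columns(flags, c("patient_id", condition), "flags table")
  only_r <- setdiff(responses$patient_id, flags$patient_id)
  only_f <- setdiff(flags$patient_id, responses$patient_id)
  if (length(only_r) > 0 || length(only_f) > 0) {
    stop(sprintf(
      "patient sets differ between responses and flags (e.g. %s)",
      paste(utils::head(c(only_r, only_f), 5), collapse = ", ")
    ), call. = FALSE)
  }
  p <- responses[[condition]][match(flags$patient_id, responses$patient_id)]
  a <- flags[[condition]]
  tibble::tibble(
    condition = condition,
    both = sum(p & a),
    admin_only = sum(!p & a),
    patient_only = sum(p & !a),
    neither = sum(!p & !a)
  )
}

check_cells <- function(table) {
  check_columns(table, c("both", "admin_only", "patient_only", "neither"),
                "agreement table")
  cells <- as.matrix(table[, c("both", "admin_only", "patient_only", "neither")])
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("agreement cell counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(cells) <= 0)) {
    stop("agreement table has zero total count", call. = FALSE)
  }
  invisible(table)
}

# Binomial interval for x successes out of n, truncated to [0, 1].
prop_ci <- function(x, n, level, method) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else { # wilson
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  list(lower = pmax(0, lo), upper = pmin(1, hi))
}

#' Sensitivity and specificity of patient report
#'
#' With the administrative flag as the reference standard, sensitivity is
#' `both / (both + admin_only)` and specificity is
#' `neither / (neither + patient_only)`. Intervals are normal-approximation
#' (Wald) by default — the convention matched by published validation
#' tables at this scale — with Wilson available via `method`. A zero
#' denominator yields `NA` estimates with a reason in the `note` column
#' rather than an error.
#'
#' @param table Data frame with columns `both`, `admin_only`,
#'   `patient_only`, `neither` (one row per condition; a `condition` column
#'   is carried through if present).
#' @param ci_level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Tibble with sensitivity and specificity estimates and bounds
#'   (fractions in `[0, 1]`).
#' @examples
#' sens_spec(data.frame(both = 68952, admin_only = 9864,
#'                      patient_only = 7046, neither = 590566))
#' @export
sens_spec <- function(table, ci_level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  check_cells(table)
  n_sens <- table$both + table$admin_only
  n_spec <- table$neither + table$patient_only
  sens <- ifelse(n_sens > 0, table$both / n_sens, NA_real_)
  spec <- ifelse(n_spec > 0, table$neither / n_spec, NA_real_)
  ci_sens <- prop_ci(table$both, pmax(n_sens, 1), ci_level, method)
  ci_spec <- prop_ci(table$neither, pmax(n_spec, 1), ci_level, method)
  note <- dplyr::case_when(
    n_sens == 0 & n_spec == 0 ~ "no administrative positives or negatives",
    n_sens == 0 ~ "undefined sensitivity: no administrative positives",
    n_spec == 0 ~ "undefined specificity: no administrative negatives",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(
    sensitivity = sens,
    sens_low = ifelse(n_sens > 0, ci_sens$lower, NA_real_),
    sens_high = ifelse(n_sens > 0, ci_sens$upper, NA_real_),
    specificity = spec,
    spec_low = ifelse(n_spec > 0, ci_spec$lower, NA_real_),
    spec_high = ifelse(n_spec > 0, ci_spec$upper, NA_real_),
    note = note
  )
  if ("condition" %in% names(table)) {
    out <- dplyr::bind_cols(tibble::tibble(condition = table$condition), out)
  }
  out
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` where `po` is the
#' observed agreement proportion and `pe` the agreement expected from the
#' marginal prevalences. The confidence interval uses the
#' Fleiss-Cohen-Everitt large-sample standard error, truncated to
#' `[-1, 1]`. Degenerate marginals (`pe = 1`) yield `NA` with a reason in
#' `note`.
#'
#' @inheritParams sens_spec
#' @return Tibble with `kappa`, `kappa_low`, `kappa_high`, `note` (and
#'   `condition` if present in the input).
#' @examples
#' cohens_kappa(data.frame(both = 68952, admin_only = 9864,
#'                         patient_only = 7046, neither = 590566))
#' @export
cohens_kappa <- function(table, ci_level = 0.95) {
  check_cells(table)
  n <- table$both + table$admin_only + table$patient_only + table$neither
  # rows: patient report; columns: administrative flag
  p11 <- table$both / n
  p12 <- table$patient_only / n
  p21 <- table$admin_only / n
  p22 <- table$neither / n
  pr1 <- p11 + p12   # patient yes
  pr2 <- p21 + p22
  pc1 <- p11 + p21   # admin yes
  pc2 <- p12 + p22
  po <- p11 + p22
  pe <- pr1 * pc1 + pr2 * pc2

  degenerate <- abs(1 - pe) < .Machine$double.eps * 4
  kappa <- ifelse(degenerate, NA_real_, (po - pe) / (1 - pe))

  # Fleiss, Cohen & Everitt large-sample variance
  a_term <- p11 * ((1 - pe) - (pc1 + pr1) * (1 - po))^2 +
    p22 * ((1 - pe) - (pc2 + pr2) * (1 - po))^2
  b_term <- (1 - po)^2 * (p12 * (pc1 + pr2)^2 + p21 * (pc2 + pr1)^2)
  c_term <- (po * pe - 2 * pe + po)^2
  var_k <- (a_term + b_term - c_term) / (n * (1 - pe)^4)
  var_k <- pmax(var_k, 0)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lo <- pmax(-1, kappa - z * sqrt(var_k))
  hi <- pmin(1, kappa + z * sqrt(var_k))

  out <- tibble::tibble(
    kappa = kappa,
    kappa_low = ifelse(degenerate, NA_real_, lo),
    kappa_high = ifelse(degenerate, NA_real_, hi),
    note = ifelse(degenerate,
                  "undefined kappa: degenerate marginals (expected agreement 1)",
                  NA_character_)
  )
  if ("condition" %in% names(table)) {
    out <- dplyr::bind_cols(tibble::tibble(condition = table$condition), out)
  }
  out
}

#' Qualitative agreement band for a kappa value
#'
#' Conventional cut-points: below 0.40 "poor agreement", 0.40-0.60
#' "moderate agreement", above 0.60 up to 0.80 "substantial agreement",
#' above 0.80 "near perfect agreement". The printed convention leaves
#' (0.60, 0.61) unassigned; this implementation assigns the whole of
#' (0.60, 0.80] to the substantial band. Negative values are "poor
#' agreement".
#'
#' @param kappa Numeric vector in `[-1, 1]` (NAs pass through).
#' @return Character vector of band labels.
#' @examples
#' kappa_band(c(0.88, 0.54, 0.25))
#' @export
kappa_band <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 | kappa > 1))) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    kappa < 0.40 ~ "poor agreement",
    kappa <= 0.60 ~ "moderate agreement",
    kappa <= 0.80 ~ "substantial agreement",
    TRUE ~ "near perfect agreement"
  )
}

agreement_from_cells <- function(cells, ci_level, ci_method) {
  check_cells(cells)
  n <- cells$both + cells$admin_only + cells$patient_only + cells$neither
  ss <- sens_spec(cells, ci_level = ci_level, method = ci_method)
  kk <- cohens_kappa(cells, ci_level = ci_level)
  out <- tibble::tibble(
    condition = if ("condition" %in% names(cells)) cells$condition else NA_character_,
    both = cells$both,
    admin_only = cells$admin_only,
    patient_only = cells$patient_only,
    neither = cells$neither,
    n = n,
    patient_n = cells$both + cells$patient_only,
    admin_n = cells$both + cells$admin_only,
    either_n = n - cells$neither
  )
  out$patient_pct <- 100 * out$patient_n / n
  out$admin_pct <- 100 * out$admin_n / n
  out$either_pct <- 100 * out$either_n / n
  out$sensitivity <- ss$sensitivity
  out$sens_low <- ss$sens_low
  out$sens_high <- ss$sens_high
  out$specificity <- ss$specificity
  out$spec_low <- ss$spec_low
  out$spec_high <- ss$spec_high
  out$kappa <- kk$kappa
  out$kappa_low <- kk$kappa_low
  out$kappa_high <- kk$kappa_high
  out$kappa_band <- kappa_band(out$kappa)
  note <- dplyr::coalesce(ss$note, kk$note)
  if (!all(is.na(note))) out$note <- note
  structure(out,
            ci_level = ci_level, ci_method = ci_method,
            class = c("disease_agreement", class(out)))
}

#' Agreement statistics for every condition
#'
#' Runs [crosstab()], [sens_spec()], [cohens_kappa()] and [kappa_band()]
#' per condition, with the administrative flag as the reference standard.
#' Arthritis is excluded by default because it is the indication for the
#' index procedure itself.
#'
#' @param responses Table with `patient_id` and one logical column per
#'   condition (e.g. `cohort$questionnaire`).
#' @param flags An `admin_flags` table covering the same patients.
#' @param conditions Conditions to analyse; defaults to the condition
#'   columns shared by both tables.
#' @param exclude Conditions to drop (default `"arthritis"`).
#' @inheritParams sens_spec
#' @param ci_method `"wald"` (default) or `"wilson"` for the proportion CIs.
#' @return A `disease_agreement` tibble: one row per condition with the
#'   four cells, prevalences, sensitivity, specificity and kappa with
#'   confidence bounds, and the qualitative kappa band. Proportions are
#'   kept at full precision; use [format()] or [generics::tidy()] for
#'   display.
#' @export
agreement <- function(responses, flags, conditions = NULL,
                      exclude = "arthritis", ci_level = 0.95,
                      ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (is.null(conditions)) {
    conditions <- intersect(condition_cols(responses),
                            setdiff(names(flags), "patient_id"))
  }
  conditions <- setdiff(conditions, exclude)
  if (length(conditions) == 0) {
    return(agreement_from_counts(
      tibble::tibble(condition = character(0), both = integer(0),
                     admin_only = integer(0), patient_only = integer(0),
                     neither = integer(0)),
      ci_level = ci_level, ci_method = ci_method
    ))
  }
  cells <- purrr::map_dfr(conditions, function(cond) crosstab(responses, flags, cond))
  agreement_from_cells(cells, ci_level, ci_method)
}

#' Agreement statistics directly from 2x2 counts
#'
#' Computes the full statistics table from pre-tabulated agreement counts —
#' e.g. the cell counts printed in a published validation table — without
#' any patient-level data.
#'
#' @param counts Data frame with columns `condition`, `both`, `admin_only`,
#'   `patient_only`, `neither`.
#' @inheritParams agreement
#' @return A `disease_agreement` tibble (see [agreement()]).
#' @examples
#' agreement_from_counts(data.frame(
#'   condition = "diabetes",
#'   both = 68952, admin_only = 9864, patient_only = 7046, neither = 590566
#' ))
#' @export
agreement_from_counts <- function(counts, ci_level = 0.95,
                                  ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  check_columns(counts, c("condition", "both", "admin_only", "patient_only", "neither"),
                "counts table")
  counts <- tibble::as_tibble(counts)
  if (nrow(counts) == 0) {
    out <- tibble::tibble(
      condition = character(0), both = integer(0), admin_only = integer(0),
      patient_only = integer(0), neither = integer(0), n = integer(0),
      patient_n = integer(0), admin_n = integer(0), either_n = integer(0),
      patient_pct = numeric(0), admin_pct = numeric(0), either_pct = numeric(0),
      sensitivity = numeric(0), sens_low = numeric(0), sens_high = numeric(0),
      specificity = numeric(0), spec_low = numeric(0), spec_high = numeric(0),
      kappa = numeric(0), kappa_low = numeric(0), kappa_high = numeric(0),
      kappa_band = character(0)
    )
    return(structure(out, ci_level = ci_level, ci_method = ci_method,
                     class = c("disease_agreement", class(out))))
  }
  agreement_from_cells(counts, ci_level, ci_method)
}

#' Read pre-tabulated agreement counts from CSV
#'
#' Expects columns `condition`, `both`, `admin_only`, `patient_only`,
#' `neither`; counts must be non-negative integers.
#'
#' @param path CSV file path.
#' @return Tibble of validated counts (possibly zero rows).
#' @export
read_counts <- function(path) {
  counts <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      condition = readr::col_character(),
      both = readr::col_double(),
      admin_only = readr::col_double(),
      patient_only = readr::col_double(),
      neither = readr::col_double()
    )
  )
  check_columns(counts, c("condition", "both", "admin_only", "patient_only", "neither"),
                "counts file")
  cells <- as.matrix(counts[, c("both", "admin_only", "patient_only", "neither")])
  if (nrow(counts) > 0 &&
      (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts
}

#' Display formatting for an agreement table
#'
#' Percentages to one decimal place and kappa to two, the customary
#' precision of published validation tables; the underlying tibble keeps
#' full precision.
#'
#' @param x A `disease_agreement` tibble.
#' @param ... Unused.
#' @return A tibble of formatted character columns.
#' @export
format.disease_agreement <- function(x, ...) {
  pct <- function(p) sprintf("%.1f", 100 * p)
  ci <- function(lo, hi) sprintf("(%.1f, %.1f)", 100 * lo, 100 * hi)
  tibble::tibble(
    condition = x$condition,
    patient_reported = sprintf("%d (%.1f%%)", x$patient_n, x$patient_pct),
    administrative = sprintf("%d (%.1f%%)", x$admin_n, x$admin_pct),
    sensitivity = pct(x$sensitivity),
    sensitivity_ci = ci(x$sens_low, x$sens_high),
    specificity = pct(x$specificity),
    specificity_ci = ci(x$spec_low, x$spec_high),
    kappa = sprintf("%.2f", x$kappa),
    kappa_ci = sprintf("(%.2f, %.2f)", x$kappa_low, x$kappa_high),
    band = x$kappa_band
  )
}
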