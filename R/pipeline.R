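#' Run the full self-report validation pipeline
#'
#' Orchestrates the end-to-end analysis: build the cohort (deduplication,
#' first-procedure selection, high-count exclusion), optionally augment the
#' code map by backward coding, derive administrative flags at one or more
#' look-back windows, and compute agreement and subcategory-sensitivity
#' tables per window.
#'
#' @param questionnaire,admissions Input tables in the fixture schema (see
#'   [simulate_cohort()] / [read_cohort()]).
#' @param map A [code_map()] (default [default_code_map()]).
#' @param lookbacks Integer vector of look-back windows in days (default
#'   `c(365, 1826)`: 12 months and five years).
#' @param backward Run backward coding before flag derivation (default
#'   `TRUE`).
#' @param backward_lookback Window (days) used for backward-coding
#'   prevalences (default 365).
#' @param threshold High-count exclusion threshold (default 7).
#' @param dedup Duplicate handling, `"drop-all"` or `"keep-first"`.
#' @param exclude Conditions excluded from agreement analyses (default
#'   `"arthritis"`).
#' @param ci_level,ci_method Interval settings as in [sens_spec()].
#' @return A `validation_run` list: `cohort`, `exclusions`, `map`
#'   (augmented), `audit` (backward-coding candidates), `flags`,
#'   `agreement` and `subcategory` (each a list named `lookback_<days>`),
#'   and `config` (an echo of the run parameters).
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 300, seed = 9,
#'                                   conditions = c("diabetes", "stroke")))
#' run <- run_pipeline(sim$questionnaire, sim$admissions,
#'                     lookbacks = 365, backward = FALSE)
#' run$agreement$lookback_365
#' @export
run_pipeline <- function(questionnaire, admissions, map = default_code_map(),
                         lookbacks = c(365L, 1826L), backward = TRUE,
                         backward_lookback = 365L, threshold = 7L,
                         dedup = c("drop-all", "keep-first"),
                         exclude = "arthritis", ci_level = 0.95,
                         ci_method = c("wald", "wilson")) {
  dedup <- match.arg(dedup)
  ci_method <- match.arg(ci_method)
  if (length(lookbacks) < 1) {
    stop("configuration error: at least one look-back window is required",
         call. = FALSE)
  }

  cohort <- build_cohort(questionnaire, admissions, threshold = threshold,
                         dedup = dedup)

  audit <- NULL
  if (backward) {
    bc <- backward_code(cohort, map, spec = lookback_spec(backward_lookback))
    map <- bc$map
    audit <- bc$audit
  }

  flags <- agreement_tbls <- subcats <- list()
  for (days in lookbacks) {
    key <- paste0("lookback_", days)
    spec <- lookback_spec(days)
    fl <- derive_admin_flags(cohort, map, spec)
    flags[[key]] <- fl
    agreement_tbls[[key]] <- agreement(
      cohort$questionnaire, fl, exclude = exclude,
      ci_level = ci_level, ci_method = ci_method
    )
    subcats[[key]] <- subcategory_sensitivity(
      cohort, map, spec, exclude = exclude,
      ci_level = ci_level, ci_method = ci_method
    )
  }

  structure(list(
    cohort = cohort,
    exclusions = cohort$exclusions,
    map = map,
    audit = audit,
    flags = flags,
    agreement = agreement_tbls,
    subcategory = subcats,
    config = list(
      lookbacks = as.integer(lookbacks), backward = backward,
      backward_lookback = as.integer(backward_lookback),
      threshold = as.integer(threshold), dedup = dedup, exclude = exclude,
      ci_level = ci_level, ci_method = ci_method,
      package_version = as.character(utils::packageVersion("chronicagree"))
    )
  ), class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf(
    "<validation_run> %d patients, look-backs: %s days\n",
    x$exclusions$n_final, paste(x$config$lookbacks, collapse = ", ")
  ))
  for (key in names(x$agreement)) {
    cat("\n--", key, "--\n")
    print(format(x$agreement[[key]]))
  }
  invisible(x)
}

#' @rdname glance.disease_agreement
#' @export
glance.validation_run <- function(x, ...) {
  tibble::tibble(
    n_input = x$exclusions$n_input,
    n_final = x$exclusions$n_final,
    n_conditions = nrow(x$agreement[[1]]),
    n_lookbacks = length(x$config$lookbacks),
    n_backward_coded = if (is.null(x$audit)) 0L else sum(x$audit$accepted)
  )
}

#' Write a validation run to disk with a reproducibility manifest
#'
#' Writes, per look-back window, the agreement table (full precision CSV),
#' the flag table and the subcategory sensitivities; plus the exclusion
#' report (JSON), the backward-coding audit (CSV), the final code map
#' (JSON) and `manifest.json` listing every file with its MD5 checksum
#' together with the run configuration.
#'
#' @param run A `validation_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  files <- character(0)

  for (key in names(run$agreement)) {
    p <- file.path(dir, paste0("agreement_", key, ".csv"))
    readr::write_csv(tibble::as_tibble(run$agreement[[key]]), p, na = "")
    files <- c(files, p)
    fl <- run$flags[[key]]
    fl_out <- fl
    conds <- setdiff(names(fl_out), "patient_id")
    fl_out[conds] <- lapply(fl_out[conds], as.integer)
    p <- file.path(dir, paste0("flags_", key, ".csv"))
    readr::write_csv(tibble::as_tibble(fl_out), p, na = "")
    files <- c(files, p)
    p <- file.path(dir, paste0("subcategory_", key, ".csv"))
    readr::write_csv(tibble::as_tibble(run$subcategory[[key]]), p, na = "")
    files <- c(files, p)
  }
  p <- file.path(dir, "exclusions.json")
  jsonlite::write_json(as.list(run$exclusions), p, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, p)
  if (!is.null(run$audit)) {
    p <- file.path(dir, "backward_coding_audit.csv")
    readr::write_csv(run$audit, p, na = "")
    files <- c(files, p)
  }
  p <- file.path(dir, "codemap.json")
  write_code_map(run$map, p)
  files <- c(files, p)

  manifest <- list(
    config = run$config,
    codemap_checksum = unname(tools::md5sum(file.path(dir, "codemap.json"))),
    files = stats::setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
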