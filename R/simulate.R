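#' Configuration for the synthetic linked-cohort generator
#'
#' Describes a population of arthroplasty patients with latent (true)
#' chronic-disease status, a pre-operative questionnaire whose answers are a
#' noisy report of that status, and a hospital admission history whose
#' diagnosis codes are a noisy per-admission recording of it. The defaults
#' emulate the situation the package is designed for: per-condition true
#' prevalences close to the administrative prevalences observed in English
#' arthroplasty patients, reporting probabilities in the range observed for
#' self-report, and duplicate/repeat/high-count rates matching the orders of
#' magnitude seen in national PROMs-HES linkage.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the generator is byte-for-byte deterministic
#'   given the full configuration.
#' @param conditions Character vector of condition identifiers (default: the
#'   twelve questionnaire conditions, see [proms_conditions()]).
#' @param true_prevalence,report_sensitivity,report_specificity Per-condition
#'   probabilities (named vector, or a scalar recycled to all conditions).
#'   `report_sensitivity` is P(patient answers yes | truly has the disease).
#' @param code_sensitivity_per_admission P(an admission of a diseased patient
#'   carries a mapped code for the condition); independent across admissions.
#' @param code_false_positive_per_admission P(an admission of a disease-free
#'   patient carries a mapped code).
#' @param admissions_per_patient_mean Poisson mean of the number of prior
#'   (non-index) admissions per patient.
#' @param history_span_days Prior admissions are dated uniformly within this
#'   many days before the index admission.
#' @param duplicate_questionnaire_rate Fraction of patients whose
#'   questionnaire row is duplicated (an exact copy with a new row id linked
#'   to the same procedure).
#' @param repeat_procedure_rate Fraction of patients who have a second, later
#'   index procedure with its own linked questionnaire.
#' @param high_count_responder_rate Fraction of patients who tick exactly 8
#'   conditions "yes" regardless of their true status (the exclusion target
#'   of [exclude_high_count()]).
#' @return A `sim_config` object (validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 10000,
                       seed = 1L,
                       conditions = proms_conditions()$condition,
                       true_prevalence = NULL,
                       report_sensitivity = NULL,
                       report_specificity = NULL,
                       code_sensitivity_per_admission = 0.7,
                       code_false_positive_per_admission = 0.002,
                       admissions_per_patient_mean = 1.5,
                       history_span_days = 1826L,
                       duplicate_questionnaire_rate = 0.014,
                       repeat_procedure_rate = 0.13,
                       high_count_responder_rate = 0.0008) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1 ||
      n_patients != as.integer(n_patients)) {
    stop("configuration error: n_patients must be a positive integer", call. = FALSE)
  }
  if (length(conditions) < 1 || anyDuplicated(conditions) > 0) {
    stop("configuration error: conditions must be a non-empty set of unique names",
         call. = FALSE)
  }

  defaults <- list(
    true_prevalence = c(
      heart_disease = 0.18, high_blood_pressure = 0.50, stroke = 0.011,
      leg_pain_circulation = 0.016, lung_disease = 0.148, diabetes = 0.117,
      kidney_disease = 0.054, nervous_system = 0.029, liver_disease = 0.006,
      cancer = 0.019, depression = 0.044, arthritis = 0.81
    ),
    report_sensitivity = c(
      heart_disease = 0.46, high_blood_pressure = 0.74, stroke = 0.32,
      leg_pain_circulation = 0.26, lung_disease = 0.47, diabetes = 0.875,
      kidney_disease = 0.19, nervous_system = 0.21, liver_disease = 0.34,
      cancer = 0.69, depression = 0.61, arthritis = 0.95
    ),
    report_specificity = c(
      heart_disease = 0.98, high_blood_pressure = 0.90, stroke = 0.99,
      leg_pain_circulation = 0.93, lung_disease = 0.985, diabetes = 0.99,
      kidney_disease = 0.99, nervous_system = 0.997, liver_disease = 0.997,
      cancer = 0.965, depression = 0.93, arthritis = 0.70
    )
  )

  per_condition <- function(value, field) {
    if (is.null(value)) {
      value <- defaults[[field]]
      if (!all(conditions %in% names(value))) {
        stop(sprintf(
          "configuration error: no default %s for condition(s) %s; supply it explicitly",
          field, paste(setdiff(conditions, names(value)), collapse = ", ")
        ), call. = FALSE)
      }
      value <- value[conditions]
    } else if (length(value) == 1 && is.null(names(value))) {
      value <- stats::setNames(rep(as.numeric(value), length(conditions)), conditions)
    } else {
      if (!setequal(names(value), conditions)) {
        stop(sprintf(
          "configuration error: %s must be named for exactly the configured conditions",
          field
        ), call. = FALSE)
      }
      value <- as.numeric(value[conditions])
      names(value) <- conditions
    }
    if (any(is.na(value)) || any(value < 0) || any(value > 1)) {
      stop(sprintf("configuration error: %s must be probabilities in [0, 1]", field),
           call. = FALSE)
    }
    value
  }

  check_prob <- function(value, field) {
    if (length(value) != 1 || is.na(value) || value < 0 || value > 1) {
      stop(sprintf("configuration error: %s must be a probability in [0, 1]", field),
           call. = FALSE)
    }
    as.numeric(value)
  }
  if (length(admissions_per_patient_mean) != 1 || is.na(admissions_per_patient_mean) ||
      admissions_per_patient_mean < 0) {
    stop("configuration error: admissions_per_patient_mean must be non-negative",
         call. = FALSE)
  }
  if (length(history_span_days) != 1 || is.na(history_span_days) || history_span_days < 1) {
    stop("configuration error: history_span_days must be a positive integer", call. = FALSE)
  }

  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    conditions = as.character(conditions),
    true_prevalence = per_condition(true_prevalence, "true_prevalence"),
    report_sensitivity = per_condition(report_sensitivity, "report_sensitivity"),
    report_specificity = per_condition(report_specificity, "report_specificity"),
    code_sensitivity_per_admission =
      per_condition(code_sensitivity_per_admission, "code_sensitivity_per_admission"),
    code_false_positive_per_admission =
      per_condition(code_false_positive_per_admission, "code_false_positive_per_admission"),
    admissions_per_patient_mean = as.numeric(admissions_per_patient_mean),
    history_span_days = as.integer(history_span_days),
    duplicate_questionnaire_rate =
      check_prob(duplicate_questionnaire_rate, "duplicate_questionnaire_rate"),
    repeat_procedure_rate = check_prob(repeat_procedure_rate, "repeat_procedure_rate"),
    high_count_responder_rate =
      check_prob(high_count_responder_rate, "high_count_responder_rate")
  ), class = "sim_config")
}

# Draw a concrete (four-character where possible) diagnosis code for a
# condition: a random seed code of the condition, with three-character seeds
# refined by a random final digit so the data exercise prefix matching.
draw_codes <- function(seed_codes, n) {
  if (n == 0) return(character(0))
  base <- seed_codes[sample.int(length(seed_codes), n, replace = TRUE)]
  short <- nchar(base) == 3L
  base[short] <- paste0(base[short], sample(0:9, sum(short), replace = TRUE))
  base
}

# Benign filler codes; none share a three-character category with the
# default map, so filler never triggers a condition flag there.
FILLER_CODES <- c(
  "Z511", "Z961", "Z966", "R073", "R104", "K590", "N390", "J069",
  "A099", "L031", "S720", "T814", "Z864", "M545", "E780", "D509"
)

#' Simulate a linked questionnaire + admissions dataset with known truth
#'
#' Generates, deterministically given the configuration seed, one completed
#' pre-operative questionnaire per patient linked (via a procedure link id)
#' to an index hospital admission, plus a Poisson number of prior admissions
#' dated uniformly over the configured history span. Each admission carries
#' up to 20 ICD-10 diagnosis codes: per-condition mapped codes drawn with
#' the configured per-admission coding probabilities given the latent true
#' status, plus benign filler codes in random positions. Configured
#' fractions of patients receive an exact duplicate questionnaire row, a
#' second later index procedure (with its own linked questionnaire), or
#' "high-count" answers (exactly 8 conditions ticked regardless of truth).
#'
#' @param config A [sim_config()].
#' @param map A [code_map()] providing the codes to emit per condition; must
#'   cover every configured condition.
#' @return A `sim_cohort` list with elements `questionnaire` (tibble:
#'   `row_id`, `patient_id`, `procedure_link_id`, `completion_day`, one
#'   logical column per condition), `admissions` (tibble: `admission_id`,
#'   `patient_id`, `procedure_link_id`, `admission_day`,
#'   `is_index_procedure`, `diag_01` ... `diag_20`), `truth` (tibble:
#'   `patient_id` plus one logical column per condition) and `config`.
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 42, conditions = c("diabetes", "stroke"))
#' sim <- simulate_cohort(cfg)
#' head(sim$questionnaire)
#' @export
simulate_cohort <- function(config, map = default_code_map()) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created with sim_config()", call. = FALSE)
  }
  missing_map <- setdiff(config$conditions, map_conditions(map))
  if (length(missing_map) > 0) {
    stop("code map lacks configured condition(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  withr::local_seed(config$seed)

  n <- config$n_patients
  conds <- config$conditions
  k <- length(conds)
  patient_id <- sprintf("P%07d", seq_len(n))

  # latent true status
  truth_mat <- matrix(FALSE, n, k, dimnames = list(NULL, conds))
  for (j in seq_len(k)) {
    truth_mat[, j] <- stats::runif(n) < config$true_prevalence[[conds[j]]]
  }

  # index admission day, leaving room for the full look-back history
  index_day <- config$history_span_days + sample.int(730L, n, replace = TRUE)

  # questionnaire answers: noisy report of truth
  resp_mat <- matrix(FALSE, n, k, dimnames = list(NULL, conds))
  for (j in seq_len(k)) {
    tr <- truth_mat[, j]
    u <- stats::runif(n)
    resp_mat[, j] <- ifelse(tr,
                            u < config$report_sensitivity[[conds[j]]],
                            u < 1 - config$report_specificity[[conds[j]]])
  }
  # high-count responders tick exactly 8 conditions (all, if fewer configured)
  hc <- stats::runif(n) < config$high_count_responder_rate
  n_tick <- min(8L, k)
  for (i in which(hc)) {
    ticked <- sample.int(k, n_tick)
    resp_mat[i, ] <- FALSE
    resp_mat[i, ticked] <- TRUE
  }

  # admissions: one index per patient + Poisson prior history (+ repeats below)
  n_prior <- stats::rpois(n, config$admissions_per_patient_mean)
  prior_owner <- rep.int(seq_len(n), n_prior)
  prior_day <- index_day[prior_owner] -
    sample.int(config$history_span_days, length(prior_owner), replace = TRUE)

  repeat_flag <- stats::runif(n) < config$repeat_procedure_rate
  n_rep <- sum(repeat_flag)
  rep_owner <- which(repeat_flag)
  rep_day <- index_day[rep_owner] + sample(30:365, n_rep, replace = TRUE)

  link_id <- sprintf("L%07d", seq_len(n))
  rep_link_id <- sprintf("L%07d", n + seq_len(n_rep))

  adm <- tibble::tibble(
    patient_idx = c(seq_len(n), rep_owner, prior_owner),
    procedure_link_id = c(link_id, rep_link_id, rep(NA_character_, length(prior_owner))),
    admission_day = c(index_day, rep_day, prior_day),
    is_index_procedure = c(rep(TRUE, n + n_rep), rep(FALSE, length(prior_owner)))
  )
  adm <- adm[order(adm$patient_idx, adm$admission_day,
                   !adm$is_index_procedure), ]
  adm$admission_id <- sprintf("A%07d", seq_len(nrow(adm)))
  n_adm <- nrow(adm)

  # per-admission condition coding given the owner's true status
  code_long <- purrr::map_dfr(seq_len(k), function(j) {
    cond <- conds[j]
    tr <- truth_mat[adm$patient_idx, j]
    p <- ifelse(tr,
                config$code_sensitivity_per_admission[[cond]],
                config$code_false_positive_per_admission[[cond]])
    hit <- stats::runif(n_adm) < p
    idx <- which(hit)
    tibble::tibble(
      adm_idx = idx,
      code = draw_codes(codes_for(map, cond)$code, length(idx))
    )
  })
  n_filler <- 1L + stats::rbinom(n_adm, 2L, 0.5)
  filler_long <- tibble::tibble(
    adm_idx = rep.int(seq_len(n_adm), n_filler),
    code = FILLER_CODES[sample.int(length(FILLER_CODES), sum(n_filler), replace = TRUE)]
  )
  long <- dplyr::bind_rows(code_long, filler_long)
  long$slot <- stats::runif(nrow(long))      # random diagnosis positions
  long <- long[order(long$adm_idx, long$slot), c("adm_idx", "code")]
  long <- dplyr::mutate(dplyr::group_by(long, .data$adm_idx),
                        pos = dplyr::row_number())
  long <- dplyr::ungroup(dplyr::filter(long, .data$pos <= 20L))
  long$pos <- sprintf("diag_%02d", long$pos)
  wide <- tidyr::pivot_wider(long, names_from = "pos", values_from = "code")
  missing_diag <- setdiff(diag_cols(), names(wide))
  for (col in missing_diag) wide[[col]] <- NA_character_
  adm$adm_idx <- seq_len(n_adm)
  adm <- dplyr::left_join(adm, wide, by = "adm_idx")

  admissions <- tibble::tibble(
    admission_id = adm$admission_id,
    patient_id = patient_id[adm$patient_idx],
    procedure_link_id = adm$procedure_link_id,
    admission_day = as.integer(adm$admission_day),
    is_index_procedure = adm$is_index_procedure
  )
  for (col in diag_cols()) admissions[[col]] <- adm[[col]]

  # questionnaires: one per index procedure, plus exact duplicates
  questionnaire <- tibble::tibble(
    patient_id = patient_id,
    procedure_link_id = link_id,
    completion_day = as.integer(index_day)
  )
  for (j in seq_len(k)) questionnaire[[conds[j]]] <- resp_mat[, j]
  if (n_rep > 0) {
    rep_q <- tibble::tibble(
      patient_id = patient_id[rep_owner],
      procedure_link_id = rep_link_id,
      completion_day = as.integer(rep_day)
    )
    for (j in seq_len(k)) rep_q[[conds[j]]] <- resp_mat[rep_owner, j]
    questionnaire <- dplyr::bind_rows(questionnaire, rep_q)
  }
  dup <- stats::runif(n) < config$duplicate_questionnaire_rate
  if (any(dup)) {
    questionnaire <- dplyr::bind_rows(questionnaire, questionnaire[which(dup), ])
  }
  questionnaire <- tibble::as_tibble(cbind(
    tibble::tibble(row_id = sprintf("Q%07d", seq_len(nrow(questionnaire)))),
    questionnaire
  ))

  truth <- tibble::tibble(patient_id = patient_id)
  for (j in seq_len(k)) truth[[conds[j]]] <- truth_mat[, j]

  structure(
    list(questionnaire = questionnaire, admissions = admissions,
         truth = truth, config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d patients, %d questionnaire rows, %d admissions, %d conditions\n",
    nrow(x$truth), nrow(x$questionnaire), nrow(x$admissions),
    length(x$config$conditions)
  ))
  invisible(x)
}

#' Write / read a simulated cohort as plain-text fixtures
#'
#' `write_cohort()` writes `questionnaire.csv` and `admissions.csv` (yes/no
#' and index flags as 0/1, empty diagnosis slots as empty fields) and
#' `truth.json` (patient id to condition to true status). `read_cohort()`
#' reads them back; the round trip reproduces the in-memory tables exactly,
#' and regenerating with the same configuration reproduces the files
#' byte-for-byte.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()], or any list with
#'   conforming `questionnaire` and `admissions` tables (plus `truth`).
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns the written paths invisibly;
#'   `read_cohort()` returns a list with `questionnaire`, `admissions` and
#'   (if present on disk) `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  q <- cohort$questionnaire
  conds <- condition_cols(q)
  q[conds] <- lapply(q[conds], as.integer)
  a <- cohort$admissions
  a$is_index_procedure <- as.integer(a$is_index_procedure)
  paths <- c(
    questionnaire = file.path(dir, "questionnaire.csv"),
    admissions = file.path(dir, "admissions.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(q, paths[["questionnaire"]], na = "")
  readr::write_csv(a, paths[["admissions"]], na = "")
  truth <- cohort$truth
  truth_obj <- stats::setNames(
    purrr::map(seq_len(nrow(truth)), function(i) as.list(truth[i, -1])),
    truth$patient_id
  )
  jsonlite::write_json(truth_obj, paths[["truth"]], auto_unbox = TRUE, pretty = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  q_path <- file.path(dir, "questionnaire.csv")
  a_path <- file.path(dir, "admissions.csv")
  if (!file.exists(q_path) || !file.exists(a_path)) {
    stop("directory does not contain questionnaire.csv and admissions.csv: ", dir,
         call. = FALSE)
  }
  q <- readr::read_csv(q_path, show_col_types = FALSE, progress = FALSE)
  check_columns(q, QUESTIONNAIRE_KEYS, "questionnaire table")
  conds <- condition_cols(q)
  q[conds] <- lapply(q[conds], function(x) as.logical(as.integer(x)))
  q$completion_day <- as.integer(q$completion_day)

  a <- readr::read_csv(
    a_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      admission_id = readr::col_character(),
      patient_id = readr::col_character(),
      procedure_link_id = readr::col_character(),
      admission_day = readr::col_integer(),
      is_index_procedure = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  check_columns(a, c("admission_id", "patient_id", "procedure_link_id",
                     "admission_day", "is_index_procedure", diag_cols()),
                "admissions table")
  a$is_index_procedure <- as.logical(a$is_index_procedure)

  out <- list(questionnaire = q, admissions = a)
  t_path <- file.path(dir, "truth.json")
  if (file.exists(t_path)) {
    raw <- jsonlite::read_json(t_path)
    truth <- tibble::tibble(patient_id = names(raw))
    if (length(raw) > 0) {
      for (cond in names(raw[[1]])) {
        truth[[cond]] <- purrr::map_lgl(raw, cond)
      }
    }
    out$truth <- truth
  }
  out
}
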