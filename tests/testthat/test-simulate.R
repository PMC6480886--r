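test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(n_patients = 10, conditions = c("diabetes", "diabetes")),
               "conditions")
  expect_error(
    sim_config(n_patients = 10, conditions = "diabetes",
               true_prevalence = c(diabetes = 1.2)),
    "true_prevalence"
  )
  expect_error(
    sim_config(n_patients = 10, conditions = "diabetes",
               true_prevalence = c(diabetes = 0.1),
               report_sensitivity = c(stroke = 0.5)),
    "report_sensitivity"
  )
  expect_error(sim_config(duplicate_questionnaire_rate = -0.1),
               "duplicate_questionnaire_rate")
  expect_error(sim_config(admissions_per_patient_mean = -1),
               "admissions_per_patient_mean")
})

test_that("identical configurations give identical cohorts and files", {
  cfg <- sim_config(n_patients = 300, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$questionnaire, b$questionnaire)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in c("questionnaire.csv", "admissions.csv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("marginal prevalences are calibrated and structure holds at n = 10^4", {
  cfg <- sim_config(n_patients = 10000, seed = 7)
  sim <- simulate_cohort(cfg)

  for (cond in cfg$conditions) {
    p <- cfg$true_prevalence[[cond]]
    se <- sqrt(p * (1 - p) / cfg$n_patients)
    expect_lt(abs(mean(sim$truth[[cond]]) - p), 4 * se)
  }
  # every questionnaire row's patient exists in the admissions table
  expect_true(all(sim$questionnaire$patient_id %in% sim$admissions$patient_id))
  # no admission carries more than 20 codes
  diag_mat <- as.matrix(sim$admissions[, sprintf("diag_%02d", 1:20)])
  expect_true(all(rowSums(!is.na(diag_mat)) <= 20))
  # every patient has at least one index admission; exactly one plus repeats
  idx <- sim$admissions[sim$admissions$is_index_procedure, ]
  expect_setequal(unique(idx$patient_id), sim$truth$patient_id)
  n_rep_expected <- sum(table(idx$patient_id) == 2)
  expect_gt(n_rep_expected, 0)
  expect_true(all(table(idx$patient_id) <= 2))
})

test_that("high-count responders tick exactly eight conditions", {
  cfg <- sim_config(n_patients = 2000, seed = 5, high_count_responder_rate = 0.2,
                    duplicate_questionnaire_rate = 0, repeat_procedure_rate = 0)
  sim <- simulate_cohort(cfg)
  counts <- rowSums(as.matrix(sim$questionnaire[, cfg$conditions]))
  expect_gt(sum(counts == 8), 0.1 * cfg$n_patients)
})

test_that("noiseless limit yields perfect downstream agreement", {
  conds <- c("diabetes", "stroke", "lung_disease")
  cfg <- sim_config(
    n_patients = 400, seed = 10, conditions = conds,
    true_prevalence = c(diabetes = 0.3, stroke = 0.2, lung_disease = 0.25),
    report_sensitivity = 1, report_specificity = 1,
    code_sensitivity_per_admission = 1, code_false_positive_per_admission = 0,
    admissions_per_patient_mean = 1,
    duplicate_questionnaire_rate = 0, repeat_procedure_rate = 0,
    high_count_responder_rate = 0
  )
  sim <- simulate_cohort(cfg)
  coh <- build_cohort(sim$questionnaire, sim$admissions)
  flags <- derive_admin_flags(coh, default_code_map(), lookback_spec(365),
                              conditions = conds)
  # flags equal the latent truth exactly
  truth <- sim$truth[match(flags$patient_id, sim$truth$patient_id), ]
  for (cond in conds) expect_identical(flags[[cond]], truth[[cond]])

  res <- agreement(coh$questionnaire, flags)
  expect_equal(res$sensitivity, rep(1, 3))
  expect_equal(res$specificity, rep(1, 3))
  expect_equal(res$kappa, rep(1, 3))
})

test_that("configured reporting probabilities are recovered through the pipeline", {
  cfg <- sim_config(
    n_patients = 20000, seed = 1, conditions = "diabetes",
    true_prevalence = c(diabetes = 0.12),
    report_sensitivity = c(diabetes = 0.875),
    report_specificity = c(diabetes = 0.99),
    admissions_per_patient_mean = 0.2,
    duplicate_questionnaire_rate = 0, repeat_procedure_rate = 0,
    high_count_responder_rate = 0
  )
  sim <- simulate_cohort(cfg)

  # direct Monte-Carlo check of the generator before the pipeline runs
  tr <- sim$truth$diabetes
  rep_rate <- mean(sim$questionnaire$diabetes[match(sim$truth$patient_id,
                                                    sim$questionnaire$patient_id)][tr])
  expect_lt(abs(rep_rate - 0.875), 4 * sqrt(0.875 * 0.125 / sum(tr)))

  # pipeline estimate with truth-faithful flags covers the configured value
  coh <- build_cohort(sim$questionnaire, sim$admissions)
  flags <- sim$truth
  class(flags) <- c("admin_flags", class(flags))
  res <- agreement(coh$questionnaire, flags, conditions = "diabetes")
  expect_true(res$sens_low <= 0.875 && 0.875 <= res$sens_high)
  expect_true(res$spec_low <= 0.99 && 0.99 <= res$spec_high)
})

test_that("fixtures round-trip losslessly and truth JSON conserves size", {
  cfg <- sim_config(n_patients = 3, seed = 2)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$questionnaire), as.data.frame(sim$questionnaire))
  expect_equal(as.data.frame(back$admissions), as.data.frame(sim$admissions))
  expect_equal(as.data.frame(back$truth), as.data.frame(sim$truth))

  truth_json <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth_json, 3)
  expect_true(all(lengths(truth_json) == 12))
})
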