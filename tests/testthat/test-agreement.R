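# direct scalar formulas used as the independent oracle throughout
oracle_stats <- function(b, ao, po, ne) {
  n <- b + ao + po + ne
  p_adm <- (b + ao) / n
  p_pat <- (b + po) / n
  pobs <- (b + ne) / n
  pe <- p_adm * p_pat + (1 - p_adm) * (1 - p_pat)
  list(sens = b / (b + ao), spec = ne / (ne + po),
       kappa = (pobs - pe) / (1 - pe))
}

test_that("crosstab counts every patient exactly once", {
  resp <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                         diabetes = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  flags <- tibble::tibble(patient_id = sprintf("P%d", 6:1),  # shuffled order
                          diabetes = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  tab <- crosstab(resp, flags, "diabetes")
  # brute-force double loop
  cells <- c(both = 0, admin_only = 0, patient_only = 0, neither = 0)
  for (pid in resp$patient_id) {
    p <- resp$diabetes[resp$patient_id == pid]
    a <- flags$diabetes[flags$patient_id == pid]
    key <- if (p && a) "both" else if (a) "admin_only" else if (p) "patient_only" else "neither"
    cells[key] <- cells[key] + 1
  }
  expect_equal(unlist(tab[, names(cells)]), cells, ignore_attr = TRUE)
  expect_equal(sum(unlist(tab[, names(cells)])), nrow(resp))

  expect_error(crosstab(resp[-1, ], flags, "diabetes"), "P1")
})

test_that("degenerate tables return reasons, not errors", {
  perfect <- data.frame(both = 5, admin_only = 0, patient_only = 0, neither = 5)
  ss <- sens_spec(perfect)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  expect_equal(cohens_kappa(perfect)$kappa, 1)

  no_pos <- data.frame(both = 0, admin_only = 0, patient_only = 2, neither = 8)
  ss2 <- sens_spec(no_pos)
  expect_true(is.na(ss2$sensitivity))
  expect_match(ss2$note, "no administrative positives")
  expect_false(is.na(ss2$specificity))

  all_both <- data.frame(both = 10, admin_only = 0, patient_only = 0, neither = 0)
  kk <- cohens_kappa(all_both)
  expect_true(is.na(kk$kappa))
  expect_match(kk$note, "degenerate")

  expect_error(sens_spec(data.frame(both = 0, admin_only = 0,
                                    patient_only = 0, neither = 0)), "zero total")
  expect_error(cohens_kappa(data.frame(both = -1, admin_only = 1,
                                       patient_only = 1, neither = 1)),
               "non-negative")
})

test_that("kappa respects its structural invariants", {
  tab <- data.frame(both = 30, admin_only = 10, patient_only = 5, neither = 55)
  k <- cohens_kappa(tab)$kappa
  # invariant under uniform scaling of all four cells
  tab10 <- tab * 10
  expect_equal(cohens_kappa(tab10)$kappa, k, tolerance = 1e-12)
  # exchange symmetry: swapping the two sources leaves kappa unchanged
  swapped <- data.frame(both = 30, admin_only = 5, patient_only = 10, neither = 55)
  expect_equal(cohens_kappa(swapped)$kappa, k, tolerance = 1e-12)
  # and swaps the roles in sensitivity
  expect_equal(sens_spec(swapped)$sensitivity,
               tab$both / (tab$both + tab$patient_only))
  # kappa <= observed agreement when both are non-negative
  po <- (tab$both + tab$neither) / sum(tab)
  expect_lte(k, po)
})

test_that("statistics match direct formula evaluation on random tables", {
  set.seed(99)
  n_tab <- 2000
  cells <- matrix(rpois(4 * n_tab, lambda = 30) + 1, ncol = 4)
  colnames(cells) <- c("both", "admin_only", "patient_only", "neither")
  tab <- tibble::as_tibble(cells)
  ss <- sens_spec(tab)
  kk <- cohens_kappa(tab)
  o <- lapply(seq_len(n_tab), function(i) {
    oracle_stats(cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4])
  })
  expect_lt(max(abs(ss$sensitivity - vapply(o, `[[`, numeric(1), "sens"))), 1e-12)
  expect_lt(max(abs(ss$specificity - vapply(o, `[[`, numeric(1), "spec"))), 1e-12)
  expect_lt(max(abs(kk$kappa - vapply(o, `[[`, numeric(1), "kappa"))), 1e-12)
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, 40) + 1
    tab <- data.frame(both = cells[1], admin_only = cells[2],
                      patient_only = cells[3], neither = cells[4])
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2, 2)
    expect_equal(cohens_kappa(tab)$kappa, e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("confidence intervals behave at the edges", {
  tab <- data.frame(both = 99, admin_only = 1, patient_only = 0, neither = 10)
  wald <- sens_spec(tab)
  wilson <- sens_spec(tab, method = "wilson")
  expect_true(wald$sens_low <= wald$sensitivity &&
                wald$sensitivity <= wald$sens_high)
  expect_true(all(c(wilson$sens_low, wilson$sens_high,
                    wilson$spec_low, wilson$spec_high) >= 0))
  expect_true(all(c(wilson$sens_high, wilson$spec_high) <= 1))
  # specificity 10/10: Wald interval collapses but stays in [0, 1]
  expect_equal(wald$spec_high, 1)
})

test_that("kappa bands follow the published cut-points with a closed 0.40", {
  expect_equal(
    kappa_band(c(0.88, 0.54, 0.25, 0.40, 0.60, 0.605, 0.80, 0.81, -0.2, 1)),
    c("near perfect agreement", "moderate agreement", "poor agreement",
      "moderate agreement", "moderate agreement", "substantial agreement",
      "substantial agreement", "near perfect agreement", "poor agreement",
      "near perfect agreement")
  )
  expect_error(kappa_band(1.2), "kappa")
  expect_true(is.na(kappa_band(NA_real_)))
})

test_that("the per-condition suite excludes arthritis and matches manual scalars", {
  sim <- simulate_cohort(sim_config(n_patients = 800, seed = 31))
  coh <- build_cohort(sim$questionnaire, sim$admissions)
  flags <- derive_admin_flags(coh, default_code_map(), lookback_spec(365))
  res <- agreement(coh$questionnaire, flags)
  expect_false("arthritis" %in% res$condition)
  expect_equal(nrow(res), 11)
  expect_true(all(res$both + res$admin_only + res$patient_only + res$neither ==
                    nrow(coh$questionnaire)))
  for (i in seq_len(nrow(res))) {
    o <- oracle_stats(res$both[i], res$admin_only[i], res$patient_only[i],
                      res$neither[i])
    expect_equal(res$sensitivity[i], o$sens, tolerance = 1e-12)
    expect_equal(res$specificity[i], o$spec, tolerance = 1e-12)
    expect_equal(res$kappa[i], o$kappa, tolerance = 1e-12)
  }
  expect_equal(res$kappa_band, kappa_band(res$kappa))

  empty <- agreement(coh$questionnaire, flags, conditions = character(0))
  expect_equal(nrow(empty), 0)
})
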