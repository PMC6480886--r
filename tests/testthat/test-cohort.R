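test_that("duplicate questionnaires remove the whole linked group by default", {
  pid <- sprintf("P%d", 1:5)
  q <- mk_q(pid, diabetes = FALSE)
  q <- dplyr::bind_rows(q, q[3, ] |> dplyr::mutate(row_id = "Q9999"))
  adm <- mk_adm(pid, day = 1000, index = TRUE, link = paste0("L", pid))

  out <- drop_duplicates(q, adm)
  expect_equal(out$n_duplicate_questionnaires, 2)
  expect_equal(sort(unique(out$questionnaire$patient_id)), sort(pid[-3]))

  kept <- drop_duplicates(q, adm, mode = "keep-first")
  expect_equal(kept$n_duplicate_questionnaires, 1)
  expect_setequal(unique(kept$questionnaire$patient_id), pid)
})

test_that("duplicate index procedures drop the linked questionnaire and admissions", {
  pid <- c("P1", "P2")
  q <- mk_q(pid, diabetes = FALSE, link = c("L1", "L2"))
  adm <- dplyr::bind_rows(
    mk_adm("P1", 1000, index = TRUE, link = "L1"),
    mk_adm("P1", 1000, index = TRUE, link = "L1", id_offset = 1L),
    mk_adm("P2", 1000, index = TRUE, link = "L2", id_offset = 2L)
  )
  out <- drop_duplicates(q, adm)
  expect_equal(out$n_duplicate_procedures, 1)
  expect_equal(out$questionnaire$patient_id, "P2")
  expect_equal(sum(out$admissions$is_index_procedure), 1)
})

test_that("clean input passes through unchanged with zero counts", {
  pid <- sprintf("P%d", 1:4)
  q <- mk_q(pid, diabetes = c(TRUE, FALSE, TRUE, FALSE))
  adm <- mk_adm(pid, day = 1000, index = TRUE, link = paste0("L", pid))
  out <- drop_duplicates(q, adm)
  expect_equal(out$n_duplicate_questionnaires + out$n_duplicate_procedures, 0)
  expect_equal(nrow(out$questionnaire), 4)

  coh <- build_cohort(q, adm)
  expect_equal(coh$exclusions$n_final, coh$exclusions$n_input)

  # missing column is a schema error naming the column
  expect_error(drop_duplicates(q[, -3], adm), "procedure_link_id")
})

test_that("the first index procedure by admission day is kept", {
  q <- mk_q(c("P1", "P1"), link = c("L1a", "L1b"), diabetes = FALSE,
            row_id = c("Q1", "Q2"))
  adm <- dplyr::bind_rows(
    mk_adm("P1", 400, index = TRUE, link = "L1b"),
    mk_adm("P1", 100, index = TRUE, link = "L1a", id_offset = 1L)
  )
  out <- keep_first_procedure(adm)
  expect_equal(out$n_removed, 1)
  expect_equal(out$admissions$admission_day[out$admissions$is_index_procedure], 100)

  coh <- build_cohort(q, adm)
  expect_equal(coh$exclusions$n_subsequent_procedures, 1)
  expect_equal(coh$questionnaire$procedure_link_id, "L1a")
})

test_that("the high-count threshold is inclusive at seven", {
  conds <- proms_conditions()$condition
  q <- mk_q(c("P1", "P2"))
  for (i in seq_along(conds)) {
    q[[conds[i]]] <- c(i <= 7, i <= 6)   # P1 ticks 7, P2 ticks 6
  }
  out <- exclude_high_count(q)
  expect_equal(out$n_removed, 1)
  expect_equal(out$questionnaire$patient_id, "P2")
  expect_error(exclude_high_count(q, threshold = 0), "threshold")
})

test_that("exclusion counts match independent group-by audits of the raw fixture", {
  sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 7,
                                    duplicate_questionnaire_rate = 0.05,
                                    high_count_responder_rate = 0.01))
  q <- sim$questionnaire
  adm <- sim$admissions
  coh <- build_cohort(q, adm)

  # oracle 1: duplicate questionnaires = all rows of link groups of size > 1
  link_n <- table(q$procedure_link_id)
  expect_equal(coh$exclusions$n_duplicate_questionnaires,
               sum(link_n[link_n > 1]))

  # oracle 2: subsequent procedures = rows (net of duplicates) linked to a
  # non-first index admission of their patient
  q1 <- q[!q$procedure_link_id %in% names(link_n)[link_n > 1], ]
  idx <- adm[adm$is_index_procedure, ]
  first_day <- tapply(idx$admission_day, idx$patient_id, min)
  idx_day <- idx$admission_day[match(q1$procedure_link_id, idx$procedure_link_id)]
  expect_equal(coh$exclusions$n_subsequent_procedures,
               sum(idx_day > first_day[q1$patient_id]))

  # oracle 3: high-count rows among what remains after the first two stages
  q2 <- q1[idx_day <= first_day[q1$patient_id], ]
  n_yes <- rowSums(as.matrix(q2[, sim$config$conditions]))
  expect_equal(coh$exclusions$n_high_count_responders, sum(n_yes >= 7))

  # conservation and idempotence
  ex <- coh$exclusions
  expect_equal(ex$n_final,
               ex$n_input - ex$n_duplicate_questionnaires -
                 ex$n_duplicate_procedures - ex$n_subsequent_procedures -
                 ex$n_high_count_responders)
  again <- build_cohort(coh$questionnaire, coh$admissions)
  expect_equal(again$exclusions$n_final, again$exclusions$n_input)
  expect_equal(nrow(again$questionnaire), nrow(coh$questionnaire))
})

test_that("exclusion_report enforces its conservation identity", {
  expect_error(exclusion_report(100, 10, 0, 0, 0, n_final = 95), "balance")
  expect_error(exclusion_report(10, 20), "exceed")
  expect_error(exclusion_report(100, -1), "non-negative")
  rep <- exclusion_report(100, 10, 5, 20, 1)
  expect_equal(rep$n_final, 64)
})
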