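# Hand-built table constructors used across the test files.

mk_q <- function(patient_id, ..., link = NULL, day = 1000L, row_id = NULL) {
  n <- length(patient_id)
  if (is.null(link)) link <- paste0("L", patient_id)
  if (is.null(row_id)) row_id <- sprintf("Q%04d", seq_len(n))
  conds <- lapply(list(...), function(x) rep_len(as.logical(x), n))
  tibble::as_tibble(c(
    list(row_id = row_id, patient_id = patient_id,
         procedure_link_id = rep_len(link, n),
         completion_day = rep_len(as.integer(day), n)),
    conds
  ))
}

mk_adm <- function(patient_id, day, index = FALSE, link = NA_character_,
                   codes = list(), id_offset = 0L) {
  n <- length(patient_id)
  codes <- rep_len(codes, max(n, 1L))
  out <- tibble::tibble(
    admission_id = sprintf("A%04d", id_offset + seq_len(n)),
    patient_id = patient_id,
    procedure_link_id = rep_len(link, n),
    admission_day = rep_len(as.integer(day), n),
    is_index_procedure = rep_len(index, n)
  )
  mat <- matrix(NA_character_, n, 20,
                dimnames = list(NULL, sprintf("diag_%02d", 1:20)))
  for (i in seq_len(n)) {
    cs <- codes[[i]]
    if (length(cs) > 0) mat[i, seq_along(cs)] <- cs
  }
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

# A single-condition cohort where every patient has one index admission on
# `day` carrying the given codes. `reported` is a logical vector.
single_condition_cohort <- function(reported, codes, condition = "diabetes",
                                    day = 2000L) {
  n <- length(reported)
  pid <- sprintf("P%04d", seq_len(n))
  q <- mk_q(pid, day = day)
  q[[condition]] <- reported
  adm <- mk_adm(pid, day = day, index = TRUE, link = paste0("L", pid),
                codes = codes)
  build_cohort(q, adm)
}

# Planted backward-coding fixture: 200 reporters, 200 non-reporters of
# `diabetes`; map contains only E11 and nobody carries it, so all reporters
# are unexplained. Planted four-character codes under category E16:
#   E160: 60/200 reporters vs 10/200 non-reporters  -> ratio 6, added
#   E161: 20/200 vs 20/200                          -> ratio 1, never added
#   E162: 20/200 vs 10/200                          -> ratio exactly 2, added
#   E163:  5/200 vs  0/200                          -> infinite ratio, added
# Category frequency controls: E20 in 1/200 reporters (0.5% <= 1%), E21 in
# exactly 2/200 (1.0%, not strictly above the threshold) -> neither screened.
backward_fixture <- function() {
  n_rep <- 200L
  n_non <- 200L
  reported <- c(rep(TRUE, n_rep), rep(FALSE, n_non))
  codes <- vector("list", n_rep + n_non)
  for (i in seq_along(codes)) codes[[i]] <- character(0)
  give <- function(codes, code, rep_idx, non_idx = integer(0)) {
    for (i in rep_idx) codes[[i]] <- c(codes[[i]], code)
    for (i in non_idx) codes[[n_rep + i]] <- c(codes[[n_rep + i]], code)
    codes
  }
  codes <- give(codes, "E160", 1:60, 1:10)
  codes <- give(codes, "E161", 61:80, 11:30)
  codes <- give(codes, "E162", 81:100, 31:40)
  codes <- give(codes, "E163", 101:105)
  codes <- give(codes, "E200", 106)        # category below 1%
  codes <- give(codes, "E210", 107:108)    # category at exactly 1%
  cohort <- single_condition_cohort(reported, codes)
  map <- code_map(tibble::tibble(condition = "diabetes", code = "E11"),
                  chapters = list(diabetes = "E"))
  list(cohort = cohort, map = map)
}

# Printed validation-study reference values (1 d.p. percentages, 2 d.p.
# kappa) for the eleven conditions of the published Table, in the row order
# of inst/extdata/table2_counts.csv.
printed_table2 <- function() {
  tibble::tribble(
    ~condition,             ~sens, ~sens_lo, ~sens_hi, ~spec, ~kappa,
    "heart_disease",         46.4,     46.2,     46.7,  98.1,   0.54,
    "high_blood_pressure",   74.3,     74.1,     74.4,  90.3,   0.65,
    "stroke",                32.2,     31.1,     33.3,  98.7,   0.25,
    "leg_pain_circulation",  26.1,     25.3,     27.0,  93.2,   0.07,
    "lung_disease",          46.8,     46.4,     47.1,  98.5,   0.55,
    "diabetes",              87.5,     87.3,     87.7,  98.8,   0.88,
    "kidney_disease",        18.8,     18.4,     19.2,  99.1,   0.26,
    "nervous_system",        20.9,     20.4,     21.5,  99.7,   0.31,
    "liver_disease",         34.3,     32.8,     35.7,  99.7,   0.36,
    "cancer",                68.8,     68.0,     69.6,  96.4,   0.37,
    "depression",            61.0,     60.5,     61.6,  93.3,   0.36
  )
}

table2_path <- function() {
  system.file("extdata", "table2_counts.csv", package = "chronicagree")
}
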