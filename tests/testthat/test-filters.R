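test_that("filter parameter validation rejects out-of-range values", {
  expect_error(filter_params(control_fc = 0.5))
  expect_error(filter_params(q_value_max = 0))
  expect_error(filter_params(data_completeness = 1.5))
  expect_error(filter_params(num_peptides_min = 0))
})

test_that("ion filters are conjunctive on q-value and replicate CV", {
  # 10 ions x 4 replicates; ions 1-3 built with CV > 0.2, ion 4 with a
  # failing q-value, the rest clean
  mk_ion <- function(i, ratios, q = 0.001) {
    tibble::tibble(sample_type = "BAIT_WT", replicate = 1:4,
                   protein_id = "P1", peptide_seq = strrep(LETTERS[i], 5),
                   ratio_lh_norm = ratios, q_value = q)
  }
  wide <- c(0.5, 0.8, 1.2, 1.8)   # cv ~ 0.52
  tight <- c(0.95, 1.0, 1.0, 1.05) # cv ~ 0.04
  df <- mk_normalized(dplyr::bind_rows(
    lapply(1:3, function(i) mk_ion(i, wide)),
    mk_ion(4, tight, q = 0.02),
    lapply(5:10, function(i) mk_ion(i, tight))
  ))
  res <- apply_ion_filters(df, filter_params())
  passed_ions <- unique(res$peptides$peptide_seq[res$peptides$ion_pass])
  expect_length(passed_ions, 6)
  aud <- res$audit
  expect_equal(aud$n_failed[aud$filter == "q_value"], 4L)
  expect_equal(aud$n_failed[aud$filter == "ion_cv"], 12L)
  # survivors never increase along the ledger
  expect_true(all(diff(aud$n_surviving) <= 0))
  # undefined CV (single replicate) fails
  single <- mk_normalized(tibble::tibble(
    sample_type = "BAIT_WT", replicate = 1, protein_id = "P1",
    peptide_seq = "AAAAA", ratio_lh_norm = 1
  ))
  expect_false(any(apply_ion_filters(single, filter_params())$peptides$ion_pass))
})

test_that("control-FC rule flags a peptide everywhere once any control replicate strays", {
  base <- tidyr::expand_grid(sample_type = c("WT_WT", "BAIT_WT", "BAIT_BAIT"),
                             replicate = 1:2)
  mk <- function(pep, bb_r1) {
    df <- base
    df$protein_id <- "P1"
    df$peptide_seq <- pep
    df$ratio_lh_norm <- 1
    df$ratio_lh_norm[df$sample_type == "BAIT_BAIT" & df$replicate == 1] <- bb_r1
    df
  }
  df <- mk_normalized(dplyr::bind_rows(
    mk("AAAAA", 2.5),  # strays beyond 2-fold in one bait-control replicate
    mk("CCCCC", 2.0),  # exactly 2-fold: kept (strict inequality)
    mk("DDDDD", 1.0)
  ))
  out <- apply_control_fc_filter(df, control_fc = 2)
  flagged <- out[out$peptide_seq == "AAAAA", ]
  expect_true(all(!flagged$control_pass))
  expect_true(all(out$control_pass[out$peptide_seq %in% c("CCCCC", "DDDDD")]))
})

test_that("protein filters enforce completeness, peptide count and coverage", {
  summ <- tibble::tibble(
    protein_id = c("FULL", "MISSREP", "ONEPEP", "LOWCOV"),
    sample_type = "BAIT_WT", condition = "control", fa_level = "fa_0.2",
    n_reps_detected = c(4L, 3L, 4L, 4L),
    n_peptides = c(5L, 5L, 1L, 5L),
    seq_coverage = c(55, 55, 55, 30)
  )
  out <- apply_protein_filters(summ, filter_params(), n_replicates = 4)
  pass <- out$summary$protein_pass
  names(pass) <- out$summary$protein_id
  expect_true(pass[["FULL"]])
  expect_false(pass[["MISSREP"]])
  expect_false(pass[["ONEPEP"]])
  expect_false(pass[["LOWCOV"]])
  # fractional completeness scales with the design
  out2 <- apply_protein_filters(summ, filter_params(data_completeness = 0.75),
                                n_replicates = 4)
  expect_true(out2$summary$protein_pass[out2$summary$protein_id == "MISSREP"])
})

test_that("tightening any single filter parameter never enlarges the survivor set", {
  sim <- make_fixture_suite()$tiers
  norm <- normalize_runs(sim$report, sim$sample_sheet)
  survivors <- function(params) {
    flagged <- apply_ion_filters(norm, params)$peptides
    summ <- summarize_protein_groups(flagged, sim$proteins)
    out <- apply_protein_filters(summ, params, 4)$summary
    paste(out$protein_id, out$sample_type)[out$protein_pass]
  }
  base <- survivors(filter_params(ion_cv_max = 0.3))
  tighter <- list(filter_params(ion_cv_max = 0.2),
                  filter_params(ion_cv_max = 0.3, q_value_max = 0.005),
                  filter_params(ion_cv_max = 0.3, seq_coverage_min = 60),
                  filter_params(ion_cv_max = 0.3, num_peptides_min = 8))
  for (p in tighter) {
    expect_true(all(survivors(p) %in% base))
  }
})

test_that("bait tuning walks the grid to the first feasible stringency pair", {
  # bait with ion CV 0.28 and coverage 35%: the classic relaxation to (0.3, 30)
  fx <- make_tune_fixture(bait_cv = 0.28, bait_pep_lens = c(30, 20, 20),
                          bait_len = 200)
  tuned <- tune_filters(fx$peptides, fx$sheet, fx$db, fx$bait_id)
  expect_equal(tuned$params$ion_cv_max, 0.3)
  expect_equal(tuned$params$seq_coverage_min, 30)
  expect_equal(nrow(tuned$trace), 9)
  expect_true(sum(tuned$trace$feasible) == 1)
  expect_true("ion_cv" %in% tuned$trace$bait_failing_filter)
  expect_true("seq_coverage" %in% tuned$trace$bait_failing_filter)

  # a bait already passing the defaults keeps them
  fx2 <- make_tune_fixture(bait_cv = 0.05, bait_pep_lens = c(40, 30, 30),
                           bait_len = 200)
  tuned2 <- tune_filters(fx2$peptides, fx2$sheet, fx2$db, fx2$bait_id)
  expect_equal(tuned2$params$ion_cv_max, 0.2)
  expect_equal(tuned2$params$seq_coverage_min, 40)
  expect_equal(nrow(tuned2$trace), 1)

  # a bait failing only coverage relaxes only the coverage threshold
  fx3 <- make_tune_fixture(bait_cv = 0.05, bait_pep_lens = c(30, 20, 20),
                           bait_len = 200)
  tuned3 <- tune_filters(fx3$peptides, fx3$sheet, fx3$db, fx3$bait_id)
  expect_equal(tuned3$params$ion_cv_max, 0.2)
  expect_equal(tuned3$params$seq_coverage_min, 30)
})

test_that("an infeasible bait raises a tuning failure carrying the trace", {
  fx <- make_tune_fixture(bait_cv = 0.6)
  err <- tryCatch(
    tune_filters(fx$peptides, fx$sheet, fx$db, fx$bait_id),
    error = function(e) e
  )
  expect_match(conditionMessage(err), "tuning failure")
  expect_equal(nrow(err$trace), 9)
  expect_false(any(err$trace$feasible))
})
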