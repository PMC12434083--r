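# Compact builder for hand-written enrichment tables.
mk_results <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(protein_id = r[[1]], sample_type = r[[2]],
                   condition = "control", fa_level = "fa_0.2",
                   enrichment_fold = r[[3]], adj_p = r[[4]],
                   mean_log2 = log2(r[[3]]), significant = NA)
  }))
}

test_that("the decision table assigns each protein exactly one status", {
  res <- mk_results(
    list("BAIT", "BAIT_WT", 250, 1e-12),
    list("BAIT", "BAIT_BAIT", 1.0, 0.9),
    list("CAND", "BAIT_WT", 5.0, 1e-6),
    list("CAND", "WT_WT", 1.0, 0.9),
    list("CAND", "BAIT_BAIT", 1.1, 0.8),
    # biotinylated-contaminant pattern: enriched in experiment AND bait control
    list("PURA_LIKE", "BAIT_WT", 3.6, 1e-5),
    list("PURA_LIKE", "BAIT_BAIT", 3.4, 1e-4),
    list("REDCASE", "BAIT_WT", 4.0, 1e-5),
    list("REDCASE", "WT_WT", 4.2, 1e-6),
    list("FLAT", "BAIT_WT", 1.0, 0.99),
    list("FLAT", "WT_WT", 1.0, 0.99),
    # significant p but sub-threshold fold: not called
    list("LOWFOLD", "BAIT_WT", 1.5, 1e-8)
  )
  cls <- classify_interactors(res, bait_id = "BAIT")
  status <- setNames(cls$status, cls$protein_id)
  expect_equal(unname(status[c("BAIT", "CAND", "PURA_LIKE", "REDCASE",
                               "FLAT", "LOWFOLD")]),
               c("bait", "candidate", "excluded_bait_control",
                 "excluded_wt_control", "not_significant", "not_significant"))
  # partition: one row and one known status per universe protein
  expect_equal(sort(cls$protein_id), sort(unique(res$protein_id)))
  expect_true(all(cls$status %in% c("bait", "candidate", "excluded_wt_control",
                                    "excluded_bait_control", "not_significant")))
})

test_that("bait status overrides controls; a filtered-out bait warns", {
  res <- mk_results(
    list("BAIT", "BAIT_WT", 250, 1e-12),
    list("BAIT", "BAIT_BAIT", 5, 1e-9) # enriched even in the bait control
  )
  cls <- classify_interactors(res, bait_id = "BAIT")
  expect_equal(cls$status[cls$protein_id == "BAIT"], "bait")
  expect_warning(
    classify_interactors(mk_results(list("OTHER", "BAIT_WT", 3, 1e-5)),
                         bait_id = "BAIT"),
    "tune_filters"
  )
})

test_that("removing controls can only promote excluded proteins to candidates", {
  set.seed(41)
  for (i in 1:20) {
    n <- 15
    res <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      mk_results(
        list(paste0("P", j), "BAIT_WT", 2^runif(1, -1, 4), 10^runif(1, -8, 0)),
        list(paste0("P", j), "WT_WT", 2^runif(1, -1, 2.5), 10^runif(1, -5, 0)),
        list(paste0("P", j), "BAIT_BAIT", 2^runif(1, -1, 2.5),
             10^runif(1, -5, 0))
      )
    }))
    with_ctrl <- classify_interactors(res, bait_id = "NONE_SUCH") |>
      suppressWarnings()
    no_ctrl <- classify_interactors(
      dplyr::filter(res, sample_type == "BAIT_WT"), bait_id = "NONE_SUCH") |>
      suppressWarnings()
    j <- dplyr::inner_join(with_ctrl[c("protein_id", "status")],
                           no_ctrl[c("protein_id", "status")],
                           by = "protein_id", suffix = c("_ctrl", "_free"))
    was_excluded <- startsWith(j$status_ctrl, "excluded")
    # excluded proteins become candidates or stay non-significant ...
    expect_true(all(j$status_free[was_excluded] %in%
                      c("candidate", "not_significant")))
    # ... and no protein moves the other way
    expect_false(any(startsWith(j$status_free, "excluded")))
    expect_equal(j$status_ctrl[!was_excluded], j$status_free[!was_excluded])
  }
})

test_that("planted control decoys are excluded by the matching control", {
  sim <- make_fixture_suite()$decoys
  out <- run_pipeline(sim$report, sim$sample_sheet, sim$proteins,
                      bait_id = "BAIT_TS")
  cls <- out$interactors
  expect_equal(cls$status[cls$protein_id == "DEC_WT"], "excluded_wt_control")
  expect_equal(cls$status[cls$protein_id == "DEC_BB"], "excluded_bait_control")
  # dropping the control tables converts both decoys to candidates
  cls_free <- classify_interactors(
    dplyr::filter(out$results, sample_type == "BAIT_WT"), bait_id = "BAIT_TS")
  expect_equal(cls_free$status[cls_free$protein_id == "DEC_WT"], "candidate")
  expect_equal(cls_free$status[cls_free$protein_id == "DEC_BB"], "candidate")
})

test_that("condition contrasts detect stress-specific interactors and are antisymmetric", {
  sim <- simulate_experiment(sim_config(
    seed = 77, n_background_proteins = 80,
    conditions = c("control", "etoh_stress"),
    interactors = tibble::tibble(
      accession = c("INT_BOTH", "INT_STRESS"),
      true_fold = c(8, 4),
      condition = c(NA, "etoh_stress")
    ),
    peptide_count_range = c(10, 14)
  ))
  norm <- normalize_runs(sim$report, sim$sample_sheet)
  res <- run_differential(norm, sim$proteins)
  cc <- compare_conditions(res, "etoh_stress", "control")
  stress_row <- cc[cc$protein_id == "INT_STRESS", ]
  expect_true(stress_row$in_both)
  expect_lt(stress_row$adj_p, 0.01)
  expect_lt(abs(stress_row$contrast - 2), 0.75)
  # shared interactors and background show no differential signal
  expect_gt(cc$adj_p[cc$protein_id == "INT_BOTH"], 0.01)
  # antisymmetry
  cc_rev <- compare_conditions(res, "control", "etoh_stress")
  m <- match(cc$protein_id, cc_rev$protein_id)
  expect_equal(cc$contrast, -cc_rev$contrast[m])
  expect_equal(cc$adj_p, cc_rev$adj_p[m])
})

test_that("identical conditions yield no significant contrasts", {
  sim <- simulate_experiment(sim_config(
    seed = 78, n_background_proteins = 120, bait = NULL,
    interactors = tibble::tibble(accession = character(),
                                 true_fold = numeric()),
    conditions = c("a", "b")
  ))
  norm <- normalize_runs(sim$report, sim$sample_sheet)
  res <- run_differential(norm, sim$proteins)
  cc <- compare_conditions(res, "a", "b")
  expect_false(any(cc$adj_p[cc$in_both] <= 0.01, na.rm = TRUE))
})
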