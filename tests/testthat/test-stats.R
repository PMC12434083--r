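test_that("protein aggregation is the median of surviving peptide ratios", {
  mk <- function(pep, ratios) {
    tibble::tibble(sample_type = "BAIT_WT", replicate = 1,
                   protein_id = "P1", peptide_seq = pep,
                   ratio_lh_norm = ratios)
  }
  df <- mk_normalized(mk(c("AAAAA", "CCCCC", "DDDDD"), c(2, 4, 8)))
  df$ion_pass <- TRUE
  agg <- aggregate_proteins(df)
  expect_equal(agg$protein_ratio, 4)
  expect_equal(agg$log2_ratio, 2)
  expect_equal(agg$n_peptides, 3L)

  # robust to a single outlier peptide
  df2 <- mk_normalized(mk(c("AAAAA", "CCCCC", "DDDDD", "EEEEE"),
                          c(1, 1, 1, 9)))
  df2$ion_pass <- TRUE
  expect_equal(aggregate_proteins(df2)$protein_ratio, 1)

  # duplicate rows of one peptide: both ratios enter the median,
  # the sequence counts once
  df3 <- mk_normalized(mk(c("AAAAA", "AAAAA", "CCCCC"), c(1, 3, 2)))
  df3$ion_pass <- TRUE
  agg3 <- aggregate_proteins(df3)
  expect_equal(agg3$protein_ratio, 2)
  expect_equal(agg3$n_peptides, 2L)

  # failing peptides never reach the median
  df4 <- mk_normalized(mk(c("AAAAA", "CCCCC"), c(1, 100)))
  df4$ion_pass <- c(TRUE, FALSE)
  expect_equal(aggregate_proteins(df4)$protein_ratio, 1)
})

test_that("variance-prior fit recovers known hyperparameters and handles degeneracy", {
  # degenerate: identical variances carry no dispersion information
  fit0 <- fit_variance_prior(rep(0.05, 50), df = 3)
  expect_equal(fit0$d0, 1e6)
  expect_error(fit_variance_prior(0.05, df = 3), "hyperparameter")

  # recovery from a scaled inverse-chi-square prior
  set.seed(202)
  d0 <- 4
  s0_2 <- 0.04
  d_g <- 3
  n <- 2000
  sigma2 <- d0 * s0_2 / rchisq(n, df = d0)
  s2 <- sigma2 * rchisq(n, df = d_g) / d_g
  fit <- fit_variance_prior(s2, df = d_g)
  expect_lt(abs(fit$d0 / d0 - 1), 0.25)
  expect_lt(abs(fit$s0_2 / s0_2 - 1), 0.10)
})

test_that("variance-prior fit agrees with an independent empirical-Bayes implementation", {
  set.seed(7)
  s2 <- 0.04 * rchisq(500, df = 3) / 3 * (4 / rchisq(500, df = 4) * 0.9 + 0.1)
  fit <- fit_variance_prior(s2, df = 3)
  sq <- limma::squeezeVar(s2, df = 3)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, sq$var.prior, tolerance = 1e-6)
  post <- (fit$d0 * fit$s0_2 + 3 * s2) / (fit$d0 + 3)
  expect_equal(post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated t reproduces the worked example and its classical limit", {
  res <- moderated_t_test(c(1.0, 1.2, 0.8, 1.0), d0 = 4, s0_2 = 0.04)
  expect_equal(res$mean_log2, 1.0)
  expect_equal(res$s2_g, 0.02666667, tolerance = 1e-6)
  expect_equal(res$s2_post, 0.03428571, tolerance = 1e-6)
  expect_equal(res$t_mod, 10.80123, tolerance = 1e-5)
  expect_equal(res$df, 7)

  # d0 = 0: exactly the classical one-sample t-test
  set.seed(31)
  for (i in 1:100) {
    y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.05, 1))
    res <- moderated_t_test(y, d0 = 0, s0_2 = 0.5)
    tt <- t.test(y)
    expect_equal(res$t_mod, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }

  # exact null
  res0 <- moderated_t_test(c(0, 0, 0, 0), d0 = 0, s0_2 = 0.5)
  expect_equal(res0$t_mod, 0)
  expect_equal(res0$p, 1)
  expect_error(moderated_t_test(1.5, d0 = 0, s0_2 = 1), "insufficient")
})

test_that("posterior variance is a shrinkage between s2_g and s0_2", {
  set.seed(17)
  for (i in 1:50) {
    y <- rnorm(4, 0, runif(1, 0.1, 2))
    d0 <- runif(1, 0.1, 50)
    s0_2 <- runif(1, 0.001, 4)
    res <- moderated_t_test(y, d0, s0_2)
    expect_gte(res$s2_post, min(res$s2_g, s0_2) - 1e-12)
    expect_lte(res$s2_post, max(res$s2_g, s0_2) + 1e-12)
  }
  # capped prior df pins the posterior to the prior variance
  y <- c(0.1, 0.5, -0.2, 0.3)
  res_cap <- moderated_t_test(y, d0 = 1e6, s0_2 = 0.04)
  expect_lt(abs(res_cap$s2_post - 0.04), 1e-6)
  # |t| decreases as the prior variance grows (s2_g below s0_2)
  ts <- vapply(c(0.5, 1, 2, 4), function(s0) {
    abs(moderated_t_test(y, d0 = 10, s0_2 = s0)$t_mod)
  }, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, brute_force_bh(p), tolerance = 1e-14)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("noiseless simulations are recovered exactly by the differential analysis", {
  sim <- make_fixture_suite()$smoke
  norm <- normalize_runs(sim$report, sim$sample_sheet)
  res <- run_differential(norm, sim$proteins)
  bw <- res[res$sample_type == "BAIT_WT", ]
  expect_equal(bw$enrichment_fold[bw$protein_id == "INT_A"], 8)
  expect_equal(bw$enrichment_fold[bw$protein_id == "BAIT_TS"], 256)
  ww <- res[res$sample_type == "WT_WT", ]
  expect_true(all(abs(ww$enrichment_fold - 1) < 1e-9))
  expect_false(any(ww$significant))
})
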