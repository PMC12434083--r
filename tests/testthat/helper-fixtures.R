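# Shared fixture builders and independent oracles.

# Brute-force step-up BH oracle: adj_(i) = min_{j >= i} p_(j) * m / j,
# clipped to 1, mapped back to input order.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(ps[i:m] * m / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force coverage oracle: scan every start position of every peptide.
oracle_coverage <- function(seq, peps) {
  cov <- logical(nchar(seq))
  for (p in unique(peps)) {
    l <- nchar(p)
    if (l == 0 || l > nchar(seq)) next
    for (s in seq_len(nchar(seq) - l + 1)) {
      if (substr(seq, s, s + l - 1) == p) cov[s:(s + l - 1)] <- TRUE
    }
  }
  100 * sum(cov) / length(cov)
}

# Minimal normalized-peptide tibble for filter/aggregation unit tests.
# `df` needs sample_type, replicate, protein_id, peptide_seq, ratio_lh_norm
# and optionally q_value; everything else is filled with defaults.
mk_normalized <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"q_value" %in% names(df)) df$q_value <- 0.001
  if (!"condition" %in% names(df)) df$condition <- "control"
  if (!"fa_level" %in% names(df)) df$fa_level <- "fa_0.2"
  df$sample_id <- paste0(df$sample_type, "_", df$condition, "_",
                         df$fa_level, "_BR", df$replicate)
  df$ratio_lh <- df$ratio_lh_norm
  df$ratio_hl <- 1 / df$ratio_lh
  df$norm_factor <- 1
  df$qc_cv <- NA_real_
  df$qc_pass <- TRUE
  df
}

# Deterministic hand-built dataset for the bait-inclusion tuning walk:
# three fully well-behaved background proteins (ratio exactly 1, coverage
# 60%) plus a bait whose BAIT_WT ions have an exact across-replicate CV of
# `bait_cv` and whose sequence coverage is sum(bait_pep_lens)/bait_len.
make_tune_fixture <- function(bait_cv = 0.28,
                              bait_pep_lens = c(30, 20, 20),
                              bait_len = 200,
                              bait_id = "SIGA_TS") {
  sheet <- enumerate_samples("control", "fa_0.2", 4)
  bait_peps <- c(strrep("C", bait_pep_lens[1]),
                 strrep("D", bait_pep_lens[2]),
                 strrep("E", bait_pep_lens[3]))
  filler <- bait_len - sum(bait_pep_lens)
  bait_seq <- paste0(bait_peps[1], strrep("A", ceiling(filler / 2)),
                     bait_peps[2], strrep("A", floor(filler / 2)),
                     bait_peps[3])
  bg_ids <- c("BGA", "BGB", "BGC")
  bg_peps <- c(strrep("F", 20), strrep("G", 20), strrep("H", 20))
  bg_seq <- paste0(bg_peps[1], strrep("A", 20), bg_peps[2],
                   strrep("A", 20), bg_peps[3])
  db <- tibble::tibble(
    protein_id = c(bait_id, bg_ids),
    description = "tuning fixture",
    sequence = c(bait_seq, rep(bg_seq, 3)),
    length = nchar(c(bait_seq, rep(bg_seq, 3)))
  )
  # bait BAIT_WT ratios: 200 * (1 -/+ c) twice each -> sample cv == bait_cv
  c_off <- bait_cv * sqrt(3) / 2
  bait_mult <- c(1 - c_off, 1 - c_off, 1 + c_off, 1 + c_off)
  rows <- list()
  for (r in seq_len(nrow(sheet))) {
    st <- sheet$sample_type[r]
    rep_i <- sheet$replicate[r]
    for (pid in bg_ids) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sheet$sample_id[r], protein_id = pid,
        peptide_seq = bg_peps, ratio_hl = 1, q_value = 0.001
      )
    }
    if (st != "WT_WT") {
      lh <- if (st == "BAIT_WT") 200 * bait_mult[rep_i] else 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sheet$sample_id[r], protein_id = bait_id,
        peptide_seq = bait_peps, ratio_hl = 1 / lh, q_value = 0.001
      )
    }
  }
  list(peptides = dplyr::bind_rows(rows), sheet = sheet, db = db,
       bait_id = bait_id)
}
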