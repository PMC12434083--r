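#' Aggregate surviving peptides to protein-level ratios per run
#'
#' Within one run, each protein's ratio is the median of its surviving
#' peptides' normalized L/H ratios (robust to single outlier peptides), then
#' log2-transformed. Duplicate rows of one peptide sequence (e.g. several
#' charge states) each contribute a ratio to the median but count once in
#' `n_peptides`.
#'
#' @param flagged Peptides with `ion_pass` (and optionally `control_pass`)
#'   flags; only rows passing all available flags are aggregated.
#' @return A tibble with one row per (protein, run): `protein_id`,
#'   `sample_type`, `condition`, `fa_level`, `replicate`, `sample_id`,
#'   `protein_ratio`, `log2_ratio`, `n_peptides`.
#' @export
aggregate_proteins <- function(flagged) {
  df <- dplyr::filter(flagged, .data$ion_pass)
  if ("control_pass" %in% names(df)) {
    df <- dplyr::filter(df, .data$control_pass)
  }
  df |>
    dplyr::group_by(.data$protein_id, .data$sample_type, .data$condition,
                    .data$fa_level, .data$replicate, .data$sample_id) |>
    dplyr::summarise(
      protein_ratio = stats::median(.data$ratio_lh_norm),
      n_peptides = dplyr::n_distinct(.data$peptide_seq),
      .groups = "drop"
    ) |>
    dplyr::mutate(log2_ratio = log2(.data$protein_ratio))
}

#' Fit the empirical-Bayes variance prior by method of moments
#'
#' Models per-protein residual variances as draws from a scaled inverse
#' chi-square prior with `d0` prior degrees of freedom and prior variance
#' `s0_2`, and estimates both by the method of moments on the log scale:
#' with `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` for `d0` by monotone
#' root-finding on the trigamma function, and
#' `s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the observed
#' log-variance dispersion does not exceed its expected sampling dispersion,
#' `d0` is set to `d0_cap` ("effectively infinite" shrinkage).
#'
#' @param s2 Numeric vector of per-protein sample variances (> 0; zero or
#'   non-finite entries are dropped from the fit).
#' @param df Residual degrees of freedom, a scalar or a vector parallel to
#'   `s2`.
#' @param d0_cap Finite stand-in for an infinite prior df (default 1e6).
#' @return A list with elements `d0` and `s0_2`.
#' @export
fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  if (length(df) == 1) df <- rep(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  s2 <- s2[ok]
  df <- df[ok]
  if (length(s2) < 2) {
    stop("hyperparameter error: need >= 2 positive variances with df >= 1",
         call. = FALSE)
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- d0_cap
  } else {
    f <- function(d0) trigamma(d0 / 2) - evar
    lo <- 1e-3
    hi <- 1e7
    if (f(hi) > 0) {
      d0 <- hi # dispersion below anything resolvable on the bracket
    } else if (f(lo) < 0) {
      d0 <- lo
    } else {
      d0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }
    d0 <- min(d0, d0_cap)
  }
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated one-sample t-test on log2 ratios
#'
#' Shrinks the protein's sample variance toward the prior:
#' `s2_post = (d0 * s0_2 + d_g * s2_g) / (d0 + d_g)` with `d_g = n - 1`,
#' forms `t_mod = mean(y) / sqrt(s2_post / n)` and a two-sided p-value on
#' `d0 + d_g` degrees of freedom. With `d0 = 0` this is the classical
#' one-sample t-test; as `d0` grows, `s2_post` approaches `s0_2`.
#'
#' @param y Numeric vector of log2 ratios across replicates (length >= 2).
#' @param d0,s0_2 Prior degrees of freedom and prior variance, e.g. from
#'   [fit_variance_prior()].
#' @return A list with `mean_log2`, `s2_g`, `d_g`, `s2_post`, `t_mod`,
#'   `df`, `p`.
#' @examples
#' moderated_t_test(c(1.0, 1.2, 0.8, 1.0), d0 = 4, s0_2 = 0.04)
#' @export
moderated_t_test <- function(y, d0, s0_2) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 2) {
    stop("insufficient replicates: need >= 2 log2 ratios", call. = FALSE)
  }
  m <- mean(y)
  s2_g <- stats::var(y)
  d_g <- n - 1
  s2_post <- (d0 * s0_2 + d_g * s2_g) / (d0 + d_g)
  df <- d0 + d_g
  if (s2_post <= 0) {
    # degenerate: all mass at the mean
    t_mod <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_mod <- m / sqrt(s2_post / n)
    p <- 2 * stats::pt(-abs(t_mod), df = df)
  }
  list(mean_log2 = m, s2_g = s2_g, d_g = d_g, s2_post = s2_post,
       t_mod = t_mod, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_p_(i) = min_(j >= i) p_(j) * m / j`, clipped to 1, mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-protein moderated differential enrichment across sample types
#'
#' The full protein-level analysis for one or more (condition, FA) cells:
#' ion filters, optional peptide-level control-FC exclusion, median
#' aggregation, protein filters, then per cell a single empirical-Bayes
#' variance-prior fit pooling the residual variances of all three
#' sample-type groups, per-(protein, sample type) moderated one-sample
#' tests, and BH correction within each sample type's p-value vector.
#'
#' @param normalized Output of [normalize_runs()].
#' @param db Protein database tibble (for coverage), or `NULL` to use a
#'   report-provided `seq_coverage` column.
#' @param params A [filter_params()] object.
#' @param alpha Significance threshold on the BH-adjusted p-value
#'   (default 0.001).
#' @param fc_threshold Minimum enrichment fold for a significant call
#'   (default 2).
#' @param control_fc_scope Where the control-FC threshold acts:
#'   `"classifier"` (default) leaves peptides intact and lets
#'   [classify_interactors()] use `params$control_fc` as the control
#'   exclusion fold; `"peptide"` additionally removes control-inconsistent
#'   peptide ions from aggregation everywhere (see
#'   [apply_control_fc_filter()]).
#' @param per_group_prior If `TRUE`, fit a separate variance prior per
#'   sample type instead of one pooled fit per cell.
#' @param d0_cap Cap for the prior degrees of freedom.
#' @return A tibble with one row per (protein, sample type, condition, FA):
#'   estimates (`mean_log2`, `enrichment_fold`), moderated statistics
#'   (`s2_g`, `s2_post`, `t_mod`, `df`, `p`, `adj_p`), the fitted prior
#'   (`d0`, `s0_2`), detection metadata and the `significant` flag
#'   (`adj_p <= alpha & enrichment_fold >= fc_threshold`). The filter audit
#'   ledger is attached as attribute `"audit"`.
#' @export
run_differential <- function(normalized, db = NULL,
                             params = filter_params(),
                             alpha = 0.001, fc_threshold = 2,
                             control_fc_scope = c("classifier", "peptide"),
                             per_group_prior = FALSE,
                             d0_cap = 1e6) {
  control_fc_scope <- match.arg(control_fc_scope)
  flt <- apply_ion_filters(normalized, params)
  flagged <- flt$peptides
  audit <- flt$audit
  if (control_fc_scope == "peptide") {
    flagged <- apply_control_fc_filter(flagged, params$control_fc)
    audit <- dplyr::bind_rows(
      audit,
      new_audit_row("control_fc", "ion rows", sum(flagged$ion_pass),
                    sum(flagged$ion_pass & !flagged$control_pass))
    )
  }
  summary <- summarize_protein_groups(flagged, db)
  n_reps <- max(normalized$replicate)
  pf <- apply_protein_filters(summary, params, n_reps)
  audit <- dplyr::bind_rows(audit, pf$audit)
  surviving <- pf$summary |> dplyr::filter(.data$protein_pass)

  quants <- aggregate_proteins(flagged) |>
    dplyr::semi_join(surviving,
                     by = c("protein_id", "sample_type", "condition",
                            "fa_level"))

  cells <- dplyr::distinct(quants, .data$condition, .data$fa_level)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- quants |>
      dplyr::filter(.data$condition == cells$condition[i],
                    .data$fa_level == cells$fa_level[i])
    grouped <- cell |>
      dplyr::group_by(.data$protein_id, .data$sample_type) |>
      dplyr::summarise(y = list(.data$log2_ratio),
                       n_reps = dplyr::n(),
                       n_peptides_min = min(.data$n_peptides),
                       .groups = "drop")
    few <- grouped$n_reps < 2
    if (any(few)) {
      dropped <- grouped[few, ]
      for (st in unique(dropped$sample_type)) {
        if (all(grouped$n_reps[grouped$sample_type == st] < 2)) {
          warning("sample type ", st, " in (", cells$condition[i], ", ",
                  cells$fa_level[i],
                  ") has < 2 replicates for every protein; group skipped",
                  call. = FALSE)
        }
      }
      grouped <- grouped[!few, ]
    }
    if (nrow(grouped) == 0) next
    grouped$s2_g <- vapply(grouped$y, stats::var, numeric(1))
    grouped$d_g <- grouped$n_reps - 1

    fit_for <- function(rows) {
      prior <- tryCatch(
        fit_variance_prior(rows$s2_g, rows$d_g, d0_cap = d0_cap),
        error = function(e) {
          # all-degenerate variances (e.g. noiseless data): maximal
          # shrinkage toward a vanishing prior variance
          list(d0 = d0_cap, s0_2 = 1e-12)
        }
      )
      prior
    }
    if (per_group_prior) {
      grouped <- grouped |>
        dplyr::group_by(.data$sample_type) |>
        dplyr::group_modify(function(g, key) {
          prior <- fit_for(g)
          g$d0 <- prior$d0
          g$s0_2 <- prior$s0_2
          g
        }) |>
        dplyr::ungroup()
    } else {
      prior <- fit_for(grouped)
      grouped$d0 <- prior$d0
      grouped$s0_2 <- prior$s0_2
    }
    tests <- purrr::pmap(
      list(grouped$y, grouped$d0, grouped$s0_2),
      function(y, d0, s0_2) moderated_t_test(y, d0, s0_2)
    )
    res <- grouped |>
      dplyr::mutate(
        mean_log2 = vapply(tests, `[[`, numeric(1), "mean_log2"),
        s2_post = vapply(tests, `[[`, numeric(1), "s2_post"),
        t_mod = vapply(tests, `[[`, numeric(1), "t_mod"),
        df = vapply(tests, `[[`, numeric(1), "df"),
        p = vapply(tests, `[[`, numeric(1), "p"),
        enrichment_fold = 2^.data$mean_log2,
        condition = cells$condition[i],
        fa_level = cells$fa_level[i]
      ) |>
      dplyr::select(-"y") |>
      dplyr::group_by(.data$sample_type) |>
      dplyr::mutate(adj_p = bh_adjust(.data$p)) |>
      dplyr::ungroup() |>
      dplyr::mutate(significant = .data$adj_p <= alpha &
                      .data$enrichment_fold >= fc_threshold)
    out[[i]] <- res
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) {
    res <- res |>
      dplyr::left_join(
        dplyr::select(surviving, "protein_id", "sample_type", "condition",
                      "fa_level", "seq_coverage", "n_peptides"),
        by = c("protein_id", "sample_type", "condition", "fa_level")
      ) |>
      dplyr::select("protein_id", "sample_type", "condition", "fa_level",
                    "n_reps", "n_peptides", "n_peptides_min", "seq_coverage",
                    "mean_log2", "enrichment_fold", "s2_g", "s2_post",
                    "t_mod", "df", "p", "adj_p", "significant", "d0", "s0_2")
  }
  attr(res, "audit") <- audit
  res
}
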