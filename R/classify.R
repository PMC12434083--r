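#' Classify proteins into interactor statuses using the triple-sample logic
#'
#' Turns the three per-sample-type enrichment tables of one analysis cell
#' into a classified interactor list. Every protein in the union universe of
#' the three tables receives exactly one status, assigned in order:
#'
#' 1. `bait` - the configured bait accession, regardless of controls;
#' 2. `excluded_wt_control` ("red") - significantly enriched in the `WT_WT`
#'    nonspecific-binding control;
#' 3. `excluded_bait_control` ("yellow") - significantly enriched in the
#'    `BAIT_BAIT` labeling/tag control (the biotinylated-carboxylase type of
#'    case: enriched in the experiment but also in the bait control);
#' 4. `candidate` - significantly enriched in `BAIT_WT` and in neither
#'    control;
#' 5. `not_significant` otherwise.
#'
#' "Significantly enriched" in a control uses the same rule shape as in the
#' experiment - BH-adjusted p at most `control_alpha` and fold at least
#' `control_fc` - so that merely detected nonspecific binders sitting at
#' ratio 1 are never excluded.
#'
#' @param results Enrichment table from [run_differential()], covering one
#'   or more (condition, FA) cells; classification is per cell. Absence of a
#'   protein from a control table is treated as not enriched there.
#' @param bait_id Bait protein accession.
#' @param alpha,fc_threshold Significance rule for the experiment sample
#'   (defaults 0.001 and 2).
#' @param control_alpha,control_fc Significance rule for the controls
#'   (default: same alpha; fold threshold defaults to `fc_threshold`, and
#'   the pipeline passes its `control_fc` filter parameter here).
#' @return A tibble with one row per (protein, condition, FA): `status`,
#'   `reason`, and the fold/adjusted-p of all three sample types.
#' @export
classify_interactors <- function(results, bait_id,
                                 alpha = 0.001, fc_threshold = 2,
                                 control_alpha = alpha,
                                 control_fc = fc_threshold) {
  cells <- dplyr::distinct(results, .data$condition, .data$fa_level)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- results |>
      dplyr::filter(.data$condition == cells$condition[i],
                    .data$fa_level == cells$fa_level[i])
    if (!bait_id %in% cell$protein_id[cell$sample_type == "BAIT_WT"]) {
      warning("bait ", bait_id, " absent from BAIT_WT results in (",
              cells$condition[i], ", ", cells$fa_level[i],
              "); it may have been lost by filtering - consider tune_filters()",
              call. = FALSE)
    }
    wide <- cell |>
      dplyr::select("protein_id", "sample_type", "enrichment_fold", "adj_p") |>
      tidyr::pivot_wider(names_from = "sample_type",
                         values_from = c("enrichment_fold", "adj_p"))
    for (col in c("enrichment_fold_WT_WT", "adj_p_WT_WT",
                  "enrichment_fold_BAIT_WT", "adj_p_BAIT_WT",
                  "enrichment_fold_BAIT_BAIT", "adj_p_BAIT_BAIT")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
    }
    enr <- function(fold, adj, a, fc) {
      !is.na(fold) & !is.na(adj) & adj <= a & fold >= fc
    }
    wide <- wide |>
      dplyr::mutate(
        sig_exp = enr(.data$enrichment_fold_BAIT_WT, .data$adj_p_BAIT_WT,
                      alpha, fc_threshold),
        sig_wt = enr(.data$enrichment_fold_WT_WT, .data$adj_p_WT_WT,
                     control_alpha, control_fc),
        sig_bb = enr(.data$enrichment_fold_BAIT_BAIT, .data$adj_p_BAIT_BAIT,
                     control_alpha, control_fc),
        status = dplyr::case_when(
          .data$protein_id == bait_id ~ "bait",
          .data$sig_wt ~ "excluded_wt_control",
          .data$sig_bb ~ "excluded_bait_control",
          .data$sig_exp ~ "candidate",
          TRUE ~ "not_significant"
        ),
        reason = dplyr::case_when(
          .data$status == "bait" ~ "configured bait accession",
          .data$status == "excluded_wt_control" ~
            "enriched in WT/WT nonspecific-binding control",
          .data$status == "excluded_bait_control" ~
            "enriched in Bait/Bait labeling control",
          .data$status == "candidate" ~
            "enriched in Bait/WT only: specific interactor candidate",
          TRUE ~ "no significant enrichment in Bait/WT"
        ),
        condition = cells$condition[i],
        fa_level = cells$fa_level[i]
      )
    out[[i]] <- wide
  }
  dplyr::bind_rows(out) |>
    dplyr::select("protein_id", "condition", "fa_level", "status", "reason",
                  bait_wt_fold = "enrichment_fold_BAIT_WT",
                  bait_wt_adj_p = "adj_p_BAIT_WT",
                  wt_wt_fold = "enrichment_fold_WT_WT",
                  wt_wt_adj_p = "adj_p_WT_WT",
                  bait_bait_fold = "enrichment_fold_BAIT_BAIT",
                  bait_bait_adj_p = "adj_p_BAIT_BAIT")
}

#' Moderated contrast of bait enrichment between two conditions
#'
#' Compares each protein's `BAIT_WT` log2 enrichment between two conditions
#' with a moderated two-group contrast: the difference of the group means,
#' its standard error from the posterior variances pooled by residual
#' degrees of freedom, a t-statistic on the combined degrees of freedom
#' (both groups' residual df plus one prior df contribution), and BH
#' adjustment within the contrast vector. Swapping the conditions negates
#' every contrast.
#'
#' @param results Enrichment table from [run_differential()] containing
#'   both conditions at one FA level.
#' @param condition_a,condition_b Condition labels to contrast (A - B).
#' @param sample_type Sample type to contrast within (default `BAIT_WT`).
#' @return A tibble with one row per protein in the union of the two
#'   conditions: `contrast` (`mean_log2_a - mean_log2_b`), `t_contrast`,
#'   `df`, `p`, `adj_p`, and `in_both` flagging proteins present in both
#'   conditions (the contrast is `NA` otherwise).
#' @export
compare_conditions <- function(results, condition_a, condition_b,
                               sample_type = "BAIT_WT") {
  pick <- function(cond) {
    results |>
      dplyr::filter(.data$sample_type == !!sample_type,
                    .data$condition == cond) |>
      dplyr::select("protein_id", "mean_log2", "s2_post", "d_g" = "df",
                    "n_reps", "d0")
  }
  a <- pick(condition_a) |>
    dplyr::mutate(d_g = .data$d_g - .data$d0)
  b <- pick(condition_b) |>
    dplyr::mutate(d_g = .data$d_g - .data$d0)
  joined <- dplyr::full_join(a, b, by = "protein_id",
                             suffix = c("_a", "_b"))
  joined |>
    dplyr::mutate(
      in_both = !is.na(.data$mean_log2_a) & !is.na(.data$mean_log2_b),
      contrast = .data$mean_log2_a - .data$mean_log2_b,
      s2_pool = (.data$d_g_a * .data$s2_post_a +
                   .data$d_g_b * .data$s2_post_b) /
        (.data$d_g_a + .data$d_g_b),
      se = sqrt(.data$s2_pool * (1 / .data$n_reps_a + 1 / .data$n_reps_b)),
      # the prior df contribution enters once, symmetrically in the two
      # per-condition fits
      df = .data$d_g_a + .data$d_g_b + (.data$d0_a + .data$d0_b) / 2,
      t_contrast = .data$contrast / .data$se,
      p = 2 * stats::pt(-abs(.data$t_contrast), df = .data$df)
    ) |>
    dplyr::mutate(
      adj_p = dplyr::if_else(.data$in_both, NA_real_, NA_real_)
    ) |>
    (\(d) {
      ok <- d$in_both & is.finite(d$p)
      d$adj_p[ok] <- bh_adjust(d$p[ok])
      d
    })() |>
    dplyr::select("protein_id", "in_both", "contrast", "t_contrast", "df",
                  "p", "adj_p",
                  mean_log2_a = "mean_log2_a", mean_log2_b = "mean_log2_b")
}
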