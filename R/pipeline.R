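#' Run the full quantification pipeline end to end
#'
#' Orchestrates ingest, normalization, filtering, protein-level moderated
#' statistics and interactor classification, and writes all result
#' artifacts: `normalized_peptides.tsv`, `enrichment_results.tsv`,
#' `interactors.tsv`, `filter_audit.tsv` and a `run_metadata.json` sidecar
#' echoing every effective parameter and the ingest rejection counts.
#' Re-running on identical inputs produces byte-identical outputs.
#'
#' @param report Peptide report: a path to a TSV or an in-memory tibble.
#' @param sample_sheet Sample sheet: a path or a tibble from
#'   [enumerate_samples()].
#' @param fasta Protein database: a FASTA path, a tibble from
#'   [read_fasta()], or `NULL` to use a report-provided coverage column.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param bait_id Bait accession for classification (`NULL` to skip
#'   classification).
#' @param params A [filter_params()] object.
#' @param alpha,fc_threshold Significance rule (defaults 0.001 and 2).
#' @param column_map Column mapping for file-based reports.
#' @param control_fc_scope See [run_differential()].
#' @return A list with `normalized`, `results`, `interactors`, `audit`,
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(report, sample_sheet, fasta = NULL, out_dir = NULL,
                         bait_id = NULL, params = filter_params(),
                         alpha = 0.001, fc_threshold = 2,
                         column_map = default_column_map(),
                         control_fc_scope = c("classifier", "peptide")) {
  control_fc_scope <- match.arg(control_fc_scope)
  peptides <- if (is.character(report)) {
    read_peptide_report(report, column_map)
  } else {
    validate_peptide_measurements(report)
  }
  sheet <- if (is.character(sample_sheet)) {
    read_sample_sheet(sample_sheet)
  } else {
    sample_sheet
  }
  db <- if (is.character(fasta)) read_fasta(fasta) else fasta

  normalized <- normalize_runs(peptides, sheet,
                               q_value_max = params$q_value_max,
                               ion_cv_max = params$ion_cv_max)
  results <- run_differential(normalized, db, params, alpha = alpha,
                              fc_threshold = fc_threshold,
                              control_fc_scope = control_fc_scope)
  interactors <- if (!is.null(bait_id)) {
    classify_interactors(results, bait_id, alpha = alpha,
                         fc_threshold = fc_threshold,
                         control_fc = params$control_fc)
  } else {
    NULL
  }
  audit <- attr(results, "audit")

  out <- list(normalized = normalized, results = results,
              interactors = interactors, audit = audit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(normalized, file.path(out_dir, "normalized_peptides.tsv"))
    write_result_table(results, file.path(out_dir, "enrichment_results.tsv"))
    if (!is.null(interactors)) {
      write_result_table(interactors, file.path(out_dir, "interactors.tsv"))
    }
    write_result_table(audit, file.path(out_dir, "filter_audit.tsv"))
    meta <- list(
      package = "isopull",
      version = as.character(utils::packageVersion("isopull")),
      parameters = c(unclass(params),
                     list(alpha = alpha, fc_threshold = fc_threshold,
                          control_fc_scope = control_fc_scope,
                          bait_id = bait_id)),
      n_runs = length(unique(peptides$sample_id)),
      n_peptide_rows = nrow(peptides),
      ingest_rejections = as.list(attr(peptides, "rejections"))
    )
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Volcano plot of protein enrichment
#'
#' One panel per sample type: log2 enrichment on the x-axis,
#' -log10 adjusted p on the y-axis, with the significance and fold
#' thresholds drawn as reference lines.
#'
#' @param results Enrichment table from [run_differential()].
#' @param alpha,fc_threshold Thresholds to draw (defaults 0.001 and 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.001, fc_threshold = 2) {
  df <- results |>
    dplyr::mutate(neg_log10_adj_p = -log10(pmax(.data$adj_p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_log2,
                                   y = .data$neg_log10_adj_p,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(fc_threshold), linetype = "solid") +
    ggplot2::facet_wrap(~sample_type) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d94801",
                                           `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 enrichment (L/H)",
                  y = "-log10 adjusted p-value") +
    ggplot2::theme_bw()
}
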