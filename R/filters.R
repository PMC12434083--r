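#' Stringent filter parameter set
#'
#' The threshold set driving ion- and protein-level filtering, with the
#' standard initial values of the workflow. Boundary conventions (documented
#' constants of the implementation): q-value passes when `<=` the cutoff;
#' ion CV passes when strictly `<` its threshold ("CVs must be smaller");
#' sequence coverage passes when strictly `>` its threshold ("coverage must
#' be greater"); peptide count and completeness use `>=`; the control-FC
#' rule flags strictly `>` `control_fc`-fold deviations.
#'
#' @param control_fc Fold threshold for the control-consistency rule
#'   (default 2): control-sample observations deviating from 1 by more than
#'   this factor are flagged.
#' @param q_value_max Ion q-value cutoff (default 0.01).
#' @param ion_cv_max Ion CV threshold across replicates (default 0.2).
#' @param data_completeness Fraction of replicates a protein must be detected
#'   in (default 1 = all replicates).
#' @param seq_coverage_min Sequence coverage threshold in percent
#'   (default 40).
#' @param num_peptides_min Minimum distinct peptides per protein (default 2).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(control_fc = 2,
                          q_value_max = 0.01,
                          ion_cv_max = 0.2,
                          data_completeness = 1,
                          seq_coverage_min = 40,
                          num_peptides_min = 2) {
  stopifnot(control_fc >= 1,
            q_value_max > 0, q_value_max <= 1,
            ion_cv_max > 0,
            data_completeness > 0, data_completeness <= 1,
            seq_coverage_min >= 0, seq_coverage_min <= 100,
            num_peptides_min >= 1)
  structure(
    list(control_fc = control_fc,
         q_value_max = q_value_max,
         ion_cv_max = ion_cv_max,
         data_completeness = data_completeness,
         seq_coverage_min = seq_coverage_min,
         num_peptides_min = as.integer(num_peptides_min)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat("Filter parameters:\n")
  for (nm in names(x)) cat("  ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

new_audit_row <- function(filter, scope, n_tested, n_failed) {
  tibble::tibble(filter = filter, scope = scope,
                 n_tested = as.integer(n_tested),
                 n_failed = as.integer(n_failed),
                 n_surviving = as.integer(n_tested - n_failed))
}

#' Apply ion-level quality filters
#'
#' A peptide ion observation passes iff its q-value is `<=` `q_value_max`
#' and its ion CV (sd/mean of the normalized L/H ratio across the
#' replicates of its condition) is strictly `<` `ion_cv_max`. Ions whose CV
#' is undefined (fewer than two replicate observations) fail. Pass/fail is
#' recorded per row, nothing is deleted.
#'
#' @param normalized Output of [normalize_runs()].
#' @param params A [filter_params()] object.
#' @return A list with `peptides` (input plus `norm_cv`, `q_pass`,
#'   `cv_pass`, `ion_pass`) and `audit` (a filter ledger tibble).
#' @export
apply_ion_filters <- function(normalized, params = filter_params()) {
  df <- normalized |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ION_GROUP_KEY))) |>
    dplyr::mutate(norm_cv = ion_cv(.data$ratio_lh_norm)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      q_pass = .data$q_value <= params$q_value_max,
      cv_pass = !is.na(.data$norm_cv) & .data$norm_cv < params$ion_cv_max,
      ion_pass = .data$q_pass & .data$cv_pass
    )
  audit <- dplyr::bind_rows(
    new_audit_row("q_value", "ion rows", nrow(df), sum(!df$q_pass)),
    new_audit_row("ion_cv", "ion rows", sum(df$q_pass),
                  sum(df$q_pass & !df$cv_pass))
  )
  list(peptides = df, audit = audit)
}

#' Flag peptides with dissimilar control-sample ratios
#'
#' A peptide ion is deemed unreliable if, in any replicate of a control
#' sample type (`WT_WT` or `BAIT_BAIT`) of its condition/FA cell, its
#' normalized L/H ratio deviates from 1 by strictly more than `control_fc`
#' fold (i.e. `|log2(ratio)| > log2(control_fc)`). The flag applies to that
#' peptide ion in every sample type of the cell.
#'
#' Note this peptide-level rule is one of two homes for the control-FC
#' threshold; by default the pipeline applies `control_fc` in the
#' protein-level control-exclusion logic instead (see the
#' `control_fc_scope` argument of [run_differential()] and the methods
#' vignette), because a global peptide exclusion would also erase the
#' control-enrichment signal that the classifier's exclusion statuses are
#' built from.
#'
#' @param normalized Output of [normalize_runs()] (or of
#'   [apply_ion_filters()]`$peptides`).
#' @param control_fc Fold threshold (default 2).
#' @return The input with an added logical `control_pass` column.
#' @export
apply_control_fc_filter <- function(normalized, control_fc = 2) {
  key <- c("protein_id", "peptide_seq", "condition", "fa_level")
  viol <- normalized |>
    dplyr::filter(.data$sample_type %in% c("WT_WT", "BAIT_BAIT"),
                  abs(log2(.data$ratio_lh_norm)) > log2(control_fc)) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(key))) |>
    dplyr::mutate(control_pass = FALSE)
  normalized |>
    dplyr::left_join(viol, by = key) |>
    dplyr::mutate(control_pass = dplyr::coalesce(.data$control_pass, TRUE))
}

#' Apply protein-level filters
#'
#' A protein survives for one (sample type, condition, FA) group iff it is
#' detected (>= 1 ion-passing peptide observation) in at least
#' `ceiling(data_completeness * n_replicates)` replicates, has at least
#' `num_peptides_min` distinct ion-passing peptide sequences in the group,
#' and its sequence coverage exceeds `seq_coverage_min` percent. Coverage is
#' recomputed from the protein database using the protein's q-passing
#' detected peptides (an identification-quality metric, deliberately not
#' conditioned on the CV filter).
#'
#' @param summary Protein-group summary from [summarize_protein_groups()].
#' @param params A [filter_params()] object.
#' @param n_replicates Number of replicates in the design.
#' @return A list with `summary` (input plus pass flags and `protein_pass`)
#'   and `audit`.
#' @export
apply_protein_filters <- function(summary, params, n_replicates) {
  need <- ceiling(params$data_completeness * n_replicates)
  df <- summary |>
    dplyr::mutate(
      completeness_pass = .data$n_reps_detected >= need,
      num_peptides_pass = .data$n_peptides >= params$num_peptides_min,
      coverage_pass = .data$seq_coverage > params$seq_coverage_min,
      protein_pass = .data$completeness_pass & .data$num_peptides_pass &
        .data$coverage_pass
    )
  audit <- dplyr::bind_rows(
    new_audit_row("data_completeness", "protein groups", nrow(df),
                  sum(!df$completeness_pass)),
    new_audit_row("num_peptides", "protein groups", sum(df$completeness_pass),
                  sum(df$completeness_pass & !df$num_peptides_pass)),
    new_audit_row("seq_coverage", "protein groups",
                  sum(df$completeness_pass & df$num_peptides_pass),
                  sum(df$completeness_pass & df$num_peptides_pass &
                        !df$coverage_pass))
  )
  list(summary = df, audit = audit)
}

#' Summarize protein detection per analysis group
#'
#' Builds the per-(protein, sample type, condition, FA) summary feeding the
#' protein-level filters: replicates detected, distinct ion-passing
#' peptides, and sequence coverage recomputed from the FASTA database (or
#' taken from a report-provided column when `db` is `NULL` and a
#' `seq_coverage` column is present).
#'
#' @param flagged Output of [apply_ion_filters()]`$peptides`.
#' @param db Protein database tibble from [read_fasta()], or `NULL`.
#' @return A tibble with one row per protein group.
#' @export
summarize_protein_groups <- function(flagged, db = NULL) {
  grp <- c("protein_id", "sample_type", "condition", "fa_level")
  det <- flagged |>
    dplyr::filter(.data$ion_pass) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_reps_detected = dplyr::n_distinct(.data$replicate),
                     n_peptides = dplyr::n_distinct(.data$peptide_seq),
                     .groups = "drop")
  cov <- flagged |>
    dplyr::filter(.data$q_pass) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(grp, "peptide_seq"))))
  if (is.null(db)) {
    if (!"seq_coverage" %in% names(flagged)) {
      stop("configuration error: no protein database given and the report ",
           "carries no seq_coverage column", call. = FALSE)
    }
    covs <- flagged |>
      dplyr::distinct(dplyr::across(dplyr::all_of(grp)), .data$seq_coverage) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(seq_coverage = max(.data$seq_coverage), .groups = "drop")
  } else {
    missing_prot <- setdiff(unique(cov$protein_id), db$protein_id)
    if (length(missing_prot) > 0) {
      stop("configuration error: accession(s) absent from protein database: ",
           paste(utils::head(missing_prot, 5), collapse = ", "), call. = FALSE)
    }
    seq_of <- stats::setNames(db$sequence, db$protein_id)
    covs <- cov |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        seq_coverage = compute_sequence_coverage(
          seq_of[[.data$protein_id[1]]], .data$peptide_seq),
        .groups = "drop"
      )
  }
  dplyr::left_join(det, covs, by = grp)
}

#' Tune ion-CV and coverage thresholds until the bait survives
#'
#' Starting from the stringent initial thresholds, walks an ordered grid of
#' (sequence coverage, ion CV) pairs from most to least stringent - sorted
#' by coverage threshold descending, then CV threshold ascending - and
#' returns the first pair under which the bait protein passes all ion- and
#' protein-level filters in every `BAIT_WT` analysis group (hence is
#' detected in every replicate). This mirrors the iterative relaxation used
#' to keep the bait in the result set while staying as stringent as
#' possible.
#'
#' @param peptides Peptide measurements (pre-normalization).
#' @param sample_sheet Sample sheet for the runs in `peptides`.
#' @param db Protein database tibble (for coverage), or `NULL`.
#' @param bait_id Bait protein accession.
#' @param params Base [filter_params()]; tuned fields are overwritten.
#' @param cv_grid Candidate `ion_cv_max` values, most stringent first.
#' @param seqcov_grid Candidate `seq_coverage_min` values, most stringent
#'   first.
#' @return A list with `params` (the tuned [filter_params()]) and `trace`
#'   (a tibble of every tried pair with the bait's first failing filter).
#' @export
tune_filters <- function(peptides, sample_sheet, db, bait_id,
                         params = filter_params(),
                         cv_grid = c(0.2, 0.25, 0.3),
                         seqcov_grid = c(40, 35, 30)) {
  if (!is.null(db) && !bait_id %in% db$protein_id) {
    stop("bait accession not in protein database: ", bait_id, call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    seq_coverage_min = sort(seqcov_grid, decreasing = TRUE),
    ion_cv_max = sort(cv_grid)
  )
  n_reps <- max(sample_sheet$replicate)
  trace <- list()
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$seq_coverage_min <- grid$seq_coverage_min[i]
    p$ion_cv_max <- grid$ion_cv_max[i]
    failing <- bait_failing_filter(peptides, sample_sheet, db, bait_id, p,
                                   n_reps)
    trace[[i]] <- tibble::tibble(seq_coverage_min = p$seq_coverage_min,
                                 ion_cv_max = p$ion_cv_max,
                                 feasible = is.na(failing),
                                 bait_failing_filter = failing)
    if (is.na(failing)) {
      return(list(params = p, trace = dplyr::bind_rows(trace)))
    }
  }
  trace <- dplyr::bind_rows(trace)
  msg <- paste0("tuning failure: bait ", bait_id,
                " never survives the filter grid")
  cond <- simpleError(msg)
  cond$trace <- trace
  stop(cond)
}

# First filter the bait fails in BAIT_WT under `p`, or NA if it survives.
bait_failing_filter <- function(peptides, sample_sheet, db, bait_id, p,
                                n_reps) {
  norm <- normalize_runs(peptides, sample_sheet,
                         q_value_max = p$q_value_max,
                         ion_cv_max = p$ion_cv_max)
  flagged <- apply_ion_filters(norm, p)$peptides
  bw <- flagged |> dplyr::filter(.data$sample_type == "BAIT_WT",
                                 .data$protein_id == bait_id)
  if (nrow(bw) == 0) return("not_detected")
  if (!any(bw$ion_pass)) {
    return(if (any(bw$q_pass)) "ion_cv" else "q_value")
  }
  summ <- summarize_protein_groups(flagged, db) |>
    dplyr::filter(.data$sample_type == "BAIT_WT",
                  .data$protein_id == bait_id)
  prot <- apply_protein_filters(summ, p, n_reps)$summary
  if (nrow(prot) == 0) return("not_detected")
  if (!all(prot$completeness_pass)) return("data_completeness")
  if (!all(prot$num_peptides_pass)) return("num_peptides")
  if (!all(prot$coverage_pass)) return("seq_coverage")
  NA_character_
}
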