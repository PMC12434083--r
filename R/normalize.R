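#' Invert exported heavy/light ratios to light/heavy
#'
#' The search engine exports H/L ratios; the analysis keeps the light (14N)
#' channel in the numerator, so ratios are inverted (1 / (H/L)) before
#' normalization.
#'
#' @param ratio_hl Numeric vector of positive, finite H/L ratios.
#' @return `1 / ratio_hl`.
#' @examples
#' invert_ratio(c(0.5, 1, 4)) # 2, 1, 0.25
#' @export
invert_ratio <- function(ratio_hl) {
  if (!is.numeric(ratio_hl) || length(ratio_hl) == 0) {
    stop("ratio_hl must be numeric", call. = FALSE)
  }
  if (any(!is.finite(ratio_hl)) || any(ratio_hl <= 0)) {
    stop("ratio_hl must be positive and finite", call. = FALSE)
  }
  1 / ratio_hl
}

#' Coefficient of variation of an ion's ratios across replicates
#'
#' Sample standard deviation (n - 1 denominator) over the mean, on the linear
#' ratio scale. Undefined (NA) for fewer than two observations; downstream
#' filters treat an undefined CV as a failure.
#'
#' @param ratios Numeric vector of ratios for one peptide ion across the
#'   biological replicates of one condition.
#' @return `sd(ratios) / mean(ratios)`, or `NA_real_` when `length < 2`.
#' @examples
#' ion_cv(c(0.9, 1.0, 1.1)) # 0.1
#' @export
ion_cv <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) return(NA_real_)
  stats::sd(ratios) / mean(ratios)
}

#' Run-specific normalization factor
#'
#' The median L/H ratio of the QC-passing peptides of one run. Dividing every
#' peptide ratio of the run by this factor centers the nonspecific background
#' on 1 and corrects minor pellet-mixing errors. Even-count medians are the
#' arithmetic mean of the two central order statistics.
#'
#' @param ratio_lh Numeric vector of QC-passing L/H ratios for one run.
#' @param sample_id Run label used in the error message when the run has no
#'   usable peptide.
#' @return The median, a positive scalar.
#' @examples
#' normalization_factor(c(0.5, 1, 2, 4)) # 1.5
#' @export
normalization_factor <- function(ratio_lh, sample_id = "<run>") {
  ratio_lh <- ratio_lh[is.finite(ratio_lh)]
  if (length(ratio_lh) == 0) {
    stop("normalization error: no QC-passing peptides in run ", sample_id,
         call. = FALSE)
  }
  stats::median(ratio_lh)
}

# Group key used for ion CVs: one peptide ion within one condition, across
# biological replicates.
ION_GROUP_KEY <- c("protein_id", "peptide_seq", "sample_type", "condition",
                   "fa_level")

#' Invert and median-normalize peptide ratios per run
#'
#' For every run (`sample_id`) the exported H/L ratios are inverted to L/H
#' and a QC set is formed in two passes: (1) q-value filter, then a
#' provisional per-run centering by the median L/H of the q-passing
#' peptides; (2) an ion-CV filter computed on the provisionally centered
#' ratios across replicates. The run's normalization factor is the median
#' L/H (original scale) of the resulting QC set, and every peptide of the
#' run - including QC failures, whose status is carried for audit - is
#' divided by it. The provisional centering exists because an ion CV taken
#' on uncentered ratios would be confounded with the very run-level mixing
#' shifts the factor must estimate, biasing it toward 1; centering first
#' makes the CV a pure replicate-noise measure.
#'
#' @param peptides Peptide measurement tibble (see [read_peptide_report()]).
#' @param sample_sheet Sample sheet from [enumerate_samples()]; joined on
#'   `sample_id` to supply `sample_type`, `condition`, `fa_level`,
#'   `replicate`.
#' @param q_value_max Ion q-value cutoff feeding the QC set (default 0.01).
#' @param ion_cv_max Ion CV threshold feeding the QC set; pass iff CV is
#'   strictly smaller (default 0.2).
#' @return The input tibble with added columns `ratio_lh`, `qc_cv` (the
#'   centered QC ion CV), `qc_pass`, `norm_factor`, `ratio_lh_norm`.
#' @export
normalize_runs <- function(peptides, sample_sheet,
                           q_value_max = 0.01, ion_cv_max = 0.2) {
  unknown <- setdiff(unique(peptides$sample_id), sample_sheet$sample_id)
  if (length(unknown) > 0) {
    stop("sample_id(s) absent from sample sheet: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  df <- peptides |>
    dplyr::inner_join(
      dplyr::select(sample_sheet, "sample_id", "sample_type", "condition",
                    "fa_level", "replicate"),
      by = "sample_id"
    ) |>
    dplyr::mutate(ratio_lh = invert_ratio(.data$ratio_hl),
                  q_pass = .data$q_value <= q_value_max)

  df <- df |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(provisional_factor = normalization_factor(
      .data$ratio_lh[.data$q_pass], .data$sample_id[1])) |>
    dplyr::ungroup() |>
    dplyr::mutate(ratio_lh_centered = .data$ratio_lh /
                    .data$provisional_factor) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ION_GROUP_KEY))) |>
    dplyr::mutate(qc_cv = ion_cv(.data$ratio_lh_centered[.data$q_pass])) |>
    dplyr::ungroup() |>
    dplyr::mutate(qc_pass = .data$q_pass & !is.na(.data$qc_cv) &
                    .data$qc_cv < ion_cv_max)

  factors <- df |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      norm_factor = normalization_factor(.data$ratio_lh[.data$qc_pass],
                                         .data$sample_id[1]),
      .groups = "drop"
    )
  df |>
    dplyr::left_join(factors, by = "sample_id") |>
    dplyr::mutate(ratio_lh_norm = .data$ratio_lh / .data$norm_factor) |>
    dplyr::select(-"q_pass", -"provisional_factor", -"ratio_lh_centered")
}
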