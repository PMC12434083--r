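#' @importFrom rlang .data
NULL

#' Sample types of the triple-sample pull-down design
#'
#' The design mixes differentially labeled cell pellets three ways:
#' `WT_WT` (light WT + heavy WT; nonspecific-binding control), `BAIT_WT`
#' (light bait strain + heavy WT; the experiment, where the bait and its
#' crosslinked partners are enriched in the light channel) and `BAIT_BAIT`
#' (light bait + heavy bait; labeling/tag control in which every protein,
#' including the bait, sits at L/H ratio 1).
#'
#' @export
SAMPLE_TYPES <- c("WT_WT", "BAIT_WT", "BAIT_BAIT")

#' Enumerate the full factorial sample sheet of a triple-sample experiment
#'
#' Expands conditions x formaldehyde levels x replicates x the three sample
#' types into an ordered sample sheet. Within each condition/FA cell the
#' ordering is replicate-major, and within a replicate the three mixes appear
#' in the order `WT_WT`, `BAIT_WT`, `BAIT_BAIT` (the mixing-table row order).
#'
#' @param conditions Character vector of condition labels (e.g. `"control"`,
#'   `"etoh_stress"`). Must be non-empty and duplicate-free.
#' @param fa_levels Character vector of formaldehyde crosslinker levels
#'   (metadata only, e.g. `"fa_0.2"` for 0.2 percent w/v).
#' @param n_replicates Number of biological replicates (>= 1).
#' @param wt_label,bait_label Strain labels used to fill the light/heavy
#'   channel columns; only the WT/bait roles are enforced, the labels are free.
#' @param swap_labels If `TRUE`, swap the light and heavy channel strains
#'   (a reciprocal, label-swapped layout). Off by default: the light channel
#'   carries the bait strain in `BAIT_WT`.
#'
#' @return A tibble with columns `sample_id`, `sample_type`, `condition`,
#'   `fa_level`, `replicate`, `light_strain`, `heavy_strain`; one row per run.
#'   `sample_id` is `"{sample_type}_{condition}_{fa_level}_BR{replicate}"`.
#'
#' @examples
#' nrow(enumerate_samples(c("control", "etoh_stress"), c("fa_0.2", "fa_0.4"), 4))
#' @export
enumerate_samples <- function(conditions = "control",
                              fa_levels = "fa_0.2",
                              n_replicates = 4,
                              wt_label = "WT",
                              bait_label = "Bait",
                              swap_labels = FALSE) {
  conditions <- unique(as.character(conditions))
  fa_levels <- unique(as.character(fa_levels))
  if (length(conditions) < 1 || length(fa_levels) < 1) {
    stop("invalid design: 'conditions' and 'fa_levels' must be non-empty",
         call. = FALSE)
  }
  if (length(n_replicates) != 1 || is.na(n_replicates) ||
      n_replicates < 1 || n_replicates != as.integer(n_replicates)) {
    stop("invalid design: 'n_replicates' must be an integer >= 1",
         call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)

  sheet <- tidyr::expand_grid(
    condition = conditions,
    fa_level = fa_levels,
    replicate = seq_len(n_replicates),
    sample_type = SAMPLE_TYPES
  )
  light <- c(WT_WT = wt_label, BAIT_WT = bait_label, BAIT_BAIT = bait_label)
  heavy <- c(WT_WT = wt_label, BAIT_WT = wt_label, BAIT_BAIT = bait_label)
  if (swap_labels) {
    tmp <- light
    light <- heavy
    heavy <- tmp
  }
  sheet |>
    dplyr::mutate(
      light_strain = unname(light[.data$sample_type]),
      heavy_strain = unname(heavy[.data$sample_type]),
      sample_id = paste0(.data$sample_type, "_", .data$condition, "_",
                         .data$fa_level, "_BR", .data$replicate)
    ) |>
    dplyr::select("sample_id", "sample_type", "condition", "fa_level",
                  "replicate", "light_strain", "heavy_strain")
}

#' Write a sample sheet as TSV
#'
#' @param sheet A sample sheet from [enumerate_samples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path)
  invisible(path)
}

#' Read a sample sheet written by [write_sample_sheet()]
#'
#' @param path TSV file path.
#' @return A sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(replicate = "i",
                                                   .default = "c"))
  required <- c("sample_id", "sample_type", "condition", "fa_level",
                "replicate", "light_strain", "heavy_strain")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(sheet$sample_type), SAMPLE_TYPES)
  if (length(bad) > 0) {
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sheet
}
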