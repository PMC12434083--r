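#' Nitrogen atoms per amino-acid residue
#'
#' Element counts of the water-loss residue (backbone amide nitrogen
#' included): one nitrogen for most residues, two for K/Q/N/W, three for
#' histidine, four for arginine. Uniform 15N metabolic labeling replaces
#' every one of these nitrogens, so a peptide's heavy-channel mass shift is
#' proportional to its total nitrogen count.
#'
#' @export
RESIDUE_NITROGEN <- c(
  G = 1L, A = 1L, S = 1L, P = 1L, V = 1L, T = 1L, C = 1L, L = 1L, I = 1L,
  M = 1L, F = 1L, Y = 1L, E = 1L, D = 1L,
  K = 2L, Q = 2L, N = 2L, W = 2L,
  H = 3L,
  R = 4L
)

#' Mass difference between 15N and 14N in Da
#'
#' The exact isotopic mass difference (0.9970349 Da) is used everywhere;
#' the popular "1 Da per nitrogen" is an approximation of this constant.
#' @export
DELTA_M_15N <- 0.9970349

#' Proton mass in Da (for m/z arithmetic)
#' @export
PROTON_MASS <- 1.007276466

check_canonical <- function(peptide_seq) {
  chars <- strsplit(peptide_seq, "")[[1]]
  bad <- which(!chars %in% names(RESIDUE_NITROGEN))
  if (length(bad) > 0) {
    stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1],
         " of peptide ", peptide_seq, call. = FALSE)
  }
  chars
}

#' Total nitrogen count of a peptide
#'
#' @param peptide_seq Peptide sequence over the 20 canonical letters.
#' @return Integer number of nitrogen atoms.
#' @examples
#' nitrogen_count("GG") # 2 backbone nitrogens
#' nitrogen_count("R")  # 4
#' @export
nitrogen_count <- function(peptide_seq) {
  stopifnot(length(peptide_seq) == 1, is.character(peptide_seq))
  chars <- check_canonical(peptide_seq)
  sum(RESIDUE_NITROGEN[chars])
}

#' Heavy-channel mass shift of a uniformly 15N-labeled peptide
#'
#' @param peptide_seq Peptide sequence.
#' @return Mass shift in Da: `nitrogen_count(peptide_seq) * DELTA_M_15N`.
#' @examples
#' heavy_mass_shift("GG") # 1.9940698
#' @export
heavy_mass_shift <- function(peptide_seq) {
  nitrogen_count(peptide_seq) * DELTA_M_15N
}

#' Predicted heavy precursor m/z
#'
#' Heavy precursors are generated in silico from a light-channel library by
#' shifting the m/z by the full 15N mass shift divided by the charge.
#'
#' @param light_mz Light precursor m/z (> 0).
#' @param charge Precursor charge (integer >= 1).
#' @param peptide_seq Peptide sequence.
#' @return `light_mz + heavy_mass_shift(peptide_seq) / charge`.
#' @export
heavy_mz <- function(light_mz, charge, peptide_seq) {
  if (!is.numeric(light_mz) || any(light_mz <= 0)) {
    stop("light_mz must be positive", call. = FALSE)
  }
  if (!is.numeric(charge) || any(charge < 1) ||
      any(charge != as.integer(charge))) {
    stop("charge must be an integer >= 1", call. = FALSE)
  }
  light_mz + heavy_mass_shift(peptide_seq) / charge
}
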