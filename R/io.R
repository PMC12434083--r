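#' Default column mapping for peptide quantification reports
#'
#' The canonical input is a long-format TSV with one row per peptide ion per
#' run. Vendor exports with different headers are adapted by passing a
#' modified mapping to [read_peptide_report()]; logical fields on the left,
#' source column names on the right.
#'
#' @return Named character vector mapping logical field -> source column.
#' @export
default_column_map <- function() {
  c(sample_id = "sample_id",
    protein_id = "protein_id",
    peptide_seq = "peptide_seq",
    ratio_hl = "ratio_hl",
    q_value = "q_value")
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a peptide-level two-channel quantification report
#'
#' Reads a delimited report (one row per peptide ion per run) and validates
#' it into peptide measurements. Heavy/light ratios are kept in the exported
#' H/L direction; inversion to L/H is a pipeline step ([normalize_runs()]),
#' not an I/O step. Rows violating the measurement invariants are rejected
#' with a logged count, never silently dropped:
#' non-finite or non-positive `ratio_hl`, `q_value` outside \[0, 1\] or
#' missing, stripped peptide sequences shorter than 5 residues or containing
#' non-canonical letters.
#'
#' @param path Path to a tab-delimited report with a header row.
#' @param column_map Named character vector as in [default_column_map()];
#'   `light_quantity`/`heavy_quantity` entries are optional extras.
#' @return A tibble of valid measurements with columns `sample_id`,
#'   `protein_id`, `peptide_seq`, `ratio_hl`, `q_value` (plus optional
#'   quantities). The named integer vector of per-reason rejection counts is
#'   attached as attribute `"rejections"`.
#' @export
read_peptide_report <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) stop("empty report: ", path, call. = FALSE)
  required <- c("sample_id", "protein_id", "peptide_seq", "ratio_hl", "q_value")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map is missing field(s): ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    stop("report is missing mapped column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    sample_id = raw[[column_map[["sample_id"]]]],
    protein_id = raw[[column_map[["protein_id"]]]],
    peptide_seq = toupper(raw[[column_map[["peptide_seq"]]]]),
    ratio_hl = suppressWarnings(as.numeric(raw[[column_map[["ratio_hl"]]]])),
    q_value = suppressWarnings(as.numeric(raw[[column_map[["q_value"]]]]))
  )
  for (opt in c("light_quantity", "heavy_quantity")) {
    if (opt %in% names(column_map)) {
      df[[opt]] <- suppressWarnings(as.numeric(raw[[column_map[[opt]]]]))
    }
  }
  validate_peptide_measurements(df)
}

#' Validate a peptide-measurement table
#'
#' Applies the ingest invariants to an in-memory table (used by
#' [read_peptide_report()] and available for data built in code). Rejection
#' counts per reason are attached as attribute `"rejections"` and reported
#' via `message()`.
#'
#' @param df Data frame with at least `sample_id`, `protein_id`,
#'   `peptide_seq`, `ratio_hl`, `q_value`.
#' @return The validated tibble of surviving rows.
#' @export
validate_peptide_measurements <- function(df) {
  df <- tibble::as_tibble(df)
  bad_ratio <- !is.finite(df$ratio_hl) | df$ratio_hl <= 0
  bad_q <- is.na(df$q_value) | df$q_value < 0 | df$q_value > 1
  short_pep <- nchar(df$peptide_seq) < 5
  bad_seq <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"),
                   df$peptide_seq)
  rejections <- c(
    nonfinite_ratio = sum(bad_ratio, na.rm = TRUE),
    bad_q_value = sum(bad_q & !bad_ratio, na.rm = TRUE),
    short_peptide = sum(short_pep & !bad_ratio & !bad_q, na.rm = TRUE),
    noncanonical_peptide = sum(bad_seq & !short_pep & !bad_ratio & !bad_q,
                               na.rm = TRUE)
  )
  keep <- !(bad_ratio | bad_q | short_pep | bad_seq)
  if (sum(rejections) > 0) {
    message("rejected ", sum(rejections), " row(s) at ingest [",
            paste(names(rejections)[rejections > 0], rejections[rejections > 0],
                  sep = "=", collapse = ", "), "]")
  }
  out <- df[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Read a protein sequence database from FASTA
#'
#' The accession is the header token up to the first whitespace; the rest of
#' the header is kept as the description. Duplicate accessions and empty
#' sequence records are errors.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id`, `description`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lens <- Biostrings::width(seqs)
  if (any(lens == 0)) {
    stop("empty sequence record(s) in FASTA: ",
         paste(ids[lens == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(protein_id = ids, description = desc,
                 sequence = unname(as.character(seqs)), length = lens)
}

#' Write a protein database to FASTA
#'
#' @param db Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- ifelse(nchar(db$description) > 0,
                        paste(db$protein_id, db$description),
                        db$protein_id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# All start positions (1-based) of exact substring occurrences of `peptide`
# in `protein_seq`, overlapping occurrences included.
peptide_positions <- function(protein_seq, peptide) {
  L <- nchar(protein_seq)
  l <- nchar(peptide)
  if (l == 0 || l > L) return(integer(0))
  starts <- seq_len(L - l + 1)
  starts[substring(protein_seq, starts, starts + l - 1) == peptide]
}

#' Protein sequence coverage from a peptide set
#'
#' Coverage is the percentage of protein residues contained in the union of
#' all exact substring occurrences of the given stripped peptide sequences
#' (every occurrence counts, including overlapping ones; I/L are not
#' collapsed). Peptides that do not occur contribute nothing.
#'
#' @param protein_seq Protein amino-acid sequence (single string, non-empty).
#' @param peptide_seqs Character vector of stripped peptide sequences.
#' @return Coverage percentage in \[0, 100\].
#'
#' @examples
#' compute_sequence_coverage("MKVLINTSGG", c("MKVL", "VLIN")) # union -> 60
#' @export
compute_sequence_coverage <- function(protein_seq, peptide_seqs) {
  if (length(protein_seq) != 1 || is.na(protein_seq) || nchar(protein_seq) == 0) {
    stop("protein_seq must be a single non-empty string", call. = FALSE)
  }
  covered <- logical(nchar(protein_seq))
  for (pep in unique(peptide_seqs)) {
    for (s in peptide_positions(protein_seq, pep)) {
      covered[s:(s + nchar(pep) - 1)] <- TRUE
    }
  }
  100 * sum(covered) / length(covered)
}

#' Write a result table as TSV
#'
#' Values round-trip through [read_result_table()] to at least 12 significant
#' digits.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
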