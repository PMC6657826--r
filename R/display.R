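#' @importFrom rlang .data
NULL

# Residue-level display classes in patient mode. OUT: not covered by any
# panel-allele window. D0: covered by a panel window but by no allele the
# patient carries (excluded from patient-mode in/out counts — neither
# patient-immunogenic nor clean background). D1 / D2: covered by exactly one
# / at least two displaying allele copies carried by the patient.
DISPLAY_CLASSES <- c("OUT", "D0", "D1", "D2")

check_windows <- function(length, starts, peptide_length) {
  if (length(starts) == 0L) return(invisible())
  if (any(starts < 1L | starts > length - peptide_length + 1L)) {
    data_error(sprintf(
      "binding window out of bounds for protein of length %d (starts %s)",
      length, paste(starts[starts < 1L | starts > length - peptide_length + 1L],
                    collapse = ", ")
    ))
  }
  invisible()
}

coverage_from_starts <- function(length, starts, peptide_length) {
  # interval-union coverage via a difference array; O(length + windows)
  delta <- integer(length + 1L)
  if (length(starts) > 0L) {
    tab_s <- tabulate(starts, nbins = length)
    ends <- pmin(starts + peptide_length, length + 1L)
    tab_e <- tabulate(ends, nbins = length + 1L)
    delta[seq_len(length)] <- tab_s
    delta <- delta - tab_e
  }
  cumsum(delta[seq_len(length)])
}

#' Build the pan-allele display mask of a protein
#'
#' Marks every residue covered by at least one retained strong-binder window
#' of any panel allele. A 9-mer starting at `s` covers residues `s..s+8`
#' (1-based, inclusive).
#'
#' @param protein_length Protein length in residues.
#' @param windows Tibble of retained windows for this protein (needs a
#'   `start` column; other columns ignored).
#' @param peptide_length Window length (default 9).
#' @return Logical vector of length `protein_length`: `TRUE` where displayed.
#' @export
build_panel_mask <- function(protein_length, windows, peptide_length = 9L) {
  starts <- if (is.data.frame(windows)) windows$start else as.integer(windows)
  check_windows(protein_length, starts, peptide_length)
  coverage_from_starts(protein_length, starts, peptide_length) > 0L
}

#' Per-allele display mask matrix of a protein
#'
#' @param protein_length Protein length in residues.
#' @param windows Tibble of retained windows for this protein (`allele`,
#'   `start`).
#' @param panel Character vector of panel alleles (matrix columns, in order).
#' @param peptide_length Window length (default 9).
#' @return Integer 0/1 matrix, `protein_length` x `length(panel)`;
#'   `[i, a] == 1` iff some window of allele `a` covers residue `i`.
#' @export
allele_mask_matrix <- function(protein_length, windows, panel,
                               peptide_length = 9L) {
  m <- matrix(0L, nrow = protein_length, ncol = length(panel),
              dimnames = list(NULL, panel))
  if (nrow(windows) > 0L) {
    check_windows(protein_length, windows$start, peptide_length)
    for (a in intersect(unique(windows$allele), panel)) {
      st <- windows$start[windows$allele == a]
      m[, a] <- as.integer(
        coverage_from_starts(protein_length, st, peptide_length) > 0L
      )
    }
  }
  m
}

#' Build a patient's displaying-allele copy-count track
#'
#' For each residue, sums the genotype copy counts of carried alleles that
#' have a strong-binder window covering that residue. Carried alleles outside
#' the prediction panel contribute nothing (no prediction model exists for
#' them).
#'
#' @param mask_matrix Per-allele mask matrix from [allele_mask_matrix()].
#' @param copies Named integer vector of the patient's allele copy counts
#'   (names in any dialect accepted by [normalize_hla_allele()]).
#' @return Integer vector of per-residue displaying-allele copy counts.
#' @export
build_patient_mask <- function(mask_matrix, copies) {
  panel <- colnames(mask_matrix)
  v <- numeric(length(panel))
  names(v) <- panel
  nm <- normalize_hla_allele(names(copies))
  carried <- !is.na(nm) & nm %in% panel
  if (any(carried)) {
    agg <- tapply(as.numeric(copies[carried]), nm[carried], sum)
    v[names(agg)] <- agg
  }
  as.integer(mask_matrix %*% v)
}

#' Classify residue sites by display status
#'
#' Pan-allele mode distinguishes `IN` (covered by the panel mask) from `OUT`.
#' Patient mode refines `IN` by the patient's displaying-allele copy count:
#' `D0` (in the panel mask but displayed by no carried allele; excluded from
#' patient-mode ratios), `D1` (one copy), `D2` (two or more copies, pooling
#' homozygous-displaying and two-distinct-displaying-allele sites).
#'
#' @param positions 1-based residue positions to classify.
#' @param panel_mask Logical pan-panel mask from [build_panel_mask()].
#' @param copy_count Integer copy-count track from [build_patient_mask()]
#'   (patient mode), or `NULL` (pan-allele mode).
#' @return Character vector: `"IN"`/`"OUT"` in pan mode; one of
#'   `"OUT"`, `"D0"`, `"D1"`, `"D2"` in patient mode.
#' @export
classify_site <- function(positions, panel_mask, copy_count = NULL) {
  if (any(positions < 1L | positions > length(panel_mask))) {
    data_error("variant position outside protein mask")
  }
  if (is.null(copy_count)) {
    return(ifelse(panel_mask[positions], "IN", "OUT"))
  }
  stopifnot(length(copy_count) == length(panel_mask))
  cc <- copy_count[positions]
  inp <- panel_mask[positions]
  dplyr::case_when(
    !inp ~ "OUT",
    cc == 0L ~ "D0",
    cc == 1L ~ "D1",
    TRUE ~ "D2"
  )
}

site_class_track <- function(panel_mask, copy_count = NULL) {
  if (is.null(copy_count)) {
    return(ifelse(panel_mask, "IN", "OUT"))
  }
  out <- rep("OUT", length(panel_mask))
  out[panel_mask & copy_count == 0L] <- "D0"
  out[panel_mask & copy_count == 1L] <- "D1"
  out[panel_mask & copy_count >= 2L] <- "D2"
  out
}

#' Export a display track as BED-like intervals
#'
#' Collapses a per-residue class track into maximal runs, converting internal
#' 1-based inclusive coordinates to 0-based half-open intervals on export.
#' Rows are ordered by protein then interval start.
#'
#' @param protein_id Protein identifier.
#' @param classes Per-residue class track (e.g. from [site_class_track()]).
#' @return Tibble with `protein_id`, `start` (0-based), `end` (exclusive),
#'   `class`.
#' @export
mask_to_bed <- function(protein_id, classes) {
  r <- rle(classes)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    protein_id = protein_id,
    start = ends - r$lengths,      # 0-based
    end = ends,                    # half-open
    class = r$values
  )
}
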