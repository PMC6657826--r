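#' @importFrom dplyr %>%
NULL

#' Variant class dialect table
#'
#' Input variant tables come in several annotation dialects; this explicit
#' mapping normalizes them to the two classes the analysis uses. Unknown
#' labels are rejected row-wise (never silently dropped).
#'
#' @return Named character vector: input label -> `"missense"`/`"synonymous"`.
#' @export
variant_class_dialects <- function() {
  c(
    "missense" = "missense",
    "Missense" = "missense",
    "Missense_Mutation" = "missense",
    "missense_variant" = "missense",
    "synonymous" = "synonymous",
    "Synonymous" = "synonymous",
    "Silent" = "synonymous",
    "synonymous_variant" = "synonymous"
  )
}

read_tsv_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    config_error(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read a somatic variant table
#'
#' Parses a MAF-like TSV of protein-space somatic variants. Parsing is total:
#' every input row becomes either a parsed variant or an itemized reject with
#' a reason; the two counts always sum to the number of input rows.
#'
#' Required columns: `sample_id`, `protein_id`, `position` (1-based residue
#' index), `ref_residue`, `alt_residue`, `variant_class`, `cancer_type`.
#' Unknown columns are ignored. Variant-class labels are normalized through
#' [variant_class_dialects()].
#'
#' @param path Path to the TSV file.
#' @return A list with `variants` (tibble, one row per parsed variant, with
#'   integer `position`), `rejects` (tibble with `row` and `reason`), and
#'   `n_input` (number of data rows read).
#' @export
read_variants <- function(path) {
  raw <- read_tsv_chr(path)
  require_columns(raw, c("sample_id", "protein_id", "position", "ref_residue",
                         "alt_residue", "variant_class", "cancer_type"),
                  "variant table")
  n <- nrow(raw)
  if (n == 0L) {
    return(list(
      variants = tibble::tibble(
        sample_id = character(), protein_id = character(),
        position = integer(), ref_residue = character(),
        alt_residue = character(), variant_class = character(),
        cancer_type = character()
      ),
      rejects = tibble::tibble(row = integer(), reason = character()),
      n_input = 0L
    ))
  }

  pos <- suppressWarnings(as.integer(raw$position))
  cls <- unname(variant_class_dialects()[raw$variant_class])
  ref <- toupper(raw$ref_residue)
  alt <- toupper(raw$alt_residue)

  reason <- rep(NA_character_, n)
  bad <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(is.na(pos) | pos < 1L, "position is not a positive integer")
  reason <- bad(is.na(cls), "unknown variant_class label")
  reason <- bad(!(ref %in% AA_ALPHABET), "ref_residue not a standard amino acid")
  reason <- bad(!(alt %in% AA_ALPHABET), "alt_residue not a standard amino acid")
  reason <- bad(!is.na(cls) & cls == "missense" & ref == alt,
                "missense variant with identical ref and alt residues")

  keep <- is.na(reason)
  variants <- tibble::tibble(
    sample_id = raw$sample_id[keep],
    protein_id = raw$protein_id[keep],
    position = pos[keep],
    ref_residue = ref[keep],
    alt_residue = alt[keep],
    variant_class = cls[keep],
    cancer_type = raw$cancer_type[keep]
  )
  if ("gene_id" %in% names(raw)) {
    # optional column enabling the longest-isoform fallback in map_variants()
    variants$gene_id <- raw$gene_id[keep]
  }
  rejects <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  list(variants = variants, rejects = rejects, n_input = n)
}

#' Read protein sequences from FASTA
#'
#' Headers carry the protein identifier as the first token and optionally a
#' `gene=<id>` key. Sequences are uppercased; records containing characters
#' outside the 20-letter amino-acid alphabet are flagged (`valid = FALSE`) and
#' excluded from display-mask construction downstream.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Tibble with `protein_id`, `gene_id` (`NA` when absent), `sequence`,
#'   `length`, `valid`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  protein_id <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  dup <- unique(protein_id[duplicated(protein_id)])
  if (length(dup) > 0L) {
    data_error(sprintf("duplicate protein_id in FASTA: %s",
                       paste(dup, collapse = ", ")))
  }
  gene_id <- ifelse(
    grepl("gene=", headers),
    sub(".*gene=([^\\s]+).*", "\\1", headers, perl = TRUE),
    NA_character_
  )
  sequence <- toupper(as.character(seqs))
  valid <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), sequence)
  tibble::tibble(
    protein_id = protein_id,
    gene_id = gene_id,
    sequence = unname(sequence),
    length = nchar(sequence),
    valid = valid
  )
}

#' Read per-patient HLA class I genotypes
#'
#' One row per sample with two allele columns per locus (`A1`, `A2`, `B1`,
#' `B2`, optionally `C1`, `C2`). Allele names may be in any dialect accepted
#' by [normalize_hla_allele()]. Homozygous calls yield copy count 2. A locus
#' with only one parseable allele is an error, because allele copy number
#' (zygosity) is meaningful downstream.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `sample_id`, `locus`, `allele`, `copies`; per sample
#'   and locus, `copies` sums to 2.
#' @export
read_hla <- function(path) {
  raw <- read_tsv_chr(path)
  require_columns(raw, c("sample_id", "A1", "A2", "B1", "B2"), "HLA genotype table")
  loci <- c("A", "B")
  if (all(c("C1", "C2") %in% names(raw))) loci <- c(loci, "C")
  rows <- lapply(loci, function(lc) {
    a1 <- normalize_hla_allele(raw[[paste0(lc, "1")]])
    a2 <- normalize_hla_allele(raw[[paste0(lc, "2")]])
    half <- is.na(a1) != is.na(a2)
    if (any(half)) {
      data_error(sprintf(
        "sample(s) %s have only one parseable allele at locus %s; zygosity would be undefined",
        paste(raw$sample_id[half], collapse = ", "), lc
      ))
    }
    bad <- is.na(a1) & is.na(a2)
    if (any(bad)) {
      data_error(sprintf(
        "sample(s) %s are missing locus %s calls",
        paste(raw$sample_id[bad], collapse = ", "), lc
      ))
    }
    tibble::tibble(
      sample_id = rep(raw$sample_id, 2L),
      locus = lc,
      allele = c(a1, a2)
    )
  })
  dplyr::bind_rows(rows) %>%
    dplyr::count(.data$sample_id, .data$locus, .data$allele, name = "copies") %>%
    dplyr::arrange(.data$sample_id, .data$locus, .data$allele)
}

#' Read strong-binder 9-mer predictions
#'
#' Long-format table with columns `protein_id`, `allele`, `start` (1-based
#' residue index of the 9-mer), `affinity` (prediction score, lower =
#' stronger). Only rows at or below the configured strong-binder threshold
#' are retained. When `proteins` is supplied, windows extending beyond a
#' protein's end (or on unknown/invalid proteins) are rejected with a reason.
#'
#' @param path Path to the TSV file.
#' @param config An [analysis_config()] (threshold and peptide length).
#' @param proteins Optional tibble from [read_fasta()] for bounds validation.
#' @return List with `windows` (tibble `protein_id`, `allele`, `start`,
#'   `affinity`), `rejects` (tibble `row`, `reason`), `n_input`,
#'   `n_retained`.
#' @export
read_binding_predictions <- function(path, config = analysis_config(),
                                     proteins = NULL) {
  raw <- read_tsv_chr(path)
  require_columns(raw, c("protein_id", "allele", "start", "affinity"),
                  "binding prediction table")
  n <- nrow(raw)
  start <- suppressWarnings(as.integer(raw$start))
  affinity <- suppressWarnings(as.numeric(raw$affinity))
  allele <- normalize_hla_allele(raw$allele)

  reason <- rep(NA_character_, n)
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(start) | start < 1L, "start is not a positive integer")
  reason <- bad(is.na(affinity) | affinity <= 0, "affinity is not a positive number")
  reason <- bad(is.na(allele), "unparseable allele name")
  if (!is.null(proteins)) {
    idx <- match(raw$protein_id, proteins$protein_id)
    reason <- bad(is.na(idx), "unknown protein_id")
    reason <- bad(!is.na(idx) & !proteins$valid[idx],
                  "protein flagged invalid (non-standard residues)")
    maxstart <- proteins$length[idx] - config$peptide_length + 1L
    reason <- bad(!is.na(idx) & !is.na(start) & start > maxstart,
                  "window extends beyond protein end")
  }
  ok <- is.na(reason)
  retained <- ok & affinity <= config$strong_binder_threshold
  windows <- tibble::tibble(
    protein_id = raw$protein_id[retained],
    allele = allele[retained],
    start = start[retained],
    affinity = affinity[retained]
  )
  list(
    windows = windows,
    rejects = tibble::tibble(row = which(!ok), reason = reason[!ok]),
    n_input = n,
    n_retained = sum(retained)
  )
}

#' Read a gene-by-cancer-type expression table
#'
#' Accepts either a long table (`gene_id`, `cancer_type`, `value`: one
#' RSEM-normalized median per gene and cancer type) or a wide per-sample
#' table (`gene_id` plus one column per sample named
#' `<cancer_type>.<sample>`), which is reduced to per-cancer-type medians.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `gene_id`, `cancer_type`, `value` (median RSEM-scale
#'   expression, one row per pair).
#' @export
read_expression <- function(path) {
  raw <- read_tsv_chr(path)
  if (all(c("gene_id", "cancer_type", "value") %in% names(raw))) {
    out <- tibble::tibble(
      gene_id = raw$gene_id,
      cancer_type = raw$cancer_type,
      value = suppressWarnings(as.numeric(raw$value))
    )
    if (anyNA(out$value)) data_error("non-numeric expression value")
    out <- out %>%
      dplyr::group_by(.data$gene_id, .data$cancer_type) %>%
      dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  } else {
    require_columns(raw, "gene_id", "expression table")
    sample_cols <- setdiff(names(raw), "gene_id")
    if (length(sample_cols) == 0L) data_error("expression table has no sample columns")
    if (!all(grepl("\\.", sample_cols))) {
      config_error("wide expression table columns must be named <cancer_type>.<sample>")
    }
    out <- raw %>%
      tidyr::pivot_longer(-"gene_id", names_to = "column", values_to = "value") %>%
      dplyr::mutate(
        cancer_type = sub("\\..*$", "", .data$column),
        value = suppressWarnings(as.numeric(.data$value))
      )
    if (anyNA(out$value)) data_error("non-numeric expression value")
    out <- out %>%
      dplyr::group_by(.data$gene_id, .data$cancer_type) %>%
      dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  }
  if (any(out$value < 0)) data_error("negative expression value")
  dplyr::arrange(out, .data$gene_id, .data$cancer_type)
}

#' Write analysis results to disk
#'
#' Emits a machine-readable TSV of per-cell results and a structured JSON run
#' report (config echo, stage counts, results, seed). Given identical inputs
#' and configuration, the written bytes are identical across runs.
#'
#' @param analysis A `"depletion_analysis"` object from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`tsv`, `json`).
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "depletion_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "results.tsv")
  json <- file.path(dir, "report.json")
  readr::write_tsv(analysis$results, tsv, progress = FALSE)
  payload <- list(
    tool = "neodeplete",
    version = as.character(utils::packageVersion("neodeplete")),
    config = unclass(analysis$config),
    manifest = analysis$manifest,
    results = analysis$results
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(tsv = tsv, json = json))
}
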