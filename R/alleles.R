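#' Normalize HLA class I allele names to 4-digit form
#'
#' Collapses the common naming dialects for class I HLA alleles
#' (`"HLA-A*02:01"`, `"A*02:01"`, `"HLA-A0201"`, `"A0201"`, `"A*0201"`) onto a
#' single 4-digit representation, `"A*0201"`. All downstream genotype and
#' binding-prediction matching happens at this resolution.
#'
#' @param x Character vector of allele names in any supported dialect.
#' @return Character vector of normalized names (`"<locus>*<4 digits>"`).
#'   Unparseable entries are returned as `NA` (callers decide whether that is
#'   an error).
#' @examples
#' normalize_hla_allele(c("HLA-A*02:01", "A*0201", "HLA-B0702", "B*07:02"))
#' @export
normalize_hla_allele <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^HLA-?", "", x, ignore.case = TRUE)
  m <- regmatches(x, regexec("^([ABC])\\*?([0-9]{2}):?([0-9]{2})$", x))
  vapply(m, function(g) {
    if (length(g) == 4L) paste0(g[2L], "*", g[3L], g[4L]) else NA_character_
  }, character(1))
}

#' The default 12-allele class I prediction panel
#'
#' The twelve common HLA-A/HLA-B alleles for which strong-binder predictions
#' are assumed available, with approximate population allele frequencies
#' (European-ancestry estimates, used only by the synthetic cohort generator
#' when sampling genotypes). Per locus the frequencies sum to less than 1; the
#' remainder is carried by panel-external alleles for which no display
#' predictions exist, which therefore never display.
#'
#' @return A tibble with columns `allele`, `locus`, `frequency`.
#' @export
default_hla_panel <- function() {
  tibble::tibble(
    allele = c(
      "A*0101", "A*0201", "A*0301", "A*2402", "A*2601",
      "B*0702", "B*0801", "B*1501", "B*2705", "B*3901", "B*4001", "B*5801"
    ),
    locus = substr(allele, 1L, 1L),
    frequency = c(
      0.16, 0.27, 0.13, 0.17, 0.05,
      0.13, 0.12, 0.07, 0.04, 0.03, 0.07, 0.04
    )
  )
}

# 20-letter amino-acid alphabet used for sequence validation throughout.
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
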