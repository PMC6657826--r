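STRATUM_LEVELS <- c("UNDETECTED", "Q1", "Q2", "Q3", "Q4")

#' Assign genes of one cancer type to expression strata
#'
#' Genes with a median RSEM-normalized expression of exactly 0 are
#' `UNDETECTED`. Detectably expressed genes (value > 0) are split into four
#' quantiles `Q1`–`Q4` at the 25/50/75th percentiles of their values within
#' that cancer type; a gene whose value falls exactly on a boundary goes to
#' the lower stratum, so tied values always share a stratum. Assignments are
#' invariant to input row order.
#'
#' @param expr Expression tibble from [read_expression()] (`gene_id`,
#'   `cancer_type`, `value`).
#' @param cancer_type Cancer type code to stratify.
#' @return Tibble with `gene_id`, `cancer_type`, `median_value`, `stratum`
#'   (factor with levels `UNDETECTED`, `Q1`..`Q4`).
#' @export
assign_strata <- function(expr, cancer_type) {
  sub <- expr[expr$cancer_type == cancer_type, , drop = FALSE]
  if (nrow(sub) == 0L) {
    data_error(sprintf("cancer type '%s' absent from expression table", cancer_type))
  }
  sub <- sub[order(sub$gene_id), , drop = FALSE]
  stratum <- rep("UNDETECTED", nrow(sub))
  expressed <- sub$value > 0
  if (any(expressed)) {
    v <- sub$value[expressed]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    idx <- 1L + (v > qs[1]) + (v > qs[2]) + (v > qs[3])
    stratum[expressed] <- paste0("Q", idx)
  }
  tibble::tibble(
    gene_id = sub$gene_id,
    cancer_type = cancer_type,
    median_value = sub$value,
    stratum = factor(stratum, levels = STRATUM_LEVELS)
  )
}

#' Stratum table for every cancer type in an expression table
#'
#' @param expr Expression tibble from [read_expression()].
#' @return Row-bound [assign_strata()] tables for all cancer types present.
#' @export
assign_strata_all <- function(expr) {
  dplyr::bind_rows(lapply(sort(unique(expr$cancer_type)),
                          function(ct) assign_strata(expr, ct)))
}

#' Look up the expression stratum of variants
#'
#' Each variant takes the stratum of its gene in its own cancer type (the
#' same gene can be `UNDETECTED` in one cancer type and `Q4` in another).
#' Variants whose gene has no expression data for their cancer type get `NA`
#' and are excluded from the analysis with a logged count.
#'
#' @param variants Tibble with at least `gene_id` and `cancer_type`.
#' @param strata Stratum table from [assign_strata_all()].
#' @return Factor vector of strata aligned to `variants` rows (`NA` =
#'   missing expression data).
#' @export
stratum_of_variant <- function(variants, strata) {
  key <- paste(variants$gene_id, variants$cancer_type, sep = "\r")
  skey <- paste(strata$gene_id, strata$cancer_type, sep = "\r")
  strata$stratum[match(key, skey)]
}
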