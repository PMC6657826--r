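#' Map somatic variants onto protein sequences
#'
#' Resolves each variant to a protein record and validates that the reported
#' wild-type residue is found at the reported position of that protein's
#' sequence; only validated variants enter any downstream count. Rows whose
#' `protein_id` is blank but that carry a `gene_id` fall back to the gene's
#' longest isoform (a deterministic convention, flagged in the manifest).
#'
#' @param variants Variant tibble from [read_variants()]`$variants` (an
#'   optional `gene_id` column enables the isoform fallback).
#' @param proteins Protein tibble from [read_fasta()].
#' @return The variant tibble with resolved `protein_id` and a `validated`
#'   logical column; attribute `"n_isoform_fallback"` counts fallback rows.
#' @export
map_variants <- function(variants, proteins) {
  v <- variants
  n_fallback <- 0L
  blank <- is.na(v$protein_id) | v$protein_id == ""
  if (any(blank) && "gene_id" %in% names(v)) {
    iso <- proteins[proteins$valid & !is.na(proteins$gene_id), , drop = FALSE]
    iso <- iso[order(iso$gene_id, -iso$length, iso$protein_id), , drop = FALSE]
    longest <- iso[!duplicated(iso$gene_id), , drop = FALSE]
    idx <- match(v$gene_id[blank], longest$gene_id)
    v$protein_id[blank] <- longest$protein_id[idx]
    n_fallback <- sum(blank & !is.na(idx))
  }
  pi <- match(v$protein_id, proteins$protein_id)
  known <- !is.na(pi) & proteins$valid[pi]
  in_range <- known & v$position >= 1L & v$position <= proteins$length[pi]
  wt <- rep(NA_character_, nrow(v))
  wt[in_range] <- substr(proteins$sequence[pi[in_range]],
                         v$position[in_range], v$position[in_range])
  v$validated <- in_range & wt == v$ref_residue
  v$validated[is.na(v$validated)] <- FALSE
  attr(v, "n_isoform_fallback") <- n_fallback
  v
}

#' Run the full depletion analysis
#'
#' End-to-end orchestration: validates variants against protein sequences,
#' builds display masks, stratifies genes by expression within each cancer
#' type, accumulates opportunity-adjusted counts per (stratum, display
#' class), and computes density ratios, Fisher's exact p-values, corrected
#' ratios (each cell against the same-class `UNDETECTED` control, plus a
#' pooled-expressed row), optional patient-bootstrap confidence intervals,
#' and the implied clearance percentage. Running with
#' `variant_class = "synonymous"` applies the identical machinery to the
#' synonymous negative control.
#'
#' @param cohort A list with `proteins`, `windows`, `genotypes`,
#'   `expression`, `variants` (the in-memory forms returned by the readers,
#'   or by [generate_cohort()]).
#' @param config An [analysis_config()].
#' @param bootstrap Compute patient-bootstrap CIs for the pooled-expressed
#'   corrected ratios (patient mode only)?
#' @return An object of class `"depletion_analysis"`: list with `results`
#'   (tibble, one row per stratum x display class), `cells`, `per_patient`,
#'   `manifest`, `config`.
#' @export
run_analysis <- function(cohort, config = analysis_config(), bootstrap = FALSE) {
  mapped <- map_variants(cohort$variants, cohort$proteins)
  strata <- assign_strata_all(cohort$expression)
  acc <- accumulate_counts(mapped, cohort$proteins, cohort$windows,
                           cohort$genotypes, strata, config)

  cells <- acc$cells
  pooled <- cells[cells$stratum %in% paste0("Q", 1:4), , drop = FALSE]
  pooled <- pooled |>
    dplyr::group_by(.data$display_class) |>
    dplyr::summarise(dplyr::across(c("mut_in", "site_in", "mut_out", "site_out"),
                                   sum), .groups = "drop") |>
    dplyr::mutate(stratum = "EXPRESSED", .before = 1L)
  tab <- dplyr::bind_rows(cells, pooled)
  if (config$mode == "pan_allele") {
    tab <- tab[tab$display_class == "ANY", , drop = FALSE]
  } else {
    tab <- tab[tab$display_class %in% config$display_classes |
                 (tab$display_class == "ANY" & "ANY" %in% config$display_classes), ,
               drop = FALSE]
  }

  tab$ratio <- mapply(ratio_from_counts, tab$mut_in, tab$site_in,
                      tab$mut_out, tab$site_out)
  tab$p_value <- mapply(function(mi, si, mo, so) {
    if (si <= 0 || so <= 0) return(NA_real_)
    fisher_test(mi, si, mo, so)
  }, tab$mut_in, tab$site_in, tab$mut_out, tab$site_out)

  ctrl <- tab[tab$stratum == "UNDETECTED",
              c("display_class", "ratio"), drop = FALSE]
  names(ctrl)[2] <- "control_ratio"
  tab <- dplyr::left_join(tab, ctrl, by = "display_class")
  tab$corrected_ratio <- ifelse(
    tab$stratum %in% c("UNDETECTED") | is.na(tab$ratio) |
      is.na(tab$control_ratio) | tab$control_ratio <= 0,
    NA_real_, tab$ratio / tab$control_ratio
  )
  tab$control_ratio <- NULL

  tab$ci_low <- NA_real_
  tab$ci_high <- NA_real_
  n_boot <- 0L
  if (bootstrap && config$mode == "patient") {
    ci <- bootstrap_ci(acc$per_patient, reps = config$bootstrap_reps,
                       seed = config$rng_seed)
    n_boot <- config$bootstrap_reps
    hit <- tab$stratum == "EXPRESSED"
    m <- match(tab$display_class[hit], ci$display_class)
    tab$ci_low[hit] <- ci$ci_low[m]
    tab$ci_high[hit] <- ci$ci_high[m]
  }

  tab$clearance_percent <- ifelse(
    is.na(tab$corrected_ratio) | tab$corrected_ratio <= 0, NA_real_,
    pmax(0, 100 * (1 - tab$corrected_ratio))
  )

  scope <- if (identical(config$cancer_types, "ALL")) "ALL" else
    paste(config$cancer_types, collapse = "+")
  results <- tibble::tibble(
    cancer_scope = scope,
    variant_class = config$variant_class,
    mode = config$mode,
    stratum = tab$stratum,
    display_class = tab$display_class,
    mut_in = tab$mut_in, site_in = tab$site_in,
    mut_out = tab$mut_out, site_out = tab$site_out,
    ratio = tab$ratio, p_value = tab$p_value,
    corrected_ratio = tab$corrected_ratio,
    ci_low = tab$ci_low, ci_high = tab$ci_high,
    clearance_percent = tab$clearance_percent,
    n_bootstrap = n_boot,
    seed = config$rng_seed
  )

  manifest <- list(
    n_variant_rows = nrow(cohort$variants),
    n_validated = sum(mapped$validated),
    n_not_validated = sum(!mapped$validated),
    n_isoform_fallback = attr(mapped, "n_isoform_fallback"),
    n_in_scope = nrow(scoped_variants(mapped, config)),
    excluded = as.list(acc$excluded),
    n_proteins = nrow(cohort$proteins),
    n_invalid_proteins = sum(!cohort$proteins$valid),
    n_windows = nrow(cohort$windows),
    n_patients = length(unique(cohort$variants$sample_id))
  )

  structure(
    list(results = results, cells = acc$cells, per_patient = acc$per_patient,
         excluded = acc$excluded, manifest = manifest, config = config),
    class = "depletion_analysis"
  )
}

#' Human-readable summary of a depletion analysis
#'
#' Per-stratum table of in/out mutation densities and (corrected) ratios,
#' rounded to the configured number of decimals at display time only, with a
#' clearance line when the pooled-expressed corrected ratio shows depletion.
#'
#' @param analysis A `"depletion_analysis"` object.
#' @return Invisibly, the rounded summary tibble (also printed).
#' @export
report_summary <- function(analysis) {
  stopifnot(inherits(analysis, "depletion_analysis"))
  d <- analysis$config$rounding
  r <- analysis$results
  out <- tibble::tibble(
    stratum = r$stratum,
    display_class = r$display_class,
    density_in = round(r$mut_in / pmax(r$site_in, 1), d + 4L),
    density_out = round(r$mut_out / pmax(r$site_out, 1), d + 4L),
    ratio = round(r$ratio, d),
    corrected_ratio = round(r$corrected_ratio, d),
    p_value = signif(r$p_value, 3)
  )
  print(out, n = nrow(out))
  top <- r[r$stratum == "EXPRESSED" & !is.na(r$corrected_ratio), , drop = FALSE]
  if (nrow(top) > 0L) {
    best <- top[which.min(top$corrected_ratio), ]
    if (best$corrected_ratio < 1) {
      cat(sprintf(
        "Strongest depletion: %s corrected ratio %.2f -> implied immune clearance %.0f%%\n",
        best$display_class, best$corrected_ratio,
        100 * (1 - best$corrected_ratio)
      ))
    }
  }
  invisible(out)
}

#' @export
print.depletion_analysis <- function(x, ...) {
  cat(sprintf("<depletion_analysis: mode=%s class=%s scope=%s>\n",
              x$config$mode, x$config$variant_class,
              if (identical(x$config$cancer_types, "ALL")) "ALL"
              else paste(x$config$cancer_types, collapse = "+")))
  report_summary(x)
  invisible(x)
}
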