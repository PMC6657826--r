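DEPLETION_CLASSES <- c("ANY", "D1", "D2")

#' Mutation density ratio of a 2x2 opportunity table
#'
#' The ratio of mutation density inside displayed positions
#' (`mut_in / site_in`) to the density outside (`mut_out / site_out`).
#' Values below 1 indicate depletion of mutations within displayed peptides.
#'
#' @param mut_in,site_in Mutation count and residue-site opportunity inside
#'   the display class.
#' @param mut_out,site_out Mutation count and opportunity outside displayed
#'   positions.
#' @return The density ratio; `NA` with a warning when a denominator is zero
#'   (never silently 0).
#' @export
density_ratio <- function(mut_in, site_in, mut_out, site_out) {
  r <- ratio_from_counts(mut_in, site_in, mut_out, site_out)
  if (is.na(r)) {
    warning("density ratio undefined: zero denominator (site_in, site_out or mut_out)")
  }
  r
}

ratio_from_counts <- function(mut_in, site_in, mut_out, site_out) {
  if (site_in <= 0 || site_out <= 0 || mut_out <= 0) return(NA_real_)
  (mut_in / site_in) / (mut_out / site_out)
}

#' Fisher's exact test on an opportunity table
#'
#' Two-sided exact test on the 2x2 table of mutated vs non-mutated residue
#' sites, inside vs outside displayed positions:
#' `[[mut_in, site_in - mut_in], [mut_out, site_out - mut_out]]`. With this
#' orientation the table's odds ratio approximates the density ratio.
#'
#' @inheritParams density_ratio
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_test <- function(mut_in, site_in, mut_out, site_out) {
  cells <- c(mut_in, site_in - mut_in, mut_out, site_out - mut_out)
  if (any(cells < 0)) data_error("negative cell in 2x2 opportunity table")
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  stats::fisher.test(m, conf.int = FALSE)$p.value
}

#' Sequence-bias-corrected density ratio
#'
#' Display masks are enriched for allele-preferred residues, so even with no
#' immune selection the in/out densities can differ. Dividing the density
#' ratio of expressed genes by that of undetectably expressed genes (where
#' no display-dependent selection can act) cancels this composition bias.
#'
#' @param expressed_ratio Density ratio among detectably expressed genes.
#' @param nonexpressed_ratio Density ratio among undetected genes (the
#'   negative control); must be positive.
#' @return `expressed_ratio / nonexpressed_ratio`, at full precision
#'   (rounding happens only at the reporting layer).
#' @export
corrected_ratio <- function(expressed_ratio, nonexpressed_ratio) {
  if (is.na(nonexpressed_ratio) || nonexpressed_ratio <= 0) {
    data_error("non-expressed control ratio must be positive")
  }
  expressed_ratio / nonexpressed_ratio
}

#' Implied immune-clearance percentage
#'
#' A corrected density ratio `r <= 1` implies that cells carrying a mutation
#' at such a site were cleared `100 * (1 - r)` percent of the time before
#' sampling. Ratios above 1 (no depletion) return 0, flagged via the
#' `"no_depletion"` attribute.
#'
#' @param corrected Corrected density ratio; must be positive.
#' @return Clearance percentage in `[0, 100]`.
#' @export
clearance_percent <- function(corrected) {
  if (is.na(corrected) || corrected <= 0) {
    data_error("corrected ratio must be positive to imply a clearance rate")
  }
  if (corrected > 1) {
    return(structure(0, no_depletion = TRUE))
  }
  100 * (1 - corrected)
}

# ---- cell bookkeeping ----------------------------------------------------
# Cells are (stratum x display class); each holds mut_in, site_in, mut_out,
# site_out. Flattened as a vector of length 5 * 3 * 4 so that per-patient
# contributions are rows of a matrix and bootstrap resampling is a weighted
# column sum.

n_cells <- function() length(STRATUM_LEVELS) * length(DEPLETION_CLASSES)

cell_index <- function(stratum, class) {
  si <- match(stratum, STRATUM_LEVELS)
  ci <- match(class, DEPLETION_CLASSES)
  (si - 1L) * length(DEPLETION_CLASSES) + ci
}

cell_slot <- function(stratum, class, field) {
  fi <- match(field, c("mut_in", "site_in", "mut_out", "site_out"))
  (cell_index(stratum, class) - 1L) * 4L + fi
}

empty_cell_vector <- function() numeric(n_cells() * 4L)

cells_to_tibble <- function(flat) {
  grid <- expand.grid(class = DEPLETION_CLASSES, stratum = STRATUM_LEVELS,
                      stringsAsFactors = FALSE)
  idx <- (cell_index(grid$stratum, grid$class) - 1L) * 4L
  tibble::tibble(
    stratum = grid$stratum,
    display_class = grid$class,
    mut_in = flat[idx + 1L],
    site_in = flat[idx + 2L],
    mut_out = flat[idx + 3L],
    site_out = flat[idx + 4L]
  )
}

# Pooled-expressed corrected ratio for one display class from a flat cell
# vector; NA when undefined (empty cells). Used by both the point estimate
# and every bootstrap replicate.
corrected_from_flat <- function(flat, class) {
  expressed <- paste0("Q", 1:4)
  mi <- sum(flat[cell_slot(expressed, class, "mut_in")])
  si <- sum(flat[cell_slot(expressed, class, "site_in")])
  mo <- sum(flat[cell_slot(expressed, class, "mut_out")])
  so <- sum(flat[cell_slot(expressed, class, "site_out")])
  r_expr <- ratio_from_counts(mi, si, mo, so)
  r_ctrl <- ratio_from_counts(
    flat[cell_slot("UNDETECTED", class, "mut_in")],
    flat[cell_slot("UNDETECTED", class, "site_in")],
    flat[cell_slot("UNDETECTED", class, "mut_out")],
    flat[cell_slot("UNDETECTED", class, "site_out")]
  )
  if (is.na(r_expr) || is.na(r_ctrl) || r_ctrl <= 0) return(NA_real_)
  r_expr / r_ctrl
}

# ---- accumulation --------------------------------------------------------

scoped_variants <- function(mapped, config) {
  v <- mapped[mapped$validated & mapped$variant_class == config$variant_class, ,
              drop = FALSE]
  if (!identical(config$cancer_types, "ALL")) {
    v <- v[v$cancer_type %in% config$cancer_types, , drop = FALSE]
  }
  v
}

# Per-protein display structures for the proteins named in `ids`.
protein_store <- function(proteins, windows, config, ids, patient_mode) {
  panel <- config$allele_panel
  keep <- proteins$protein_id %in% ids & proteins$valid
  sub <- proteins[keep, , drop = FALSE]
  win_split <- split(windows[windows$allele %in% panel, , drop = FALSE],
                     factor(windows$protein_id[windows$allele %in% panel],
                            levels = sub$protein_id))
  store <- vector("list", nrow(sub))
  names(store) <- sub$protein_id
  for (i in seq_len(nrow(sub))) {
    pid <- sub$protein_id[i]
    L <- sub$length[i]
    w <- win_split[[pid]]
    if (is.null(w)) w <- windows[0, , drop = FALSE]
    entry <- list(length = L, gene_id = sub$gene_id[i])
    if (patient_mode) {
      M <- allele_mask_matrix(L, w, panel, config$peptide_length)
      entry$mask_matrix <- M
      entry$panel_mask <- rowSums(M) > 0L
    } else {
      entry$panel_mask <- build_panel_mask(L, w, config$peptide_length)
    }
    store[[i]] <- entry
  }
  store
}

#' Accumulate opportunity-adjusted mutation counts
#'
#' Builds the (expression stratum x display class) 2x2 opportunity tables.
#' The opportunity set follows the run mode: in pan-allele mode, each
#' protein's residue sites are counted once per cancer type in which that
#' protein carries at least one in-scope variant; in patient mode, sites are
#' counted once per (patient, mutated protein) pair, since each patient has
#' their own copy-count track. Patient-mode `D0` sites (displayed only by
#' panel alleles the patient does not carry) contribute to neither side.
#'
#' @param mapped Mapped variant tibble from [map_variants()].
#' @param proteins Protein tibble from [read_fasta()].
#' @param windows Retained strong-binder windows
#'   (from [read_binding_predictions()]).
#' @param genotypes Genotype tibble from [read_hla()] (patient mode).
#' @param strata Stratum table from [assign_strata_all()].
#' @param config An [analysis_config()].
#' @return List with `cells` (tibble of per-cell counts), `per_patient`
#'   (patient-mode matrix of per-patient cell contributions, for
#'   bootstrapping; `NULL` in pan mode), and `excluded` (named counts of
#'   variants left out and why).
#' @export
accumulate_counts <- function(mapped, proteins, windows, genotypes, strata,
                              config) {
  v <- scoped_variants(mapped, config)
  patient_mode <- config$mode == "patient"

  known <- v$protein_id %in% proteins$protein_id[proteins$valid]
  excluded <- c(unknown_protein = sum(!known))
  v <- v[known, , drop = FALSE]

  store <- protein_store(proteins, windows, config, unique(v$protein_id),
                         patient_mode)
  v$gene_id <- vapply(store[v$protein_id], `[[`, character(1), "gene_id")

  # unit = (protein, cancer type) in pan mode, (patient, protein) in patient
  # mode; stratum resolved per unit through the unit's cancer type
  if (patient_mode) {
    v$unit <- paste(v$sample_id, v$protein_id, sep = "\r")
  } else {
    v$unit <- paste(v$protein_id, v$cancer_type, sep = "\r")
  }
  units <- v[!duplicated(v$unit), c("unit", "sample_id", "protein_id",
                                    "cancer_type", "gene_id")]
  units$stratum <- as.character(stratum_of_variant(units, strata))

  miss <- is.na(units$stratum)
  excluded["missing_expression"] <- sum(v$unit %in% units$unit[miss])
  units <- units[!miss, , drop = FALSE]
  v <- v[v$unit %in% units$unit, , drop = FALSE]
  vsplit <- split(v$position, factor(v$unit, levels = units$unit))

  excluded["d0_site"] <- 0L
  excluded["non_neoantigenic_unit"] <- 0L
  flat <- empty_cell_vector()
  per_patient <- NULL

  if (patient_mode) {
    samples <- sort(unique(units$sample_id))
    panel <- config$allele_panel
    copies_mat <- matrix(0, nrow = length(samples), ncol = length(panel),
                         dimnames = list(samples, panel))
    g <- genotypes[genotypes$allele %in% panel &
                     genotypes$sample_id %in% samples, , drop = FALSE]
    if (nrow(g) > 0L) {
      copies_mat[cbind(match(g$sample_id, samples), match(g$allele, panel))] <-
        g$copies
    }
    per_patient <- matrix(0, nrow = length(samples), ncol = n_cells() * 4L,
                          dimnames = list(samples, NULL))

    for (u in seq_len(nrow(units))) {
      p <- store[[units$protein_id[u]]]
      cc <- as.integer(p$mask_matrix %*% copies_mat[units$sample_id[u], ])
      inmask <- p$panel_mask
      nD0 <- sum(inmask & cc == 0L)
      nD1 <- sum(cc == 1L)
      nD2 <- sum(cc >= 2L)
      nOUT <- p$length - nD0 - nD1 - nD2
      pos <- vsplit[[u]]
      mcc <- cc[pos]
      min_mask <- inmask[pos]
      mD0 <- sum(min_mask & mcc == 0L)
      mD1 <- sum(mcc == 1L)
      mD2 <- sum(mcc >= 2L)
      mOUT <- length(pos) - mD0 - mD1 - mD2
      if (config$patient_universe == "neoantigenic" && nD1 + nD2 == 0L) {
        excluded["non_neoantigenic_unit"] <-
          excluded["non_neoantigenic_unit"] + length(pos)
        next
      }
      excluded["d0_site"] <- excluded["d0_site"] + mD0
      s <- units$stratum[u]
      row <- match(units$sample_id[u], samples)
      contrib <- c(
        mD1 + mD2, nD1 + nD2, mOUT, nOUT,  # ANY
        mD1, nD1, mOUT, nOUT,              # D1
        mD2, nD2, mOUT, nOUT               # D2
      )
      slots <- c(
        cell_slot(s, "ANY", c("mut_in", "site_in", "mut_out", "site_out")),
        cell_slot(s, "D1", c("mut_in", "site_in", "mut_out", "site_out")),
        cell_slot(s, "D2", c("mut_in", "site_in", "mut_out", "site_out"))
      )
      per_patient[row, slots] <- per_patient[row, slots] + contrib
    }
    flat <- colSums(per_patient)
  } else {
    for (u in seq_len(nrow(units))) {
      p <- store[[units$protein_id[u]]]
      inmask <- p$panel_mask
      nIN <- sum(inmask)
      pos <- vsplit[[u]]
      mIN <- sum(inmask[pos])
      s <- units$stratum[u]
      slots <- cell_slot(s, "ANY", c("mut_in", "site_in", "mut_out", "site_out"))
      flat[slots] <- flat[slots] +
        c(mIN, nIN, length(pos) - mIN, p$length - nIN)
    }
  }

  list(cells = cells_to_tibble(flat), flat = flat, per_patient = per_patient,
       excluded = excluded)
}

#' Patient-resampling bootstrap interval for the corrected ratio
#'
#' Resamples patients with replacement, recomputing the pooled-expressed
#' corrected density ratio for each display class on every replicate, and
#' returns the 2.5/97.5 percentile interval. The patient is the resampling
#' unit because all of a patient's mutations share one genotype. Replicates
#' with an undefined ratio (an empty cell after resampling) are dropped and
#' counted. Fully determined by `seed`.
#'
#' @param per_patient Per-patient contribution matrix from
#'   [accumulate_counts()] (patient mode).
#' @param reps Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param conf Interval coverage (default 0.95).
#' @return Tibble with `display_class`, `ci_low`, `ci_high`, `n_used`,
#'   `n_missing`.
#' @export
bootstrap_ci <- function(per_patient, reps = 500L, seed = 1L, conf = 0.95) {
  if (is.null(per_patient) || nrow(per_patient) < 2L) {
    data_error("bootstrap requires patient mode with at least 2 patients")
  }
  set.seed(seed)
  n <- nrow(per_patient)
  draws <- matrix(NA_real_, nrow = reps, ncol = length(DEPLETION_CLASSES),
                  dimnames = list(NULL, DEPLETION_CLASSES))
  for (r in seq_len(reps)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    flat <- colSums(per_patient * w)
    for (cl in DEPLETION_CLASSES) {
      draws[r, cl] <- corrected_from_flat(flat, cl)
    }
  }
  alpha <- (1 - conf) / 2
  dplyr::bind_rows(lapply(DEPLETION_CLASSES, function(cl) {
    x <- draws[, cl]
    ok <- !is.na(x)
    ci <- if (any(ok)) {
      stats::quantile(x[ok], c(alpha, 1 - alpha), names = FALSE, type = 7)
    } else {
      c(NA_real_, NA_real_)
    }
    tibble::tibble(display_class = cl, ci_low = ci[1], ci_high = ci[2],
                   n_used = sum(ok), n_missing = sum(!ok))
  }))
}
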