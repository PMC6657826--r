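# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations kept separate from the package's code
# paths: direct enumeration, double loops, sort-and-slice.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins, via log-binomial coefficients (the
# package route goes through stats::fisher.test / dhyper instead).
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  ks <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[ks == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Position-by-window containment scan.
oracle_mask <- function(L, starts, k = 9L) {
  vapply(seq_len(L), function(i) any(starts <= i & i <= starts + k - 1L),
         logical(1))
}

# Patient copy-count track by direct summation over carried alleles.
oracle_copy_count <- function(L, windows, copies, k = 9L) {
  cc <- integer(L)
  for (al in names(copies)) {
    st <- windows$start[windows$allele == al]
    if (length(st) == 0L) next
    cc <- cc + copies[[al]] * as.integer(oracle_mask(L, st, k))
  }
  cc
}

# Sort-and-slice quartile assignment for expressed genes: boundaries at the
# 25/50/75th percentiles, boundary values to the lower stratum.
oracle_strata <- function(values) {
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  paste0("Q", 1L + (values > qs[1]) + (values > qs[2]) + (values > qs[3]))
}

# A handcrafted miniature cohort used by IO round-trip and brute-force
# accumulation tests (3 patients, 5 proteins, 2 cancer types).
tiny_manual_cohort <- function() {
  set.seed(404)
  aas <- names(aa_frequencies())
  lens <- c(30L, 45L, 25L, 60L, 40L)
  proteins <- tibble::tibble(
    protein_id = paste0("P", 1:5),
    gene_id = paste0("G", 1:5),
    sequence = vapply(lens, function(L)
      paste(sample(aas, L, replace = TRUE), collapse = ""), character(1)),
    length = lens,
    valid = TRUE
  )
  windows <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P4", "P4", "P5"),
    allele = c("A*0101", "A*0201", "A*0201", "B*0702", "A*0101", "A*0201"),
    start = c(3L, 10L, 5L, 1L, 20L, 12L),
    affinity = c(10, 25, 40, 15, 30, 45)
  )
  genotypes_wide <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    A1 = c("A*0101", "A*0201", "A*1101"),
    A2 = c("A*0101", "A*0301", "A*3201"),
    B1 = c("B*0702", "B*0702", "B*0801"),
    B2 = c("B*4402", "B*0702", "B*1501")
  )
  genotypes <- genotypes_wide |>
    tidyr::pivot_longer(-sample_id, names_to = "slot", values_to = "allele") |>
    dplyr::mutate(locus = substr(slot, 1, 1)) |>
    dplyr::count(sample_id, locus, allele, name = "copies")
  expression <- tidyr::expand_grid(
    gene_id = proteins$gene_id, cancer_type = c("BRCA", "THCA")
  )
  expression$value <- c(0, 12, 55, 3, 0, 0, 140, 7, 31, 0)
  ct <- c(S1 = "BRCA", S2 = "BRCA", S3 = "THCA")
  n <- 40L
  pid <- sample(proteins$protein_id, n, replace = TRUE)
  pos <- vapply(pid, function(p)
    sample.int(proteins$length[match(p, proteins$protein_id)], 1L), integer(1))
  ref <- substr(proteins$sequence[match(pid, proteins$protein_id)], pos, pos)
  cls <- sample(c("missense", "synonymous"), n, replace = TRUE)
  alt <- ifelse(cls == "missense",
                vapply(ref, function(r) sample(setdiff(aas, r), 1L), character(1)),
                ref)
  sam <- sample(names(ct), n, replace = TRUE)
  variants <- tibble::tibble(
    sample_id = sam, protein_id = pid, position = unname(pos),
    ref_residue = unname(ref), alt_residue = unname(alt),
    variant_class = cls, cancer_type = unname(ct[sam])
  )
  list(proteins = proteins, windows = windows, genotypes = genotypes,
       genotypes_wide = genotypes_wide, expression = expression,
       variants = variants)
}

# Brute-force accumulation: loops every (unit, position), classifying each
# site by direct containment scans. Mirrors the semantics of
# accumulate_counts() with none of its vectorization.
oracle_accumulate <- function(cohort, config) {
  proteins <- cohort$proteins
  strata <- assign_strata_all(cohort$expression)
  mapped <- map_variants(cohort$variants, proteins)
  v <- mapped[mapped$validated & mapped$variant_class == config$variant_class, ]
  if (!identical(config$cancer_types, "ALL")) {
    v <- v[v$cancer_type %in% config$cancer_types, ]
  }
  v <- v[v$protein_id %in% proteins$protein_id[proteins$valid], ]
  cells <- list()
  add <- function(stratum, class, mi, si, mo, so) {
    key <- paste(stratum, class)
    old <- cells[[key]]
    if (is.null(old)) old <- c(0, 0, 0, 0)
    cells[[key]] <<- old + c(mi, si, mo, so)
  }
  stratum_of <- function(gene, ctype) {
    hit <- strata$gene_id == gene & strata$cancer_type == ctype
    if (!any(hit)) NA_character_ else as.character(strata$stratum[hit])
  }
  if (config$mode == "pan_allele") {
    units <- unique(v[, c("protein_id", "cancer_type")])
    for (u in seq_len(nrow(units))) {
      p <- proteins[proteins$protein_id == units$protein_id[u], ]
      s <- stratum_of(p$gene_id, units$cancer_type[u])
      if (is.na(s)) next
      w <- cohort$windows[cohort$windows$protein_id == p$protein_id &
                            cohort$windows$allele %in% config$allele_panel, ]
      inmask <- oracle_mask(p$length, w$start, config$peptide_length)
      vv <- v[v$protein_id == p$protein_id & v$cancer_type == units$cancer_type[u], ]
      add(s, "ANY", sum(inmask[vv$position]), sum(inmask),
          sum(!inmask[vv$position]), sum(!inmask))
    }
  } else {
    units <- unique(v[, c("sample_id", "protein_id", "cancer_type")])
    for (u in seq_len(nrow(units))) {
      p <- proteins[proteins$protein_id == units$protein_id[u], ]
      s <- stratum_of(p$gene_id, units$cancer_type[u])
      if (is.na(s)) next
      w <- cohort$windows[cohort$windows$protein_id == p$protein_id &
                            cohort$windows$allele %in% config$allele_panel, ]
      g <- cohort$genotypes[cohort$genotypes$sample_id == units$sample_id[u], ]
      copies <- stats::setNames(as.list(g$copies), g$allele)
      copies <- copies[names(copies) %in% config$allele_panel]
      cc <- oracle_copy_count(p$length, w, copies, config$peptide_length)
      inmask <- oracle_mask(p$length, w$start, config$peptide_length)
      cls <- ifelse(!inmask, "OUT",
                    ifelse(cc == 0, "D0", ifelse(cc == 1, "D1", "D2")))
      vv <- v[v$sample_id == units$sample_id[u] &
                v$protein_id == p$protein_id, ]
      vc <- cls[vv$position]
      if (config$patient_universe == "neoantigenic" &&
          sum(cls %in% c("D1", "D2")) == 0) next
      add(s, "ANY", sum(vc %in% c("D1", "D2")), sum(cls %in% c("D1", "D2")),
          sum(vc == "OUT"), sum(cls == "OUT"))
      add(s, "D1", sum(vc == "D1"), sum(cls == "D1"),
          sum(vc == "OUT"), sum(cls == "OUT"))
      add(s, "D2", sum(vc == "D2"), sum(cls == "D2"),
          sum(vc == "OUT"), sum(cls == "OUT"))
    }
  }
  cells
}

# Compare oracle_accumulate cells with accumulate_counts output.
expect_cells_match <- function(cohort, config) {
  mapped <- map_variants(cohort$variants, cohort$proteins)
  strata <- assign_strata_all(cohort$expression)
  acc <- accumulate_counts(mapped, cohort$proteins, cohort$windows,
                           cohort$genotypes, strata, config)
  oc <- oracle_accumulate(cohort, config)
  for (i in seq_len(nrow(acc$cells))) {
    row <- acc$cells[i, ]
    key <- paste(row$stratum, row$display_class)
    got <- c(row$mut_in, row$site_in, row$mut_out, row$site_out)
    want <- oc[[key]]
    if (is.null(want)) want <- c(0, 0, 0, 0)
    expect_equal(unname(got), unname(want),
                 info = paste("cell", key, config$mode))
  }
}
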