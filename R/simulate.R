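#' Amino-acid composition used by the cohort generator
#'
#' Approximate human proteome residue frequencies; random protein sequences
#' are drawn from this composition so that binder preferences and
#' residue-dependent mutation rates act on a realistic alphabet.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_frequencies <- function() {
  f <- c(
    A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
    Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
    L = 0.100, K = 0.058, M = 0.021, F = 0.037, P = 0.063,
    S = 0.083, T = 0.054, W = 0.012, Y = 0.027, V = 0.060
  )
  f / sum(f)
}

# Per-allele residue preferences of the toy position-weight-matrix binder.
# Every allele shares a hydrophobic core (L, V, I) plus three allele-specific
# residues, so that (a) display masks of different alleles overlap partially
# (creating D2 sites) and (b) masks are enriched for particular residues
# (creating the sequence-composition confounder the correction removes).
toy_pwm_preferences <- function() {
  core <- c("L", "V", "I")
  spec <- list(
    "A*0101" = c("Y", "T", "S"), "A*0201" = c("M", "A", "T"),
    "A*0301" = c("K", "F", "S"), "A*2402" = c("F", "Y", "W"),
    "A*2601" = c("E", "T", "F"), "B*0702" = c("P", "R", "M"),
    "B*0801" = c("K", "R", "F"), "B*1501" = c("Q", "Y", "F"),
    "B*2705" = c("R", "K", "H"), "B*3901" = c("R", "H", "Q"),
    "B*4001" = c("E", "D", "A"), "B*5801" = c("A", "T", "W")
  )
  lapply(spec, function(s) c(core, s))
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 200 patients, 1000 proteins of 200-400 residues (~100k missense
#' mutations at the default rates), the 12-allele panel with population
#' frequencies, a toy PWM binder whose masks are residue-biased, 35%
#' undetected genes with log-normal expression otherwise, a hydrophobic
#' mutation-rate multiplier of 1.15 (the confounder; it shifts the raw
#' in/out ratio of non-expressed genes by a few percent, the scale seen in
#' real cohorts), and immune survival
#' probabilities 0.9 (D1) and 0.77 (D2) for missense mutations at expressed,
#' patient-displayed sites. Synonymous candidates always survive.
#'
#' @param seed Integer seed; every stochastic step of the generator flows
#'   from it.
#' @param n_proteins,protein_length Number of proteins and (min, max) length
#'   range in residues.
#' @param n_patients Number of patients.
#' @param panel Tibble of panel alleles with `allele`, `locus`, `frequency`
#'   (see [default_hla_panel()]); per locus the remainder frequency is
#'   carried by panel-external alleles without display predictions.
#' @param binder_model `"toy_pwm"` (sequence-biased windows) or
#'   `"random_windows"` (sequence-independent windows).
#' @param window_density Per-start binder probability for
#'   `"random_windows"`.
#' @param expression List: `frac_undetected`, `meanlog`, `sdlog` of the
#'   log-normal RSEM-scale medians of detectably expressed genes.
#' @param mutation List: `missense_rate` and `synonymous_rate` (per-site
#'   candidate probability per patient) and `residue_multiplier` (named
#'   per-residue rate multipliers; unnamed residues get 1).
#' @param survival Named vector, survival probability of a missense candidate
#'   at an expressed site displayed by one (`D1`) or two or more (`D2`)
#'   carried allele copies; all other candidates survive with probability 1.
#' @param cancer_types Named probability vector over cancer type codes.
#' @param peptide_length Binder window length (default 9).
#' @return List of class `"nd_simconfig"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 1000L,
                              protein_length = c(200L, 400L),
                              n_patients = 200L,
                              panel = default_hla_panel(),
                              binder_model = c("toy_pwm", "random_windows"),
                              window_density = 0.004,
                              expression = list(frac_undetected = 0.35,
                                                meanlog = 4, sdlog = 2),
                              mutation = list(
                                missense_rate = 0.0015,
                                synonymous_rate = 0.0015,
                                residue_multiplier = c(
                                  F = 1.15, I = 1.15, L = 1.15, M = 1.15,
                                  V = 1.15, W = 1.15, Y = 1.15
                                )
                              ),
                              survival = c(D1 = 0.9, D2 = 0.77),
                              cancer_types = c(BRCA = 0.4, THCA = 0.2,
                                               STAD = 0.2, UCEC = 0.2),
                              peptide_length = 9L) {
  binder_model <- match.arg(binder_model)
  stopifnot(
    length(protein_length) == 2L, protein_length[1] <= protein_length[2],
    all(survival >= 0), all(survival <= 1),
    expression$frac_undetected >= 0, expression$frac_undetected < 1,
    abs(sum(cancer_types) - 1) < 1e-8
  )
  if (protein_length[1] < peptide_length) {
    config_error("minimum protein length is shorter than the peptide length")
  }
  for (lc in unique(panel$locus)) {
    if (sum(panel$frequency[panel$locus == lc]) > 1 + 1e-8) {
      config_error(sprintf("panel allele frequencies at locus %s exceed 1", lc))
    }
  }
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length),
         n_patients = as.integer(n_patients), panel = panel,
         binder_model = binder_model, window_density = window_density,
         expression = expression, mutation = mutation, survival = survival,
         cancer_types = cancer_types,
         peptide_length = as.integer(peptide_length)),
    class = "nd_simconfig"
  )
}

# External (carried-but-unpredicted) alleles used to fill the remainder of
# each locus's frequency mass; they can never display.
external_alleles <- function(locus) {
  switch(locus,
         A = c("A*1101", "A*3201", "A*6801"),
         B = c("B*3501", "B*4402", "B*5101"),
         paste0(locus, "*9901"))
}

simulate_proteins <- function(sim) {
  comp <- aa_frequencies()
  lens <- sample(seq(sim$protein_length[1], sim$protein_length[2]),
                 sim$n_proteins, replace = TRUE)
  ids <- sprintf("P%04d", seq_len(sim$n_proteins))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(comp), L, replace = TRUE, prob = comp), collapse = "")
  }, character(1))
  tibble::tibble(
    protein_id = ids,
    gene_id = sprintf("G%04d", seq_len(sim$n_proteins)),
    sequence = seqs,
    length = lens,
    valid = TRUE
  )
}

# Window score = number of allele-preferred residues in the 9-mer; affinity
# maps the score onto the prediction scale so that ~score >= 7 windows fall
# at or below the strong-binder threshold of 50. Only near-threshold windows
# (score >= 6) are emitted, mimicking a prediction table pre-filtered to
# candidate binders; weaker windows carry no information for this analysis.
toy_pwm_windows <- function(protein, sim) {
  prefs <- toy_pwm_preferences()
  res <- strsplit(protein$sequence, "")[[1]]
  k <- sim$peptide_length
  n_start <- protein$length - k + 1L
  if (n_start < 1L) return(NULL)
  out <- vector("list", length(prefs))
  for (i in seq_along(prefs)) {
    hit <- as.integer(res %in% prefs[[i]])
    cs <- c(0L, cumsum(hit))
    score <- cs[(k + 1L):(protein$length + 1L)] - cs[1:n_start]
    cand <- which(score >= 6L)
    if (length(cand) == 0L) next
    aff <- 50 * 2 ^ (6.5 - score[cand]) * stats::runif(length(cand), 0.9, 1.1)
    out[[i]] <- tibble::tibble(
      protein_id = protein$protein_id,
      allele = names(prefs)[i],
      start = cand,
      affinity = aff
    )
  }
  dplyr::bind_rows(out)
}

random_windows <- function(protein, sim) {
  k <- sim$peptide_length
  n_start <- protein$length - k + 1L
  if (n_start < 1L) return(NULL)
  out <- vector("list", nrow(sim$panel))
  for (i in seq_len(nrow(sim$panel))) {
    strong <- which(stats::runif(n_start) < sim$window_density)
    weak <- which(stats::runif(n_start) < sim$window_density / 2)
    n_s <- length(strong); n_w <- length(weak)
    if (n_s + n_w == 0L) next
    out[[i]] <- tibble::tibble(
      protein_id = protein$protein_id,
      allele = sim$panel$allele[i],
      start = c(strong, weak),
      affinity = c(stats::runif(n_s, 25, 50), stats::runif(n_w, 51, 200))
    )
  }
  dplyr::bind_rows(out)
}

simulate_predictions <- function(proteins, sim) {
  gen <- switch(sim$binder_model,
                toy_pwm = toy_pwm_windows,
                random_windows = random_windows)
  rows <- lapply(seq_len(nrow(proteins)), function(i) gen(proteins[i, ], sim))
  preds <- dplyr::bind_rows(rows)
  if (nrow(preds) == 0L) {
    config_error("binder model produced no candidate windows; proteins too short?")
  }
  preds
}

simulate_genotypes <- function(sim) {
  draws <- list()
  for (lc in unique(sim$panel$locus)) {
    alleles <- sim$panel$allele[sim$panel$locus == lc]
    freq <- sim$panel$frequency[sim$panel$locus == lc]
    ext <- external_alleles(lc)
    pool <- c(alleles, ext)
    prob <- c(freq, rep((1 - sum(freq)) / length(ext), length(ext)))
    draws[[paste0(lc, "1")]] <- sample(pool, sim$n_patients, TRUE, prob)
    draws[[paste0(lc, "2")]] <- sample(pool, sim$n_patients, TRUE, prob)
  }
  tibble::as_tibble(c(
    list(sample_id = sprintf("S%04d", seq_len(sim$n_patients))), draws
  ))
}

simulate_expression <- function(proteins, sim) {
  cts <- names(sim$cancer_types)
  grid <- expand.grid(gene_id = proteins$gene_id, cancer_type = cts,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  undetected <- stats::runif(n) < sim$expression$frac_undetected
  value <- ifelse(undetected, 0,
                  stats::rlnorm(n, sim$expression$meanlog, sim$expression$sdlog))
  tibble::tibble(gene_id = grid$gene_id, cancer_type = grid$cancer_type,
                 value = value) |>
    dplyr::arrange(.data$gene_id, .data$cancer_type)
}

#' Draw immune-thinned somatic mutations for one patient
#'
#' The generator's causal core. Candidate mutations arise site-by-site with
#' probability `rate * residue_multiplier`; a missense candidate at an
#' expressed site displayed by `c` carried allele copies survives immune
#' surveillance with probability `survival["D1"]` (`c == 1`) or
#' `survival["D2"]` (`c >= 2`), and with probability 1 everywhere else.
#' Synonymous candidates always survive (they leave the peptide unchanged),
#' which builds the negative control into the cohort by construction.
#'
#' @param residues Character vector of wild-type residues (concatenated
#'   sites, any number of proteins).
#' @param copy_count Integer vector: displaying-allele copies the patient
#'   carries at each site.
#' @param expressed Logical vector: is the site's gene detectably expressed
#'   in the patient's cancer type?
#' @param sim A [simulation_config()].
#' @return List with `missense` and `synonymous` integer site indices of
#'   surviving mutations, plus `n_thinned` (missense candidates removed by
#'   immune clearance).
#' @export
sample_thinned_mutations <- function(residues, copy_count, expressed, sim) {
  mult <- rep(1, length(residues))
  rm_ <- sim$mutation$residue_multiplier
  hit <- residues %in% names(rm_)
  mult[hit] <- rm_[residues[hit]]

  cand_mis <- which(stats::runif(length(residues)) <
                      sim$mutation$missense_rate * mult)
  surv <- rep(1, length(cand_mis))
  cc <- copy_count[cand_mis]
  ex <- expressed[cand_mis]
  surv[ex & cc == 1L] <- sim$survival[["D1"]]
  surv[ex & cc >= 2L] <- sim$survival[["D2"]]
  keep <- stats::runif(length(cand_mis)) < surv
  mis <- cand_mis[keep]

  cand_syn <- which(stats::runif(length(residues)) <
                      sim$mutation$synonymous_rate * mult)
  list(missense = mis, synonymous = cand_syn,
       n_thinned = sum(!keep),
       n_candidates = length(cand_mis))
}

#' Generate a complete synthetic cohort
#'
#' Produces every input the depletion analysis consumes — protein sequences,
#' strong-binder predictions, patient HLA genotypes, a gene-by-cancer-type
#' expression table, and a somatic variant table in which missense mutations
#' at expressed, patient-displayed sites have been thinned by the configured
#' survival probabilities — plus a truth record of the generating
#' parameters. Fully deterministic given `sim$seed`. When `dir` is given the
#' five input files and `truth.json` are also written in the formats the
#' readers accept.
#'
#' @param sim A [simulation_config()].
#' @param dir Optional output directory.
#' @return A cohort list (`proteins`, `windows` (threshold-retained),
#'   `predictions` (full table incl. above-threshold rows), `genotypes`,
#'   `genotypes_wide`, `expression`, `variants`, `truth`).
#' @export
generate_cohort <- function(sim = simulation_config(), dir = NULL) {
  set.seed(sim$seed)
  proteins <- simulate_proteins(sim)
  predictions <- simulate_predictions(proteins, sim)
  genotypes_wide <- simulate_genotypes(sim)
  expression <- simulate_expression(proteins, sim)

  threshold <- 50
  windows <- predictions[predictions$affinity <= threshold, , drop = FALSE]

  # concatenated site-level structures shared by all patients
  n_sites <- sum(proteins$length)
  site_protein <- rep.int(seq_len(nrow(proteins)), proteins$length)
  site_pos <- sequence(proteins$length)
  site_res <- unlist(strsplit(proteins$sequence, ""), use.names = FALSE)
  offset <- c(0L, cumsum(proteins$length))

  panel <- sim$panel$allele
  G <- matrix(0, nrow = n_sites, ncol = length(panel),
              dimnames = list(NULL, panel))
  if (nrow(windows) > 0L) {
    wp <- match(windows$protein_id, proteins$protein_id)
    for (j in seq_along(panel)) {
      sel <- windows$allele == panel[j]
      if (!any(sel)) next
      starts <- offset[wp[sel]] + windows$start[sel]
      covered <- rep(starts, each = sim$peptide_length) +
        rep(0:(sim$peptide_length - 1L), times = length(starts))
      G[unique(covered), j] <- 1
    }
  }

  cts <- names(sim$cancer_types)
  patient_ct <- sample(cts, sim$n_patients, TRUE, prob = sim$cancer_types)
  expr_mat <- matrix(FALSE, nrow = nrow(proteins), ncol = length(cts),
                     dimnames = list(NULL, cts))
  for (ct in cts) {
    e <- expression[expression$cancer_type == ct, , drop = FALSE]
    expr_mat[, ct] <- e$value[match(proteins$gene_id, e$gene_id)] > 0
  }

  # per-patient panel copy counts
  copies_mat <- matrix(0, nrow = sim$n_patients, ncol = length(panel),
                       dimnames = list(genotypes_wide$sample_id, panel))
  allele_cols <- setdiff(names(genotypes_wide), "sample_id")
  for (col in allele_cols) {
    j <- match(genotypes_wide[[col]], panel)
    ok <- !is.na(j)
    idx <- cbind(which(ok), j[ok])
    copies_mat[idx] <- copies_mat[idx] + 1
  }

  truth_counts <- c(candidates = 0L, thinned = 0L)
  out <- vector("list", sim$n_patients)
  for (p in seq_len(sim$n_patients)) {
    cc <- as.integer(G %*% copies_mat[p, ])
    expressed <- expr_mat[site_protein, patient_ct[p]]
    draws <- sample_thinned_mutations(site_res, cc, expressed, sim)
    idx <- c(draws$missense, draws$synonymous)
    if (length(idx) == 0L) next
    cls <- rep(c("missense", "synonymous"),
               c(length(draws$missense), length(draws$synonymous)))
    ref <- site_res[idx]
    alt <- ifelse(cls == "missense",
                  vapply(ref, function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                         character(1)),
                  ref)
    out[[p]] <- tibble::tibble(
      sample_id = genotypes_wide$sample_id[p],
      protein_id = proteins$protein_id[site_protein[idx]],
      gene_id = proteins$gene_id[site_protein[idx]],
      position = site_pos[idx],
      ref_residue = ref,
      alt_residue = unname(alt),
      variant_class = cls,
      cancer_type = patient_ct[p]
    )
    truth_counts["candidates"] <- truth_counts["candidates"] + draws$n_candidates
    truth_counts["thinned"] <- truth_counts["thinned"] + draws$n_thinned
  }
  variants <- dplyr::bind_rows(out)

  genotypes <- genotypes_wide |>
    tidyr::pivot_longer(-"sample_id", names_to = "slot", values_to = "allele") |>
    dplyr::mutate(locus = substr(.data$slot, 1L, 1L)) |>
    dplyr::count(.data$sample_id, .data$locus, .data$allele, name = "copies") |>
    dplyr::arrange(.data$sample_id, .data$locus, .data$allele)

  truth <- list(
    seed = sim$seed,
    survival = as.list(sim$survival),
    expected_corrected_ratio = as.list(sim$survival),
    n_patients = sim$n_patients,
    n_proteins = sim$n_proteins,
    n_missense = sum(variants$variant_class == "missense"),
    n_synonymous = sum(variants$variant_class == "synonymous"),
    n_missense_candidates = unname(truth_counts["candidates"]),
    n_thinned = unname(truth_counts["thinned"])
  )

  cohort <- list(
    proteins = proteins, windows = windows, predictions = predictions,
    genotypes = genotypes, genotypes_wide = genotypes_wide,
    expression = expression, variants = variants, truth = truth
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Emits `proteins.fasta`, `predictions.tsv`, `genotypes.tsv`,
#' `expression.tsv`, `variants.tsv` and `truth.json` in the dialects the
#' package readers accept. Byte-identical across runs for the same cohort.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.fasta"),
    predictions = file.path(dir, "predictions.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    variants = file.path(dir, "variants.tsv"),
    truth = file.path(dir, "truth.json")
  )
  seqs <- Biostrings::BStringSet(cohort$proteins$sequence)
  names(seqs) <- paste0(cohort$proteins$protein_id,
                        " gene=", cohort$proteins$gene_id)
  Biostrings::writeXStringSet(seqs, paths["proteins"], width = 70L)
  readr::write_tsv(cohort$predictions, paths["predictions"], progress = FALSE)
  readr::write_tsv(cohort$genotypes_wide, paths["genotypes"], progress = FALSE)
  readr::write_tsv(cohort$expression, paths["expression"], progress = FALSE)
  readr::write_tsv(cohort$variants, paths["variants"], progress = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Convenience loader running every reader with validation; errors if any
#' table produces rejects (generated cohorts must parse cleanly).
#'
#' @param dir Cohort directory.
#' @param config An [analysis_config()] (threshold for window retention).
#' @return A cohort list usable by [run_analysis()].
#' @export
read_cohort <- function(dir, config = analysis_config()) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  preds <- read_binding_predictions(file.path(dir, "predictions.tsv"),
                                    config, proteins)
  vars <- read_variants(file.path(dir, "variants.tsv"))
  if (nrow(preds$rejects) > 0L || nrow(vars$rejects) > 0L) {
    data_error("cohort directory contains unparseable rows")
  }
  list(
    proteins = proteins,
    windows = preds$windows,
    genotypes = read_hla(file.path(dir, "genotypes.tsv")),
    expression = read_expression(file.path(dir, "expression.tsv")),
    variants = vars$variants
  )
}
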