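#' Analysis configuration
#'
#' Bundles every tunable of a depletion run. Defaults reproduce the headline
#' setup: 9-mer strong binders at prediction score <= 50 (lower = stronger),
#' the 12-allele HLA-A/B panel, missense variants, 500 bootstrap replicates,
#' ratios reported to 2 decimals.
#'
#' @param mode `"pan_allele"` (an idealized patient carrying every panel
#'   allele) or `"patient"` (only display predictions for alleles the patient
#'   actually carries count).
#' @param variant_class `"missense"` or `"synonymous"` (the latter is the
#'   negative control: synonymous changes leave the peptide intact).
#' @param display_classes Display-copy classes to report in patient mode, a
#'   subset of `c("ANY", "D1", "D2")`. `ANY` pools sites displayed by at least
#'   one carried allele copy.
#' @param cancer_types `"ALL"` or a character vector restricting the run to
#'   those cancer type codes.
#' @param strong_binder_threshold Retain predicted 9-mers with affinity score
#'   at or below this value (default 50; lower score = stronger binder).
#' @param peptide_length Peptide window length in residues (default 9).
#' @param allele_panel Character vector of alleles with available predictions
#'   (default: the 12-allele panel of [default_hla_panel()]).
#' @param patient_universe Opportunity universe in patient mode:
#'   `"all_mutated"` counts sites once per (patient, mutated protein) pair;
#'   `"neoantigenic"` restricts to pairs where the patient carries at least
#'   one displaying allele for some residue of the protein.
#' @param bootstrap_reps Number of patient-resampling bootstrap replicates.
#' @param rng_seed Seed driving every stochastic step of the run.
#' @param rounding Decimals used at the reporting layer only; all arithmetic
#'   is done at full precision.
#' @return A list of class `"nd_config"`.
#' @export
analysis_config <- function(mode = c("pan_allele", "patient"),
                            variant_class = c("missense", "synonymous"),
                            display_classes = c("ANY", "D1", "D2"),
                            cancer_types = "ALL",
                            strong_binder_threshold = 50,
                            peptide_length = 9L,
                            allele_panel = default_hla_panel()$allele,
                            patient_universe = c("all_mutated", "neoantigenic"),
                            bootstrap_reps = 500L,
                            rng_seed = 1L,
                            rounding = 2L) {
  mode <- match.arg(mode)
  variant_class <- match.arg(variant_class)
  patient_universe <- match.arg(patient_universe)
  display_classes <- match.arg(display_classes, c("ANY", "D1", "D2"),
                               several.ok = TRUE)
  stopifnot(
    strong_binder_threshold > 0,
    peptide_length >= 8L,
    bootstrap_reps >= 1L
  )
  structure(
    list(
      mode = mode,
      variant_class = variant_class,
      display_classes = display_classes,
      cancer_types = cancer_types,
      strong_binder_threshold = strong_binder_threshold,
      peptide_length = as.integer(peptide_length),
      allele_panel = allele_panel,
      patient_universe = patient_universe,
      bootstrap_reps = as.integer(bootstrap_reps),
      rng_seed = as.integer(rng_seed),
      rounding = as.integer(rounding)
    ),
    class = "nd_config"
  )
}

nd_error <- function(msg, class) {
  stop(structure(
    class = c(class, "nd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) nd_error(msg, "nd_config_error")
data_error <- function(msg) nd_error(msg, "nd_data_error")
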