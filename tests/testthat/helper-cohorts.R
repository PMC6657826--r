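# Shared cohort constructors for the acceptance suite. The reference cohort
# (full study conditions: 200 patients, ~100k missense mutations, survival
# D1 = 0.9 / D2 = 0.77) is generated once per test run and shared between
# the missense-recovery and synonymous-control tests.

.cohort_cache <- new.env(parent = emptyenv())

reference_cohort <- function() {
  if (is.null(.cohort_cache$reference)) {
    .cohort_cache$reference <- generate_cohort(simulation_config(seed = 101L))
  }
  .cohort_cache$reference
}

# Null study conditions: no immune thinning, but windows remain
# residue-biased (toy PWM) and mutation rates residue-dependent, so the raw
# in/out ratio is confounded while the corrected ratio should be 1. Many
# small proteins keep the gene-set composition variance (which patient
# resampling cannot see) well below the bootstrap width.
null_calibration_sim <- function(seed) {
  simulation_config(
    seed = seed, n_proteins = 800L, protein_length = c(100L, 200L),
    n_patients = 60L,
    mutation = list(
      missense_rate = 0.00075, synonymous_rate = 0.00075,
      residue_multiplier = c(F = 1.15, I = 1.15, L = 1.15, M = 1.15,
                             V = 1.15, W = 1.15, Y = 1.15)
    ),
    survival = c(D1 = 1, D2 = 1)
  )
}

tiny_fixture_sim <- function(seed = 5L) {
  simulation_config(
    seed = seed, n_proteins = 5L, protein_length = c(40L, 90L),
    n_patients = 10L,
    mutation = list(missense_rate = 0.01, synonymous_rate = 0.01,
                    residue_multiplier = c(L = 1.15))
  )
}
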