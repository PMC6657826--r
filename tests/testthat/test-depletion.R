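test_that("density ratio arithmetic", {
  expect_equal(density_ratio(3, 10, 3, 10), 1)
  expect_equal(density_ratio(1, 10, 3, 10), 1 / 3)
  expect_equal(density_ratio(5, 100, 10, 100), 0.5)
  expect_equal(density_ratio(2, 50, 9, 150), 0.04 / 0.06)
  expect_warning(r <- density_ratio(1, 10, 0, 10), "undefined")
  expect_true(is.na(r))
})

test_that("Fisher test handles degenerate and oracle-checked tables", {
  # no signal
  expect_equal(fisher_test(0, 10, 0, 10), 1)
  # strong contingency vs exhaustive enumeration
  expect_equal(fisher_test(1, 10, 9, 10), oracle_fisher_p(1, 9, 9, 1),
               tolerance = 1e-12)
  # same proportions, 10x the counts -> smaller p (power grows with n)
  p_small <- fisher_test(2, 10, 6, 10)
  p_big <- fisher_test(20, 100, 60, 100)
  expect_lt(p_big, p_small)
  expect_equal(p_small, oracle_fisher_p(2, 8, 6, 4), tolerance = 1e-12)
  expect_equal(p_big, oracle_fisher_p(20, 80, 60, 40), tolerance = 1e-12)
  expect_error(fisher_test(5, 3, 1, 10), "negative", class = "nd_data_error")
})

test_that("corrected ratio divides out the non-expressed control", {
  expect_equal(round(corrected_ratio(0.91, 0.99), 2), 0.92)
  expect_equal(round(corrected_ratio(0.79, 1.02), 2), 0.77)
  for (r in c(0.2, 0.77, 1, 1.3)) expect_equal(corrected_ratio(r, 1), r)
  expect_error(corrected_ratio(0.9, 0), "positive", class = "nd_data_error")
})

test_that("clearance percent converts corrected ratios; >1 flags no depletion", {
  expect_equal(clearance_percent(0.77), 23)
  expect_equal(clearance_percent(0.54), 46)
  expect_equal(clearance_percent(1), 0)
  flagged <- clearance_percent(1.1)
  expect_equal(as.numeric(flagged), 0)
  expect_true(attr(flagged, "no_depletion"))
  expect_error(clearance_percent(0), class = "nd_data_error")
})

test_that("worked 2x2 example: equal opportunity, unequal mutations", {
  # one protein, 10 in-sites, 10 out-sites
  expect_equal(density_ratio(3, 10, 3, 10), 1)
  expect_equal(density_ratio(1, 10, 3, 10), 0.3333333, tolerance = 1e-6)
})

test_that("accumulated counts equal a brute-force double loop (both modes)", {
  cohort <- tiny_manual_cohort()
  for (mode in c("pan_allele", "patient")) {
    for (cls in c("missense", "synonymous")) {
      expect_cells_match(cohort, analysis_config(mode = mode, variant_class = cls))
    }
  }
  expect_cells_match(cohort, analysis_config(mode = "patient",
                                             patient_universe = "neoantigenic"))
  expect_cells_match(cohort, analysis_config(mode = "patient",
                                             cancer_types = "BRCA"))
})

test_that("accumulation on a randomized small cohort matches brute force", {
  sim <- simulation_config(seed = 77, n_proteins = 8L,
                           protein_length = c(30L, 90L), n_patients = 5L,
                           mutation = list(missense_rate = 0.02,
                                           synonymous_rate = 0.02,
                                           residue_multiplier = c(L = 1.2)))
  cohort <- generate_cohort(sim)
  for (mode in c("pan_allele", "patient")) {
    expect_cells_match(cohort, analysis_config(mode = mode))
  }
})

test_that("mutation conservation: in + out + excluded = validated in scope", {
  cohort <- tiny_manual_cohort()
  cfg <- analysis_config(mode = "patient")
  mapped <- map_variants(cohort$variants, cohort$proteins)
  strata <- assign_strata_all(cohort$expression)
  acc <- accumulate_counts(mapped, cohort$proteins, cohort$windows,
                           cohort$genotypes, strata, cfg)
  any_cells <- acc$cells[acc$cells$display_class == "ANY", ]
  counted <- sum(any_cells$mut_in) + sum(any_cells$mut_out)
  in_scope <- sum(mapped$validated & mapped$variant_class == "missense")
  expect_equal(
    counted + acc$excluded[["d0_site"]] + acc$excluded[["missing_expression"]] +
      acc$excluded[["unknown_protein"]],
    in_scope
  )
})

test_that("bootstrap is seed-deterministic and collapses for identical patients", {
  cohort <- tiny_manual_cohort()
  cfg <- analysis_config(mode = "patient")
  mapped <- map_variants(cohort$variants, cohort$proteins)
  strata <- assign_strata_all(cohort$expression)
  acc <- accumulate_counts(mapped, cohort$proteins, cohort$windows,
                           cohort$genotypes, strata, cfg)
  ci1 <- bootstrap_ci(acc$per_patient, reps = 100, seed = 5)
  ci2 <- bootstrap_ci(acc$per_patient, reps = 100, seed = 5)
  expect_identical(ci1, ci2)
  # seed sensitivity, on a cohort large enough for non-degenerate replicates
  big <- generate_cohort(simulation_config(
    seed = 3, n_proteins = 40L, protein_length = c(60L, 120L),
    n_patients = 12L,
    mutation = list(missense_rate = 0.01, synonymous_rate = 0.01,
                    residue_multiplier = c(L = 1.15))
  ))
  mb <- map_variants(big$variants, big$proteins)
  accb <- accumulate_counts(mb, big$proteins, big$windows, big$genotypes,
                            assign_strata_all(big$expression), cfg)
  cb1 <- bootstrap_ci(accb$per_patient, reps = 100, seed = 5)
  cb2 <- bootstrap_ci(accb$per_patient, reps = 100, seed = 6)
  expect_false(identical(cb1$ci_low, cb2$ci_low))
  # two identical patients: no between-patient variance, interval width ~0
  one <- acc$per_patient[1, , drop = FALSE]
  twin <- rbind(one, one)
  point <- neodeplete:::corrected_from_flat(colSums(twin), "ANY")
  ci <- bootstrap_ci(twin, reps = 50, seed = 1)
  if (!is.na(point)) {
    expect_equal(ci$ci_low[ci$display_class == "ANY"], point, tolerance = 1e-12)
    expect_equal(ci$ci_high[ci$display_class == "ANY"], point, tolerance = 1e-12)
  }
  expect_error(bootstrap_ci(one), "2 patients", class = "nd_data_error")
})
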