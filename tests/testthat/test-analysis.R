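test_that("variant mapping validates the wild-type residue", {
  proteins <- tibble::tibble(
    protein_id = c("P1", "P2"), gene_id = c("G1", "G1"),
    sequence = c("ACDEFGHIKL", "ACDEFGHIKLMNPQ"),
    length = c(10L, 14L), valid = TRUE
  )
  v <- tibble::tibble(
    sample_id = "S1", protein_id = c("P1", "P1", "P1", ""),
    position = c(3L, 3L, 99L, 2L),
    ref_residue = c("D", "W", "A", "C"), alt_residue = c("V", "V", "V", "V"),
    variant_class = "missense", cancer_type = "BRCA",
    gene_id = "G1"
  )
  mapped <- map_variants(v, proteins)
  expect_equal(mapped$validated, c(TRUE, FALSE, FALSE, TRUE))
  # blank protein_id resolved to the longest isoform of the gene
  expect_equal(mapped$protein_id[4], "P2")
  expect_equal(attr(mapped, "n_isoform_fallback"), 1L)
})

test_that("run_analysis produces the documented results schema", {
  cohort <- tiny_manual_cohort()
  an <- run_analysis(cohort, analysis_config(mode = "patient"))
  expect_s3_class(an, "depletion_analysis")
  expect_named(
    an$results,
    c("cancer_scope", "variant_class", "mode", "stratum", "display_class",
      "mut_in", "site_in", "mut_out", "site_out", "ratio", "p_value",
      "corrected_ratio", "ci_low", "ci_high", "clearance_percent",
      "n_bootstrap", "seed")
  )
  expect_setequal(unique(an$results$display_class), c("ANY", "D1", "D2"))
  expect_true(all(an$results$stratum %in%
                    c("UNDETECTED", paste0("Q", 1:4), "EXPRESSED")))
  pan <- run_analysis(cohort, analysis_config(mode = "pan_allele"))
  expect_setequal(unique(pan$results$display_class), "ANY")
  # manifest reaches every reported number
  expect_equal(pan$manifest$n_variant_rows, nrow(cohort$variants))
  expect_true(pan$manifest$n_validated <= pan$manifest$n_variant_rows)
})

test_that("cancer-type scoping restricts the analysis and labels the scope", {
  cohort <- tiny_manual_cohort()
  an <- run_analysis(cohort, analysis_config(mode = "pan_allele",
                                             cancer_types = "BRCA"))
  expect_equal(unique(an$results$cancer_scope), "BRCA")
  all_ct <- run_analysis(cohort, analysis_config(mode = "pan_allele"))
  expect_true(sum(an$results$mut_in + an$results$mut_out, na.rm = TRUE) <=
                sum(all_ct$results$mut_in + all_ct$results$mut_out, na.rm = TRUE))
})

test_that("report summary prints rounded ratios and a clearance line", {
  cohort <- generate_cohort(
    simulation_config(seed = 12, n_proteins = 80L,
                      protein_length = c(60L, 150L), n_patients = 25L,
                      mutation = list(missense_rate = 0.008,
                                      synonymous_rate = 0.008,
                                      residue_multiplier = c(L = 1.15)),
                      survival = c(D1 = 0.5, D2 = 0.5))
  )
  an <- run_analysis(cohort, analysis_config(mode = "patient"))
  out_text <- utils::capture.output(tbl <- report_summary(an))
  expect_true(any(grepl("corrected_ratio", out_text)))
  e <- an$results[an$results$stratum == "EXPRESSED" &
                    an$results$display_class == "ANY", ]
  if (!is.na(e$corrected_ratio) && e$corrected_ratio < 1) {
    expect_true(any(grepl("clearance", out_text)))
  }
  expect_equal(tbl$ratio, round(an$results$ratio, 2))
})

test_that("written results round-trip and reruns are byte-identical", {
  cohort <- tiny_manual_cohort()
  cfg <- analysis_config(mode = "patient", bootstrap_reps = 25L, rng_seed = 2L)
  d1 <- tempfile(); d2 <- tempfile()
  an1 <- run_analysis(cohort, cfg, bootstrap = TRUE)
  write_results(an1, d1)
  an2 <- run_analysis(cohort, cfg, bootstrap = TRUE)
  write_results(an2, d2)
  expect_identical(readBin(file.path(d1, "report.json"), "raw", 1e7),
                   readBin(file.path(d2, "report.json"), "raw", 1e7))
  back <- readr::read_tsv(file.path(d1, "results.tsv"),
                          show_col_types = FALSE)
  expect_equal(back$ratio, an1$results$ratio, tolerance = 1e-12)
  expect_equal(nrow(back), nrow(an1$results))
  # empty results still write a header-only TSV
  an_empty <- an1
  an_empty$results <- an1$results[0, ]
  write_results(an_empty, file.path(d1, "empty"))
  hdr <- readLines(file.path(d1, "empty", "results.tsv"))
  expect_equal(length(hdr), 1L)
})

test_that("null cohort: confounded raw ratio but corrected ratio near 1", {
  sim <- simulation_config(
    seed = 33, n_proteins = 400L, protein_length = c(100L, 200L),
    n_patients = 60L,
    mutation = list(missense_rate = 0.004, synonymous_rate = 0.004,
                    residue_multiplier = c(F = 1.5, I = 1.5, L = 1.5,
                                           M = 1.5, V = 1.5, W = 1.5, Y = 1.5)),
    survival = c(D1 = 1, D2 = 1)
  )
  cohort <- generate_cohort(sim)
  an <- run_analysis(cohort, analysis_config(mode = "patient"))
  undet <- an$results[an$results$stratum == "UNDETECTED" &
                        an$results$display_class == "ANY", ]
  e <- an$results[an$results$stratum == "EXPRESSED" &
                    an$results$display_class == "ANY", ]
  # masks are enriched for high-mutation-rate residues: raw ratio is inflated
  expect_gt(undet$ratio, 1.02)
  # the non-expressed control removes the composition bias
  expect_equal(e$corrected_ratio, 1, tolerance = 0.06)
})
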