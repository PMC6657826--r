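#!/usr/bin/env Rscript

# Step 4: dependence of depletion on displaying-allele copy number.
#
# Splits patient-displayed sites by the number of carried allele copies that
# can display them: D1 (one copy) vs D2 (two or more, pooling homozygous
# and two-distinct-allele display). Stronger depletion at D2 than D1 is the
# incomplete-dominance signature; the generator's truth is 0.9 vs 0.77.

suppressPackageStartupMessages(library(neodeplete))

cohort <- read_cohort("scratch/cohort")
an <- run_analysis(cohort,
                   analysis_config(mode = "patient", rng_seed = 101L,
                                   bootstrap_reps = 500L),
                   bootstrap = TRUE)
res <- an$results[an$results$display_class %in% c("D1", "D2"), ]
dir.create("results", showWarnings = FALSE)
readr::write_tsv(res, "results/allele_dosage.tsv")

e <- res[res$stratum == "EXPRESSED", ]
d1 <- e[e$display_class == "D1", ]
d2 <- e[e$display_class == "D2", ]
cat(sprintf("D1 corrected ratio: %.3f (CI %.3f-%.3f)\n",
            d1$corrected_ratio, d1$ci_low, d1$ci_high))
cat(sprintf("D2 corrected ratio: %.3f (CI %.3f-%.3f)\n",
            d2$corrected_ratio, d2$ci_low, d2$ci_high))
if (d2$corrected_ratio < d1$corrected_ratio) {
  cat("D2 < D1: two displaying allele copies deplete mutations more strongly\n")
  cat(sprintf("Implied clearance: %.0f%% (D1), %.0f%% (D2)\n",
              d1$clearance_percent, d2$clearance_percent))
} else {
  cat("No D2 < D1 ordering in this cohort draw\n")
}
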