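# neodeplete

Quantifying immune counterselection (immunoediting) of somatic mutations
inside predicted MHC class I–displayed peptides.

## The problem

Somatic missense mutations can create neoantigens: mutant peptides that MHC
class I receptors display to cytotoxic T cells. Tumor cells carrying a
displayed mutation are preferentially eliminated, so in sequenced tumors
such mutations should be *depleted* relative to comparable non-displayed
sites. `neodeplete` is for researchers who want to measure that depletion in
a cohort of protein-annotated somatic variants, given strong-binder peptide
predictions, per-patient 4-digit HLA class I genotypes, and gene expression
per cancer type — and for anyone who wants to validate such an estimator
against cohorts with a known, planted selection signal.

## The statistic

For opportunity sites split into displayed (*in*) and non-displayed (*out*)
classes, with m mutations over s residue-site opportunities, the mutation
density ratio is

    R = (m_in / s_in) / (m_out / s_out)

tested with a two-sided Fisher's exact test on the 2×2 table of mutated vs
non-mutated sites. Because MHC alleles prefer particular residue
compositions and mutation rates are residue-dependent, R is confounded; the
same ratio computed in undetectably expressed genes (R0, where no
display-dependent selection can act) measures exactly that bias, giving the
corrected ratio

    Rc = R_expr / R0,        implied clearance = 100 × (1 − Rc) %.

Patient mode refines "in" by displaying-allele dosage: D1 sites (one carried
displaying allele copy) vs D2 (two or more); stronger depletion at D2 than
D1 is the signature of incompletely dominant HLA alleles. Sites displayed
only by panel alleles the patient does not carry (D0) are excluded from both
sides. Uncertainty comes from a patient-resampling bootstrap (percentile
CI); expression strata are per-cancer-type quartiles of detectably expressed
genes, plus an UNDETECTED control stratum.

Because no consortium dataset can ship with the package, a seed-deterministic
synthetic cohort generator produces every input file with the structure the
analysis assumes — sequence-biased binding windows, genotypes from population
allele frequencies, log-normal expression, residue-dependent mutation rates,
and a configurable survival probability for missense candidates at expressed
displayed sites (synonymous candidates always survive, building the negative
control in by construction).

## Worked example

Simulate a cohort of 80 patients with immune survival 0.9 at expressed D1
sites and 0.77 at expressed D2 sites, then analyze it in patient mode:

```r
library(neodeplete)

sim <- simulation_config(
  seed = 42, n_proteins = 300, protein_length = c(100, 200), n_patients = 80,
  mutation = list(missense_rate = 0.004, synonymous_rate = 0.004,
                  residue_multiplier = c(F = 1.15, I = 1.15, L = 1.15,
                                         M = 1.15, V = 1.15, W = 1.15, Y = 1.15)),
  survival = c(D1 = 0.9, D2 = 0.77)
)
cohort <- generate_cohort(sim)
an <- run_analysis(cohort, analysis_config(mode = "patient", rng_seed = 42),
                   bootstrap = TRUE)
report_summary(an)
```

```
   stratum    display_class density_in density_out ratio corrected_ratio p_value
 1 UNDETECTED ANY              0.00866     0.00889  0.97           NA    0.623
 4 Q1         ANY              0.00769     0.00853  0.9             0.93 0.174
 7 Q2         ANY              0.00809     0.00885  0.91            0.94 0.262
10 Q3         ANY              0.00859     0.00876  0.98            1.01 0.827
13 Q4         ANY              0.00749     0.00876  0.86            0.88 0.0464
16 EXPRESSED  ANY              0.00796     0.00872  0.91            0.94 0.0143
17 EXPRESSED  D1               0.00827     0.00872  0.95            1.02 0.21
18 EXPRESSED  D2               0.00690     0.00872  0.79            0.71 0.00312
Strongest depletion: D2 corrected ratio 0.71 -> implied immune clearance 29%
```

(Rows for the D1/D2 classes within each quartile are printed too; excerpt
shown.) Reading the output: mutation density inside patient-displayed
peptides of expressed genes is 9% below background (ratio 0.91), while
undetectably expressed genes show only the composition bias (0.97, p =
0.62). Dividing the two gives the corrected ratio, and D2 sites are depleted
more strongly than D1 sites — at this small cohort size the D1 estimate
(1.02) is noisy, while the pooled and D2 estimates recover the planted
signal. The clearance line converts the strongest corrected ratio into the
implied fraction of mutant cells cleared by immune surveillance before
sampling.

The `analysis/` directory holds the full workflow at reference scale
(200 patients, ~100k missense mutations): `01_simulate_cohort.R` writes the
cohort to `scratch/cohort/`, then `02`–`05` run the pan-allele analysis,
the patient-displayed analysis with bootstrap, the allele-dosage (D1/D2)
comparison, and the synonymous control, writing tables under `results/`.

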