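---
title: "Quantifying immune counterselection of somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune counterselection of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

As a tumor develops, somatic missense mutations can create mutant peptides
("neoantigens") that MHC class I receptors display to cytotoxic T cells.
Cells carrying a displayed mutation may be eliminated, so in sequenced
tumors such mutations should be *depleted* relative to otherwise comparable
sites. `neodeplete` quantifies that depletion: it compares the density of
somatic missense mutations inside residues covered by predicted
strong-binder 9-mers against the density outside them, stratified by the
gene's expression level and by how many displaying HLA allele copies the
patient carries, and converts the resulting corrected ratio into an implied
immune clearance rate.

## The statistic

For a set of opportunity sites split into *in* (displayed) and *out*
(non-displayed) classes, with $m_{in}$, $m_{out}$ mutations over $s_{in}$,
$s_{out}$ residue-site opportunities, the mutation density ratio is

$$ R = \frac{m_{in}/s_{in}}{m_{out}/s_{out}}. $$

$R < 1$ indicates depletion. Significance comes from a two-sided Fisher's
exact test on the 2x2 table of mutated vs non-mutated sites, in vs out
(`stats::fisher.test`; with this orientation the odds ratio approximates
$R$).

A raw $R \ne 1$ is not yet evidence of immune selection: MHC alleles prefer
peptides of particular residue composition, and mutation rates are
themselves residue-dependent, so display masks can overlap
systematically-faster- or slower-mutating sequence. Genes that are not
detectably expressed cannot be displayed, so their in/out ratio $R_0$
measures exactly this composition bias. The corrected ratio

$$ R_c = R_{expr} / R_0 $$

cancels it. All arithmetic is done at full precision; ratios are rounded
(default 2 decimals) only at the reporting layer. A corrected ratio
$R_c \le 1$ implies that cells bearing such mutations were cleared
$100\,(1 - R_c)\%$ of the time before sampling; values above 1 report a
clearance of 0 with a "no depletion" flag.

## Display masks and allele dosage

Strong binders are predicted 9-mers with an affinity score at or below 50
(lower = stronger); a window starting at $s$ covers residues $s..s{+}8$
(1-based, inclusive). Masks are built on the wild-type sequence — display
prediction is mutation-independent, mutations are overlaid afterwards.

* **Pan-allele mode** treats the union of all 12 panel alleles
  (HLA-A\*0101, A\*0201, A\*0301, A\*2402, A\*2601, B\*0702, B\*0801,
  B\*1501, B\*2705, B\*3901, B\*4001, B\*5801) as available in every
  patient. This is deliberately conservative: it dilutes patient-specific
  display.
* **Patient mode** counts, per residue, the genotype copy number of carried
  alleles with a covering window: class D1 (one copy), D2 (two or more —
  pooling homozygous display and display by two distinct alleles, since
  copy numbers above 2 per peptide are not distinguished), and D0 (covered
  by the panel mask but by no carried allele). D0 sites are excluded from
  both numerator and denominator: they are not immunogenic in this patient,
  but neither are they clean background, because "out of the panel mask"
  already concentrates peptides more likely displayed by alleles *outside*
  the panel. HLA-C and panel-external alleles are treated as
  non-displaying (no predictions exist for them).

Incomplete dominance is the prediction that D2 sites are more strongly
depleted than D1 sites — two displaying copies make display (and hence
clearance) more reliable.

## Expression strata

Expression is the per-cancer-type median of RSEM-normalized values. A gene
with median exactly 0 is UNDETECTED; detectably expressed genes are split
at the 25/50/75th percentiles of their cancer type into Q1-Q4. A value
exactly on a boundary goes to the lower stratum, so ties always share a
stratum; assignments are invariant to row order. Quantiles are computed per
cancer type, never pooled, because mutations are compared within
matched cancer types. Genes absent from the expression table are excluded
(with a logged count) rather than treated as undetected: absence of
evidence is not zero expression.

## Opportunity sets

Mutation densities need denominators. In pan-allele mode each protein's
sites are counted once per cancer type in which the protein carries at
least one in-scope variant (strata are per cancer type, so "once per
cohort" is applied within each stratum cell). In patient mode sites are
counted once per (patient, mutated protein) pair — each patient has their
own copy-count track, so the same protein legitimately contributes
different in/out splits for different patients. A configuration switch
(`patient_universe = "neoantigenic"`) optionally restricts patient-mode
units to pairs where the patient carries at least one displaying allele
for the protein, mirroring a gene universe defined by predicted
neo-antigenicity; the default keeps all mutated pairs.

Because candidate mutations arise independently across sites,
conditioning a unit on containing at least one observed variant scales the
expected in- and out-counts by the same factor, so the density ratio is
unbiased under this opportunity definition.

## Bootstrap and clearance

Uncertainty in $R_c$ comes from resampling *patients* with replacement
(default 500 replicates, percentile 2.5/97.5 interval): mutations within a
patient share one genotype and are not exchangeable across patients.
Replicates where a resample empties a cell are dropped and counted.
Internally each patient's contribution to every (stratum, class) cell is
precomputed once, so a replicate is a weighted column sum — the bootstrap
costs far less than the initial accumulation. The interval reflects
patient-level sampling; variability from the gene panel itself (which gene
happens to be expressed where) is not resampled, which matters mainly for
small cohorts with few proteins.

## The synthetic cohort generator

No consortium data ships with the package; a seed-deterministic generator
produces cohorts with the statistical structure the analysis assumes:

* proteins drawn from human-like amino-acid composition (default 1000
  proteins of 200-400 residues);
* per-allele binding windows from a toy PWM: every allele prefers a shared
  hydrophobic core (L, V, I) plus three allele-specific residues; a 9-mer's
  score is its count of preferred residues, mapped to the affinity scale so
  windows with about seven or more preferred residues fall at or below the
  threshold of 50. Window sets of different alleles therefore overlap
  partially (creating D2 sites) and are residue-biased (creating the
  confounder). A `random_windows` model provides sequence-independent masks
  for calibration work;
* 4-digit genotypes sampled from population allele frequencies, with the
  per-locus remainder carried by named panel-external alleles, which
  exercises the D0 exclusion logic;
* per-cancer-type expression: 35% undetected, log-normal
  (meanlog 4, sdlog 2 on the RSEM scale) otherwise;
* mutations: per-site candidate probability 0.0015 per patient
  (~100k missense over 200 patients), with a 1.15x multiplier on
  hydrophobic residues — chosen so the undetected-control ratio deviates
  from 1 by a few percent, the magnitude real cohorts show;
* immune thinning: a missense candidate at an *expressed*,
  *patient-displayed* site survives with probability 0.9 (D1) or 0.77 (D2);
  all other candidates, and all synonymous candidates, survive. The
  configured survival equals the expected corrected ratio per class, which
  is what makes parameter recovery a meaningful end-to-end test.

What the generator does **not** model: real HLA binding motifs, codon
structure (synonymous "positions" are protein residues carrying a
same-residue label), mutational signatures, per-sample expression
variation, linkage between genes, or cancer-type-specific mutation burden.
Passing tests therefore demonstrate that the estimator recovers a known
planted selection signal under realistic confounding — not that any
particular real cohort shows a particular depletion.

## Numerical and design choices

* Allele dialects are normalized to the 4-digit `A*0201` form; analysis
  never distinguishes finer typing.
* Interval coverage uses a difference-array union, checked against
  brute-force containment in the tests.
* The Fisher p-value is delegated to `stats::fisher.test`; an independent
  exhaustive hypergeometric enumeration in the test suite verifies
  agreement to 1e-9 over all tables with margins up to 30.
* Zero denominators yield flagged `NA` ratios, never silent zeros; an
  analysis cell that cannot be corrected (undefined control) reports `NA`.
* Variants are validated against the protein sequence (reported wild-type
  residue must match); rows with a blank protein id but a gene id fall back
  to the gene's longest isoform, deterministically, with a manifest count.
* Reruns with the same config and seed produce byte-identical TSV/JSON
  outputs.

## Problem sizes used by the test suite

The suite exercises the estimator at sizes chosen to keep statistical
margins meaningful: parameter recovery and the synonymous control run on
the full reference cohort (200 patients, ~100k missense mutations, seed
101); null calibration uses 50 cohorts of 60 patients and 800 small
proteins (~6k mutations each), a design in which the patient bootstrap's
interval width comfortably dominates the gene-panel variability it cannot
see; the survival sweep and law-of-large-numbers checks use intermediate
cohorts. These sizes are the package's own choices and are documented here
so that anyone rescaling them knows what margin each test was designed
with.

## Known limitations

* Only 9-mer windows and a single affinity threshold are supported, by
  design; peptide lengths 10-11 and rank-based thresholds are out of scope.
* MHC class II display, HLA-C, and alleles without predictions are treated
  as non-displaying.
* The implied clearance rate reads a corrected ratio causally; real
  confounding (e.g. expression measured in different tumors of matched
  type) biases it toward no depletion, so estimates are conservative.
* Per-cancer analyses reuse the same machinery via `cancer_types`, but the
  generator assigns expression independently per cancer type rather than
  modeling correlated expression across types.
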