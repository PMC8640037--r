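# editatlas

Cohort-scale analysis of A-to-I RNA editing in brain tissue, with
proteogenomic validation and a two-stage disease-association framework.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing events surface in
RNA-seq variant tables as A>G calls (T>C for minus-strand transcripts).
`editatlas` takes per-sample call tables (chrom, pos, ref, alt, ref
depth, alt depth) through the full analysis a multi-dataset editing
atlas requires:

- **QC and annotation** — four posterior filters applied in order
  (total reads ≥ 20; alternative reads ≥ 5; subject frequency ≥ 10%;
  no known-variant overlap) with a conservation-checked audit trail;
  editing level = alt/(ref+alt); region annotation by precedence
  (CDS exon > 5'UTR > 3'UTR > intron > ncRNA > 1 kb flanks >
  intergenic); reported/not-reported status against a RADAR/GTEx-style
  reference.
- **Re-coding proteogenomics** — strand-aware codon translation of
  exonic edits, all 2^k − 1 within-transcript edit combinations as
  proteoforms, fully tryptic digestion (Keil rule, ≤ 2 missed
  cleavages, length ≥ 6), and an edited-peptide search database of
  peptides that cover an edited residue and are absent from the
  unedited proteome's digest.
- **TAMPOR** — iterated two-way median polish removing batch-specific
  variance from a TMT peptide matrix: each abundance is divided by its
  row's batch-wise GIS-channel median and scaled by
  grand-median/batch-median of median-centred ratios, then
  log2-column-centred and restored to the row geometric mean, until
  convergence. Plus ≥ 50%-missingness culling (edited peptides exempt),
  3-SD connectivity outlier flagging, and edited/non-edited ratios.
- **Association** — per-dataset GLMs of editing level on diagnosis
  (0/1/2) with dataset-specific covariates; two-stage design
  (suggestive p ≤ 1e-3, then inverse-variance fixed-effects
  meta-analysis, β_meta = Σwᵢβᵢ/Σwᵢ with wᵢ = 1/seᵢ²) with genomic
  inflation λ = median(χ²₁)/0.4549; mixed-model regional contrasts
  (subject random intercept); pathology/cognition GLMs; cis-effect
  classification; PCA of top events.

Everything runs on a synthetic cohort with planted ground truth
(regional shift 0.30, disease effect 0.05 level-units per diagnosis
step, known batch factors), so every estimator is scored against what
was planted — no protected human data required.

## Worked example

```r
library(editatlas)

# simulate the default study: 4 datasets x 150 subjects, 2 regions,
# 240 sites, planted effects
design <- simulation_design()
ref    <- generate_reference(design)
cohort <- generate_calls(design, ref)

# QC one dataset and inspect the audit
qc <- qc_filter(subset(cohort$calls, dataset == "ROSMAP"),
                known_variants = ref$known_variants)
qc$audit
#>           input_sites     removed_low_total       removed_low_alt
#>                   240                     0                     2
#> removed_low_frequency removed_known_variant         passing_sites
#>                    10                    10                   218

# inverse-variance fixed-effects meta-analysis, hand-checkable:
meta_fixed(beta = c(0.5, 0.3), se = c(0.1, 0.2))
#>   beta_meta    se_meta        z       p_meta k_datasets   Q       p_Q
#> 1      0.46 0.08944272 5.142956 2.704485e-07          2 0.8 0.3710934
```

The numbered drivers under `analysis/` run the five stages over the
packaged functions and narrate what they find
(`Rscript analysis/01_simulate.R` … `05_association.R`); with the
default seed the final stage prints, among others:

```
regional: planted delta 0.30 estimated 0.2997 at 45 planted sites; 45/45 significant at 0.00023
stage I: 24 suggestive (p <= 1e-3) of 218 tested; stage II lambda 565.747
stage II: planted beta 0.050 estimated 0.0477; 23/23 planted sites genome-wide (p <= 0.00023)
TAMPOR converged in 32 iterations; batch factors 1/1.466/0.69/1.186 (planted 1/1.6/0.7/1.2)
```

(The large λ on the *selected* Stage II sites is expected — they are
true positives; the null-calibration λ over all sites is ≈ 1.0, see
below.)

## Layout

```
R/                 package code (generator, QC/annotation, recoding,
                   TAMPOR, association, pipeline orchestration, I/O)
analysis/          numbered narrative drivers over the package
tests/testthat/    unit + property tests, brute-force oracles
scripts/           acceptance.R
vignettes/         methods vignette (model, assumptions, design choices)
```
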