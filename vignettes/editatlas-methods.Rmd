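---
title: "Methods: editing-atlas QC, re-coding proteomics, TAMPOR, and two-stage association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: editing-atlas QC, re-coding proteomics, TAMPOR, and two-stage association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`editatlas` implements a cohort-scale analysis of A-to-I RNA editing in
postmortem brain tissue. Adenosine deamination by ADAR enzymes produces
inosine, which sequencers read as guanosine; editing events therefore
appear in RNA-seq variant tables as A>G calls (or T>C when the edited
transcript lies on the minus strand). The *editing level* of a site in a
sample is the fraction of reads carrying the edited allele,
alt / (ref + alt), and a site's *frequency* is the proportion of a
dataset's subjects in which the event survives QC; "frequent" means
frequency ≥ 10%.

The package covers four layers, each exercised end to end on synthetic
data with planted ground truth:

1. **Editing events** — per-call and per-site QC, substitution
   classification, per-sample summaries, and genomic annotation.
2. **Re-coding proteogenomics** — amino-acid consequences of exonic
   edits, enumeration of edited proteoforms, fully tryptic in-silico
   digestion, and an edited-peptide search database.
3. **TAMPOR** — iterated two-way median-polish removal of batch-specific
   variance from a TMT peptide abundance matrix, anchored on pooled
   global internal standard (GIS) channels, plus connectivity-based
   sample outlier flagging and edited/non-edited ratios.
4. **Association** — per-dataset general linear models of editing level
   on diagnosis, a two-stage design with inverse-variance fixed-effects
   meta-analysis and genomic inflation λ, mixed-model regional
   contrasts, pathology/cognition models, cis-effect classification, and
   principal components of top events.

# Quality control

Four posterior filters are applied in a fixed order within each dataset:
(1) calls with total reads < 20 fail; (2) calls with alternative reads
< 5 fail; (3) sites detected in fewer than 10% of the dataset's subjects
are removed; (4) sites at known genomic-variant positions are removed.
The audit trail attributes each removed site to the first filter
responsible, so input sites always equal passing sites plus the sum of
per-filter removals — a conservation property tested against a
brute-force per-call re-check.

The term "frequency" in filter (3) is ambiguous between subject
prevalence and per-call allele fraction; both produce "≥ 10%" phrasing.
We implement prevalence as the default — consistent with plotting level
and frequency as distinct axes, and with a subject "having" an event
when at least one of their samples passes filters (1)–(2) — and provide
`frequency_mode = "level"` to threshold the per-call allele fraction
instead.

Annotation assigns exactly one region category per site by precedence:
CDS exon > 5'UTR > 3'UTR > intron > ncRNA > upstream > downstream >
intergenic (flanks are 1 kb from the transcript boundaries,
strand-aware). The precedence order reports the most transcript-internal
consequence when features overlap. Closest genes are ties-broken
lexicographically so outputs are deterministic. Canonical A-to-I status
is decided from the genome-reported pair alone (A>G or T>C), independent
of transcript annotation.

# Re-coding proteogenomics

For a site in a coding region, the edited base is substituted on the
coding strand (a genomic T>C on a minus-strand transcript is A>G in the
mRNA), the affected codon is translated with the standard genetic code,
and the effect is *re-coding* when the amino acid changes. All
2^k − 1 non-empty combinations of a transcript's k re-coding edits are
enumerated as proteoforms (the unedited form already exists in the
reference proteome); a combinatorial guard refuses k > 16 (65,535
proteoforms), well above the per-transcript k implied by realistic
editing databases. An edit that creates a premature stop truncates the
proteoform with a warning; the initiator methionine is retained.

Digestion is fully tryptic under the Keil rule — cleave C-terminal to K
or R except before P, the convention of the common search engines — with
at most two missed cleavages and a minimum length of six residues. The
digest is validated against an exhaustive substring enumerator on random
proteins up to 50 residues. Database peptides must cover at least one
edited residue and be absent from the digest of the unedited proteome;
uniqueness is by sequence, with all source proteoforms recorded.
Genetic variation is deliberately excluded from the database: including
it would inflate false discovery through additional decoy-like entries.
Whether combinations should span all exonic edits or re-coding edits
only is not externally fixed; re-coding only is the default (a switchable
choice), since synonymous edits cannot change peptide sequences.

# TAMPOR

The peptide matrix (positive abundances, missing allowed) is first
culled of rows with ≥ 50% missing values — except editing-specific
peptides, which are retained regardless of missingness because they are
the analytes of interest and are inherently sparse. Each iteration then:

1. divides every entry by its row's batch-wise median computed over the
   batch's GIS channels (the default; an all-samples denominator mode is
   provided),
2. multiplies by a batch-specific normalization factor: the row's grand
   median of batch medians divided by that batch's median of
   median-centred ratios over non-GIS case samples,
3. log2-transforms and subtracts each sample's median log2 ratio, and
4. anti-logs and multiplies by the row-wise geometric mean extracted
   once before the first iteration.

Extracting the restore scale once is essential: the iteration then acts
purely on the within-row/column pattern (the first-term division makes
the update invariant to row scale), and the process converges; a
per-iteration re-extraction would compound the mean-versus-median gap of
skewed rows into a geometric drift. Convergence is declared when the
maximum entry-wise relative change falls below `tol = 1e-8` (default),
with a 250-iteration cap that flags rather than silently truncates.
Medians ignore missing entries; a row whose GIS denominators are all
missing in a batch propagates missingness there. On noise-free inputs
the algorithm is exact: a single batch is a fixed point, and a planted
2× batch factor is removed completely in two iterations.

Sample outliers are flagged by connectivity — the per-sample sum of
Pearson correlations of log2 abundances over shared-present rows —
using a |z| > 3 rule, with one re-iteration after removing the first
round's flags, matching common sample-network practice. Pearson on log2
values is our choice where the upstream convention names a script but
not a metric. Edited/non-edited ratios are computed within samples and
are documented as comparable only across samples within a peptide pair,
never across pairs, because per-peptide ionization efficiencies differ.

# Association framework

Editing levels are proportions; we model them with identity-link
Gaussian GLMs (a logit-level option is provided). The direction of each
analysis follows its scientific question: editing level is the
*response* for diagnosis models (effect in level units per diagnosis
step 0 = control, 1 = MCI, 2 = AD; the MAYO-like dataset codes 0/2), and
the *exposure* for pathology/cognition and cis-effect models. Covariate
sets are dataset-specific (e.g. batch and study for ROSMAP-like, race
for MSBB-like, tissue source for MAYO-like); covariates that collapse to
a single level within an analyzed subset are dropped from that fit.
Missing covariates cause listwise deletion with the analyzed n reported.

The many-site path fits all sites at once via `limma::lmFit` with
**ordinary** (unmoderated) t-statistics — no empirical-Bayes shrinkage —
and is tested to agree exactly with the per-site `stats::glm` path.
Regional contrasts use a linear mixed model with subject random
intercept (`lmerTest`, Satterthwaite two-sided p-values); constant-level
and identical-region degeneracies are flagged and excluded from the
multiplicity count, which always derives from the realized number of
cleanly tested events.

Stage II meta-analysis is inverse-variance fixed effects:
β_meta = Σ(βᵢ/seᵢ²)/Σ(1/seᵢ²), se_meta = (Σ1/seᵢ²)^(−1/2), normal
two-sided p. Cochran's Q is reported but never used to filter.
Stage II runs on sites with Stage I p ≤ 1e-3 and includes the Stage I
dataset among the meta-analyzed sets, as in the source design; the
resulting sample overlap is a documented statistical caveat of that
design, not corrected here. Sites present in fewer than two datasets are
carried forward unmeta-analyzed and flagged. The genomic inflation
factor is λ = median(χ²₁(p)) / 0.4549. Cis effects are classified by
sign × significance tier (non / nominal / genome-wide at the
Bonferroni threshold over realized events). Principal components
standardize each event's levels (mean 0, SD 1) before decomposition and
fix component signs so the largest-magnitude loading is positive.

# The synthetic cohort

The generator (`simulation_design()`, `generate_reference()`,
`generate_calls()`, `generate_peptide_matrix()`) emulates the study's
structure at desk scale. Its defaults are the package's reference
conditions, chosen once:

- **4 datasets × 150 subjects** (600 total — the scale at which the
  recovery properties are stated), 2 regions per dataset, paired
  subjects.
- **240 sites** on a toy genome of alternating-strand genes (5'UTR, two
  CDS exons, intron, 3'UTR; occasional ncRNA genes), 10% at
  non-synonymous CDS adenosines; 50% listed in the reported-editing
  reference; 5% overlapping known variants (QC contamination); 5% at
  low prevalence so the frequency filter fires naturally.
- **Depth**: negative binomial with mean 500 and size 4, so low-depth QC
  failures occur without construction.
- **Planted effects**: regional delta 0.30 at 20% of sites (last
  region), disease effect 0.05 level-units per diagnosis step at a
  disjoint 10%; subject-level biological SD 0.05 shared across regions
  (making the subject random intercept meaningful) plus region-level SD
  0.03; per-site carrier prevalence so binary status varies.
- **Peptide matrix**: one batch per `batch_factors` entry, 8 case + 2
  GIS channels each; abundance = row baseline × batch factor × case
  loading (log-normal SD 0.10) × entry noise (log-normal SD 0.05); 10%
  of case entries of non-edited rows missing; GIS channels complete, as
  pooled standards.
- Traits (tangles, amyloid, plaques, cognitive slope) are linear in the
  latent level of a designated disease site; cis effects of ±0.8 (log2
  expression units) are planted for a subset of re-coding sites.

A genome-free twin, `simulate_level_matrix()`, shares the sampling model
and serves the large calibration studies (5,000-site null).

What the generator does **not** emulate: alignment artifacts,
hyper-editing clusters, Alu context, linkage between nearby sites,
population structure, and non-ignorable missingness in the peptide
matrix. Passing tests therefore demonstrate correctness of the
estimators under the stated sampling model, not robustness to every
pathology of real data.

Two numerical consequences of the model are worth noting. First,
regression *attenuation*: models using editing level as the exposure
(traits, cis effects) see slopes shrunk toward zero by binomial
measurement noise in the observed level — at depth 500 and biological SD
0.05 roughly a 10–15% shrinkage — whereas diagnosis and regional models,
where level is the response, are unbiased. Second, levels are clamped to
[0.001, 0.999] after adding planted effects; with base levels drawn from
[0.05, 0.55] the clamp is essentially never active, so planted effects
are recovered without clamp-induced bias.

# Problem sizes and numerical choices

The shipped analyses use the default design (240 sites, 600 subjects;
about 290,000 call rows), a 5,000-site × 4-dataset × 300-subject null
for calibration, 200 random proteins for the digestion oracle, and k =
10 for the proteoform-count check — sizes chosen so the whole suite and
the acceptance script run comfortably on a single CPU while keeping
Monte-Carlo error well inside the asserted tolerances. Determinism: all
generator functions seed their own RNG streams from `design$seed` (with
small fixed offsets per stage), so a fixed seed reproduces every table
byte-for-byte; the pipeline manifest records seed, versions, row counts
and output checksums.

Known limitations: the Stage II overlap caveat above; fixed-effects-only
meta-analysis (heterogeneity reported, not modelled); identity-link
Gaussian models for proportion-valued responses (adequate at these
depths; the logit option exists for boundary-heavy data); and exact
string matching for observed peptides (no I/L disambiguation or FDR
machinery, which are out of scope).
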