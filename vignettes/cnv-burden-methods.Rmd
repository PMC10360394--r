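---
title: "Methods: consensus CNV calling, classification and burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CNV calling, classification and burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures implemented in
`cnvburden`, the assumptions behind them, the choices made where the
design was genuinely open, and what the synthetic-cohort calibration does
and does not establish.

## The analysis problem

Array-based CNV calling produces, for each participant, deletion (DEL)
and duplication (DUP) segments from several detection algorithms, each
with caller-specific boundary error and false positives. Downstream
questions are cohort-level: which participants carry clinically
meaningful CNVs, whether those carriers report more mental-health /
neurodevelopmental diagnoses or more extreme quantitative traits, and
whether the per-participant burden of genes disrupted by rare CNVs
predicts trait scores globally, within functional gene-sets, or at
individual loci.

## Consensus events and frequency strata

Two calls are considered the same event when their **reciprocal overlap**
(RO) — the intersection length divided by each interval's length, taking
the minimum — reaches a threshold. RO is symmetric, lies in [0, 1], and
penalizes both partial overlap and size discrepancy.

* **Consensus merging** (`consensus_merge()`): within one participant,
  chromosome and CNV type, calls are single-linkage clustered at RO ≥ 0.5
  and merged to their union extent, carrying the union of supporting
  callers; only events supported by ≥ 2 distinct callers survive. Union
  (rather than intersection) coordinates match how multi-caller pipelines
  report a single supported event; intersection is available via the
  policy object. Merging is order-invariant: the clustering depends only
  on the interval set.
* **Size floor**: events shorter than 10 kb are removed (boundary
  inclusive). This is the resolution floor of array-based calling; below
  it, calls are dominated by probe-level noise.
* **Cohort frequency** (`annotate_frequency()`): consensus events are
  clustered *across* participants (same chromosome and type, RO ≥ 0.5,
  single linkage); each event's frequency is the number of distinct
  carriers in its cluster divided by the cohort size. No public standard
  fixes this estimator; 50% reciprocal overlap with single linkage is the
  field convention for equating recurrent events, and the threshold is a
  parameter.
* **Rarity strata**: rare (< 0.5%), less-rare (1–5%), common (> 5%,
  excluded from burden analyses as too few and too noisy). The 0.5–1%
  gap between the strata definitions is assigned to *rare* — the
  conservative choice that keeps the strata exhaustive — and a warning
  lists the affected calls.

All coordinates are 0-based half-open internally; BED files pass through
unchanged and GFF3 is shifted on ingest.

## Tier classification

Classification is a data-driven catalog engine rather than a hard-coded
gene list, so any curated locus/gene catalog can be supplied
(`read_catalog()`). Each consensus event receives exactly one tier by
fixed precedence:

1. **aneuploidy** — the event covers ≥ 90% of its chromosome (array calls
   rarely reach 100% of the assembly length); karyotype-style labels
   (e.g. 45,X; 47,XYY) are emitted using participant sex;
2. **recurrent** — reciprocal overlap with a catalog genomic-disorder
   locus at or above the entry's threshold (default 0.5) with a matching
   type;
3. **non-recurrent clinically significant** — ≥ 1 bp overlap with a
   clinically significant gene, type matching;
4. **susceptibility** — overlap with a susceptibility gene, type
   matching;
5. **unclassified** otherwise.

Tiers 1–3 constitute "clinically significant". At the participant level,
a carrier of both a significant and a susceptibility CNV is grouped under
*significant* — carrier groups must be mutually exclusive for the
three-way enrichment comparisons, and the stronger evidence class takes
precedence; both flags remain set so the overlap is auditable. Catalog
entries carry an explicit `required_type` (DEL/DUP/any) because
pathogenicity is often dosage-direction specific.

## Phenotype harmonization

Raw trait scores are standardized to **T-scores** (mean 50, SD 10)
within gender — and within gender × study phase when instruments differ
by phase — so that trait scales are comparable across strata. The
transform is affine within each group; zero-variance groups are an
error, not silently propagated. **High-trait flags** mark the most
extreme 10% of scored participants; ties at the empirical quantile are
all flagged, and all supported traits (including stop-signal reaction
time and reaction-time variability) are higher-is-worse. Disorders with
fewer than 20 reported cases are excluded from per-disorder models —
with rarer outcomes the logistic fits separate or produce degenerate
Wald intervals — but still count toward the composite any-diagnosis
indicator.

## Association models

* 2×2 carrier × outcome tables: odds ratio `ad/bc` with the Woolf
  (log-OR) interval; a 0.5 continuity correction is applied to all cells
  (and flagged) when any cell is zero. Enrichment p-values come from the
  Pearson chi-square without Yates correction by default.
* Per-disorder carrier effects: logistic regression of each retained
  diagnosis on the carrier indicator; separated fits are flagged and
  report no estimate.
* Traits: OLS of the T-score on carrier group with non-carriers as
  reference; SSRT/RTV models include the stimulant-medication flag as a
  covariate because stimulant treatment directly shifts those measures.
* Carrier demographics: one-way ANOVA for age, chi-square for sex and
  respondent.

## Burden machinery

The **burden matrix** maps each participant to distinct-gene counts per
(CNV type × rarity stratum), total lengths per type, per-gene-set
distinct-gene counts, per-gene binary carrier indicators, and a combined
global gene count (distinct genes hit by deletions or duplications). A
gene hit by two calls of one participant counts once: the estimand is
per-participant disrupted-gene load, not call count. "Hit" means ≥ 1 bp
overlap with the gene body — at ≥ 10 kb resolution, exon-level
intersection would suggest a precision the data do not have.

* **Global burden**: OLS of a trait on a burden count, adjusting
  principal components, genotyping batch and platform; ancestry strata
  are analyzed separately (the pipeline fits each stratum with ≥ 50
  participants).
* **Gene-set burden**: OLS of the trait on the set-specific count *plus
  the global gene count*. Without this correction every set inherits the
  nonspecific association between total CNV load and the trait; with it,
  a set coefficient reflects set-specific signal. A side effect worth
  knowing: conditioning on the global count induces a small negative
  partial correlation between a truly causal set and the other sets, so
  "null" sets sit slightly below zero rather than at it. BH-FDR is
  applied within each (trait × type × stratum) family, matching how
  per-panel results are usually presented; a pooled family is one
  argument away.
* **Locus tests**: genes restricted to the union of gene-sets passing
  the screen (p < 0.05 and q < 0.2 for that trait), with ≥ 3 carriers.
  Each gene's carrier indicator is binary — in the rare-variant setting
  carriers per gene number in the handfuls, and dosage coding would be
  dominated by single individuals. Family-wise error is controlled by
  **max-T permutation**: the outcome is residualized on the covariates,
  residuals are permuted (10 000 times by default, seeded), and the
  maximum |t| across genes in each permutation forms the reference
  distribution. This is assumption-light for sparse indicators, where
  Bonferroni is badly conservative given the correlated tests. The
  same covariates are used as in the gene-set models.
* **Sex differences**: likelihood-ratio tests comparing covariate-only
  to covariate+sex linear models for the four burden totals (length and
  gene count, by type). As a companion for *estimating* a multiplicative
  sex effect, `sex_burden_glm()` fits a quasi-Poisson log-link model:
  per-participant gene counts are compound-Poisson (a Poisson number of
  CNVs, each hitting a variable number of genes), so a plain Poisson
  interval would be anti-conservative.

## The synthetic cohort generator

`sim_config()` / `simulate_genome()` / `simulate_cohort()` emulate the
study design the analyses target: two ancestry strata (80/20) with a PC1
offset between them; ~4% carriers of catalog-classified CNVs split
across recurrent-locus, significant-gene and susceptibility-gene
classes; whole-chromosome aneuploidies at 0.1%; polymorphic loci planted
at 0.2%, 3% and 8% population frequency so all three rarity strata are
realized; background CNVs Poisson per participant with log-uniform sizes
from the 10 kb floor to 5 Mb; and three pseudo-callers that each detect
every true CNV independently with configurable sensitivity (default
0.85 — the real callers' sensitivities are unpublished, so this is a
free calibration parameter) and ±2% boundary jitter, so that
two-of-three consensus is actually exercised.

Planted effects define known estimands:

* a carrier → diagnosis odds ratio (`planted_or`, default 1.9) on the
  logit scale;
* a per-gene effect of causal-set deletions on the ADHD-trait analogue
  (`planted_beta`, default 0.15);
* a per-gene effect of *total* rare-deletion burden on the inattention
  analogue (`planted_beta_global`). Two separate traits are used because
  a single trait cannot make both the set-specific and the diffuse
  global coefficient well-defined truths at once;
* optionally, a multiplicative male deletion-rate factor for the
  sex-difference analyses.

Continuous planted effects act on deletions that are rare by
construction (background events, aneuploidies, and sub-0.5% polymorphic
loci), while the diagnosis effect acts on classified-carrier status;
catalog genes are kept out of the causal set. This separation keeps each
recovery check interpretable. Covariate effects (0.1·PC1 and a small
batch shift) are planted so covariate adjustment is genuinely exercised.

What the generator does **not** emulate: linkage structure, genotyping
intensity noise (callers are Bernoulli thinning plus jitter, with no
locus-specific failure modes), pedigree structure, differential
ascertainment, or realistic trait distributions (traits are Gaussian
with additive effects). Passing calibration therefore shows the
*statistical machinery* is correct and calibrated under the stated
generative model — it does not validate caller behavior on real
intensity data.

## Calibration results and problem sizes

The test suite runs, at cohort size n = 5000 with 800 genes and full
caller sensitivity, 100 end-to-end replicates (simulate → consensus →
frequency → classification → burden) and checks that the 95% CIs for the
four planted estimands — global burden beta, causal-set beta, carrier
odds ratio, and the sex rate effect — cover their true values in at
least 90 of 100 replicates. Null calibration uses 500–1000 replicates
per procedure (chi-square, carrier logistic, sex LRT, max-T FWER at 300
permutations over 20 genes) and requires the type-I error to sit within
a three-sigma binomial band of 0.05 (FWER ≤ 0.07). Oracle checks compare
the RO clustering, burden counts, BH step-up and OLS solutions against
independent brute-force implementations (all-pairs union-find, nested
loops, textbook formulas, normal equations) exactly or to 1e-8. These
sizes keep the full suite around two minutes of compute while leaving
the Monte-Carlo bands tight enough to be meaningful.

## Numerical and degenerate-input choices

* Frequencies are exact ratios of integer counts; stratum boundaries use
  `<`/`>=` comparisons on those ratios, so the 0.5% and 5% cutoffs
  behave predictably.
* High-trait cutoffs use the type-7 empirical quantile; ties at the
  cutoff are flagged together.
* Rank-deficient burden designs abort with the collinear columns named;
  inside the pipeline such fits are skipped and recorded rather than
  fatal (small ancestry strata can have constant predictors).
* Zero-carrier gene-sets are skipped with a note; genes whose residual
  indicator is numerically zero after covariate projection are dropped
  from locus tests.
* The permutation FWER p-value uses the add-one estimator
  `(1 + #{maxT ≥ |t|}) / (B + 1)`, which cannot be zero and is valid for
  any B.
* All randomness flows from explicit integer seeds; an identical
  configuration reproduces byte-identical outputs, including the
  pipeline's result files.

## Known limitations

* Frequency estimation by single-linkage RO clustering can chain through
  dense regions, deflating apparent rarity there; a stricter threshold
  mitigates this at the cost of splitting genuinely recurrent events.
* The classification engine is only as good as the supplied catalog; the
  shipped example catalog is illustrative, with approximate coordinates,
  and is not a clinical resource.
* Linear models are used for traits throughout (matching the analyses
  this package operationalizes); robust or rank-based alternatives are
  not implemented.
* X-chromosome dosage in males is handled only at the aneuploidy
  labeling level; frequency and burden logic treat X like an autosome.
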