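---
title: "Methods: polygenic and rare CNV risk across internalising disorder definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic and rare CNV risk across internalising disorder definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscnv)
```

## The scientific problem

A biobank offers many routes to calling someone a "case" for mood or
anxiety disorder: brief touchscreen questions, a nurse-led interview,
validated questionnaire instruments, self-reported diagnoses in an online
mental-health questionnaire (MHQ), and clinical code lists applied to
linked hospital and primary-care records.  The definitions differ in
sensitivity, specificity, availability and cost, and any genetic analysis
inherits those differences.  `prscnv` implements the full comparison:
common-variant polygenic risk scores (PRS) and rare psychiatric-risk CNV
(P-CNV) carrier status are associated with each of eight definitions of
mood, anxiety and combined internalising disorder, and the effect sizes
are compared *between* definitions with a test that accounts for the
overlap of the analysed samples.

## The generative model

The synthetic cohort is a stand-in for a volunteer biobank, with every
moving part the analysis assumes:

**Genotypes.** Ancestral allele frequencies are uniform on `maf_range`
(default 0.05–0.5); each of `n_populations` (default 2, mixed 94%/6% to
mimic a European-majority cohort) draws its frequency from a
Balding–Nichols beta distribution with divergence `fst` (default 0.1, the
order of continental divergence); dosages are binomial(2, p).  Small
fractions of variants are written to fail each QC filter (low INFO, high
missingness, rarity, excess homozygosity) so quality control is exercised,
not vacuous.

**Liabilities.** Per-variant effects for the two disorders are bivariate
normal with correlation `r_genetic` (default 0.8, the reported order of
the mood–anxiety genetic correlation).  Each disorder's liability is

    sqrt(h2) * G + shift * carrier + delta_f * female + beta_age * (age - 54.5) + sqrt(1 - h2) * E

with `cor(E_mood, E_anx) = env_corr` (default 0.5, producing the familiar
comorbidity) and `h2` the liability variance captured by the *observed*
score (default 0.05 — a realistic figure for what a PRS captures, far
below twin heritability).  Ages are uniform on 40–69 (recruitment-age
window) with a small positive liability slope (default 0.01/year).

**Thresholds.** Disorder status is liability above a threshold.  Rather
than the asymptotic probit quantile we use the *empirical* quantile of the
realised liability, so the target prevalence (defaults 0.20 mood, 0.15
anxiety) holds exactly in-sample, and the degenerate limit (identical
genetic and environmental components and equal prevalences) yields
identical disorder indicators by construction.  The female liability
offset is solved numerically so the female/male prevalence odds ratio
equals `female_or` (default 1.8).

**P-CNV carriers.** A panel of named recurrent loci (default 10 loci,
carrier frequencies summing to ≈1.6%, liability shifts 0.3–0.5) is drawn
independently of the polygenic score.  Carrier effects enter both
disorders' liabilities identically.

**Records.** Each source has an availability mask: touchscreen and
interview for everyone, hospital records for everyone, primary care for
40%, MHQ for 31.61% of non-carriers with carrier completion scaled by
0.2616/0.3161 ≈ 0.83 (the published completion contrast).  Conditional on
availability, each definition's observed flag is drawn with a
per-definition sensitivity/specificity against the true disorder, and raw
records (GAD-7 items, CIDI-SF items, diagnosis and medication codes, EHR
events) are generated to *realise* that flag, so the phenotyping module
works from genuine raw records.  Help-seeking is drawn once per individual
against the mood-or-anxiety truth, making it identical across disorders by
construction.  Default sensitivities (0.08 for hospital admission up to
0.75 for help-seeking) were chosen once to reproduce the broad prevalence
spread seen across definition classes (sub-1% hospital definitions up to
roughly a third of the cohort for help-seeking).

One structural caveat is faithful rather than accidental: the medication
rule counts *any antidepressant* for anxiety as well as mood, so a
mood-only medication case is necessarily also an anxiety medication case.
The generator realises mood flags as antidepressants and anxiety-only
flags as non-temazepam benzodiazepines; the derived medication-anxiety
phenotype therefore inherits the mood cases, exactly as the instrument
conflates them in real data.  Under a perfect observation model every
other definition reproduces the latent truth on available samples;
medication-anxiety and help-seeking reproduce the internalising union.

**What the generator does not emulate:** linkage disequilibrium beyond
what population structure induces (positions are surrogates), genotyping
batch effects, raw CNV intensities (QC metrics are simulated at summary
level), longitudinal record depth, and the "healthy volunteer"
selection bias of real cohorts — only the MHQ-uptake bias of P-CNV
carriers is modelled.  Passing tests therefore demonstrate the *pipeline's
correctness and calibration* under a known generative model, not the
epidemiology of any real cohort.

## Analysis components and numerical choices

* **Variant QC**: INFO ≥ 0.9, missingness ≤ 0.05, MAF ≥ 0.01, HWE p ≥
  1e-6.  The HWE test is the exact conditional test on the heterozygote
  count (ratio recurrence over the full support, two-sided as the sum of
  probabilities not exceeding the observed one) for n ≤ 1000, and the 1-df
  chi-square approximation above; monomorphic variants return p = 1.
* **Relatedness**: one member of each pair above kinship 0.0884 removed at
  random under a seed, iterating until no pair remains.
* **LD pruning**: sliding windows of 500 variants advanced by 50; within a
  window the worst pair above r² = 0.05 loses its higher-missingness
  member, ties resolved against the later position — deterministic, and
  checked against a brute-force oracle.
* **PRS**: weighted dosage sums with allele reconciliation (dosage flipped
  when the weight's effect allele is the variant's other allele; unmatched
  weights dropped and counted) and per-variant mean imputation of missing
  dosages.
* **Ancestry adjustment**: reference-panel PCA on LD-pruned standardised
  dosages (sign fixed by the largest-magnitude loading element, making the
  decomposition deterministic); targets are standardised with the
  *reference* means and variances, with missing dosages falling at the
  reference mean; the reference PRS is regressed on the first five PCs and
  scores are standardised by the residual standard deviation.  Dividing by
  the residual SD (not the residual variance) is the default because only
  it yields unit-variance adjusted scores — the point of putting ancestries
  on one scale; `scale = "variance"` restores the literal reading.  Only
  the mean is PC-modelled; a PC-dependent variance model is deliberately
  out of scope.  Association covariates use the cohort's own top ten PCs,
  kept distinct from the five reference-projection PCs used for
  adjustment.
* **Logistic models**: IRLS with relative deviance tolerance 1e-8 and at
  most 100 iterations; Wald inference from the observed information;
  separation and non-convergence are flagged in the result, never silent;
  listwise deletion per outcome, so each definition is analysed on its own
  non-missing subset.  ΔNagelkerke R² is the full-model minus
  covariate-only Nagelkerke R², both against the intercept-only baseline.
  AUC is the Mann–Whitney statistic (mid-rank ties) of the full-model
  fitted probabilities; a covariate-only AUC is emitted alongside because
  published model-level AUCs do not always say which is meant.
* **Tetrachoric correlation**: 1-D maximum likelihood over rho with
  thresholds fixed at the margins, orthant probabilities from a
  deterministic bivariate-normal algorithm; perfectly concordant tables
  return ±0.9995 rather than diverging.
* **Overlap comparison**: the correlation of two logistic estimates
  sharing subjects follows from the influence-function expansion of the
  MLE — shared cases weighted by √(control products/case products), shared
  controls conversely, normalised by √(n₁n₂).  It is 0 for disjoint and 1
  for identical designs, and is validated against the Monte-Carlo
  correlation of actual estimate pairs.  Overlap counts are taken from the
  exact analysed id sets, not approximated from prevalences.  When r
  exceeds 1 − 1e-9 the comparison is reported non-informative instead of
  producing an unstable z.

## Choices made where the design was open

* Internalising status is a union for cases; a *control* requires both
  components observed as controls — one missing component with one control
  gives missing, avoiding asymmetric misclassification when a source is
  absent.
* Lifetime semantics: any qualifying record ever makes a case; conflict
  handling across repeat assessments is not modelled.
* Minimal-phenotyping mood is a configurable rule (help-seeking plus a
  two-week low-mood/anhedonia touchscreen item); CIDI-SF thresholds
  (cardinal symptom, 5 of 9 symptoms, two-week duration, impairment for
  MDD; excessive worry, six-month duration, 3 associated symptoms for GAD)
  live in `cidi_config()` and are overridable.
* Code matching is exact on normalised codes (dots stripped, upper-case)
  with optional prefix matching for hierarchical systems.
* CNV locus matching is by (name, type); coordinate-overlap matching is
  out of scope.  Boundary semantics follow the filter wording exactly
  (e.g. 30 CNVs fails "30 or more"; waviness exactly 0.03 passes "greater
  than 0.03").
* Wald tests throughout; test families for Bonferroni default to 16 (PRS)
  and 24 (CNV) tests.

## Validation experiments and problem sizes

The test suite runs each stage against independent oracles (direct
likelihood maximisation, quadrature bivariate-normal CDFs, all-pairs AUC
enumeration, brute-force pruning and exact-test enumeration) and then four
simulation experiments, sized for a desktop single-core run:

1. **Calibration of the overlap-aware z-test**: two analyses of the same
   true effect on samples sharing 0–90% of 10,000 subjects per arm, 2,000
   replicates per overlap fraction; the rejection rate at α = 0.05 must
   stay within [0.04, 0.06] while the naive independent-samples test
   collapses at high overlap.
2. **Overlap-correlation oracle**: 5,000 replicate pairs at 50% overlap
   (2,000 per arm); the analytic correlation must match the empirical
   correlation of the estimates within ±0.03.
3. **Parameter recovery**: the liability-threshold model has no
   closed-form logistic coefficient, so the pseudo-truth is the same
   logistic estimator at n = 400,000; 200 replicates at n = 5,000 then
   check ≈95% Wald CI coverage for the PRS and carrier effects (sex and
   age offsets disabled so the replicated design matches the truth fit).
4. **Union improves prediction**: the combining-improves-prediction
   pattern is asserted in the genetic-sharing regime — correlated
   polygenic components (r_g = 0.8), idiosyncratic environments, the score
   for the *shared* component as predictor, definitions observed with
   sensitivity 0.8 and specificity 0.97, 100 replicates of n = 10,000.
   Numerical exploration of the liability model shows why the regime
   matters: with an asymmetric score the union dilutes the
   better-predicted component, and fully shared environments (or shared
   sex/age offsets) likewise erode the union's advantage; the property is
   a statement about shared liability, not about unions in general.

The end-to-end demonstration study uses n = 20,000–50,000 individuals and
1,000–2,000 variants — large enough for every stage to have resolvable
signal, small enough for a desk run.

## Known limitations

* The synthetic scale cannot reproduce published effect sizes from a
  half-million-person cohort; pipeline outputs are for structure and
  calibration, not numerical replication of any real analysis.
* The observation model draws each definition's flag conditionally
  independently given the truth (except where the instruments genuinely
  conflate, as for medication-anxiety); real definitions share error
  sources (e.g. recall) that would inflate between-definition
  correlations.
* The HWE chi-square branch above n = 1000 is an approximation; exact
  computation remains available by raising `exact_limit`.
* `ld_prune` treats variant indices as a position surrogate; there is no
  genetic map.
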