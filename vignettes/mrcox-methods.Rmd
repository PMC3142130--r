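---
title: "Mendelian randomization for survival cohorts: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization for survival cohorts: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcox)
```

## The three-stage model

`mrcox` asks whether a positive, log-normally distributed serum biomarker
is a cause of time-to-event outcomes or merely a correlate. The design
needs three ingredients, all on scales that compose:

1. **Genotype → marker.** Ordinary least squares of `ln(marker)` on a
   genotype coding (allele dose 0/1/2, or heterozygote / rare-homozygote
   indicators against the common homozygote), adjusted for age and sex.
   The coefficient `beta_gm` is the change in `ln(marker)` per coded
   unit; `100*(exp(beta_gm)-1)` is the familiar percent change in the
   marker's geometric mean.
2. **Marker → disease.** A Cox proportional-hazards model of the event
   hazard on `ln(marker)`, adjusted for the clinical covariate set.
   `beta_md` is the log hazard ratio per unit `ln(marker)`.
3. **Genotype → disease, expected.** If the marker is causal, genotypes
   are randomized at meiosis, and the genotype–disease path runs only
   through the marker, then

   `beta_gd = beta_gm * beta_md`, expected HR `= exp(beta_gd)`.

   The comparison of this *expected* hazard ratio with the *observed*
   genotype–event Cox estimate is the causal check. Observed genotype
   HRs near 1 despite a clear marker–event association are the signature
   of confounding.

The identifying assumptions are the usual instrumental-variable triple:
the variant is associated with the marker (testable, stage 1), the
variant is independent of confounders (screened, see below), and there is
no path from variant to disease other than through the marker (not
testable; a biological judgement).

### Confidence intervals for the expected hazard ratio

The expected HR is a product of two estimated coefficients, so its
sampling distribution is not normal even when both stages are. The
package propagates uncertainty by Monte Carlo (`mc_ci()`): `beta_gm` and
`beta_md` are drawn from independent normal distributions centred at
their point estimates with their standard errors, each of 1,000,000
products is exponentiated, and the empirical 2.5th/97.5th percentiles
(linear-interpolation definition, `quantile(type = 7)`) form the 95% CI.
Choices worth stating:

- **Independence of the draw streams.** The two coefficients are drawn
  independently even when both come from one cohort; the correlation
  between a genotype–marker OLS estimate and a marker–disease Cox
  estimate is small because the genotype explains a minority of marker
  variance. `mc_ci(rho = )` exposes a Gaussian coupling as a sensitivity
  switch (default 0).
- **Determinism.** A seed fixes the stream; identical seeds reproduce
  CIs to machine precision. At 10^6 draws the seed-to-seed spread of each
  bound is below 0.005 on the HR scale for coefficient magnitudes of the
  order used here (a tested invariant), so the percentile definition is
  numerically immaterial.
- **Back-derivation of standard errors.** When only printed CIs are
  available, `se_from_ci()` assumes Wald symmetry on the log scale,
  `se = (ln hi − ln lo)/(2·1.96)`; percent-change intervals are first
  converted to geometric-mean ratios. This is exact for Wald intervals
  and a close approximation for the profile-like intervals most software
  prints at these sample sizes.

When run on published summary statistics for two strong
biomarker-raising variants (+81.3% and +73.3% per allele) and a
marker–disease hazard ratio of 1.33 per unit `ln(marker)`, the engine
gives expected per-allele HRs of 1.18 and 1.17:

```{r printed}
round(expected_hr(pct_to_beta(81.3), log(1.33)), 2)
round(expected_hr(pct_to_beta(73.3), log(1.33)), 2)
mc_ci(pct_to_beta(81.3), se_from_ci(66.9, 96.9, "pct"),
      log(1.33), se_from_ci(1.09, 1.63, "hr"), n_draws = 2e5, seed = 1)
```

## Genotype quality control

- **MAF** is the allele-count frequency; if the nominally rare allele
  exceeds 0.5 the labels are flipped with a warning, so downstream doses
  always count the minor allele.
- **Hardy–Weinberg equilibrium** is tested by the Pearson χ² (1 df, no
  continuity correction) of observed genotype counts against `n·p²,
  2npq, nq²` at the sample allele frequency. The test form is a design
  choice made for transparency; with ~1000 subjects and MAF ≥ 0.05 the
  χ² and exact tests agree closely. Monomorphic SNPs are *not testable*
  (reported `NA`, never `p = 1`), and fewer than 10 genotypes refuse the
  test.
- **Exclusion rule.** SNPs with HWE `p < alpha` (default 0.05,
  strict inequality, boundary retained) are excluded from survival and
  score analyses but kept in the marker-association table — departures
  from equilibrium often indicate genotyping artefacts that bias hazard
  estimates, whereas the marker table is a descriptive survey.
- **Linkage disequilibrium** between two loci is estimated from unphased
  doses by the standard two-locus EM: haplotype counts are deterministic
  for every genotype pair except double heterozygotes, which are split
  between the cis and trans phases by their current frequency odds;
  iteration to a 1e-10 change tolerance (cap 1000 iterations). `D'` uses
  the conventional `Dmax` normalization and `r²` the allele-variance
  one. `r² = D'²` only when the two allele frequencies coincide; neither
  bounds the other in general.

## Marker-stage details

- **Complete cases per analysis.** Each SNP's models use the subjects
  called for that SNP, so per-SNP `n` varies; no imputation.
- **R² and the Kruskal–Wallis p** in the association table are
  deliberately unadjusted: R² is the one-way ANOVA between/total sum of
  squares of `ln(marker)` over the three genotype groups, and the
  Kruskal–Wallis test runs on *untransformed* values (rank invariance
  makes the transformation irrelevant; the pairing documents that the
  nonparametric test needs no normality).
- **Stepwise multi-locus selection.** Forward selection with backward
  pruning on the partial-F p-value of each SNP's column block, with
  deliberately permissive thresholds (enter `p < 0.4`, remove
  `p > 0.6`): the thresholds only shape the *path* of visited models.
  The final model is the path model (including the age/sex-only
  baseline) minimizing 10-fold cross-validated PRESS — subjects shuffled
  once by the seed into near-equal folds, PRESS the sum of held-out
  squared residuals. Selection paths of stepwise procedures are not
  unique across implementations, so the procedure is fully specified
  here: best-p candidate enters first, worst-p term leaves first,
  candidates collinear with the current model are ineligible (so of two
  identical SNPs exactly one can enter), and a 50-step cap guards
  enter/leave oscillation, possible because the stay threshold exceeds
  the entry threshold. Given data and seed the result is deterministic.
- **Weighted genotype score.** From the selected model's per-allele
  coefficients, the SNP with the largest |beta| is the reference (weight
  1) and the others get `beta_i / beta_ref`; the subject score is the
  weighted dose sum. One score unit therefore corresponds to `beta_ref`
  units of `ln(marker)`, which is exactly the genotype-stage coefficient
  the MR engine uses for the score's expected HR.

## Survival-stage details

Cox partial-likelihood fitting is delegated to `survival::coxph` with
**Efron** tie handling (a better approximation than Breslow at the
moderate tie rates yearly follow-up produces; the two agree to 1e-10 on
tie-free data, a tested invariant, and the package's fits are verified
against a brute-force Efron partial-likelihood maximizer on small
datasets). All subjects enter at time 0 (cohort recruited at a common
clinical milestone); no delayed entry, no competing risks. Zero events,
constant design columns and rank-deficient designs are errors, not
silent results; coefficients beyond ±15 trigger a monotone-likelihood
warning. The marker–event model adjusts for the full clinical covariate
set, the genotype–event models for age and sex only — the instrument
needs no further adjustment precisely because genotype is randomized.

## The confounder screen

Each SNP (unordered three-level genotype factor) is tested against each
candidate confounder — Kruskal–Wallis for continuous, Pearson χ² without
continuity correction for categorical covariates. No multiplicity
adjustment is applied; instead the summary reports the count of nominal
`p < 0.05` findings next to its binomial expectation and central 95%
interval under the global null, which is the appropriate yardstick when
the question is "does anything here look systematically non-random?"
rather than "which single test is significant?".

## The synthetic-cohort generator

No subject-level data ship with the package; the generator produces
cohorts with exactly the statistical structure the analysis assumes, so
passing tests demonstrate that every stage recovers what the generative
model put in.

- **Genotypes**: independent per SNP, Binomial(2, MAF) — Hardy–Weinberg
  by construction. Defaults: two SNPs at MAF 0.23 and 0.26 with
  per-allele effects `log(1.813)` and `log(1.733)`.
- **Marker**: `ln(marker) = base + Σ effect·dose + 0.02·(age−60) +
  0.5·female + confounder term + N(0, 0.8)`. The residual SD 0.8 makes
  the strongest SNP explain ≈ 15% of `ln(marker)` variance, and the
  overall marker distribution (median ≈ 2.5, log-scale SD ≈ 0.9) matches
  a typical inflammatory-marker distribution in cardiac cohorts.
- **Events**: exponential times with hazard `0.015·exp(log(1.33)·
  ln(marker) + confounder term)` per year — the simplest model
  satisfying proportional hazards; the real data-generating hazard of
  any cohort is unknown, so constant baseline is a modelling choice, and
  a Weibull shape could replace it without touching any downstream
  stage. Censoring is administrative at 8 years plus independent
  exponential dropout at 0.02/yr, giving ≈ 15% events.
- **Covariates**: age N(61, 8) truncated to 30–70, 15% female, and 25
  clinical stand-ins (history, discharge drugs, lipids, inflammation
  markers) generated independently of genotype — the screen's global
  null holds by construction.
- **Confounder**: a single latent standard-normal variable with
  configurable effects on marker and hazard; downstream stages never see
  it. The `causal`, `confounded` and `null` scenarios differ only in
  which arrows are switched on.
- **Determinism**: one master seed; each stage draws from its own child
  stream, so a stage re-run in isolation reproduces its in-pipeline
  values bit for bit.

What the generator does *not* emulate: linkage disequilibrium between
panel SNPs (simulated independently; the LD estimator is tested on
haplotype-level simulations instead), genotyping error, marker
measurement error and its timing relative to the index event,
non-proportional hazards, and competing risks. Passing tests therefore
show internal consistency of the estimators under the model's own
assumptions, not robustness to these real-data features.

### Problem sizes used in the test suite

Parameter-recovery and calibration properties run at cohort sizes of
2,000 subjects with 100–200 replicates, and null-calibration
uniformity checks at 500 small replicates — sizes at which binomial
error on a 95% coverage proportion is ≈ 1.5% and the standard error of
a mean per-allele log-HR is ≈ 0.007, tight enough to detect meaningful
bias while keeping the default suite quick. The marginal genotype–event
hazard ratio in a Cox model is subject to a small non-collapsibility
attenuation relative to `exp(beta_gm·beta_md)`; at the ≈ 15% event
fraction and coefficient magnitudes used here the attenuation is an
order of magnitude below the Monte-Carlo error band the tests use.

## Known limitations

- The design tests *consistency with* causality; it cannot rule out
  pleiotropy (variant–disease paths bypassing the marker). Formal IV
  estimators and pleiotropy-robust methods (ratio/2SLS, Egger, weighted
  median) are out of scope.
- Two-locus EM is the extent of haplotype handling; no phasing or block
  calling.
- The stepwise path, while fully specified, need not match other
  software's path on the same data; only the CV-PRESS criterion and the
  thresholds are transferable.
- Printed-CI back-derivation assumes log-scale Wald symmetry; asymmetric
  intervals would need the original standard errors.
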