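# mrcox

Mendelian randomization for biomarker–disease associations in survival
cohorts.

## The problem

Observational cohorts of patients with stable coronary heart disease
routinely find serum biomarkers — here, a positive, log-normally
distributed marker such as type II secretory phospholipase A2 — associated
with the hazard of secondary cardiovascular events. Such associations may
be causal or may reflect confounding. Because genotypes are allocated
randomly at meiosis, genetic variants that raise the biomarker act as
natural instruments: **if** the biomarker is causal and the
variant–disease path runs only through the biomarker, the variant's effect
on disease is predictable from two estimable stages.

With both stages modelled on the natural-log marker scale,

- β<sub>g→m</sub>: change in ln(marker) per coded genotype unit
  (age/sex-adjusted linear regression),
- β<sub>m→d</sub>: log hazard ratio per unit ln(marker)
  (covariate-adjusted Cox regression),

the genotype–disease log hazard ratio expected under causality is the
product

> β<sub>g→d</sub> = β<sub>g→m</sub> × β<sub>m→d</sub>,  expected HR = exp(β<sub>g→d</sub>),

and its 95% CI is propagated by Monte Carlo: draw 1,000,000 pairs of the
two coefficients from normal distributions around their point estimates
with their standard errors, exponentiate each product, and take the 2.5th
and 97.5th percentiles. Comparing these *expected* hazard ratios with the
*observed* genotype–event hazard ratios from Cox regression is the causal
check: agreement supports causality, observed HRs near 1 despite a strong
marker–event association indicate confounding.

`mrcox` implements the full pipeline: genotype QC (MAF, Hardy–Weinberg
χ² with an exclusion rule, two-locus EM linkage disequilibrium), the
marker stage (percent-change conversion, one-way ANOVA R², Kruskal–Wallis,
stepwise multi-locus selection by 10-fold cross-validated PRESS, a
weighted allele score), the survival stage (Efron-tie Cox models), the MR
engine (expected HRs, Monte-Carlo CIs, SE back-derivation from printed
CIs), a genotype–confounder screen, and a synthetic-cohort generator with
causal / confounded / null scenarios so every stage is testable without
patient data.

## Worked example

```r
library(mrcox)

# an 800-subject causal-scenario cohort: two biomarker-raising SNPs,
# marker-event HR 1.33 per unit ln(marker), ~15% events over 8 years
run <- run_pipeline(sim_scenario("causal", n_subjects = 800, seed = 3),
                    mc_draws = 1e4)
run$comparison[, c("label", "coding", "hr", "hr_expected",
                   "mc_low", "mc_high", "consistent")]
#>   label   coding       hr hr_expected    mc_low  mc_high consistent
#> 1 score    score 1.136364    1.076411 0.9771454 1.185041       TRUE
#> 2  snp1 additive 1.259423    1.071391 0.9775242 1.174983       TRUE
#> 3  snp1      het 1.294623    1.065295 0.9814281 1.163805       TRUE
#> 4  snp1 rare_hom 1.509968    1.162001 0.9525196 1.423175       TRUE
#> 5  snp2 additive 1.026963    1.077794 0.9766363 1.195570       TRUE
#> 6  snp2      het 1.025861    1.070849 0.9781417 1.177003       TRUE
#> 7  snp2 rare_hom 1.056986    1.178005 0.9531041 1.463740       TRUE
```

Each row compares the observed genotype–event hazard ratio (`hr`, Cox
regression adjusted for age and sex) with the hazard ratio expected if the
marker–event association were causal (`hr_expected = exp(beta_gm *
beta_md)`, Monte-Carlo CI in `mc_low`/`mc_high`). `consistent` flags rows
where the expected point estimate falls inside the observed CI — here all
rows, as it should be in a causal scenario.

The engine also runs directly from published summary statistics, with no
subject-level data:

```r
expected_hr(pct_to_beta(81.3), log(1.33))          # 1.185 -> "1.18"
mc_ci(pct_to_beta(81.3), se_from_ci(66.9, 96.9, "pct"),
      log(1.33),         se_from_ci(1.09, 1.63, "hr"),
      n_draws = 1e6, seed = 1)
#>     2.5%    97.5%
#> 1.050399 1.342450
```

A thin command-line front end with subcommands (`simulate`, `qc`,
`assoc`, `survival`, `mr`, `screen`, `all`) is installed at
`system.file("cli", "mrcox.R", package = "mrcox")`.

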