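test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_subjects = 10000,
                    snps = list(snp_spec("s", 0.25)), seed = 5)
  g <- simulate_genotypes(cfg)$s
  prop <- tabulate(g + 1L, 3L) / length(g)
  hwe <- c(0.75^2, 2 * 0.75 * 0.25, 0.25^2)
  # binomial error: 4 SE of each genotype proportion
  expect_true(all(abs(prop - hwe) < 4 * sqrt(hwe * (1 - hwe) / 10000)))

  # monomorphic limit
  cfg0 <- sim_config(n_subjects = 50, snps = list(snp_spec("s", 0)), seed = 1)
  expect_true(all(simulate_genotypes(cfg0)$s == 0L))
})

test_that("observed MAF is unbiased and HWE holds across replicate seeds", {
  se_maf <- sqrt(0.23 * 0.77 / (2 * 1000))
  ok_hwe <- 0L
  maf_ok <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_subjects = 1000, snps = list(snp_spec("s", 0.23)),
                      seed = s)
    g <- simulate_genotypes(cfg)$s
    maf <- mean(g) / 2
    if (abs(maf - 0.23) < 3 * se_maf) maf_ok <- maf_ok + 1L
    hw <- hwe_test(genotype_counts(g))
    if (hw$p > 0.01) ok_hwe <- ok_hwe + 1L
  }
  expect_gte(maf_ok, 95)   # ~99.7% nominal
  expect_gte(ok_hwe, 95)   # 99% nominal at alpha = 0.01
})

test_that("simulation is deterministic given config and seed", {
  cfg <- sim_scenario("causal", n_subjects = 200, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$survival, c2$survival)
})

test_that("marker generator recovers the configured per-allele percent change", {
  cfg <- sim_config(n_subjects = 5000,
                    snps = list(snp_spec("s", 0.23, log(1.813))), seed = 21)
  gt <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  mk <- simulate_marker(gt, cov, cfg)
  expect_true(all(mk > 0))
  est <- fit_marker_regression(log(mk), code_genotypes(gt$s, "additive", "s"),
                               cov[, c("age", "sex")])
  i <- match("s_add", est$term)
  pct <- beta_to_pct(est$beta[i], est$se[i])
  expect_gt(pct$ci_high_pct, 81.3)
  expect_lt(pct$ci_low_pct, 81.3)
})

test_that("marker degenerates to a constant when all effects and noise vanish", {
  cfg <- sim_config(n_subjects = 100, snps = list(snp_spec("s", 0.3, 0)),
                    marker_sd = 0, age_effect = 0, sex_effect = 0, seed = 2)
  gt <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  expect_equal(simulate_marker(gt, cov, cfg), rep(exp(cfg$marker_base), 100))
})

test_that("a positive confounder effect induces marker-confounder correlation", {
  cfg <- sim_config(n_subjects = 5000, confounder_effect_marker = 0.5, seed = 8)
  gt <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  mk <- simulate_marker(gt, cov, cfg)
  expect_gt(cor(log(mk), cov$confounder), 0.3)
})

test_that("row misalignment between genotypes and covariates is an error", {
  cfg <- sim_config(n_subjects = 50, seed = 1)
  gt <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  expect_error(simulate_marker(gt[1:40, ], cov, cfg), "row-aligned")
})

test_that("zero baseline hazard yields only administrative censoring", {
  cfg <- sim_config(n_subjects = 300, baseline_hazard = 0, dropout_rate = 0,
                    seed = 3)
  cov <- simulate_covariates(cfg)
  mk <- simulate_marker(simulate_genotypes(cfg), cov, cfg)
  sv <- simulate_survival(mk, cov, cfg)
  expect_true(all(sv$event == 0L))
  expect_true(all(sv$time_years == cfg$admin_censor_years))
})

test_that("event fraction and survival recovery match the generative model", {
  cohort <- tiny_cohort(n = 6000, seed = 17)
  frac <- mean(cohort$survival$event)
  expect_gt(frac, 0.08)        # ~15% events over 8 years
  expect_lt(frac, 0.25)
  mh <- marker_event_model(cohort$survival, cohort$phenotypes$marker_conc,
                           cohort$phenotypes)
  expect_gt(mh$ci_high[1], 1.33)
  expect_lt(mh$ci_low[1], 1.33)
})

test_that("cohort tables survive a write/read round trip", {
  cohort <- tiny_cohort(n = 60, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(dose_matrix(back$genotypes), dose_matrix(cohort$genotypes))
  expect_equal(back$survival$time_years, cohort$survival$time_years)
  expect_equal(back$phenotypes$marker_conc, cohort$phenotypes$marker_conc)
  expect_equal(levels(back$phenotypes$sex), c("male", "female"))
})

test_that("invalid generator parameters are rejected", {
  expect_error(snp_spec("s", 0.7), "maf")
  expect_error(sim_config(marker_sd = -1), "marker_sd")
  expect_error(sim_config(n_subjects = 0), "positive")
  expect_error(sim_config(snps = list()), "snp_spec")
})
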