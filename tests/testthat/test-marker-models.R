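test_that("percent-change conversion round-trips with the log coefficient", {
  expect_equal(pct_to_beta(81.3), log(1.813))
  expect_equal(round(pct_to_beta(81.3), 4), 0.5950)
  expect_equal(beta_to_pct(0)$delta_pct, 0)
  for (x in c(-44.8, 27.7, 199.8))
    expect_equal(beta_to_pct(pct_to_beta(x))$delta_pct, x)
  expect_error(pct_to_beta(-100), "-100")
  # strictly increasing, CI ordering preserved
  b <- seq(-1, 1, by = 0.25)
  expect_true(all(diff(vapply(b, function(z) beta_to_pct(z)$delta_pct,
                              numeric(1))) > 0))
  p <- beta_to_pct(0.3, 0.1)
  expect_lt(p$ci_low_pct, p$delta_pct)
  expect_gt(p$ci_high_pct, p$delta_pct)
})

test_that("marker regression is shift-invariant and flags collinearity", {
  cohort <- tiny_cohort(n = 500, seed = 31)
  d <- cohort$genotypes$snp1
  X <- code_genotypes(d, "additive", "snp1")
  cov <- cohort$phenotypes[, c("age", "sex")]
  e1 <- fit_marker_regression(log(cohort$phenotypes$marker_conc), X, cov)
  e2 <- fit_marker_regression(log(cohort$phenotypes$marker_conc * 7.5), X, cov)
  i <- match("snp1_add", e1$term)
  expect_equal(e1$beta[i], e2$beta[match("snp1_add", e2$term)])
  expect_equal(e1$ci_low[i], e1$beta[i] - 1.96 * e1$se[i])
  # perfect copy of a column is a named collinearity error
  X2 <- cbind(X, snp1_copy = X[, 1])
  expect_error(
    fit_marker_regression(log(cohort$phenotypes$marker_conc), X2, cov),
    "collinear")
})

test_that("regression p-values are uniform under the genetic null", {
  set.seed(404)
  ps <- replicate(500, {
    y <- rnorm(60)
    g <- rbinom(60, 2, 0.3)
    cov <- data.frame(age = rnorm(60, 60, 8),
                      sex = factor(sample(c("male", "female"), 60, TRUE)))
    e <- fit_marker_regression(y, code_genotypes(g, "additive", "g"), cov)
    e$p[match("g_add", e$term)]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ANOVA R-squared equals its sum-of-squares definition", {
  expect_equal(anova_r2(c(1, 1, 2, 2, 3, 3), c(0, 1, 0, 1, 0, 1)), 0)
  expect_equal(anova_r2(c(1, 1, 2, 2, 9, 9), c(0, 0, 1, 1, 2, 2)), 1)
  set.seed(9)
  y <- rnorm(300); g <- rbinom(300, 2, 0.4)
  # algebraic oracle: squared correlation with the group-mean prediction
  pred <- ave(y, g)
  expect_equal(anova_r2(y, g), cor(y, pred)^2, tolerance = 1e-12)
  expect_error(anova_r2(y, rep(1, 300)), "2 genotype groups")
})

test_that("Kruskal-Wallis matches the rank-sum formula and is rank-invariant", {
  v <- 1:9
  g <- rep(1:3, each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, 7.2)   # 12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)
  expect_equal(kw$p, pchisq(7.2, df = 2, lower.tail = FALSE))
  # invariance under monotone transformation
  expect_equal(kruskal_wallis(exp(v), g)$H, 7.2)
  expect_warning(kw0 <- kruskal_wallis(rep(2, 6), rep(1:2, 3)), "tied")
  expect_equal(kw0$p, 1)
})

test_that("stepwise CV-PRESS selection finds the causal SNP", {
  n_hit <- 0L
  for (s in 1:40) {
    set.seed(s)
    doses <- as.data.frame(replicate(9, rbinom(2000, 2, 0.3)))
    names(doses) <- paste0("v", 1:9)
    gt <- genotype_table(doses)
    cov <- data.frame(age = rnorm(2000, 60, 8),
                      sex = factor(sample(c("male", "female"), 2000, TRUE,
                                          prob = c(0.85, 0.15))))
    y <- 1 + 0.5 * doses$v1 + 0.01 * (cov$age - 60) + rnorm(2000, 0, 0.8)
    sw <- stepwise_cv_select(y, gt, cov, "additive", seed = s)
    if ("v1" %in% sw$selected) n_hit <- n_hit + 1L
  }
  expect_gte(n_hit, 37)  # claimed >= 95% selection consistency
})

test_that("stepwise selection stays parsimonious under the null", {
  sizes <- integer(30)
  for (s in 1:30) {
    set.seed(1000 + s)
    doses <- as.data.frame(replicate(9, rbinom(800, 2, 0.3)))
    names(doses) <- paste0("v", 1:9)
    gt <- genotype_table(doses)
    cov <- data.frame(age = rnorm(800, 60, 8),
                      sex = factor(sample(c("male", "female"), 800, TRUE)))
    y <- rnorm(800)
    sizes[s] <- length(stepwise_cv_select(y, gt, cov, "additive",
                                          seed = s)$selected)
  }
  expect_lte(median(sizes), 1)
})

test_that("stepwise selection is deterministic and guards collinear twins", {
  set.seed(55)
  doses <- data.frame(v1 = rbinom(600, 2, 0.3))
  doses$v2 <- doses$v1               # perfect copy
  gt <- genotype_table(doses)
  cov <- data.frame(age = rnorm(600, 60, 8),
                    sex = factor(sample(c("male", "female"), 600, TRUE)))
  y <- 1 + 0.5 * doses$v1 + rnorm(600, 0, 0.7)
  sw <- stepwise_cv_select(y, gt, cov, "additive", seed = 2)
  expect_length(sw$selected, 1L)     # exactly one of the twins enters
  sw2 <- stepwise_cv_select(y, gt, cov, "additive", seed = 2)
  expect_identical(sw$selected, sw2$selected)
  expect_identical(sw$cv_press, sw2$cv_press)
  expect_error(stepwise_cv_select(y, genotype_table(doses[, 0]), cov),
               "empty candidate")
})

test_that("the weighted genotype score reproduces the two-SNP formula", {
  gt <- genotype_table(data.frame(a = c(1L, 0L, 2L), b = c(2L, 0L, 1L)))
  sc <- build_genotype_score(c(a = 0.544, b = -0.120), gt)
  # score = doses_a + (-0.120/0.544) * doses_b
  expect_equal(sc$score[1], 1 + (-0.120 / 0.544) * 2, tolerance = 1e-12)
  expect_equal(round(sc$score[1], 4), 0.5588)
  expect_equal(sc$score[2], 0)
  expect_equal(sc$definition$snp[1], "a")        # largest |beta| is reference
  expect_equal(sc$reference_beta, 0.544)
  # single-term score is the dose itself
  sc1 <- build_genotype_score(c(a = 0.3), gt)
  expect_equal(sc1$score, as.numeric(gt$a))
  expect_error(build_genotype_score(c(a = 0), gt), "degenerate")
  expect_error(build_genotype_score(c(zz = 1), gt), "absent")
})

test_that("additive and genotypic effects are sign-consistent on dose-monotone data", {
  cohort <- tiny_cohort(n = 3000, seed = 77)
  lnm <- log(cohort$phenotypes$marker_conc)
  cov <- cohort$phenotypes[, c("age", "sex")]
  d <- cohort$genotypes$snp1
  ea <- fit_marker_regression(lnm, code_genotypes(d, "additive", "s"), cov)
  eg <- fit_marker_regression(lnm, code_genotypes(d, "genotypic", "s"), cov)
  b_add <- ea$beta[match("s_add", ea$term)]
  b_hom <- eg$beta[match("s_rarehom", eg$term)]
  expect_gt(b_add, 0)
  expect_gt(b_hom, b_add)   # additive slope sits below the rare-hom contrast
})

test_that("the single-SNP association table has the published shape", {
  cohort <- tiny_cohort(n = 800, seed = 13)
  tab <- marker_association_table(cohort$genotypes,
                                  cohort$phenotypes$marker_conc,
                                  cohort$phenotypes)
  expect_equal(tab$snp_id, c("snp1", "snp2"))
  expect_true(all(c("maf", "hwe_p", "r2", "kw_p", "het_pct", "rarehom_pct",
                    "add_pct", "add_lo", "add_hi") %in% names(tab)))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_true(all(tab$add_lo < tab$add_pct & tab$add_pct < tab$add_hi))
})
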