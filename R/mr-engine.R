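# Mendelian-randomization engine.  Both stage coefficients live on scales
# that compose multiplicatively through the log biomarker: beta_gm is the
# change in ln(marker) per coded genotype unit, beta_md the log hazard
# ratio per unit ln(marker).  Under causality and no confounding the
# genotype-disease log hazard ratio is their product,
#   beta_gd = beta_gm * beta_md,   expected HR = exp(beta_gd),
# and its confidence interval is propagated by Monte Carlo: the two
# coefficients are drawn from normal distributions around their point
# estimates with their standard errors, and the 2.5th/97.5th percentiles
# of the exponentiated products over 1,000,000 draws form the 95% CI.

#' Expected hazard ratio under causality
#'
#' @param beta_gm Genotype-marker coefficient (ln-marker per coded unit).
#' @param beta_md Marker-disease log hazard ratio (per unit ln-marker).
#' @return `exp(beta_gm * beta_md)`.
#' @examples
#' expected_hr(log(1.813), log(1.33))  # 1.18
#' @export
expected_hr <- function(beta_gm, beta_md) {
  stopifnot(is.finite(beta_gm), is.finite(beta_md))
  exp(beta_gm * beta_md)
}

#' Monte-Carlo confidence interval of the expected hazard ratio
#'
#' Draws `n_draws` pairs from `N(beta_gm, se_gm)` and `N(beta_md, se_md)`
#' (independent streams by default), exponentiates each product, and
#' returns the empirical 2.5th and 97.5th percentiles (linear-interpolation
#' definition, [stats::quantile()] type 7).
#'
#' The two coefficients are drawn independently even when both were
#' estimated in one cohort; `rho` exposes an optional Gaussian correlation
#' between the streams as a sensitivity switch (default 0).
#'
#' @param beta_gm,se_gm Genotype-marker coefficient and its SE.
#' @param beta_md,se_md Marker-disease log-HR and its SE.
#' @param n_draws Number of pseudo-random draws (default 1,000,000).
#' @param seed Optional integer seed; identical seeds give identical CIs.
#' @param rho Correlation between the two draw streams, in `[-1, 1]`.
#' @param probs Percentiles to return.
#' @return Numeric vector `c(low, high)` on the hazard-ratio scale.
#' @examples
#' mc_ci(log(1.813), 0.0422, log(1.33), 0.1027, n_draws = 1e5, seed = 1)
#' @export
mc_ci <- function(beta_gm, se_gm, beta_md, se_md, n_draws = 1e6,
                  seed = NULL, rho = 0, probs = c(0.025, 0.975)) {
  if (se_gm < 0 || se_md < 0) stop("standard errors must be >= 0")
  stopifnot(n_draws >= 1, abs(rho) <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (se_gm == 0 && se_md == 0) {
    hr <- expected_hr(beta_gm, beta_md)
    return(stats::setNames(rep(hr, length(probs)), paste0(100 * probs, "%")))
  }
  z1 <- stats::rnorm(n_draws)
  z2 <- stats::rnorm(n_draws)
  x <- beta_gm + se_gm * z1
  y <- beta_md + se_md * (rho * z1 + sqrt(1 - rho^2) * z2)
  stats::quantile(exp(x * y), probs = probs, type = 7, names = TRUE)
}

#' Back-derive a log-scale standard error from a printed confidence interval
#'
#' Assumes a Wald interval symmetric on the log scale:
#' `se = (ln(high) - ln(low)) / (2 * 1.96)`.  Percent-change intervals are
#' first converted to geometric-mean ratios `1 + Delta/100`.
#'
#' @param ci_low,ci_high Interval bounds, either hazard/geometric-mean
#'   ratios (`scale = "hr"`) or percent changes (`scale = "pct"`).
#' @param scale `"hr"` or `"pct"`.
#' @return Standard error on the log scale.
#' @examples
#' se_from_ci(1.09, 1.63)               # 0.1027
#' se_from_ci(66.9, 96.9, scale = "pct") # 0.0422
#' @export
se_from_ci <- function(ci_low, ci_high, scale = c("hr", "pct")) {
  scale <- match.arg(scale)
  if (scale == "pct") {
    ci_low <- 1 + ci_low / 100
    ci_high <- 1 + ci_high / 100
  }
  if (any(ci_low <= 0) || any(ci_high <= 0))
    stop("interval bounds must be positive ratios (or percent changes > -100)")
  if (any(ci_high <= ci_low)) stop("ci_high must exceed ci_low")
  (log(ci_high) - log(ci_low)) / (2 * 1.96)
}

#' Expected-under-causality result for one genotype term
#'
#' Combines a genotype-marker estimate with the marker-disease estimate
#' into the expected hazard ratio and its Monte-Carlo confidence interval.
#'
#' @param label Row label (SNP id or `"score"`).
#' @param coding Coding of the genotype term (`"additive"`, `"het"`,
#'   `"rare_hom"`, `"score"`).
#' @param beta_gm,se_gm Genotype-marker stage estimate.
#' @param beta_md,se_md Marker-disease stage estimate.
#' @param n_draws,seed,rho Passed to [mc_ci()].
#' @return One-row data frame of class `"mr_result"` with the stage
#'   coefficients, `hr_expected`, and `mc_low`/`mc_high`.
#' @export
mr_expected <- function(label, coding, beta_gm, se_gm, beta_md, se_md,
                        n_draws = 1e6, seed = NULL, rho = 0) {
  ci <- mc_ci(beta_gm, se_gm, beta_md, se_md, n_draws, seed, rho)
  out <- data.frame(label = label, coding = coding,
                    beta_gm = beta_gm, se_gm = se_gm,
                    beta_md = beta_md, se_md = se_md,
                    beta_gd_expected = beta_gm * beta_md,
                    hr_expected = expected_hr(beta_gm, beta_md),
                    mc_low = unname(ci[1]), mc_high = unname(ci[2]),
                    n_draws = n_draws,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Expected hazard ratios from published stage estimates
#'
#' Regenerates expected-under-causality hazard ratios and Monte-Carlo CIs
#' from printed summary statistics alone — percent changes in the
#' biomarker's geometric mean with their CIs for the genotype stage, and a
#' hazard ratio with CI for the marker stage — without any subject-level
#' data.  Standard errors are back-derived with [se_from_ci()].
#'
#' @param stage1 Data frame with columns `label`, `coding`, `delta_pct`,
#'   `pct_low`, `pct_high` (percent change per coded genotype unit and its
#'   95% CI); alternatively columns `beta_gm`, `se_gm` may be given
#'   directly.
#' @param hr_md Marker-disease hazard ratio per unit ln(marker).
#' @param hr_md_ci Length-2 vector, its printed 95% CI.
#' @param n_draws,seed,rho Passed to [mc_ci()]; each row uses a seed
#'   derived from `seed` and its row index.
#' @return An `"mr_result"` data frame, one row per `stage1` row.
#' @export
mr_from_printed <- function(stage1, hr_md, hr_md_ci, n_draws = 1e6,
                            seed = 1L, rho = 0) {
  stopifnot(is.data.frame(stage1), length(hr_md_ci) == 2)
  beta_md <- log(hr_md)
  se_md <- se_from_ci(hr_md_ci[1], hr_md_ci[2], "hr")
  rows <- lapply(seq_len(nrow(stage1)), function(i) {
    r <- stage1[i, ]
    if (!is.null(r$beta_gm) && !is.na(r$beta_gm)) {
      bg <- r$beta_gm
      sg <- if (!is.null(r$se_gm) && !is.na(r$se_gm)) r$se_gm else
        se_from_ci(r$pct_low, r$pct_high, "pct")
    } else {
      bg <- pct_to_beta(r$delta_pct)
      sg <- se_from_ci(r$pct_low, r$pct_high, "pct")
    }
    mr_expected(r$label, r$coding, bg, sg, beta_md, se_md,
                n_draws = n_draws, seed = seed + i - 1L, rho = rho)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Join observed and expected hazard ratios
#'
#' Produces the observed-versus-expected comparison: for each genotype
#' term, the observed hazard ratio with its CI, the expected hazard ratio
#' with its Monte-Carlo CI, the ratio of log hazard ratios, and a
#' consistency flag set when the expected point estimate lies inside the
#' observed confidence interval.
#'
#' @param observed Data frame with columns `label`, `coding`, `hr`,
#'   `ci_low`, `ci_high` (from the genotype-event Cox stage).
#' @param expected An `"mr_result"` data frame.
#' @return Data frame joined on `label` + `coding` with `log_hr_ratio`
#'   (`log(hr_observed) / log(hr_expected)`) and `consistent`.
#' @export
compare_observed_expected <- function(observed, expected) {
  stopifnot(all(c("label", "coding", "hr", "ci_low", "ci_high") %in% names(observed)),
            all(c("label", "coding", "hr_expected") %in% names(expected)))
  m <- merge(observed, expected, by = c("label", "coding"),
             suffixes = c("_obs", "_exp"))
  m$log_hr_ratio <- ifelse(m$hr_expected != 1,
                           log(m$hr) / log(m$hr_expected), NA_real_)
  m$consistent <- m$hr_expected >= m$ci_low & m$hr_expected <= m$ci_high
  m
}

#' @export
print.mr_result <- function(x, digits = 2, ...) {
  cat("Expected-under-causality hazard ratios\n")
  df <- data.frame(label = x$label, coding = x$coding,
                   hr_expected = round(x$hr_expected, digits),
                   ci = sprintf("(%s-%s)",
                                format(round(x$mc_low, digits), nsmall = digits),
                                format(round(x$mc_high, digits), nsmall = digits)))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
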