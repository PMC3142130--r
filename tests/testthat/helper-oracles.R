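# Independent oracles used to cross-check the package's model fits.
# These are deliberately naive re-derivations from first principles and
# share no code with the implementation they verify.

# Efron partial log-likelihood for a single covariate, evaluated directly
# from its definition: at each distinct event time with d tied events,
#   sum_{D} x_i b  -  sum_{l=0}^{d-1} log( S_R - (l/d) S_D )
# where S_R / S_D sum exp(x b) over the risk set / the tied deaths.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    sR <- sum(exp(x[R] * beta))
    sD <- sum(exp(x[D] * beta))
    d <- length(D)
    ll <- ll + sum(x[D]) * beta -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

# Maximize the Efron partial likelihood by direct 1-d optimization.
efron_mle <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) efron_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Quantile of the product X*Y of two independent normals by numerical
# integration of the CDF over the distribution of X:
#   F(z) = E_X[ P(Y <= z/X | X) ]   (sign of X handled explicitly)
prod_normal_quantile <- function(p, mux, sx, muy, sy) {
  xs <- seq(mux - 10 * sx, mux + 10 * sx, length.out = 4001)
  w <- stats::dnorm(xs, mux, sx)
  w <- w / sum(w)
  cdf <- function(z) {
    py <- ifelse(xs > 0, stats::pnorm((z / xs - muy) / sy),
                 ifelse(xs < 0, stats::pnorm((z / xs - muy) / sy,
                                             lower.tail = FALSE),
                        as.numeric(z >= 0)))
    sum(w * py)
  }
  lo <- mux * muy - 12 * (abs(mux) * sy + abs(muy) * sx + sx * sy + 1e-12)
  hi <- mux * muy + 12 * (abs(mux) * sy + abs(muy) * sx + sx * sy + 1e-12)
  stats::uniroot(function(z) cdf(z) - p, c(lo, hi), tol = 1e-10)$root
}

# Direct-formula Pearson chi-square over table cells.
chi2_brute <- function(observed) {
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  sum((observed - expected)^2 / expected)
}

# Direct-formula HWE chi-square from genotype counts.
hwe_chi2_brute <- function(counts) {
  n <- sum(counts)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  sum((counts - e)^2 / e)
}

# Small causal-scenario cohort shared across tests.
tiny_cohort <- function(n = 400, seed = 11, scenario = "causal", ...) {
  simulate_cohort(sim_scenario(scenario, n_subjects = n, seed = seed, ...))
}
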