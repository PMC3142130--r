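# Genotype -> marker stage.  All effects live on the ln(marker) scale;
# exp(beta) is a geometric-mean ratio, reported as a percent change.

new_effect_estimates <- function(term, beta, se, p, role = "focal",
                                 scale_tag = "log_marker") {
  out <- data.frame(term = term, beta = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    p = p, role = role, scale_tag = scale_tag,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Age- and sex-adjusted linear regression of the log biomarker
#'
#' Ordinary least squares of `ln(marker)` on the supplied genotype design
#' columns plus adjustment covariates, on complete cases.  Wald standard
#' errors, 95% confidence intervals (`beta +/- 1.96 se`) and p-values are
#' returned per design term; intercept and adjustment terms are kept with
#' `role = "adjust"`.
#'
#' @param ln_marker Numeric response, already log-transformed.
#' @param design Numeric matrix (or data frame) of genotype design columns,
#'   e.g. from [code_genotypes()].
#' @param covariates Optional data frame of adjustment covariates (default
#'   use: `age` and `sex`); factors are expanded to treatment contrasts.
#' @return An `"effect_estimates"` data frame (one row per term) with the
#'   fitted `lm` object as attribute `"fit"`.
#' @export
fit_marker_regression <- function(ln_marker, design, covariates = NULL) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("g", seq_len(ncol(design)))
  adj <- if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  else NULL
  X <- if (is.null(adj)) design else {
    cc <- stats::complete.cases(covariates)
    if (!all(cc)) stop("covariates contain missing values; subset to complete cases first")
    cbind(design, adj)
  }
  keep <- stats::complete.cases(X) & is.finite(ln_marker)
  X <- X[keep, , drop = FALSE]
  y <- ln_marker[keep]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)] - 1L)]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  role <- ifelse(rownames(sm) %in% colnames(design), "focal", "adjust")
  out <- new_effect_estimates(rownames(sm), sm[, 1], sm[, 2], sm[, 4], role)
  attr(out, "fit") <- fit
  attr(out, "n") <- length(y)
  out
}

#' Convert a log-scale coefficient to a percent change
#'
#' `Delta% = 100 (exp(beta) - 1)`; confidence bounds are transformed from
#' `beta -/+ 1.96 se` the same way, so the interval stays ordered.
#'
#' @param beta Coefficient on the log scale.
#' @param se Optional standard error; if given, 95% CI bounds are returned.
#' @return List with `delta_pct` and (if `se` given) `ci_low_pct`,
#'   `ci_high_pct`.
#' @export
beta_to_pct <- function(beta, se = NULL) {
  out <- list(delta_pct = 100 * (exp(beta) - 1))
  if (!is.null(se)) {
    stopifnot(all(se >= 0))
    out$ci_low_pct <- 100 * (exp(beta - 1.96 * se) - 1)
    out$ci_high_pct <- 100 * (exp(beta + 1.96 * se) - 1)
  }
  out
}

#' Convert a percent change back to a log-scale coefficient
#'
#' @param delta_pct Percent change, > -100.
#' @return `log(1 + delta_pct / 100)`.
#' @export
pct_to_beta <- function(delta_pct) {
  if (any(delta_pct <= -100))
    stop("percent change must be > -100")
  log(1 + delta_pct / 100)
}

#' One-way ANOVA R-squared of the log biomarker across genotype groups
#'
#' Unadjusted between-group over total sum of squares of `ln(marker)` over
#' the three genotype categories.
#'
#' @param ln_marker Numeric response.
#' @param genotype Grouping vector (0/1/2 doses or a factor); missing pairs
#'   dropped.
#' @return Fraction of variance explained, in `[0, 1]`.
#' @export
anova_r2 <- function(ln_marker, genotype) {
  keep <- !is.na(ln_marker) & !is.na(genotype)
  y <- ln_marker[keep]; g <- factor(genotype[keep])
  if (nlevels(droplevels(g)) < 2)
    stop("R-squared undefined with fewer than 2 genotype groups")
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(0)
  gm <- tapply(y, g, mean)
  between <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  unname(between / tot)
}

#' Kruskal-Wallis test of the untransformed biomarker across genotypes
#'
#' Tie-corrected rank statistic with a chi-square (k-1 df) p-value; thin
#' wrapper over [stats::kruskal.test()] that returns `p = 1` (with a
#' warning) when every value is tied, where the statistic is undefined.
#'
#' @param values Numeric outcome (untransformed biomarker).
#' @param groups Grouping vector; missing pairs dropped.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L) {
    warning("all values tied; Kruskal-Wallis statistic undefined, p set to 1")
    return(list(H = 0, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Single-SNP association table for the log biomarker
#'
#' Reproduces, per SNP, the standard association summary: call count, MAF,
#' HWE p, one-way ANOVA R-squared, Kruskal-Wallis p on the untransformed
#' marker, and age/sex-adjusted percent changes with 95% CIs under the
#' genotypic (heterozygote, rare homozygote vs common homozygote) and
#' additive (per minor allele) codings.  All SNPs are reported, including
#' HWE-excluded ones.
#'
#' @param genotypes A [genotype_table()].
#' @param marker Positive biomarker values (untransformed).
#' @param covariates Data frame with `age` and `sex` (and any further
#'   adjustment columns supplied).
#' @param hwe_alpha HWE exclusion level propagated to the `excluded` flag.
#' @return Data frame with one row per SNP.
#' @export
marker_association_table <- function(genotypes, marker, covariates,
                                     hwe_alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_table"), all(marker > 0, na.rm = TRUE))
  qc <- snp_qc(genotypes, hwe_alpha)
  lnm <- log(marker)
  rows <- lapply(snp_ids(genotypes), function(id) {
    d <- genotypes[[id]]
    keep <- !is.na(d)
    poly <- length(unique(d[keep])) > 1L
    r2 <- if (poly) anova_r2(lnm[keep], d[keep]) else NA_real_
    kw <- if (poly) kruskal_wallis(marker[keep], d[keep])$p else NA_real_
    pct <- function(est, term) {
      i <- match(term, est$term)
      if (is.na(i) || is.na(est$beta[i])) return(c(NA_real_, NA_real_, NA_real_))
      p <- beta_to_pct(est$beta[i], est$se[i])
      c(p$delta_pct, p$ci_low_pct, p$ci_high_pct)
    }
    add <- het <- hom <- c(NA_real_, NA_real_, NA_real_)
    if (poly) {
      ea <- fit_marker_regression(lnm[keep], code_genotypes(d[keep], "additive", id),
                                  covariates[keep, c("age", "sex")])
      add <- pct(ea, paste0(id, "_add"))
      if (any(d[keep] == 2L)) {
        eg <- fit_marker_regression(lnm[keep], code_genotypes(d[keep], "genotypic", id),
                                    covariates[keep, c("age", "sex")])
        het <- pct(eg, paste0(id, "_het"))
        hom <- pct(eg, paste0(id, "_rarehom"))
      } else {
        eg <- fit_marker_regression(
          lnm[keep],
          code_genotypes(d[keep], "genotypic", id)[, 1, drop = FALSE],
          covariates[keep, c("age", "sex")])
        het <- pct(eg, paste0(id, "_het"))
      }
    }
    i <- match(id, qc$snp_id)
    data.frame(snp_id = id, n = qc$n_called[i], maf = qc$maf[i],
               hwe_p = qc$hwe_p[i], excluded = qc$excluded[i],
               r2 = r2, kw_p = kw,
               het_pct = het[1], het_lo = het[2], het_hi = het[3],
               rarehom_pct = hom[1], rarehom_lo = hom[2], rarehom_hi = hom[3],
               add_pct = add[1], add_lo = add[2], add_hi = add[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Cross-validated PRESS for a fixed column set: subjects are shuffled once
# by `seed` into near-equal folds; PRESS = sum of held-out squared
# residuals over all folds.
cv_press <- function(y, X, folds = 10L, seed = 1L) {
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  press <- 0
  for (k in seq_len(folds)) {
    tr <- fold != k
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    fit <- stats::lm.fit(Xtr, y[tr])
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% fit$coefficients
    press <- press + sum((y[!tr] - pred)^2)
  }
  press
}

# Joint partial-F p-value for adding/keeping a term's column block.
block_f_p <- function(y, X_small, X_big) {
  f0 <- stats::lm.fit(cbind(1, X_small), y)
  f1 <- stats::lm.fit(cbind(1, X_big), y)
  rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
  df_num <- f1$rank - f0$rank
  df_den <- length(y) - f1$rank
  if (df_num <= 0 || df_den <= 0 || rss1 <= 0) return(NA_real_)
  Fv <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
}

#' Stepwise multi-locus selection with cross-validated PRESS
#'
#' Forward-stepwise selection of SNPs predicting `ln(marker)`, always
#' adjusted for age and sex, with permissive entry/stay p thresholds
#' (default enter if p < 0.4, remove if p > 0.6, judged by the partial
#' F-test of the SNP's column block).  Every model visited on the path —
#' including the adjustment-only baseline — is scored by `folds`-fold
#' cross-validated PRESS with fold assignment fixed by `seed`; the path
#' model minimizing CV-PRESS is refit on the full data and returned.
#'
#' Candidates whose columns are collinear with the current model (e.g. a
#' perfect copy of an already-selected SNP) are ineligible to enter.
#'
#' @param ln_marker Numeric response.
#' @param genotypes A [genotype_table()]; HWE-excluded SNPs should be
#'   removed by the caller beforehand.
#' @param covariates Data frame with `age` and `sex`.
#' @param coding `"additive"` or `"genotypic"` SNP coding.
#' @param p_enter,p_remove Entry and stay thresholds.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed fixing the fold assignment.
#' @param max_steps Cap on add/remove steps (guards oscillation).
#' @return List of class `"stepwise_fit"`: `selected` (SNP ids),
#'   `coefficients` (effect estimates of the refit final model), `cv_press`
#'   (named vector over path models), `path` (log of steps).
#' @export
stepwise_cv_select <- function(ln_marker, genotypes, covariates,
                               coding = c("additive", "genotypic"),
                               p_enter = 0.4, p_remove = 0.6,
                               folds = 10L, seed = 1L, max_steps = 50L) {
  coding <- match.arg(coding)
  stopifnot(inherits(genotypes, "genotype_table"))
  ids <- snp_ids(genotypes)
  if (!length(ids)) stop("empty candidate set")
  adj <- stats::model.matrix(~ age + sex, data = covariates)[, -1, drop = FALSE]
  blocks <- lapply(ids, function(id)
    code_genotypes(genotypes[[id]], coding, id))
  names(blocks) <- ids
  keep <- stats::complete.cases(do.call(cbind, blocks)) &
    is.finite(ln_marker) & stats::complete.cases(adj)
  y <- ln_marker[keep]
  adj <- adj[keep, , drop = FALSE]
  blocks <- lapply(blocks, function(b) b[keep, , drop = FALSE])

  bind_model <- function(sel) {
    if (!length(sel)) adj else cbind(do.call(cbind, blocks[sel]), adj)
  }
  full_rank <- function(X) qr(cbind(1, X))$rank == ncol(X) + 1L
  model_key <- function(sel) if (length(sel)) paste(sort(sel), collapse = "+") else "(baseline)"

  selected <- character(0)
  press_tab <- c(`(baseline)` = cv_press(y, adj, folds, seed))
  path <- data.frame(step = 0L, action = "start", snp = NA_character_,
                     model = "(baseline)", stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    changed <- FALSE
    # forward: best-p candidate under p_enter, skipping collinear blocks
    cand <- setdiff(ids, selected)
    if (length(cand)) {
      ps <- vapply(cand, function(id) {
        Xb <- bind_model(c(selected, id))
        if (!full_rank(Xb)) return(NA_real_)
        block_f_p(y, bind_model(selected), Xb)
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      if (length(ps) && min(ps) < p_enter) {
        add <- names(ps)[which.min(ps)]
        selected <- c(selected, add)
        key <- model_key(selected)
        if (!key %in% names(press_tab))
          press_tab[key] <- cv_press(y, bind_model(selected), folds, seed)
        path <- rbind(path, data.frame(step = step, action = "add", snp = add,
                                       model = key, stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    # backward: worst-p selected term above p_remove
    if (length(selected) > 0) {
      ps <- vapply(selected, function(id)
        block_f_p(y, bind_model(setdiff(selected, id)), bind_model(selected)),
        numeric(1))
      ps <- ps[!is.na(ps)]
      if (length(ps) && max(ps) > p_remove) {
        drop_id <- names(ps)[which.max(ps)]
        selected <- setdiff(selected, drop_id)
        key <- model_key(selected)
        if (!key %in% names(press_tab))
          press_tab[key] <- cv_press(y, bind_model(selected), folds, seed)
        path <- rbind(path, data.frame(step = step, action = "remove",
                                       snp = drop_id, model = key,
                                       stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  best_key <- names(press_tab)[which.min(press_tab)]
  best_sel <- if (best_key == "(baseline)") character(0) else
    strsplit(best_key, "+", fixed = TRUE)[[1]]
  coefs <- if (length(best_sel)) {
    fit_marker_regression(y, do.call(cbind, blocks[best_sel]),
                          as.data.frame(adj))
  } else NULL
  structure(list(selected = best_sel, coefficients = coefs,
                 cv_press = press_tab, path = path, coding = coding,
                 seed = seed, folds = folds),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise CV-PRESS selection (", x$coding, " coding)\n", sep = "")
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  cat("  CV-PRESS of winning model:",
      format(min(x$cv_press), digits = 6), "\n")
  invisible(x)
}

#' Weighted genotype score
#'
#' Builds a weighted allele score from multi-locus regression coefficients:
#' the SNP with the largest absolute coefficient (or the one named in
#' `reference`) gets weight 1, every other SNP gets `beta_i / beta_ref`,
#' and the subject score is the weighted sum of minor-allele doses.  The
#' reference coefficient is stored because one score unit corresponds to
#' `reference_beta` units of ln(marker) — the quantity the MR engine needs
#' as its genotype-stage effect.
#'
#' @param coefs Named numeric vector of per-allele ln-marker coefficients
#'   (names = SNP ids).
#' @param genotypes A [genotype_table()] supplying the doses.
#' @param reference Optional SNP id to use as reference term.
#' @return List of class `"genotype_score"`: `definition` (data frame snp,
#'   beta, weight), `reference_beta`, `score` (per-subject numeric vector).
#' @export
build_genotype_score <- function(coefs, genotypes, reference = NULL) {
  stopifnot(length(coefs) >= 1L, !is.null(names(coefs)),
            inherits(genotypes, "genotype_table"))
  if (!all(names(coefs) %in% snp_ids(genotypes)))
    stop("score SNPs absent from genotype table: ",
         paste(setdiff(names(coefs), snp_ids(genotypes)), collapse = ", "))
  ref <- if (is.null(reference)) names(coefs)[which.max(abs(coefs))] else reference
  if (!ref %in% names(coefs)) stop("reference SNP not among coefficients")
  beta_ref <- coefs[[ref]]
  if (beta_ref == 0) stop("degenerate score: reference coefficient is zero")
  ord <- c(ref, setdiff(names(coefs), ref))
  weights <- coefs[ord] / beta_ref
  doses <- dose_matrix(genotypes)[, ord, drop = FALSE]
  score <- unname(drop(doses %*% weights))
  structure(list(
    definition = data.frame(snp = ord, beta = unname(coefs[ord]),
                            weight = unname(weights), stringsAsFactors = FALSE),
    reference_beta = beta_ref, score = score),
    class = "genotype_score")
}

#' @export
print.genotype_score <- function(x, ...) {
  cat("Weighted genotype score:\n  score =",
      paste(sprintf("%+.4g x %s", x$definition$weight, x$definition$snp),
            collapse = " "), "\n")
  cat(sprintf("  reference beta (ln-marker per score unit): %.4g\n",
              x$reference_beta))
  invisible(x)
}
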