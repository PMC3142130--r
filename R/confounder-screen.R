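# Genotype-confounder screen: the check behind the "no confounding of the
# gene-disease association" assumption.  Each SNP (as an unordered
# three-level genotype factor) is tested against each candidate covariate,
# Kruskal-Wallis for continuous variables and Pearson chi-square for
# categorical ones, and the count of nominal p < 0.05 findings is reported
# against its binomial expectation under the global null.

#' Pearson chi-square test of genotype-covariate independence
#'
#' Chi-square without continuity correction on the genotype x covariate
#' contingency table, empty rows/columns dropped, df = (r-1)(c-1).
#'
#' @param genotype Genotype vector (0/1/2 doses or factor).
#' @param covariate Categorical covariate.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi2_independence <- function(genotype, covariate) {
  keep <- !is.na(genotype) & !is.na(covariate)
  tab <- table(factor(genotype[keep]), factor(covariate[keep]))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table: need >= 2 non-empty rows and columns")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware), as implemented by
#' [stats::cor()] with `method = "spearman"`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return The correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Screen genotypes against candidate confounders
#'
#' Runs one test per SNP x covariate pair: Kruskal-Wallis across the three
#' genotype categories for continuous covariates, Pearson chi-square for
#' categorical ones.  Covariates with a single observed level are skipped
#' with a warning and counted as untested.  The summary reports the number
#' of nominally significant tests (p < alpha) next to the binomial
#' expectation and central 95% interval under the global null — the
#' multiplicity argument is made by that comparison, not by adjusting
#' p-values.
#'
#' @param genotypes A [genotype_table()].
#' @param covariates Data frame of candidate confounders (one column per
#'   covariate; a `subject_id` column, marker columns and the survival
#'   columns are ignored if present).
#' @param types Optional named character vector mapping covariate names to
#'   `"continuous"` or `"categorical"`; unnamed covariates are classified
#'   automatically (factor/character/logical or <= 3 unique values =
#'   categorical).
#' @param alpha Nominal level used in the summary count.
#' @return List of class `"confounder_screen"`: `results` (snp_id,
#'   covariate, test, statistic, p), `skipped`, `summary`.
#' @export
confounder_screen <- function(genotypes, covariates, types = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_table"))
  covariates <- as.data.frame(covariates)
  drop_cols <- c("subject_id", "marker_conc", "marker_act", "time_years",
                 "event", "confounder")
  covariates <- covariates[, setdiff(names(covariates), drop_cols), drop = FALSE]
  if (!ncol(covariates)) stop("no covariates to screen")
  classify <- function(name) {
    if (!is.null(types) && name %in% names(types)) return(types[[name]])
    v <- covariates[[name]]
    if (is.factor(v) || is.character(v) || is.logical(v) ||
        length(unique(v[!is.na(v)])) <= 3) "categorical" else "continuous"
  }
  type_of <- vapply(names(covariates), classify, character(1))
  if (!all(type_of %in% c("continuous", "categorical")))
    stop("covariate types must be 'continuous' or 'categorical'")
  single <- names(covariates)[vapply(covariates, function(v)
    length(unique(v[!is.na(v)])) < 2, logical(1))]
  for (cv in single)
    warning("covariate '", cv, "' has a single level; skipped")
  results <- list(); skipped <- list()
  for (snp in snp_ids(genotypes)) {
    g <- genotypes[[snp]]
    for (cv in names(covariates)) {
      v <- covariates[[cv]]
      if (cv %in% single) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(snp_id = snp, covariate = cv, stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch({
        if (type_of[[cv]] == "continuous") {
          kw <- kruskal_wallis(as.numeric(v), g)
          c(test = "kruskal_wallis", statistic = kw$H, p = kw$p)
        } else {
          ct <- chi2_independence(g, v)
          c(test = "chi2", statistic = ct$statistic, p = ct$p)
        }
      }, error = function(e) NULL)
      if (is.null(res)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(snp_id = snp, covariate = cv, stringsAsFactors = FALSE)
        next
      }
      results[[length(results) + 1L]] <- data.frame(
        snp_id = snp, covariate = cv, test = res[["test"]],
        statistic = as.numeric(res[["statistic"]]), p = as.numeric(res[["p"]]),
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame(snp_id = character(0), covariate = character(0),
               test = character(0), statistic = numeric(0), p = numeric(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(snp_id = character(0), covariate = character(0))
  n_tests <- nrow(results)
  n_sig <- sum(results$p < alpha)
  structure(list(
    results = results, skipped = skipped,
    summary = list(
      n_tests = n_tests, n_significant = n_sig, alpha = alpha,
      expected_under_null = alpha * n_tests,
      null_central95 = if (n_tests > 0)
        stats::qbinom(c(0.025, 0.975), n_tests, alpha) else c(NA, NA))),
    class = "confounder_screen")
}

#' @export
print.confounder_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "Genotype-confounder screen: %d tests, %d with p < %.2f ",
    "(null expectation %.1f, central 95%% interval %d-%d)\n"),
    s$n_tests, s$n_significant, s$alpha, s$expected_under_null,
    s$null_central95[1], s$null_central95[2]))
  if (nrow(x$skipped))
    cat(sprintf("  %d pair(s) skipped\n", nrow(x$skipped)))
  invisible(x)
}
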