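# Marker -> event and genotype -> event Cox proportional-hazards stage.
# Partial-likelihood maximization is delegated to survival::coxph with
# Efron tie handling; this file owns the interface conventions (complete
# cases, focal vs adjustment terms, Wald CIs on the HR scale) and the
# guard rails (zero events, rank deficiency, diverging estimates).

new_hazard_estimates <- function(term, log_hr, se, p, role = "focal") {
  out <- data.frame(term = term, log_hr = log_hr, se = se,
                    hr = exp(log_hr),
                    ci_low = exp(log_hr - 1.96 * se),
                    ci_high = exp(log_hr + 1.96 * se),
                    p = p, role = role, scale_tag = "log_hazard",
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hazard_estimates", "data.frame")
  out
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization (Efron handling of
#' tied event times) of the event hazard on the supplied focal design
#' columns plus adjustment covariates, on complete cases.  Returns Wald
#' standard errors, hazard ratios and 95% CIs per focal term.
#'
#' @param time Positive follow-up times (years).
#' @param event 0/1 event indicators.
#' @param design Numeric matrix/data frame of focal columns (e.g. doses,
#'   ln(marker), a genotype score).
#' @param adjust Optional data frame of adjustment covariates; factors are
#'   expanded to treatment contrasts.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return A `"hazard_estimates"` data frame (focal terms first, adjustment
#'   terms with `role = "adjust"`), with the `coxph` fit as attribute
#'   `"fit"` and the number of events as attribute `"n_events"`.
#' @export
fit_cox <- function(time, event, design, adjust = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(time > 0, na.rm = TRUE), all(event %in% c(0, 1) | is.na(event)))
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  adjm <- if (!is.null(adjust) && ncol(as.data.frame(adjust)) > 0)
    stats::model.matrix(~ ., data = as.data.frame(adjust))[, -1, drop = FALSE]
  else NULL
  X <- if (is.null(adjm)) design else cbind(design, adjm)
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(event)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) == 0)
    stop("no events observed: Cox model carries no information")
  const <- apply(X[, colnames(design), drop = FALSE], 2,
                 function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("no-information design column(s): ",
         paste(colnames(design)[const], collapse = ", "))
  if (qr(X)$rank < ncol(X))
    stop("Cox design is rank deficient (collinear columns)")
  df <- data.frame(X, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  df$time <- time; df$event <- event
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           toler.chol = 1e-12,
                                                           iter.max = 50))
  sm <- summary(fit)$coefficients
  if (any(abs(sm[, "coef"]) > 15))
    warning("diverging coefficient(s): possible monotone likelihood ",
            "(perfect separation)")
  role <- ifelse(rownames(sm) %in% colnames(design) |
                   rownames(sm) %in% sprintf("`%s`", colnames(design)),
                 "focal", "adjust")
  term <- gsub("`", "", rownames(sm))
  out <- new_hazard_estimates(term, sm[, "coef"], sm[, "se(coef)"],
                              sm[, "Pr(>|z|)"], role)
  attr(out, "fit") <- fit
  attr(out, "n_events") <- sum(event)
  attr(out, "n") <- length(event)
  out
}

#' Marker-event Cox model
#'
#' Hazard of the event per unit of `ln(marker)`, adjusted for the clinical
#' covariate set.  The returned estimate for the `ln_marker` term is the
#' marker-disease stage coefficient (`beta_md`) consumed by the MR engine.
#'
#' @param surv Data frame with `time_years` and `event` columns.
#' @param marker Positive biomarker values (untransformed; the model uses
#'   their natural log).
#' @param covariates Data frame of adjustment covariates.
#' @param covariate_names Columns of `covariates` to adjust for; defaults
#'   to the full clinical stand-in set present in synthetic cohorts,
#'   intersected with what is available.
#' @return `"hazard_estimates"` with the `ln_marker` row first.
#' @export
marker_event_model <- function(surv, marker, covariates,
                               covariate_names = NULL) {
  stopifnot(all(marker > 0, na.rm = TRUE))
  if (is.null(covariate_names))
    covariate_names <- intersect(
      c("age", "sex", "smoking_status", "diabetes", "hypertension",
        "acute_mi", "hdl_cholesterol", "ldl_cholesterol", "lipid_lowering",
        "bmi", "n_vessels"),
      names(covariates))
  missing_cov <- setdiff(covariate_names, names(covariates))
  if (length(missing_cov))
    stop("adjustment covariate(s) absent: ", paste(missing_cov, collapse = ", "))
  design <- matrix(log(marker), ncol = 1, dimnames = list(NULL, "ln_marker"))
  fit_cox(surv$time_years, surv$event, design,
          covariates[, covariate_names, drop = FALSE])
}

#' Genotype-event Cox model
#'
#' Observed hazard ratios of one SNP under the additive (per minor allele)
#' or genotypic (heterozygote / rare homozygote vs common homozygote)
#' coding, adjusted for age and sex.  SNPs flagged as excluded by the
#' Hardy-Weinberg rule are rejected with an error rather than silently
#' fitted.
#'
#' @param surv Data frame with `time_years` and `event`.
#' @param genotypes A [genotype_table()].
#' @param snp SNP id to model.
#' @param scheme `"additive"` or `"genotypic"`.
#' @param covariates Data frame with `age` and `sex`.
#' @param qc Optional `"snp_qc"` record set; if supplied and the SNP is
#'   flagged `excluded`, the call errors.
#' @return `"hazard_estimates"` for the SNP's focal term(s).
#' @export
genotype_event_model <- function(surv, genotypes, snp,
                                 scheme = c("additive", "genotypic"),
                                 covariates, qc = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(genotypes, "genotype_table"), snp %in% snp_ids(genotypes))
  if (!is.null(qc)) {
    i <- match(snp, qc$snp_id)
    if (!is.na(i) && isTRUE(qc$excluded[i]))
      stop("SNP ", snp, " is excluded from survival analyses by the ",
           "Hardy-Weinberg equilibrium rule (hwe_p = ",
           signif(qc$hwe_p[i], 2), ")")
  }
  design <- code_genotypes(genotypes[[snp]], scheme, snp)
  fit_cox(surv$time_years, surv$event, design,
          covariates[, c("age", "sex"), drop = FALSE])
}
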