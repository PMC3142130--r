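# Synthetic-cohort generator.  Each stage uses its own child stream derived
# from the master seed, so a stage re-run in isolation reproduces exactly
# the values it produced inside simulate_cohort().

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws, independently for each SNP in the panel, minor-allele doses from
#' Binomial(2, maf) — the Hardy-Weinberg proportions p^2, 2pq, q^2.
#'
#' @param config A [sim_config()].
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_subjects
  doses <- lapply(config$snps, function(s) stats::rbinom(n, 2L, s$maf))
  names(doses) <- vapply(config$snps, `[[`, character(1), "id")
  meta <- data.frame(
    id = names(doses),
    common_allele = vapply(config$snps, `[[`, character(1), "common_allele"),
    rare_allele = vapply(config$snps, `[[`, character(1), "rare_allele"),
    stringsAsFactors = FALSE)
  genotype_table(as.data.frame(doses), sprintf("S%05d", seq_len(n)), meta)
}

# The 25 candidate confounders screened against genotype, mirroring the
# covariate panel of a secondary-prevention cardiac cohort: demographics,
# disease history, discharge drugs, lipids and inflammation markers.
# None of them depends on genotype: the generator enforces the global null
# of the genotype-confounder screen.  The latent `confounder` column is the
# only variable allowed to touch both marker and hazard; downstream model
# stages never see it.
#' Simulate subject covariates
#'
#' @param config A [sim_config()].
#' @return Data frame with `subject_id`, a latent `confounder` column, and
#'   25 clinical covariates (14 continuous, 11 categorical).
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2L))
  n <- config$n_subjects
  # age ~ Normal(61, 8) truncated to [30, 70] by resampling
  age <- stats::rnorm(n, 61, 8)
  while (any(bad <- age < 30 | age > 70)) age[bad] <- stats::rnorm(sum(bad), 61, 8)
  rlnormv <- function(ml, sl) stats::rlnorm(n, ml, sl)
  bern <- function(p) stats::rbinom(n, 1L, p)
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    confounder = stats::rnorm(n),
    age = age,
    sex = factor(ifelse(bern(0.15) == 1L, "female", "male"),
                 levels = c("male", "female")),
    smoking_status = factor(sample(c("never", "former", "current"), n,
                                   replace = TRUE, prob = c(0.31, 0.64, 0.05)),
                            levels = c("never", "former", "current")),
    acute_mi = bern(0.58),
    diabetes = bern(0.18),
    hypertension = bern(0.56),
    n_vessels = factor(sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))),
    beta_blocker = bern(0.8),
    ace_inhibitor = bern(0.53),
    diuretic = bern(0.25),
    lipid_lowering = bern(0.77),
    aspirin = bern(0.9),
    bmi = stats::rnorm(n, 26.8, 3.3),
    hdl_cholesterol = rlnormv(log(1.1), 0.25),
    ldl_cholesterol = rlnormv(log(2.9), 0.3),
    total_cholesterol = rlnormv(log(4.9), 0.2),
    triglycerides = rlnormv(log(1.5), 0.45),
    lp_pla2 = rlnormv(log(200), 0.25),
    interleukin6 = rlnormv(log(2.5), 0.7),
    hscrp = rlnormv(log(2.2), 1.0),
    nt_probnp = rlnormv(log(250), 1.1),
    rbp4 = rlnormv(log(34), 0.3),
    cystatin_c = rlnormv(log(0.9), 0.2),
    adiponectin = rlnormv(log(8.5), 0.5),
    creatinine_clearance = stats::rnorm(n, 95, 25),
    stringsAsFactors = FALSE)
}

#' Simulate biomarker values from genotype and covariates
#'
#' Generates a log-normal biomarker:
#' `ln(marker) = marker_base + sum(per_allele_log_effect * dose) +
#'  age_effect*(age-60) + sex_effect*female + confounder term +
#'  Normal(0, marker_sd)`.
#'
#' @param genotypes A [genotype_table()], row-aligned with `covariates`.
#' @param covariates Data frame from [simulate_covariates()].
#' @param config A [sim_config()].
#' @param effect_scale Multiplier applied to all genetic effects; used to
#'   derive the enzymatic-activity companion marker whose genetic
#'   determination is weaker than the mass concentration's.
#' @param stream Internal child-seed stream index.
#' @return Numeric vector of strictly positive marker values.
#' @export
simulate_marker <- function(genotypes, covariates, config, effect_scale = 1,
                            stream = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genotypes) != nrow(covariates))
    stop("genotypes and covariates are not row-aligned: ",
         nrow(genotypes), " vs ", nrow(covariates), " rows")
  set.seed(child_seed(config$seed, stream))
  doses <- dose_matrix(genotypes)
  eff <- vapply(config$snps, `[[`, numeric(1), "per_allele_log_effect")
  lp <- config$marker_base +
    drop(doses %*% (effect_scale * eff)) +
    config$age_effect * (covariates$age - 60) +
    config$sex_effect * (covariates$sex == "female") +
    config$confounder_effect_marker * covariates$confounder
  noise <- if (config$marker_sd > 0) stats::rnorm(nrow(doses), 0, config$marker_sd) else 0
  unname(exp(lp + noise))
}

#' Simulate proportional-hazards event times
#'
#' Event times are exponential with subject-specific hazard
#' `baseline_hazard * exp(beta_marker_hazard * ln(marker) + confounder
#' term)`.  The observed time is the minimum of the event time, an
#' independent exponential dropout time and the administrative censoring
#' horizon; the event indicator is 1 iff the event time is smallest.
#'
#' @param marker Positive biomarker values.
#' @param covariates Data frame from [simulate_covariates()] (supplies the
#'   latent confounder).
#' @param config A [sim_config()].
#' @return Data frame with `subject_id`, `time_years` (> 0) and `event`
#'   (0/1).
#' @export
simulate_survival <- function(marker, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(marker <= 0)) stop("marker values must be strictly positive")
  if (length(marker) != nrow(covariates))
    stop("marker and covariates are not row-aligned")
  set.seed(child_seed(config$seed, 4L))
  n <- length(marker)
  hazard <- config$baseline_hazard *
    exp(config$beta_marker_hazard * log(marker) +
        config$confounder_effect_hazard * covariates$confounder)
  t_event <- ifelse(hazard > 0, stats::rexp(n, pmax(hazard, .Machine$double.xmin)), Inf)
  t_drop <- if (config$dropout_rate > 0) stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  time <- pmin(t_event, t_drop, config$admin_censor_years)
  data.frame(subject_id = covariates$subject_id,
             time_years = pmax(time, .Machine$double.eps),
             event = as.integer(t_event <= pmin(t_drop, config$admin_censor_years) &
                                  is.finite(t_event)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs the genotype, covariate, biomarker and survival generators in order
#' and returns the assembled cohort.  The biomarker is generated twice: as
#' the mass concentration (`marker_conc`, full genetic effects) and as the
#' enzymatic activity (`marker_act`, genetic effects halved), so activity
#' analyses can reuse the same downstream operations.
#'
#' @param config A [sim_config()] or [sim_scenario()].
#' @return A list of class `"mr_cohort"` with elements `genotypes`
#'   (genotype table), `phenotypes` (covariates + `marker_conc`,
#'   `marker_act`; the latent confounder is withheld), `survival`
#'   (time/event records), and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_scenario("causal", n_subjects = 300, seed = 7))
#' str(cohort$survival)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  conc <- simulate_marker(gt, cov, config, effect_scale = 1, stream = 3L)
  act <- simulate_marker(gt, cov, config, effect_scale = 0.5, stream = 5L)
  surv <- simulate_survival(conc, cov, config)
  phen <- cov[, setdiff(names(cov), "confounder")]
  phen$marker_conc <- conc
  phen$marker_act <- act
  structure(list(genotypes = gt, phenotypes = phen, survival = surv,
                 config = config),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d SNPs, %d events over %.1f yr\n",
              nrow(x$phenotypes), ncol(x$genotypes) - 1L,
              sum(x$survival$event), x$config$admin_censor_years))
  invisible(x)
}

#' Write a cohort to tab-separated files
#'
#' Writes `genotypes.tsv`, `phenotypes.tsv` and `survival.tsv` (header row,
#' tab-separated, `.` for missing) into `dir`.
#'
#' @param cohort An `"mr_cohort"`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.tsv", "phenotypes.tsv", "survival.tsv"))
  wr <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  wr(as.data.frame(cohort$genotypes), paths[1])
  wr(cohort$phenotypes, paths[2])
  wr(cohort$survival, paths[3])
  invisible(paths)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory holding `genotypes.tsv`, `phenotypes.tsv`,
#'   `survival.tsv`.
#' @return A list of class `"mr_cohort"` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  rd <- function(name) utils::read.table(file.path(dir, name), header = TRUE,
                                         sep = "\t", na.strings = ".",
                                         stringsAsFactors = FALSE)
  g <- rd("genotypes.tsv")
  gt <- genotype_table(g[, -1, drop = FALSE], g$subject_id)
  phen <- rd("phenotypes.tsv")
  for (v in intersect(c("sex", "smoking_status", "n_vessels"), names(phen)))
    phen[[v]] <- factor(phen[[v]])
  if ("sex" %in% names(phen) && all(levels(phen$sex) %in% c("male", "female")))
    phen$sex <- factor(phen$sex, levels = c("male", "female"))
  surv <- rd("survival.tsv")
  if (!all(c("subject_id", "time_years", "event") %in% names(surv)))
    stop("survival.tsv must have columns subject_id, time_years, event")
  structure(list(genotypes = gt, phenotypes = phen, survival = surv,
                 config = NULL), class = "mr_cohort")
}
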