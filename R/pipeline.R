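# End-to-end orchestration: simulate (or read) -> genotype QC -> marker
# association + stepwise score -> Cox stage -> MR comparison -> confounder
# screen.  Every stage shares complete-case conventions; artifacts are
# plain tab-separated files plus a flat key-value summary and a log that
# records every seed, threshold and exclusion, so a run is reconstructible
# from its outputs.

#' Read a flat key:value configuration file into a simulation config
#'
#' The file is YAML with scalar keys mirroring [sim_config()] fields; SNPs
#' are given as a `snps` list of `{id, maf, per_allele_log_effect}`
#' entries.
#'
#' @param path Config file path.
#' @return A `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$snps))
    y$snps <- lapply(y$snps, function(s) do.call(snp_spec, s))
  do.call(sim_config, y)
}

#' Write a simulation config to a flat key:value file
#' @param config A `"sim_config"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- unclass(config)
  y$snps <- lapply(y$snps, function(s) unclass(s))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full Mendelian-randomization pipeline
#'
#' Executes, in order: cohort simulation (or ingestion of existing
#' tables), per-SNP quality control with the Hardy-Weinberg exclusion
#' rule, the single-SNP marker association table, stepwise multi-locus
#' selection and the weighted genotype score, the marker-event and
#' genotype-event Cox models, the expected-under-causality hazard ratios
#' with Monte-Carlo confidence intervals, the observed-versus-expected
#' comparison, and the genotype-confounder screen.
#'
#' The per-SNP genotype-marker coefficients entering the MR step come from
#' the age/sex-adjusted single-SNP models (additive and genotypic
#' codings); the score's genotype-marker coefficient is the score's
#' reference beta.
#'
#' @param config A [sim_config()] describing the cohort to simulate, or a
#'   directory path holding `genotypes.tsv`, `phenotypes.tsv`,
#'   `survival.tsv` as written by [write_cohort()].  Exactly one input
#'   source.
#' @param out_dir Output directory for artifacts (created); `NULL` to skip
#'   writing.
#' @param hwe_alpha Hardy-Weinberg exclusion level.
#' @param mc_draws Monte-Carlo draws per expected-HR interval (>= 1000).
#' @param seed Master seed for fold assignment and Monte-Carlo streams;
#'   defaults to the simulation seed when a config is given.
#' @param marker Which biomarker column to analyse, `"marker_conc"` or
#'   `"marker_act"`.
#' @return List of class `"mr_run"` with elements `qc`, `association`,
#'   `stepwise`, `score`, `marker_hazard`, `observed`, `expected`,
#'   `comparison`, `screen`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, hwe_alpha = 0.05,
                         mc_draws = 1e6, seed = NULL,
                         marker = c("marker_conc", "marker_act")) {
  marker <- match.arg(marker)
  if (mc_draws < 1000) stop("mc_draws must be >= 1000")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (inherits(config, "sim_config")) {
    if (is.null(seed)) seed <- config$seed
    cohort <- simulate_cohort(config)
    say("simulated cohort: n=%d, seed=%d", config$n_subjects, config$seed)
  } else if (is.character(config) && length(config) == 1L && dir.exists(config)) {
    cohort <- read_cohort(config)
    if (is.null(seed)) seed <- 1L
    say("read cohort from %s", config)
  } else if (inherits(config, "mr_cohort")) {
    cohort <- config
    if (is.null(seed)) seed <- if (!is.null(cohort$config)) cohort$config$seed else 1L
    say("using in-memory cohort")
  } else stop("config must be a sim_config, an mr_cohort, or a cohort directory")
  seed <- as.integer(seed)
  say("master analysis seed: %d; hwe_alpha=%g; mc_draws=%g",
      seed, hwe_alpha, mc_draws)

  gt <- cohort$genotypes
  phen <- cohort$phenotypes
  surv <- cohort$survival
  if (!all(c("age", "sex") %in% names(phen)))
    stop("phenotype table lacks required column(s): ",
         paste(setdiff(c("age", "sex"), names(phen)), collapse = ", "))
  if (!marker %in% names(phen))
    stop("phenotype table lacks marker column '", marker, "'")
  if (!identical(gt$subject_id, phen$subject_id) ||
      !identical(gt$subject_id, surv$subject_id))
    stop("subject ids are misaligned across genotypes/phenotypes/survival tables")
  mk <- phen[[marker]]

  ## QC
  qc <- snp_qc(gt, hwe_alpha)
  for (i in which(qc$excluded))
    say("SNP %s excluded by HWE rule (p=%.3g < %g)",
        qc$snp_id[i], qc$hwe_p[i], hwe_alpha)
  kept <- qc$snp_id[!qc$excluded]

  ## marker association (all SNPs, excluded ones included)
  assoc <- marker_association_table(gt, mk, phen, hwe_alpha)

  ## stepwise selection + score over HWE-passing SNPs
  gt_kept <- genotype_table(as.data.frame(gt)[, kept, drop = FALSE],
                            gt$subject_id)
  sw <- stepwise_cv_select(log(mk), gt_kept, phen, "additive", seed = seed)
  say("stepwise (additive) selected: %s",
      if (length(sw$selected)) paste(sw$selected, collapse = ", ") else "(none)")
  score <- NULL
  if (length(sw$selected)) {
    cf <- sw$coefficients
    focal <- cf[cf$role == "focal", ]
    betas <- stats::setNames(focal$beta, sub("_add$", "", focal$term))
    score <- build_genotype_score(betas, gt_kept)
  }

  ## survival stage
  mh <- marker_event_model(surv, mk, phen)
  beta_md <- mh$log_hr[mh$term == "ln_marker"]
  se_md <- mh$se[mh$term == "ln_marker"]
  say("marker-event HR per ln(marker): %.3f (SE %.3f)", exp(beta_md), se_md)

  observed <- list(); expected <- list()
  coding_map <- c(add = "additive", het = "het", rarehom = "rare_hom")
  k <- 0L
  for (snp in kept) {
    for (scheme in c("additive", "genotypic")) {
      hz <- tryCatch(
        genotype_event_model(surv, gt, snp, scheme, phen, qc),
        error = function(e) { say("skipping %s/%s: %s", snp, scheme,
                                  conditionMessage(e)); NULL })
      if (is.null(hz)) next
      # matching genotype->marker estimates, age/sex-adjusted single-SNP model
      d <- gt[[snp]]; keep_i <- !is.na(d) & !is.na(mk)
      design <- code_genotypes(d[keep_i], scheme, snp)
      design <- design[, colSums(design, na.rm = TRUE) > 0, drop = FALSE]
      if (!ncol(design)) next
      em <- fit_marker_regression(log(mk[keep_i]), design,
                                  phen[keep_i, c("age", "sex")])
      for (term in hz$term[hz$role == "focal"]) {
        suffix <- sub(paste0("^", snp, "_"), "", term)
        if (!term %in% em$term) next
        j <- match(term, em$term)
        k <- k + 1L
        observed[[k]] <- data.frame(
          label = snp, coding = unname(coding_map[suffix]),
          hr = hz$hr[hz$term == term], ci_low = hz$ci_low[hz$term == term],
          ci_high = hz$ci_high[hz$term == term], stringsAsFactors = FALSE)
        expected[[k]] <- mr_expected(snp, unname(coding_map[suffix]),
                                     em$beta[j], em$se[j], beta_md, se_md,
                                     n_draws = mc_draws, seed = seed + k)
      }
    }
  }
  if (!is.null(score)) {
    hz <- fit_cox(surv$time_years, surv$event,
                  matrix(score$score, ncol = 1,
                         dimnames = list(NULL, "score")),
                  phen[, c("age", "sex")])
    k <- k + 1L
    observed[[k]] <- data.frame(label = "score", coding = "score",
                                hr = hz$hr[1], ci_low = hz$ci_low[1],
                                ci_high = hz$ci_high[1],
                                stringsAsFactors = FALSE)
    ref <- score$definition$snp[1]
    cf <- sw$coefficients
    se_ref <- cf$se[match(paste0(ref, "_add"), cf$term)]
    expected[[k]] <- mr_expected("score", "score", score$reference_beta,
                                 se_ref, beta_md, se_md,
                                 n_draws = mc_draws, seed = seed + k)
  }
  observed <- do.call(rbind, observed)
  expected <- do.call(rbind, expected)
  comparison <- compare_observed_expected(observed, expected)
  say("MR comparison rows: %d; consistent: %d",
      nrow(comparison), sum(comparison$consistent))

  ## confounder screen
  scr <- confounder_screen(gt, phen)
  say("confounder screen: %d tests, %d with p < %g (null expectation %.1f)",
      scr$summary$n_tests, scr$summary$n_significant, scr$summary$alpha,
      scr$summary$expected_under_null)

  run <- structure(list(qc = qc, association = assoc, stepwise = sw,
                        score = score, marker_hazard = mh,
                        observed = observed, expected = expected,
                        comparison = comparison, screen = scr,
                        seed = seed, log = log_lines),
                   class = "mr_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Flat key=value summary, one block per MR row: diffable and
# machine-readable without a JSON dependency.
summary_lines <- function(run) {
  c(sprintf("seed=%d", run$seed),
    sprintf("marker_event_hr=%.6f", exp(run$marker_hazard$log_hr[1])),
    unlist(lapply(seq_len(nrow(run$comparison)), function(i) {
      r <- run$comparison[i, ]
      pre <- sprintf("mr.%s.%s", r$label, r$coding)
      sprintf("%s.%s=%.6f", pre,
              c("hr_observed", "obs_low", "obs_high", "hr_expected",
                "exp_low", "exp_high", "consistent"),
              c(r$hr, r$ci_low, r$ci_high, r$hr_expected, r$mc_low,
                r$mc_high, as.numeric(r$consistent)))
    })))
}

#' Write pipeline artifacts
#'
#' Writes `qc.tsv`, `association.tsv`, `observed_expected.tsv`,
#' `screen.tsv`, `summary.txt` (flat key=value) and `run.log` to a
#' directory.
#'
#' @param run An `"mr_run"`.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "mr_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  wr(as.data.frame(run$qc), "qc.tsv")
  wr(run$association, "association.tsv")
  wr(run$comparison, "observed_expected.tsv")
  wr(run$screen$results, "screen.tsv")
  writeLines(summary_lines(run), file.path(out_dir, "summary.txt"))
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.mr_run <- function(x, ...) {
  cat("Mendelian-randomization run\n")
  cat(sprintf("  SNPs: %d (%d HWE-excluded); events: %d\n",
              nrow(x$qc), sum(x$qc$excluded),
              attr(x$marker_hazard, "n_events")))
  cat(sprintf("  marker-event HR per ln(marker): %.2f (%.2f-%.2f)\n",
              x$marker_hazard$hr[1], x$marker_hazard$ci_low[1],
              x$marker_hazard$ci_high[1]))
  cat(sprintf("  observed-vs-expected rows: %d, consistent: %d\n",
              nrow(x$comparison), sum(x$comparison$consistent)))
  print(x$screen)
  invisible(x)
}
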