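# Genotype QC: minor allele frequency, Hardy-Weinberg chi-square, the
# exclusion rule applied before survival/score analyses, two-locus EM
# linkage disequilibrium, and design-matrix codings.

#' Minor allele frequency from genotype counts
#'
#' @param counts Numeric vector `(n_AA, n_Aa, n_aa)`: common homozygotes,
#'   heterozygotes, rare homozygotes.
#' @return The frequency of the rare allele, `(n_Aa + 2 n_aa) / (2 n)`.
#'   If the nominally rare allele turns out to be the major one (frequency
#'   > 0.5) the labels are flipped with a warning so the returned value is
#'   always a minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("degenerate input: all genotype counts are zero")
  maf <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (maf > 0.5) {
    warning("allele labelled rare has frequency ", signif(maf, 3),
            " > 0.5; alleles relabelled so the minor allele is reported")
    maf <- 1 - maf
  }
  unname(maf)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) of the observed
#' genotype counts against the Hardy-Weinberg expectations `n p^2`,
#' `2 n p q`, `n q^2` computed from the sample allele frequency.
#'
#' @param counts Numeric vector `(n_AA, n_Aa, n_aa)`.
#' @param min_n Minimum total count below which the test is refused.
#' @return List with `chi2` and `p` (upper tail of chi-square, 1 df).
#' @export
hwe_test <- function(counts, min_n = 10) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n < min_n) stop("too few genotypes for a HWE test (n = ", n, ")")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)  # rare-allele frequency
  if (q == 0 || q == 1)
    stop("monomorphic SNP: HWE test undefined")
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = unname(chi2), p = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE))
}

#' Per-SNP QC summary
#'
#' Computes call count, minor allele frequency and the Hardy-Weinberg
#' chi-square test for every SNP in a genotype table, then applies the
#' exclusion rule ([apply_hwe_exclusion()]).  Monomorphic SNPs get
#' `hwe_chi2 = hwe_p = NA` (not testable) and are never excluded by the
#' HWE rule.
#'
#' @param genotypes A [genotype_table()].
#' @param hwe_alpha Significance level of the exclusion rule.
#' @return Data frame of class `"snp_qc"` with columns `snp_id`,
#'   `n_called`, `maf`, `hwe_chi2`, `hwe_p`, `excluded`.
#' @export
snp_qc <- function(genotypes, hwe_alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_table"))
  rows <- lapply(snp_ids(genotypes), function(id) {
    cnt <- genotype_counts(genotypes[[id]])
    hw <- tryCatch(hwe_test(cnt), error = function(e) list(chi2 = NA_real_, p = NA_real_))
    maf <- if (sum(cnt) > 0) compute_maf(cnt) else NA_real_
    data.frame(snp_id = id, n_called = sum(cnt), maf = maf,
               hwe_chi2 = hw$chi2, hwe_p = hw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- apply_hwe_exclusion(out, hwe_alpha)
  class(out) <- c("snp_qc", "data.frame")
  out
}

#' Flag SNPs deviating from Hardy-Weinberg equilibrium
#'
#' A SNP is excluded iff its HWE p-value is strictly below `alpha`
#' (boundary values are retained).  Exclusion applies to survival and
#' genotype-score analyses; excluded SNPs remain in the marker-association
#' output.
#'
#' @param records Data frame with a `hwe_p` column.
#' @param alpha Significance level, default 0.05.
#' @return `records` with a logical `excluded` column (re)computed.
#' @export
apply_hwe_exclusion <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), "hwe_p" %in% names(records))
  records$excluded <- !is.na(records$hwe_p) & records$hwe_p < alpha
  records
}

#' Pairwise linkage disequilibrium from unphased doses
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' minor-allele doses by expectation-maximization (double heterozygotes are
#' split between the two phase configurations by their current odds), then
#' computes `D = p_ab - p_a p_b` for the rare-rare haplotype, the
#' normalized `D' = D / Dmax`, and `r^2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`.
#'
#' @param dose_a,dose_b Integer dose vectors (0/1/2/NA) for the two SNPs;
#'   pairs with a missing value at either locus are dropped.
#' @param tol,max_iter EM convergence tolerance (max absolute change in a
#'   haplotype frequency) and iteration cap.
#' @return List with `Dprime`, `r2`, `D`, `hap_freqs` (named `ab`, `aB`,
#'   `Ab`, `AB` with lower case = rare), `n_pairs`, `iterations`.
#' @export
pairwise_ld <- function(dose_a, dose_b, tol = 1e-10, max_iter = 1000L) {
  keep <- !is.na(dose_a) & !is.na(dose_b)
  a <- dose_a[keep]; b <- dose_b[keep]
  if (length(a) < 2) stop("need at least 2 jointly called subjects")
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("monomorphic input: LD undefined")
  n <- tabulate(3L * a + b + 1L, nbins = 9L)  # index (a, b) in row-major 3x3
  ncell <- function(i, j) n[3L * i + j + 1L]
  pa <- mean(a) / 2; pb <- mean(b) / 2      # rare-allele frequencies
  # haplotype order: (rare,rare), (rare,common), (common,rare), (common,common)
  h <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  # haplotype counts fixed by genotype, except the (1,1) double heterozygotes
  fixed <- c(
    2 * ncell(2, 2) + ncell(2, 1) + ncell(1, 2),  # rr
    2 * ncell(2, 0) + ncell(2, 1) + ncell(1, 0),  # rC
    2 * ncell(0, 2) + ncell(0, 1) + ncell(1, 2),  # Cr
    2 * ncell(0, 0) + ncell(0, 1) + ncell(1, 0))  # CC
  ndh <- ncell(1, 1)
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- h[1] * h[4]                 # (rr)+(CC) phase
    trans <- h[2] * h[3]               # (rC)+(Cr) phase
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- fixed + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / sum(cnt)
    if (max(abs(h_new - h)) < tol || it >= max_iter) { h <- h_new; break }
    h <- h_new
  }
  names(h) <- c("ab", "aB", "Ab", "AB")
  D <- h[["ab"]] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  dprime <- if (dmax > 0) D / dmax else 0
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(Dprime = unname(dprime), r2 = unname(r2), D = unname(D),
       hap_freqs = h, n_pairs = length(a), iterations = it)
}

#' Code genotype doses into regression design columns
#'
#' @param doses Integer dose vector (0/1/2/NA).
#' @param scheme `"additive"` (single 0/1/2 column) or `"genotypic"`
#'   (heterozygote and rare-homozygote indicators, common homozygote as
#'   reference).
#' @param prefix Column-name prefix, typically the SNP id.
#' @return Numeric matrix with one (`additive`) or two (`genotypic`)
#'   columns.
#' @export
code_genotypes <- function(doses, scheme = c("additive", "genotypic"),
                           prefix = "snp") {
  scheme <- match.arg(scheme)
  stopifnot(all(is.na(doses) | doses %in% 0:2))
  if (scheme == "additive") {
    m <- matrix(as.numeric(doses), ncol = 1,
                dimnames = list(NULL, paste0(prefix, "_add")))
  } else {
    m <- cbind(as.numeric(doses == 1L), as.numeric(doses == 2L))
    m[is.na(doses), ] <- NA_real_
    colnames(m) <- paste0(prefix, c("_het", "_rarehom"))
  }
  m
}

#' Read a tab-separated genotype file
#'
#' Expects a header row with `subject_id` followed by one column per SNP
#' holding 0/1/2 doses, `.` for missing.
#'
#' @param path File path.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(g))
    stop("genotype file ", path, " lacks a subject_id column")
  genotype_table(g[, setdiff(names(g), "subject_id"), drop = FALSE],
                 g$subject_id)
}

#' Read genotypes from a VCF file
#'
#' Maps diploid GT fields of biallelic records to minor-allele doses;
#' multiallelic records are skipped with a warning.  Requires the `vcfR`
#' package.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A [genotype_table()] with REF/ALT alleles as metadata.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(al != "0")
    }, integer(1))
  }
  doses <- t(apply(gt, 1, count_alt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  dm <- as.data.frame(t(doses))
  names(dm) <- ids
  genotype_table(dm, colnames(gt),
                 data.frame(id = ids, common_allele = fix$REF,
                            rare_allele = fix$ALT, stringsAsFactors = FALSE))
}
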