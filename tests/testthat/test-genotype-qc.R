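test_that("minor allele frequency matches the allele-count formula", {
  expect_equal(compute_maf(c(60, 30, 10)), 0.25)
  expect_equal(compute_maf(c(100, 0, 0)), 0)
  expect_equal(compute_maf(c(25, 50, 25)), 0.5)
  expect_error(compute_maf(c(0, 0, 0)), "degenerate")
  # relabelling when the 'rare' allele is actually major
  expect_warning(m <- compute_maf(c(10, 30, 60)), "relabelled")
  expect_equal(m, 0.25)
  # invariance under swapping homozygote labels
  for (cnt in list(c(60, 30, 10), c(5, 40, 55), c(33, 34, 33))) {
    m1 <- suppressWarnings(compute_maf(cnt))
    m2 <- suppressWarnings(compute_maf(rev(cnt)))
    expect_equal(m1, m2)
  }
})

test_that("HWE chi-square equals the direct Pearson formula", {
  hw <- hwe_test(c(25, 50, 25))
  expect_equal(hw$chi2, 0)
  expect_equal(hw$p, 1)
  # hand-evaluated case: q = 0.6 common, expected (36, 48, 16)
  expect_equal(hwe_test(c(50, 20, 30))$chi2, 34.03, tolerance = 1e-3)
  expect_error(hwe_test(c(100, 0, 0)), "monomorphic")
  expect_error(hwe_test(c(3, 2, 1)), "too few")
  set.seed(42)
  for (i in 1:100) {
    cnt <- as.numeric(rmultinom(1, 200, c(runif(1, .1, .7), runif(1, .1, .5), runif(1, .05, .4))))
    if (cnt[2] + 2 * cnt[3] == 0 || cnt[2] + 2 * cnt[1] == 0) next
    expect_equal(hwe_test(cnt)$chi2, hwe_chi2_brute(cnt), tolerance = 1e-12)
  }
  # p monotone decreasing in chi2
  p_of <- function(cnt) hwe_test(cnt)$p
  expect_gt(p_of(c(52, 38, 10)), p_of(c(70, 10, 20)))
})

test_that("the HWE exclusion rule is strict-less-than at alpha", {
  rec <- data.frame(snp_id = c("a", "b", "c", "d"),
                    hwe_p = c(0.01, 0.04, 0.05, 0.6))
  out <- apply_hwe_exclusion(rec, alpha = 0.05)
  expect_equal(out$excluded, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("snp_qc summarizes call rate, MAF, HWE and exclusion per SNP", {
  cfg <- sim_config(n_subjects = 600,
                    snps = list(snp_spec("a", 0.3), snp_spec("b", 0.1)),
                    seed = 12)
  gt <- simulate_genotypes(cfg)
  gt$a[1:13] <- NA  # failed calls
  qc <- snp_qc(gt)
  expect_equal(qc$snp_id, c("a", "b"))
  expect_equal(qc$n_called, c(587L, 600L))
  expect_true(all(qc$maf >= 0 & qc$maf <= 0.5))
  expect_true(all(qc$hwe_p >= 0 & qc$hwe_p <= 1))
  # monomorphic SNP: not testable, never excluded
  gt2 <- genotype_table(data.frame(m = rep(0L, 50)))
  qc2 <- snp_qc(gt2)
  expect_true(is.na(qc2$hwe_p))
  expect_false(qc2$excluded)
})

test_that("two-locus EM recovers linkage disequilibrium", {
  # perfect LD
  set.seed(7)
  d <- rbinom(500, 2, 0.3)
  ld <- pairwise_ld(d, d)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(abs(ld$Dprime), 1, tolerance = 1e-6)
  # independent loci
  a <- rbinom(5000, 2, 0.3); b <- rbinom(5000, 2, 0.3)
  expect_lt(pairwise_ld(a, b)$r2, 0.01)
  # recovery of known haplotype frequencies (AB, Ab, aB, ab) by EM
  h_true <- c(AB = 0.5, Ab = 0.2, aB = 0.2, ab = 0.1)
  hap <- sample(1:4, 2 * 10000, replace = TRUE, prob = h_true)
  loc1 <- matrix(as.integer(hap %in% c(3, 4)), ncol = 2)  # 'a' rare at locus 1
  loc2 <- matrix(as.integer(hap %in% c(2, 4)), ncol = 2)  # 'b' rare at locus 2
  ld2 <- pairwise_ld(rowSums(loc1), rowSums(loc2))
  expect_equal(unname(ld2$hap_freqs[c("AB", "Ab", "aB", "ab")]),
               unname(h_true), tolerance = 0.02)
  expect_true(ld2$r2 >= 0 && ld2$r2 <= 1)
  expect_true(abs(ld2$Dprime) <= 1 + 1e-12)
  expect_error(pairwise_ld(rep(0L, 10), rbinom(10, 2, 0.5)), "monomorphic")
})

test_that("genotype codings produce the documented design columns", {
  d <- c(0L, 1L, 2L, NA)
  add <- code_genotypes(d, "additive", "s")
  gen <- code_genotypes(d, "genotypic", "s")
  expect_equal(colnames(add), "s_add")
  expect_equal(colnames(gen), c("s_het", "s_rarehom"))
  expect_equal(unname(gen[3, ]), c(0, 1))
  expect_equal(unname(gen[1, ]), c(0, 0))
  expect_true(all(is.na(gen[4, ])))
  # additive column equals het + 2 * rare-hom for every subject
  set.seed(3)
  dd <- rbinom(200, 2, 0.4)
  g2 <- code_genotypes(dd, "genotypic")
  expect_equal(as.vector(code_genotypes(dd, "additive")),
               as.vector(g2[, 1] + 2 * g2[, 2]))
})

test_that("genotype files round trip through the TSV reader", {
  cfg <- sim_config(n_subjects = 40, seed = 6)
  gt <- simulate_genotypes(cfg)
  gt$snp1[5] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(gt), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  back <- read_genotypes(path)
  expect_identical(dose_matrix(back), dose_matrix(gt))
})

test_that("VCF genotypes map GT fields to doses and skip multiallelic rows", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "P1", "P2", "P3", sep = "\t"),
           paste("1", "100", "rs1", "G", "A", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", sep = "\t"),
           paste("1", "200", "rs2", "T", "C", ".", "PASS", ".", "GT",
                 "0|1", "./.", "0/0", sep = "\t"),
           paste("1", "300", "rs3", "A", "C,T", ".", "PASS", ".", "GT",
                 "0/1", "0/2", "1/2", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(gt <- read_vcf_genotypes(path), "multiallelic")
  expect_equal(snp_ids(gt), c("rs1", "rs2"))
  expect_equal(unname(gt$rs1), c(0L, 1L, 2L))
  expect_equal(unname(gt$rs2), c(1L, NA, 0L))
})
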