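#' Genotype table constructor
#'
#' A genotype table is a data frame with a `subject_id` column followed by
#' one integer column per SNP holding the minor-allele dose (0, 1, 2, or
#' `NA` for a failed call), plus per-SNP allele metadata kept as the
#' `"snp_meta"` attribute.
#'
#' @param doses Data frame or matrix of 0/1/2/NA doses, one column per SNP.
#' @param subject_ids Character or integer subject identifiers, unique.
#' @param snp_meta Optional data frame with columns `id`, `common_allele`,
#'   `rare_allele`; defaults to the dose column names with placeholder
#'   alleles.
#' @return A data frame of class `"genotype_table"`.
#' @export
genotype_table <- function(doses, subject_ids = NULL, snp_meta = NULL) {
  doses <- as.data.frame(doses)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(doses)))
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(subject_ids) != nrow(doses))
    stop("subject_ids and dose rows differ in length")
  for (j in seq_along(doses)) {
    v <- doses[[j]]
    if (!all(is.na(v) | v %in% 0:2))
      stop("dose values must be 0, 1, 2 or NA (column ", names(doses)[j], ")")
    doses[[j]] <- as.integer(v)
  }
  if (is.null(snp_meta))
    snp_meta <- data.frame(id = names(doses),
                           common_allele = rep("A", ncol(doses)),
                           rare_allele = rep("B", ncol(doses)),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "common_allele", "rare_allele") %in% names(snp_meta)),
            identical(snp_meta$id, names(doses)))
  out <- cbind(data.frame(subject_id = as.character(subject_ids),
                          stringsAsFactors = FALSE), doses)
  attr(out, "snp_meta") <- snp_meta
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d subjects x %d SNPs\n",
              nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' SNP identifiers of a genotype table
#' @param x A `genotype_table`.
#' @return Character vector of SNP column names.
#' @export
snp_ids <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  setdiff(names(x), "subject_id")
}

#' Extract the dose matrix of a genotype table
#' @param x A `genotype_table`.
#' @return Integer matrix (subjects x SNPs) of minor-allele doses.
#' @export
dose_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  m <- as.matrix(as.data.frame(x)[, snp_ids(x), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$subject_id
  m
}

#' Genotype counts (common hom, het, rare hom) for one SNP
#' @param doses Integer dose vector with values 0/1/2/NA.
#' @return Named integer vector `c(n_AA, n_Aa, n_aa)` over called genotypes.
#' @export
genotype_counts <- function(doses) {
  doses <- doses[!is.na(doses)]
  c(n_AA = sum(doses == 0L), n_Aa = sum(doses == 1L), n_aa = sum(doses == 2L))
}
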