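#' Genotype matrix container
#'
#' Holds a samples-by-SNPs matrix of biallelic genotype codes together with
#' SNP and sample identifiers and (optionally) per-SNP chromosome/position.
#' Codes are minor-allele dosages: 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous variant; -1 marks a missing genotype.
#'
#' @param genotypes integer matrix, n_samples x n_snps, entries in
#'   \{-1, 0, 1, 2\}.
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   column names or `snp1..snpP`).
#' @param sample_ids character vector of sample identifiers.
#' @param chrom optional per-SNP chromosome labels.
#' @param pos optional per-SNP base-pair positions.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `genotypes`, `snp_ids`, `sample_ids`, `chrom`, `pos`.
#' @export
geno_matrix <- function(genotypes, snp_ids = NULL, sample_ids = NULL,
                        chrom = NULL, pos = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !(genotypes %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) {
    stop("genotype codes must be in {-1, 0, 1, 2}; found ",
         paste(unique(genotypes[bad])[1:min(5, sum(bad))], collapse = ", "))
  }
  p <- ncol(genotypes); n <- nrow(genotypes)
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  snp_ids <- as.character(snp_ids); sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != p) stop("snp_ids length does not match ncol(genotypes)")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length does not match nrow(genotypes)")
  if (!is.null(chrom) && length(chrom) != p) stop("chrom length mismatch")
  if (!is.null(pos) && length(pos) != p) stop("pos length mismatch")
  dimnames(genotypes) <- list(sample_ids, snp_ids)
  structure(list(genotypes = genotypes, snp_ids = snp_ids,
                 sample_ids = sample_ids, chrom = chrom, pos = pos),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nm <- sum(x$genotypes == -1L)
  cat(sprintf("geno_matrix: %d samples x %d SNPs (%d missing calls, %.2f%%)\n",
              nrow(x$genotypes), ncol(x$genotypes), nm,
              100 * nm / max(1L, length(x$genotypes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix
#'
#' `g[i, j]` keeps samples `i` and SNPs `j`; either index may be numeric,
#' logical, or (for SNPs) a character vector of SNP ids. Metadata stays
#' aligned.
#'
#' @param x a [geno_matrix].
#' @param i sample index (missing = all).
#' @param j SNP index or SNP ids (missing = all).
#' @param ... ignored.
#' @return a [geno_matrix].
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  samples <- if (missing(i)) NULL else i
  snps <- if (missing(j)) NULL else j
  if (is.character(snps)) {
    snps <- match(snps, x$snp_ids)
    if (any(is.na(snps))) stop("unknown SNP id(s)")
  }
  if (is.logical(samples)) samples <- which(samples)
  if (is.logical(snps)) snps <- which(snps)
  subset_geno(x, samples = samples, snps = snps)
}

# subset a geno_matrix by sample rows and/or SNP columns (index vectors)
subset_geno <- function(g, samples = NULL, snps = NULL) {
  gm <- g$genotypes
  if (!is.null(samples)) gm <- gm[samples, , drop = FALSE]
  if (!is.null(snps)) gm <- gm[, snps, drop = FALSE]
  keep_snps <- if (is.null(snps)) seq_along(g$snp_ids) else snps
  geno_matrix(gm,
              snp_ids = g$snp_ids[keep_snps],
              sample_ids = if (is.null(samples)) g$sample_ids else g$sample_ids[samples],
              chrom = if (is.null(g$chrom)) NULL else g$chrom[keep_snps],
              pos = if (is.null(g$pos)) NULL else g$pos[keep_snps])
}

# validate a 0/1 phenotype against a geno_matrix; returns integer vector
check_phenotype <- function(phen, g = NULL, require_both = TRUE) {
  phen <- as.integer(phen)
  if (any(is.na(phen)) || !all(phen %in% c(0L, 1L)))
    stop("phenotype must be a binary 0/1 vector (1 = case)")
  if (!is.null(g) && length(phen) != nrow(g$genotypes))
    stop("phenotype length does not match number of samples")
  if (require_both && length(unique(phen)) < 2L)
    stop("both cases and controls must be present")
  phen
}
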