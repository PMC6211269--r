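#' Quality-control parameters
#'
#' Thresholds for the per-sample and per-marker QC steps. Defaults follow
#' common GWAS practice for a genotyping-array case-control study: samples
#' with more than 1% missing calls or outlying heterozygosity (beyond 3 SD)
#' are dropped; SNPs are dropped for call-rate below 95%, minor allele
#' frequency below 5%, or Hardy-Weinberg disequilibrium at p < 1e-4; then
#' SNPs in strong linkage disequilibrium (r^2 > 0.6 within a 2,000-SNP
#' window of retained markers) are pruned.
#'
#' Note on the HWE rule: the conventional (PLINK-style) direction is applied —
#' a SNP is *removed* when its HWE goodness-of-fit p-value falls *below*
#' `hwe_alpha`, i.e. when its genotype counts deviate significantly from
#' Hardy-Weinberg proportions, which flags genotyping error.
#'
#' @param sample_missing_max max per-sample missing proportion (default 0.01).
#' @param het_sd SD multiplier for heterozygosity outliers (default 3).
#' @param snp_missing_max max per-SNP missing proportion (default 0.05).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_alpha HWE chi-square p-value below which a SNP is removed
#'   (default 1e-4).
#' @param ld_r2_max r-squared above which the later SNP of a pair is pruned
#'   (default 0.6).
#' @param ld_window LD window size, in retained SNPs (default 2000).
#' @return list of class `qc_params`.
#' @export
qc_params <- function(sample_missing_max = 0.01, het_sd = 3,
                      snp_missing_max = 0.05, maf_min = 0.05,
                      hwe_alpha = 1e-4, ld_r2_max = 0.6, ld_window = 2000) {
  props <- c(sample_missing_max = sample_missing_max,
             snp_missing_max = snp_missing_max, maf_min = maf_min,
             hwe_alpha = hwe_alpha)
  if (any(props < 0 | props > 1))
    stop("proportions/thresholds must lie in [0, 1]")
  if (ld_r2_max < 0 || ld_r2_max > 1) stop("ld_r2_max must lie in [0, 1]")
  if (ld_window < 2) stop("ld_window must be >= 2")
  structure(list(sample_missing_max = sample_missing_max, het_sd = het_sd,
                 snp_missing_max = snp_missing_max, maf_min = maf_min,
                 hwe_alpha = hwe_alpha, ld_r2_max = ld_r2_max,
                 ld_window = as.integer(ld_window)),
            class = "qc_params")
}

#' Per-sample missing-genotype proportion
#'
#' @param g a [geno_matrix].
#' @return numeric vector, one proportion in \[0, 1\] per sample.
#' @export
sample_missingness <- function(g) {
  if (ncol(g$genotypes) < 1L) stop("need at least one SNP")
  unname(rowMeans(g$genotypes == -1L))
}

#' Heterozygosity-outlier samples
#'
#' Per-sample heterozygosity is the fraction of heterozygous calls among
#' non-missing genotypes. A sample is an outlier when its heterozygosity
#' deviates from the mean by more than `het_sd` sample standard deviations
#' (n-1 denominator). Samples with no non-missing genotypes are excluded
#' from the mean/SD and flagged.
#'
#' @param g a [geno_matrix].
#' @param het_sd SD multiplier (default 3).
#' @return logical vector flagging outlier samples.
#' @export
heterozygosity_outliers <- function(g, het_sd = 3) {
  gm <- g$genotypes
  if (nrow(gm) < 2L) stop("need at least 2 samples")
  nonmiss <- rowSums(gm != -1L)
  het <- rowSums(gm == 1L) / nonmiss  # NaN where nonmiss == 0
  usable <- nonmiss > 0L
  out <- !usable  # all-missing samples are flagged
  h <- het[usable]
  mu <- mean(h); sdev <- stats::sd(h)
  if (is.finite(sdev) && sdev > 0)
    out[usable] <- abs(h - mu) > het_sd * sdev
  unname(out)
}

# per-SNP missing proportion
snp_missingness <- function(g) unname(colMeans(g$genotypes == -1L))

# per-SNP minor allele frequency on non-missing genotypes
snp_maf <- function(g) {
  gm <- g$genotypes
  nonmiss <- colSums(gm != -1L)
  dose <- colSums(gm * (gm != -1L))  # -1 entries contribute 0
  p <- ifelse(nonmiss > 0, dose / (2 * nonmiss), NA_real_)
  unname(pmin(p, 1 - p))
}

#' SNP filters: call rate and minor allele frequency
#'
#' @param g a [geno_matrix].
#' @param params a [qc_params] object.
#' @return integer vector of surviving SNP column indices.
#' @export
snp_missingness_filter <- function(g, params = qc_params()) {
  which(snp_missingness(g) <= params$snp_missing_max)
}

#' @rdname snp_missingness_filter
#' @export
maf_filter <- function(g, params = qc_params()) {
  maf <- snp_maf(g)
  which(!is.na(maf) & maf >= params$maf_min)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts (n0, n1, n2) against the Hardy-Weinberg expectations
#' n * (p^2, 2pq, q^2), with the allele frequency p estimated from the counts.
#' Monomorphic SNPs return p-value 1 by convention.
#'
#' @param counts integer vector `c(n0, n1, n2)` of genotype counts.
#' @return the chi-square p-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0)) stop("counts must be (n0, n1, n2) >= 0")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotype")
  p <- (counts[2] + 2 * counts[3]) / (2 * n)  # frequency of the counted allele
  if (p == 0 || p == 1) return(1.0)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((counts - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# HWE chi-square statistic (used by hwe_test and reports)
hwe_chisq <- function(counts) {
  n <- sum(counts)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) return(0)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum((counts - expd)^2 / expd)
}

hwe_filter <- function(g, params = qc_params()) {
  gm <- g$genotypes
  keep <- vapply(seq_len(ncol(gm)), function(j) {
    x <- gm[, j]; x <- x[x != -1L]
    if (length(x) == 0L) return(FALSE)
    cnt <- tabulate(x + 1L, 3L)
    hwe_test(cnt) >= params$hwe_alpha
  }, logical(1))
  which(keep)
}

#' Squared correlation between two genotype columns
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples; defined as 0 when either column is constant or fewer than two
#' complete pairs exist.
#'
#' @param x,y genotype code vectors (-1 = missing).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  ok <- x != -1L & y != -1L
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)^2
}

#' Greedy window-based LD pruning
#'
#' Scans SNPs left to right (input order; order input by chromosome and
#' position beforehand when available). A SNP is removed when its r-squared
#' with any already-retained SNP among the previous `ld_window` retained
#' markers on the same chromosome exceeds `ld_r2_max`. Deterministic for a
#' fixed input order; the first SNP of a correlated block is kept.
#'
#' @param g a [geno_matrix].
#' @param params a [qc_params] object.
#' @return integer vector of surviving SNP column indices.
#' @export
ld_prune <- function(g, params = qc_params()) {
  gm <- g$genotypes
  p <- ncol(gm)
  chrom <- if (is.null(g$chrom)) rep("1", p) else as.character(g$chrom)
  kept <- integer(0)
  for (j in seq_len(p)) {
    window <- kept[chrom[kept] == chrom[j]]
    if (length(window) > params$ld_window)
      window <- utils::tail(window, params$ld_window)
    pruned <- FALSE
    for (i in rev(window)) {  # nearest retained SNPs first
      if (ld_r2(gm[, i], gm[, j]) > params$ld_r2_max) { pruned <- TRUE; break }
    }
    if (!pruned) kept <- c(kept, j)
  }
  kept
}

#' Mode imputation of missing genotypes
#'
#' Replaces each missing call with that SNP's most frequent genotype code;
#' ties break toward the smaller code. Non-missing genotypes are never
#' altered.
#'
#' @param g a [geno_matrix].
#' @return a [geno_matrix] with no missing codes.
#' @export
impute_mode <- function(g) {
  gm <- g$genotypes
  for (j in seq_len(ncol(gm))) {
    miss <- gm[, j] == -1L
    if (!any(miss)) next
    obs <- gm[!miss, j]
    if (length(obs) == 0L)
      stop("SNP ", g$snp_ids[j],
           " has no observed genotypes; filter all-missing SNPs before imputing")
    cnt <- tabulate(obs + 1L, 3L)
    gm[miss, j] <- which.max(cnt) - 1L  # which.max takes the first (smaller) tie
  }
  g$genotypes <- gm
  g
}

#' Run the full QC pipeline
#'
#' Applies, in order: per-sample filters (missingness, heterozygosity
#' outliers), per-marker filters (missingness, MAF, HWE), windowed LD
#' pruning, and mode imputation. The returned report accounts for every
#' removal.
#'
#' @param g a [geno_matrix].
#' @param phen binary phenotype (1 = case).
#' @param params a [qc_params] object.
#' @return list with `genotypes` (imputed, filtered [geno_matrix]),
#'   `phenotype`, and `report` (class `qc_report`).
#' @export
run_qc <- function(g, phen, params = qc_params()) {
  phen <- check_phenotype(phen, g)
  n0 <- nrow(g$genotypes); p0 <- ncol(g$genotypes)

  sm <- sample_missingness(g)
  keep_s <- sm <= params$sample_missing_max
  n_smiss <- sum(!keep_s)
  g1 <- subset_geno(g, samples = which(keep_s))
  phen1 <- phen[keep_s]
  if (nrow(g1$genotypes) == 0L) stop("QC removed every sample (missingness)")

  het_out <- heterozygosity_outliers(g1, params$het_sd)
  n_het <- sum(het_out)
  g2 <- subset_geno(g1, samples = which(!het_out))
  phen2 <- phen1[!het_out]
  if (nrow(g2$genotypes) == 0L) stop("QC removed every sample (heterozygosity)")
  if (length(unique(phen2)) < 2L)
    stop("phenotype became single-class after sample QC")

  keep1 <- snp_missingness_filter(g2, params)
  n_gmiss <- ncol(g2$genotypes) - length(keep1)
  g3 <- subset_geno(g2, snps = keep1)

  keep2 <- maf_filter(g3, params)
  n_maf <- ncol(g3$genotypes) - length(keep2)
  g4 <- subset_geno(g3, snps = keep2)

  keep3 <- hwe_filter(g4, params)
  n_hwe <- ncol(g4$genotypes) - length(keep3)
  g5 <- subset_geno(g4, snps = keep3)

  keep4 <- ld_prune(g5, params)
  n_ld <- ncol(g5$genotypes) - length(keep4)
  g6 <- subset_geno(g5, snps = keep4)
  if (ncol(g6$genotypes) == 0L) stop("QC removed every SNP")

  n_imputed <- sum(g6$genotypes == -1L)
  g7 <- impute_mode(g6)

  report <- structure(list(
    params = params,
    samples_in = n0, snps_in = p0,
    removed = c(sample_missingness = n_smiss,
                heterozygosity_outlier = n_het,
                snp_missingness = n_gmiss,
                snp_maf = n_maf,
                snp_hwe = n_hwe,
                snp_ld = n_ld),
    genotypes_imputed = n_imputed,
    samples_out = nrow(g7$genotypes), snps_out = ncol(g7$genotypes)),
    class = "qc_report")
  list(genotypes = g7, phenotype = phen2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d x %d -> %d x %d (samples x SNPs)\n",
              x$samples_in, x$snps_in, x$samples_out, x$snps_out))
  rm <- x$removed
  for (k in names(rm)) cat(sprintf("  removed by %-24s %d\n", paste0(k, ":"), rm[[k]]))
  cat(sprintf("  genotypes imputed:          %d\n", x$genotypes_imputed))
  invisible(x)
}

#' Serialize / read a QC report as flat key-value text
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  p <- report$params
  kv <- c(
    sprintf("samples_in\t%d", report$samples_in),
    sprintf("snps_in\t%d", report$snps_in),
    sprintf("removed_%s\t%d", names(report$removed), report$removed),
    sprintf("genotypes_imputed\t%d", report$genotypes_imputed),
    sprintf("samples_out\t%d", report$samples_out),
    sprintf("snps_out\t%d", report$snps_out),
    sprintf("param_%s\t%s", names(unclass(p)), vapply(unclass(p), format, "")))
  writeLines(kv, path)
  invisible(path)
}

#' Per-SNP chi-square association test
#'
#' Chi-square test of independence on the genotype-by-status contingency
#' table of each SNP, with degrees of freedom (observed genotype classes - 1).
#' Monomorphic SNPs get p = 1. Requires an imputed (no-missing) matrix.
#'
#' @param g an imputed [geno_matrix].
#' @param phen binary phenotype (1 = case).
#' @return data.frame with columns `snp_id`, `chisq`, `df`, `p_value`.
#' @export
single_snp_association <- function(g, phen) {
  phen <- check_phenotype(phen, g)
  gm <- g$genotypes
  if (any(gm == -1L)) stop("impute missing genotypes before association testing")
  res <- t(vapply(seq_len(ncol(gm)), function(j) {
    chisq_assoc(table3x2(gm[, j], phen))
  }, c(chisq = 0, df = 0, p_value = 0)))
  data.frame(snp_id = g$snp_ids, chisq = res[, 1], df = res[, 2],
             p_value = res[, 3], row.names = NULL)
}

# genotype (rows 0/1/2) x status (cols 0/1) count table
table3x2 <- function(geno, phen) {
  matrix(tabulate(geno + 1L + 3L * phen, 6L), nrow = 3L)
}

# chi-square independence test on a genotype x status table, dropping
# empty genotype rows; df = (observed classes - 1) * 1
chisq_assoc <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0))
    return(c(chisq = 0, df = 0, p_value = 1))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1L)
  c(chisq = stat, df = df,
    p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
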