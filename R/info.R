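# Plug-in (maximum-likelihood) entropies and information-gain decompositions
# on genotype/phenotype contingency tables. Empty cells contribute 0
# (0 log 0 = 0); no pseudo-counts or bias correction.

#' Shannon entropy in bits
#'
#' Plug-in entropy of a discrete distribution given as probabilities or
#' non-negative counts (counts are normalized).
#'
#' @param p numeric vector (or matrix) of probabilities or counts.
#' @return entropy in bits.
#' @export
entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("negative mass")
  s <- sum(p)
  if (s <= 0) stop("all-zero distribution")
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

# entropy of a raw count vector/matrix, no validation (hot path)
.H <- function(cnt) {
  p <- cnt[cnt > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Mutual information of a genotype-state x disease-status table
#'
#' I(X; D) = H(X) + H(D) - H(X, D) over the plug-in joint distribution,
#' where X is the (possibly joint, 3^k-state) genotype variable and D the
#' binary disease status. Bounded by 0 <= I <= min(H(X), H(D)).
#'
#' @param counts a (3^k) x 2 matrix of non-negative counts (rows = genotype
#'   combinations, columns = control/case).
#' @return mutual information in bits.
#' @export
mutual_info <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid contingency table")
  .H(rowSums(counts)) + .H(colSums(counts)) - .H(counts)
}

# --- internal decompositions on fixed joint-genotype indices ---------------

# marginal grouping vectors for 9-state (pair) and 27-state (trio) variables;
# locus A varies fastest
.MAP9_A <- rep(0:2, 3)
.MAP9_B <- rep(0:2, each = 3)
.MAP27_A <- rep(0:2, 9)
.MAP27_B <- rep(rep(0:2, each = 3), 3)
.MAP27_C <- rep(0:2, each = 9)

# I(grouped X; D) from a states x 2 count matrix and a grouping of its rows
.mi_grouped <- function(M, grp, HD) {
  Mf <- rowsum(M, grp)
  .H(rowSums(Mf)) + HD - .H(Mf)
}

# two-locus decomposition from the 9-state joint index (0..8) and phenotype
.info2 <- function(jidx, phen) {
  M <- matrix(tabulate(1L + jidx + 9L * phen, 18L), 9L, 2L)
  HD <- .H(colSums(M))
  I_ab <- .H(rowSums(M)) + HD - .H(M)
  I_a <- .mi_grouped(M, .MAP9_A, HD)
  I_b <- .mi_grouped(M, .MAP9_B, HD)
  c(HD = HD, I_a = I_a, I_b = I_b, gain = I_ab - I_a - I_b)
}

# three-locus decomposition from the 27-state joint index (0..26)
.info3 <- function(jidx, phen) {
  M <- matrix(tabulate(1L + jidx + 27L * phen, 54L), 27L, 2L)
  HD <- .H(colSums(M))
  I_abc <- .H(rowSums(M)) + HD - .H(M)
  I_a <- .mi_grouped(M, .MAP27_A, HD)
  I_b <- .mi_grouped(M, .MAP27_B, HD)
  I_c <- .mi_grouped(M, .MAP27_C, HD)
  I_ab <- .mi_grouped(M, .MAP27_A + 3L * .MAP27_B, HD)
  I_ac <- .mi_grouped(M, .MAP27_A + 3L * .MAP27_C, HD)
  I_bc <- .mi_grouped(M, .MAP27_B + 3L * .MAP27_C, HD)
  ig_ab <- I_ab - I_a - I_b
  ig_ac <- I_ac - I_a - I_c
  ig_bc <- I_bc - I_b - I_c
  c(HD = HD, I_a = I_a, I_b = I_b, I_c = I_c,
    ig_ab = ig_ab, ig_ac = ig_ac, ig_bc = ig_bc,
    I_abc = I_abc,
    gain = I_abc - (ig_ab + ig_ac + ig_bc) - (I_a + I_b + I_c))
}

.check_geno_col <- function(x, nm) {
  if (any(x == -1L)) stop("impute missing genotypes first (", nm, ")")
  if (!all(x %in% 0:2)) stop("genotype codes must be 0/1/2 (", nm, ")")
  as.integer(x)
}

.new_interaction_result <- function(snp_ids, main_effects, pair_gains,
                                    gain, HD, p_value = NA_real_,
                                    p_value_add1 = NA_real_,
                                    n_permutations = 0L) {
  structure(list(snp_ids = snp_ids, main_effects = main_effects,
                 pair_gains = pair_gains, gain = gain,
                 gain_pct = 100 * gain / HD, h_d = HD,
                 p_value = p_value, p_value_add1 = p_value_add1,
                 n_permutations = n_permutations),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction: %s\n", paste(x$snp_ids, collapse = " x ")))
  cat(sprintf("  information gain: %.6f bits (%.3f%% of H(D) = %.4f bits)\n",
              x$gain, x$gain_pct, x$h_d))
  cat("  main effects (bits): ",
      paste(sprintf("%.6f", x$main_effects), collapse = ", "), "\n", sep = "")
  if (!is.null(x$pair_gains))
    cat("  pairwise gains (bits): ",
        paste(sprintf("%.6f", x$pair_gains), collapse = ", "), "\n", sep = "")
  if (x$n_permutations > 0) {
    pv <- if (x$p_value == 0) sprintf("< %.4g", 1 / x$n_permutations)
          else sprintf("= %.4g", x$p_value)
    cat(sprintf("  permutation p %s (%d permutations)\n", pv, x$n_permutations))
  }
  invisible(x)
}

#' Two-way information gain
#'
#' The synergistic component of the association between a SNP pair (A, B)
#' and disease status D: `IG(A;B;D) = I(AB; D) - I(A; D) - I(B; D)`, where
#' AB is the 9-state joint genotype variable. Positive gain means the pair
#' carries information about D beyond the sum of its main effects; negative
#' gain indicates redundancy. `gain_pct` rescales to percent of the
#' phenotype entropy H(D) (equal to bits x 100 for a balanced design).
#'
#' @param gA,gB imputed genotype code vectors (0/1/2).
#' @param phen binary phenotype (1 = case).
#' @param snp_ids optional length-2 ids for labelling.
#' @return an `interaction_result` with main effects, gain in bits,
#'   `gain_pct`, and (unset) permutation fields.
#' @export
info_gain_2 <- function(gA, gB, phen, snp_ids = c("A", "B")) {
  gA <- .check_geno_col(gA, "A"); gB <- .check_geno_col(gB, "B")
  phen <- check_phenotype(phen)
  if (length(gA) != length(phen) || length(gB) != length(phen))
    stop("column lengths must match phenotype")
  st <- .info2(gA + 3L * gB, phen)
  .new_interaction_result(snp_ids, main_effects = st[c("I_a", "I_b")],
                          pair_gains = NULL, gain = unname(st["gain"]),
                          HD = unname(st["HD"]))
}

#' Three-way information gain
#'
#' Pure three-way synergy of a SNP trio on the disease status:
#' `IG(A;B;C;D) = I(ABC; D) - [IG(A;B;D) + IG(A;C;D) + IG(B;C;D)]
#'  - [I(A;D) + I(B;D) + I(C;D)]` with ABC the 27-state joint variable.
#' All component terms are carried in the result.
#'
#' @param gA,gB,gC imputed genotype code vectors (0/1/2).
#' @inheritParams info_gain_2
#' @return an `interaction_result` with `main_effects` (3), `pair_gains`
#'   (3: AB, AC, BC), `gain` and `gain_pct`.
#' @export
info_gain_3 <- function(gA, gB, gC, phen, snp_ids = c("A", "B", "C")) {
  gA <- .check_geno_col(gA, "A"); gB <- .check_geno_col(gB, "B")
  gC <- .check_geno_col(gC, "C")
  phen <- check_phenotype(phen)
  if (length(gA) != length(phen) || length(gB) != length(phen) ||
      length(gC) != length(phen))
    stop("column lengths must match phenotype")
  st <- .info3(gA + 3L * gB + 9L * gC, phen)
  .new_interaction_result(snp_ids,
                          main_effects = st[c("I_a", "I_b", "I_c")],
                          pair_gains = st[c("ig_ab", "ig_ac", "ig_bc")],
                          gain = unname(st["gain"]), HD = unname(st["HD"]))
}

#' Permutation-test configuration
#'
#' @param n_permutations number of label shuffles (default 1000).
#' @param seed integer seed for the shuffle stream.
#' @return list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 1000, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "perm_config")
}

#' Permutation significance test
#'
#' Shuffles the phenotype labels `n_permutations` times and recomputes the
#' statistic on each shuffle. The p-value counts permuted statistics
#' *strictly greater* than the observed one, divided by the number of
#' permutations; a p-value of 0 therefore means "below 1/n_permutations".
#' The add-one-corrected p-value `(b + 1) / (N + 1)` is returned alongside,
#' since a literal zero is statistically improper.
#'
#' @param statistic function taking a phenotype vector and returning a
#'   scalar (larger = stronger signal).
#' @param phen binary phenotype vector.
#' @param cfg a [perm_config].
#' @return list with `observed`, `p_value` (strict-greater), `p_value_add1`,
#'   `null` (the permuted statistics), `n_permutations`.
#' @export
permutation_test <- function(statistic, phen, cfg = perm_config()) {
  phen <- check_phenotype(phen)
  observed <- statistic(phen)
  null <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations),
           function(b) statistic(sample(phen)), numeric(1))
  })
  b <- sum(null > observed)
  list(observed = observed,
       p_value = b / cfg$n_permutations,
       p_value_add1 = (b + 1) / (cfg$n_permutations + 1),
       null = null, n_permutations = cfg$n_permutations)
}

# fast strict-greater permutation p for a precomputed joint index;
# order k = 2 or 3. Returns c(p, p_add1).
.perm_p_joint <- function(jidx, phen, observed, order_k, cfg) {
  fn <- if (order_k == 2L) .info2 else .info3
  b <- with_seed(cfg$seed, {
    cnt <- 0L
    for (r in seq_len(cfg$n_permutations)) {
      if (fn(jidx, sample(phen))[["gain"]] > observed) cnt <- cnt + 1L
    }
    cnt
  })
  c(b / cfg$n_permutations, (b + 1) / (cfg$n_permutations + 1))
}

#' Exhaustive pairwise interaction scan
#'
#' Evaluates the two-way information gain of every SNP pair in `g`, with a
#' per-pair permutation test (fresh label shuffles per pair, seeded from
#' `cfg$seed` and the pair indices). Results are sorted by gain, largest
#' first; the complete list is returned (any p-value filtering is left to
#' presentation).
#'
#' @param g an imputed [geno_matrix] of the selected SNPs (m >= 2).
#' @param phen binary phenotype (1 = case).
#' @param cfg a [perm_config]; set `n_permutations = 0` via `perms` to skip
#'   testing.
#' @param perms number of permutations per pair (default `cfg$n_permutations`;
#'   0 skips the permutation test and leaves p-values `NA`).
#' @return data.frame of class `interaction_scan` with one row per pair.
#' @export
pairwise_scan <- function(g, phen, cfg = perm_config(), perms = cfg$n_permutations) {
  phen <- check_phenotype(phen, g)
  gm <- g$genotypes
  m <- ncol(gm)
  if (m < 2L) stop("need at least 2 SNPs")
  if (any(gm == -1L)) stop("impute missing genotypes before scanning")
  pairs <- utils::combn(m, 2L)
  res <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    jidx <- gm[, i] + 3L * gm[, j]
    st <- .info2(jidx, phen)
    pv <- c(NA_real_, NA_real_)
    if (perms > 0) {
      pcfg <- perm_config(perms, derive_seed(cfg$seed, "pair", i, j))
      pv <- .perm_p_joint(jidx, phen, st[["gain"]], 2L, pcfg)
    }
    res[[q]] <- data.frame(
      snp_a = g$snp_ids[i], snp_b = g$snp_ids[j],
      mi_a = st[["I_a"]], mi_b = st[["I_b"]],
      gain_bits = st[["gain"]], gain_pct = 100 * st[["gain"]] / st[["HD"]],
      p_value = pv[1], p_value_add1 = pv[2],
      n_permutations = if (perms > 0) as.integer(perms) else 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$gain_bits), ]
  rownames(out) <- NULL
  class(out) <- c("interaction_scan", "data.frame")
  attr(out, "order_k") <- 2L
  out
}

#' Exhaustive three-way interaction scan
#'
#' As [pairwise_scan()] but over every SNP trio, ranking by the pure
#' three-way information gain.
#'
#' @inheritParams pairwise_scan
#' @return data.frame of class `interaction_scan` with one row per trio.
#' @export
threeway_scan <- function(g, phen, cfg = perm_config(), perms = cfg$n_permutations) {
  phen <- check_phenotype(phen, g)
  gm <- g$genotypes
  m <- ncol(gm)
  if (m < 3L) stop("need at least 3 SNPs")
  if (any(gm == -1L)) stop("impute missing genotypes before scanning")
  trios <- utils::combn(m, 3L)
  res <- vector("list", ncol(trios))
  for (q in seq_len(ncol(trios))) {
    i <- trios[1, q]; j <- trios[2, q]; l <- trios[3, q]
    jidx <- gm[, i] + 3L * gm[, j] + 9L * gm[, l]
    st <- .info3(jidx, phen)
    pv <- c(NA_real_, NA_real_)
    if (perms > 0) {
      pcfg <- perm_config(perms, derive_seed(cfg$seed, "trio", i, j, l))
      pv <- .perm_p_joint(jidx, phen, st[["gain"]], 3L, pcfg)
    }
    res[[q]] <- data.frame(
      snp_a = g$snp_ids[i], snp_b = g$snp_ids[j], snp_c = g$snp_ids[l],
      mi_a = st[["I_a"]], mi_b = st[["I_b"]], mi_c = st[["I_c"]],
      gain_ab = st[["ig_ab"]], gain_ac = st[["ig_ac"]], gain_bc = st[["ig_bc"]],
      gain_bits = st[["gain"]], gain_pct = 100 * st[["gain"]] / st[["HD"]],
      p_value = pv[1], p_value_add1 = pv[2],
      n_permutations = if (perms > 0) as.integer(perms) else 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$gain_bits), ]
  rownames(out) <- NULL
  class(out) <- c("interaction_scan", "data.frame")
  attr(out, "order_k") <- 3L
  out
}

#' @export
print.interaction_scan <- function(x, n = 10, ...) {
  k <- attr(x, "order_k")
  cat(sprintf("%s interaction scan: %d %s; top %d by information gain:\n",
              if (identical(k, 3L)) "three-way" else "pairwise", nrow(x),
              if (identical(k, 3L)) "trios" else "pairs", min(n, nrow(x))))
  cols <- intersect(c("snp_a", "snp_b", "snp_c", "gain_bits", "gain_pct",
                      "p_value"), names(x))
  print.data.frame(utils::head(x[, cols], n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an interaction scan as TSV
#' @param x an `interaction_scan`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
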