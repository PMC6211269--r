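#' Per-SNP importance table
#'
#' A data frame of per-SNP scores from one ranking method, with columns
#' `snp_id`, `score`, `rank` (1 = best, ties share the minimum rank) and
#' `method`.
#'
#' @param snp_ids character vector of SNP ids.
#' @param scores finite numeric scores, one per SNP.
#' @param method method tag (e.g. `"turf"`, `"rf_gini"`, `"gbm"`).
#' @return data.frame of class `importance_table`.
#' @export
importance_table <- function(snp_ids, scores, method = "unknown") {
  if (length(snp_ids) != length(scores)) stop("ids and scores must align")
  if (any(!is.finite(scores))) stop("scores must be finite")
  out <- data.frame(snp_id = as.character(snp_ids), score = as.numeric(scores),
                    rank = rank(-scores, ties.method = "min"),
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, n = 10, ...) {
  cat(sprintf("importance_table (%s): %d SNPs; top %d:\n",
              x$method[1], nrow(x), min(n, nrow(x))))
  ord <- order(x$rank, x$snp_id)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' Write / read an importance table as TSV
#' @param t an [importance_table].
#' @param path file path.
#' @return the path (write) or an [importance_table] (read).
#' @export
write_importance <- function(t, path) {
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_importance
#' @export
read_importance <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  importance_table(df$snp_id, df$score, method = df$method[1])
}

#' ReliefF parameters
#'
#' @param k_neighbors nearest hits/misses per reference sample (default 10).
#' @param turf_iterations TuRF rounds (default 10).
#' @param turf_drop_fraction fraction of surviving SNPs removed per round
#'   (default 0.1).
#' @param sd_multiplier multiplier for the mean + k*SD selection threshold
#'   (default 3).
#' @param diff genotype difference for the weight update: `"match"` treats
#'   genotypes as categories (0/1 mismatch); `"dosage"` uses |g1 - g2| / 2.
#' @return list of class `relief_params`.
#' @export
relief_params <- function(k_neighbors = 10, turf_iterations = 10,
                          turf_drop_fraction = 0.1, sd_multiplier = 3,
                          diff = c("match", "dosage")) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (turf_drop_fraction <= 0 || turf_drop_fraction >= 1)
    stop("turf_drop_fraction must lie in (0, 1)")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 turf_iterations = as.integer(turf_iterations),
                 turf_drop_fraction = turf_drop_fraction,
                 sd_multiplier = sd_multiplier, diff = match.arg(diff)),
            class = "relief_params")
}

#' ReliefF attribute weights
#'
#' For every sample (all n samples serve as reference instances), the k
#' nearest same-class samples (hits) and k nearest other-class samples
#' (misses) are found under Manhattan distance on genotype codes, with
#' distance ties broken by sample index. Each attribute's weight is
#' decreased by diff(attribute, sample, hit) / (n * k) per hit and increased
#' by diff(attribute, sample, miss) / (n * k) per miss, where diff is the
#' 0/1 genotype mismatch (or scaled dosage difference, see [relief_params]).
#' Weights lie in \[-1, 1\]; attributes that separate classes through
#' interactions accumulate positive weight even without marginal effects.
#'
#' @param g an imputed [geno_matrix].
#' @param phen binary phenotype (1 = case).
#' @param params a [relief_params].
#' @return an [importance_table] (method `"relieff"`).
#' @export
relieff_scores <- function(g, phen, params = relief_params()) {
  phen <- check_phenotype(phen, g)
  gm <- g$genotypes
  if (any(gm == -1L)) stop("impute missing genotypes before ReliefF")
  n <- nrow(gm); p <- ncol(gm)
  k <- params$k_neighbors
  min_class <- min(table(phen))
  if (min_class <= k) {
    k <- min_class - 1L
    warning("k_neighbors reduced to ", k, " (smallest class has ",
            min_class, " samples)")
    if (k < 1L) stop("smallest class too small for ReliefF")
  }
  D <- as.matrix(stats::dist(gm, method = "manhattan"))
  idx_case <- which(phen == 1L); idx_ctrl <- which(phen == 0L)
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- if (phen[i] == 1L) idx_case else idx_ctrl
    same <- same[same != i]
    other <- if (phen[i] == 1L) idx_ctrl else idx_case
    hits <- same[order(D[i, same])][seq_len(k)]      # order() is stable:
    misses <- other[order(D[i, other])][seq_len(k)]  # ties fall to lower index
    gi <- gm[i, ]
    if (params$diff == "match") {
      dh <- colSums(gm[hits, , drop = FALSE] != rep(gi, each = k))
      dm <- colSums(gm[misses, , drop = FALSE] != rep(gi, each = k))
    } else {
      dh <- colSums(abs(gm[hits, , drop = FALSE] - rep(gi, each = k))) / 2
      dm <- colSums(abs(gm[misses, , drop = FALSE] - rep(gi, each = k))) / 2
    }
    w <- w + (dm - dh)
  }
  importance_table(g$snp_ids, w / (n * k), method = "relieff")
}

#' TuRF: iterated ReliefF with worst-feature removal
#'
#' Runs ReliefF `turf_iterations` times; after each round the
#' `floor(turf_drop_fraction * current count)` (at least one, so every round
#' makes progress) lowest-scoring SNPs are removed, with score ties broken
#' by input order (earlier column dropped first). Iteration stops early
#' (with a warning) if a further removal would empty the SNP set. In the
#' returned table, survivors carry their final-round ReliefF score; removed
#' SNPs get rank-preserving scores strictly below every survivor, ordered by
#' removal round and, within a round, by their score at removal.
#'
#' @inheritParams relieff_scores
#' @return an [importance_table] (method `"turf"`).
#' @export
turf_scores <- function(g, phen, params = relief_params()) {
  phen <- check_phenotype(phen, g)
  alive <- seq_len(ncol(g$genotypes))
  removed_idx <- integer(0); removed_round <- integer(0); removed_score <- numeric(0)
  last_scores <- NULL
  for (it in seq_len(params$turf_iterations)) {
    sc <- relieff_scores(subset_geno(g, snps = alive), phen, params)
    last_scores <- sc$score
    ndrop <- max(1L, floor(params$turf_drop_fraction * length(alive)))
    if (ndrop >= length(alive)) {
      warning("TuRF stopped early at round ", it,
              ": removal would empty the SNP set")
      break
    }
    ord <- order(sc$score, seq_along(alive))  # lowest first, ties by input order
    drop_local <- ord[seq_len(ndrop)]
    removed_idx <- c(removed_idx, alive[drop_local])
    removed_round <- c(removed_round, rep(it, ndrop))
    removed_score <- c(removed_score, sc$score[drop_local])
    alive <- alive[-drop_local]
    last_scores <- last_scores[-drop_local]
  }
  scores <- numeric(ncol(g$genotypes))
  scores[alive] <- last_scores
  if (length(removed_idx)) {
    base <- min(last_scores)
    eps <- 1e-9 * max(1, abs(base))
    # order worst-first: earliest round, then lowest score within round
    ordr <- order(removed_round, removed_score, seq_along(removed_idx))
    nrem <- length(removed_idx)
    scores[removed_idx[ordr]] <- base - eps * (nrem:1)
  }
  out <- importance_table(g$snp_ids, scores, method = "turf")
  attr(out, "survivors") <- g$snp_ids[alive]
  out
}

#' Mean + k*SD importance threshold
#'
#' Selects the SNPs whose score lies strictly above
#' `mean(scores) + sd_multiplier * sd(scores)` (sample SD, n-1 denominator) —
#' the upper-tail cut used to carve a manageable candidate subset out of a
#' genome-wide importance distribution.
#'
#' @param t an [importance_table] with at least 2 scores.
#' @param sd_multiplier threshold multiplier (default 3).
#' @return character vector of selected SNP ids (score order, best first).
#' @export
mean_sd_threshold <- function(t, sd_multiplier = 3) {
  if (nrow(t) < 2L) stop("need at least 2 scores")
  sdev <- stats::sd(t$score)
  if (sdev == 0) {
    warning("all scores identical; empty selection")
    return(character(0))
  }
  cut <- mean(t$score) + sd_multiplier * sdev
  sel <- t[t$score > cut, ]
  sel$snp_id[order(-sel$score)]
}
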