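#' Stratified k-fold partition
#'
#' Splits samples into `k` disjoint test folds preserving case/control
#' proportions to within one sample per fold. Samples are shuffled within
#' class under the seed, then dealt round-robin; deterministic for a fixed
#' seed.
#'
#' @param phen binary phenotype vector.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of `k` integer index vectors (test sets).
#' @export
stratified_kfold <- function(phen, k = 10, seed = 1) {
  phen <- check_phenotype(phen)
  if (any(table(phen) < k))
    stop("each class must have at least k = ", k, " samples")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(phen == cls))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[seq(f, length(idx), by = k)])
      }
    }
  })
  lapply(folds, sort)
}

#' Repeated cross-validated fitting
#'
#' For each of `k` stratified test folds, the adapter is fitted `repeats`
#' times on the complementary training data with distinct derived seeds.
#' Every test sample thus receives `repeats` predictions; its accuracy
#' entry is the fraction of those that are correct (threshold 0.5 on the
#' predicted case probability), and its probability entry is their mean.
#' Per-fit importance vectors are collected for [aggregate_importance()].
#'
#' @param g a [geno_matrix] (imputed) or numeric matrix.
#' @param phen binary phenotype (1 = case).
#' @param adapter a [learner_adapter].
#' @param params one grid cell: named list/row of learner parameters.
#' @param k folds (default 10).
#' @param repeats fits per fold (default 10).
#' @param seed master seed; per-fit seeds are derived from (seed, fold,
#'   repeat, params).
#' @return list with `per_sample_accuracy` (fractions on the 1/repeats
#'   grid), `per_sample_prob` (mean case probability), `importances`
#'   (list of k*repeats vectors), `folds`.
#' @export
repeated_cv <- function(g, phen, adapter, params, k = 10, repeats = 10,
                        seed = 1) {
  x <- if (inherits(g, "geno_matrix")) g$genotypes else as.matrix(g)
  phen <- check_phenotype(phen)
  if (length(phen) != nrow(x)) stop("phenotype length mismatch")
  params <- as.list(params)
  phash <- paste(names(params), vapply(params, format, ""), collapse = ";")
  folds <- stratified_kfold(phen, k = k, seed = derive_seed(seed, "folds", phash))
  n <- nrow(x)
  correct <- numeric(n); prob_sum <- numeric(n)
  importances <- vector("list", k * repeats)
  fit_id <- 0L
  for (f in seq_len(k)) {
    test <- folds[[f]]; train <- setdiff(seq_len(n), test)
    for (r in seq_len(repeats)) {
      fit_id <- fit_id + 1L
      s <- derive_seed(seed, "fit", phash, f, r)
      model <- tryCatch(
        adapter$fit(x[train, , drop = FALSE], phen[train], params, s),
        error = function(e) stop("adapter '", adapter$name,
                                 "' failed at fold ", f, ", repeat ", r,
                                 ": ", conditionMessage(e)))
      pr <- adapter$predict(model, x[test, , drop = FALSE])
      pred <- as.integer(pr >= 0.5)
      correct[test] <- correct[test] + (pred == phen[test])
      prob_sum[test] <- prob_sum[test] + pr
      importances[[fit_id]] <- adapter$importance(model)
    }
  }
  list(per_sample_accuracy = correct / repeats,
       per_sample_prob = prob_sum / repeats,
       importances = importances, folds = folds)
}

#' CV accuracy and AUC
#'
#' `average_cv_accuracy` is the mean of the per-sample correct fractions.
#' `cv_auc` is the rank-based (Mann-Whitney) area under the ROC curve of
#' the pooled per-sample mean case probabilities against the labels, with
#' midranks for ties.
#'
#' @param fractions per-sample correct fractions from [repeated_cv()].
#' @return scalar in \[0, 1\].
#' @export
average_cv_accuracy <- function(fractions) {
  if (any(!is.finite(fractions))) stop("non-finite accuracy fractions")
  mean(fractions)
}

#' @rdname average_cv_accuracy
#' @param probs per-sample mean case probabilities.
#' @param phen binary phenotype (1 = case).
#' @export
cv_auc <- function(probs, phen) {
  phen <- check_phenotype(phen)
  if (length(probs) != length(phen)) stop("length mismatch")
  n1 <- sum(phen == 1L); n0 <- sum(phen == 0L)
  r <- rank(probs)  # midranks for ties
  (sum(r[phen == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grid tuning by repeated cross-validation
#'
#' Evaluates every grid cell with [repeated_cv()] and reports the average
#' CV accuracy and pooled AUC per cell. The winner maximizes average CV
#' accuracy; ties go to the higher AUC, then to the earlier cell in grid
#' order.
#'
#' @inheritParams repeated_cv
#' @param grid data.frame, one row per parameter combination.
#' @param keep_details keep per-cell per-sample vectors and importances
#'   (default TRUE; disable to save memory on big grids).
#' @return object of class `cv_report`: the grid with `accuracy` and `auc`
#'   columns, `winner` (row index), and per-cell `details`.
#' @export
tune <- function(g, phen, adapter, grid, k = 10, repeats = 10, seed = 1,
                 keep_details = TRUE) {
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("grid must be a non-empty data.frame")
  acc <- numeric(nrow(grid)); auc <- numeric(nrow(grid))
  details <- if (keep_details) vector("list", nrow(grid)) else NULL
  for (cell in seq_len(nrow(grid))) {
    params <- as.list(grid[cell, , drop = FALSE])
    cv <- repeated_cv(g, phen, adapter, params, k = k, repeats = repeats,
                      seed = seed)
    acc[cell] <- average_cv_accuracy(cv$per_sample_accuracy)
    auc[cell] <- cv_auc(cv$per_sample_prob, phen)
    if (keep_details) details[[cell]] <- cv
  }
  winner <- order(-acc, -auc, seq_len(nrow(grid)))[1]
  structure(list(grid = cbind(grid, accuracy = acc, auc = auc),
                 winner = winner, adapter = adapter$name,
                 k = k, repeats = repeats, details = details),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s): %d grid cells, %d-fold CV x %d repeats\n",
              x$adapter, nrow(x$grid), x$k, x$repeats))
  print.data.frame(x$grid, row.names = FALSE, digits = 4)
  w <- x$grid[x$winner, ]
  cat("winner (cell ", x$winner, "): ",
      paste(names(w), vapply(w, format, ""), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a CV report as TSV (one row per grid cell)
#' @param x a `cv_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cv_report <- function(x, path) {
  df <- x$grid
  df$winner <- seq_len(nrow(df)) == x$winner
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average and normalize importance vectors
#'
#' Arithmetic per-SNP mean over all fold-by-repeat fits, then min-max
#' normalized to \[0, 1\] (an all-equal mean vector normalizes to all
#' zeros).
#'
#' @param importances list of equal-length numeric vectors.
#' @param snp_ids SNP identifiers.
#' @param method tag for the resulting table.
#' @return an [importance_table].
#' @export
aggregate_importance <- function(importances, snp_ids, method = "ensemble") {
  if (length(importances) == 0) stop("need at least one importance vector")
  lens <- lengths(importances)
  if (length(unique(lens)) != 1 || lens[1] != length(snp_ids))
    stop("importance vector length mismatch")
  m <- Reduce(`+`, importances) / length(importances)
  rng <- range(m)
  norm <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else rep(0, length(m))
  importance_table(snp_ids, norm, method = method)
}

#' Two-method consensus SNP selection
#'
#' Combines the normalized importance tables of the two ensemble learners.
#' The `"diagonal"` rule selects SNPs with `rf + gbm >= t` on the unit
#' square — a separating line perpendicular to the main diagonal of the
#' scatter of the two scores; when `t` is `NULL` it is placed so that about
#' `frac` (default 1.5%) of the SNPs fall above the line. The `"top_k"`
#' rule intersects the two methods' top-k rank sets. Both are
#' deterministic.
#'
#' @param rf,gbm [importance_table]s over the same SNP ids.
#' @param rule `"diagonal"` or `"top_k"`.
#' @param t diagonal threshold in \[0, 2\] (`NULL` = auto from `frac`).
#' @param k rank cutoff for `"top_k"`.
#' @param frac target selected fraction used to auto-place the diagonal.
#' @return character vector of selected SNP ids, ordered by combined score.
#' @export
consensus_select <- function(rf, gbm, rule = c("diagonal", "top_k"),
                             t = NULL, k = NULL, frac = 0.015) {
  rule <- match.arg(rule)
  if (!setequal(rf$snp_id, gbm$snp_id)) stop("tables must share snp_ids")
  gbm <- gbm[match(rf$snp_id, gbm$snp_id), ]
  norm01 <- function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  }
  a <- norm01(rf$score); b <- norm01(gbm$score)
  if (rule == "diagonal") {
    s <- a + b
    if (is.null(t)) {
      n_sel <- max(1L, ceiling(frac * length(s)))
      t <- sort(s, decreasing = TRUE)[n_sel]
    }
    sel <- which(s >= t)
    return(rf$snp_id[sel][order(-s[sel])])
  }
  if (is.null(k)) stop("top_k rule requires k")
  ra <- rank(-a, ties.method = "min"); rb <- rank(-b, ties.method = "min")
  sel <- which(ra <= k & rb <= k)
  rf$snp_id[sel][order(-(a + b)[sel])]
}
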