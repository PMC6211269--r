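# toy adapters: the first genotype column carries the true label (0/2),
# so the oracle can read the truth from the test matrix alone
oracle_adapter <- learner_adapter(
  "oracle",
  fit = function(x, y, params, seed) list(),
  predict = function(model, x) as.numeric(x[, 1] / 2),
  importance = function(model) NA)  # patched per-test when needed

test_that("stratified folds partition samples and preserve class balance", {
  phen <- rep(c(0L, 1L), 50)
  folds <- stratified_kfold(phen, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(unlist(folds)), 1:100)
  expect_true(all(lengths(folds) == 10))
  for (f in folds) expect_equal(sum(phen[f]), 5)  # 5 cases / 5 controls
  expect_identical(folds, stratified_kfold(phen, k = 10, seed = 3))
  expect_false(identical(folds, stratified_kfold(phen, k = 10, seed = 4)))
  # unbalanced data: proportions within one sample of global
  phen2 <- c(rep(1L, 33), rep(0L, 67))
  folds2 <- stratified_kfold(phen2, k = 10, seed = 1)
  expect_equal(sort(unlist(folds2)), 1:100)
  expect_true(all(abs(sapply(folds2, function(f) sum(phen2[f])) - 3.3) <= 1))
  expect_error(stratified_kfold(c(rep(0L, 30), rep(1L, 5)), k = 10), "at least")
})


test_that("repeated_cv contracts: oracle gives accuracy 1, majority gives 0.5", {
  d <- make_label_data()
  ora <- oracle_adapter
  ora$importance <- function(model) rep(1, 5)
  cv <- repeated_cv(d$g, d$phen, ora, list(), k = 5, repeats = 4, seed = 2)
  expect_true(all(cv$per_sample_accuracy == 1))
  expect_equal(average_cv_accuracy(cv$per_sample_accuracy), 1.0)
  expect_length(cv$importances, 5 * 4)

  maj <- learner_adapter(
    "majority",
    fit = function(x, y, params, seed) mean(y),
    predict = function(model, x) rep(ifelse(model >= 0.5, 1, 0), nrow(x)),
    importance = function(model) rep(0, 5))
  cvm <- repeated_cv(d$g, d$phen, maj, list(), k = 5, repeats = 4, seed = 2)
  expect_equal(average_cv_accuracy(cvm$per_sample_accuracy), 0.5)
})

test_that("per-sample fractions lie on the 1/repeats grid; coin adapter hits 0.7-style values", {
  d <- make_label_data()
  # adapter correct with seed-dependent coin: fractions must be multiples of 1/10
  coin <- learner_adapter(
    "coin",
    fit = function(x, y, params, seed) seed,
    predict = function(model, x) {
      set.seed(model); as.numeric(stats::runif(nrow(x)) < 0.5)
    },
    importance = function(model) rep(0, 5))
  cv <- repeated_cv(d$g, d$phen, coin, list(), k = 5, repeats = 10, seed = 6)
  grid_vals <- (0:10) / 10
  expect_true(all(cv$per_sample_accuracy %in% grid_vals))
  expect_true(any(!cv$per_sample_accuracy %in% c(0, 1)))
})

test_that("adapter failures abort with fold and repeat identity", {
  d <- make_label_data()
  bad <- learner_adapter("bad",
                         fit = function(x, y, params, seed) stop("boom"),
                         predict = function(model, x) 0,
                         importance = function(model) 0)
  expect_error(repeated_cv(d$g, d$phen, bad, list(), k = 5, repeats = 2, seed = 1),
               "fold 1, repeat 1")
})

test_that("cv_auc is the Mann-Whitney area and matches pair counting", {
  labels <- rep(c(0L, 1L), 10)
  expect_equal(cv_auc(labels * 1.0, labels), 1.0)       # perfectly separated
  expect_equal(cv_auc(1 - labels, labels), 0.0)          # anti-ranked
  # 20 hand-listed probabilities incl. ties vs the pair-counting oracle
  probs <- c(0.10, 0.90, 0.40, 0.40, 0.70, 0.20, 0.55, 0.55, 0.80, 0.05,
             0.30, 0.60, 0.45, 0.45, 0.95, 0.15, 0.50, 0.50, 0.65, 0.25)
  expect_equal(cv_auc(probs, labels), oracle_auc(probs, labels))
  expect_error(cv_auc(probs, rep(1L, 20)), "both cases")
})

test_that("tune evaluates the grid, picks the argmax, and derives seeds from cell values", {
  d <- make_label_data()
  # rigged adapter: accurate only when params$good == 1
  rig <- learner_adapter(
    "rig",
    fit = function(x, y, params, seed) params$good,
    predict = function(model, x) {
      truth <- as.numeric(x[, 1] / 2)
      if (model == 1) truth else 1 - truth
    },
    importance = function(model) rep(0, 5))
  grid <- data.frame(good = c(0, 1, 0))
  rep1 <- tune(d$g, d$phen, rig, grid, k = 5, repeats = 2, seed = 9)
  expect_equal(rep1$winner, 2L)
  expect_equal(rep1$grid$accuracy, c(0, 1, 0))
  # duplicated cell -> identical metrics under the same derived seeds
  coin <- learner_adapter(
    "coin",
    fit = function(x, y, params, seed) seed,
    predict = function(model, x) {
      set.seed(model); as.numeric(stats::runif(nrow(x)) < 0.5)
    },
    importance = function(model) rep(0, 5))
  g2 <- data.frame(a = c(1, 1))
  rep2 <- tune(d$g, d$phen, coin, g2, k = 5, repeats = 3, seed = 12)
  expect_equal(rep2$grid$accuracy[1], rep2$grid$accuracy[2])
  expect_equal(rep2$grid$auc[1], rep2$grid$auc[2])
  # single-cell grid: that cell wins
  rep3 <- tune(d$g, d$phen, rig, data.frame(good = 1), k = 5, repeats = 1, seed = 1)
  expect_equal(rep3$winner, 1L)
})

test_that("importance aggregation averages then min-max normalizes", {
  ids <- paste0("s", 1:3)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  t1 <- aggregate_importance(same, ids)
  expect_equal(t1$score, c(0, 0.5, 1))
  # opposing vectors tie after averaging
  t2 <- aggregate_importance(list(c(0, 2, 1), c(2, 0, 1)), ids)
  expect_equal(t2$score, rep(0, 3))
  # 100 random vectors match direct recomputation
  set.seed(44)
  vs <- lapply(1:100, function(i) runif(6))
  m <- colMeans(do.call(rbind, vs))
  expect_equal(aggregate_importance(vs, paste0("x", 1:6))$score,
               (m - min(m)) / (max(m) - min(m)))
  expect_error(aggregate_importance(list(1:3, 1:4), ids), "mismatch")
})

test_that("consensus selection: diagonal threshold and top-k intersection", {
  rf <- importance_table(c("A", "B", "C"), c(1.0, 0.8, 0.1))
  gb <- importance_table(c("A", "B", "C"), c(0.8, 1.0, 0.1))
  expect_setequal(consensus_select(rf, gb, "top_k", k = 2), c("A", "B"))
  expect_setequal(consensus_select(rf, gb, "diagonal", t = 0), c("A", "B", "C"))
  # t = 2: only SNPs maximal in both tables
  expect_setequal(consensus_select(rf, gb, "diagonal", t = 2), character(0))
  gb2 <- importance_table(c("A", "B", "C"), c(1.0, 0.7, 0.1))
  expect_equal(consensus_select(rf, gb2, "diagonal", t = 2), "A")
  # random tables: diagonal rule equals a brute-force scan of the sum
  set.seed(55)
  ids <- paste0("r", 1:50)
  r1 <- importance_table(ids, runif(50)); r2 <- importance_table(ids, runif(50))
  n01 <- function(v) (v - min(v)) / (max(v) - min(v))
  s <- n01(r1$score) + n01(r2$score)
  got <- consensus_select(r1, r2, "diagonal", t = 1.2)
  expect_setequal(got, ids[s >= 1.2])
  expect_error(consensus_select(r1, importance_table("z", 1), "top_k", k = 1),
               "share")
})

test_that("the bundled rf and gbm adapters satisfy the contract on real fits", {
  d <- make_label_data(n = 80, p = 6, seed = 10)
  for (ad in list(adapter_rf(), adapter_gbm())) {
    params <- if (ad$name == "rf") list(mtry = 2, ntree = 50)
              else list(n.trees = 50, interaction.depth = 3, shrinkage = 0.1)
    m <- ad$fit(d$g$genotypes[1:60, ], d$phen[1:60], params, seed = 4)
    pr <- ad$predict(m, d$g$genotypes[61:80, ])
    expect_length(pr, 20)
    expect_true(all(pr >= 0 & pr <= 1))
    imp <- ad$importance(m)
    expect_length(imp, 6)
    expect_true(all(imp >= 0))
    expect_equal(which.max(imp), 1L)  # the label column dominates
    # deterministic refit
    m2 <- ad$fit(d$g$genotypes[1:60, ], d$phen[1:60], params, seed = 4)
    expect_equal(ad$predict(m2, d$g$genotypes[61:80, ]), pr)
  }
  # mtry clamp warning
  expect_warning(adapter_rf()$fit(d$g$genotypes, d$phen,
                                  list(mtry = 999, ntree = 20), 1),
                 "clamped")
})
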