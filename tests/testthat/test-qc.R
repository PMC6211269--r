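
test_that("per-sample missingness and heterozygosity behave as defined", {
  gm <- rbind(c(0L, 1L, 2L, 0L), c(-1L, 1L, 2L, 0L), c(-1L, -1L, -1L, -1L))
  g <- geno_matrix(gm)
  expect_equal(sample_missingness(g), c(0, 0.25, 1))
  # 10 SNPs, 3 heterozygous, none missing -> h = 0.3; identical rows -> SD 0
  g2 <- geno_matrix(matrix(rep(c(rep(1L, 3), rep(0L, 7)), 4), 4, 10, byrow = TRUE))
  expect_equal(sum(geno_matrix(g2$genotypes)$genotypes[1, ] == 1L) / 10, 0.3)
  expect_false(any(heterozygosity_outliers(g2, 3)))
  # 50 tight samples + one extreme: exactly the extreme flagged, verified
  # against direct mean/SD recomputation
  set.seed(5)
  gm3 <- t(sapply(1:50, function(i) {
    nh <- 33 + sample(-2:2, 1)
    sample(c(rep(1L, nh), rep(0L, 100 - nh)))
  }))
  gm3 <- rbind(gm3, sample(c(rep(1L, 90), rep(0L, 10))))
  g3 <- geno_matrix(gm3)
  flags <- heterozygosity_outliers(g3, 3)
  h <- rowMeans(gm3 == 1L)
  expect_identical(flags, abs(h - mean(h)) > 3 * sd(h))
  expect_identical(which(flags), 51L)
})

test_that("SNP missingness and MAF filters apply their thresholds", {
  col_ok <- c(0L, 0L, 1L, 1L, 2L)            # allele freq 0.4
  g <- geno_matrix(cbind(col_ok, rep(2L, 5)))
  expect_equal(maf_filter(g, qc_params(maf_min = 0.05)), 1L)  # all-2 is MAF 0
  gm <- matrix(0L, 20, 2); gm[1:2, 2] <- -1L  # 10% missing > 5%
  gm[, 1] <- rep(c(0L, 1L), 10)
  g2 <- geno_matrix(gm)
  expect_equal(snp_missingness_filter(g2, qc_params()), 1L)
})

test_that("HWE test matches the brute-force chi-square on all tables n <= 30", {
  for (n in 1:30) {
    for (n0 in 0:n) {
      for (n1 in 0:(n - n0)) {
        n2 <- n - n0 - n1
        expect_equal(hwe_test(c(n0, n1, n2)), oracle_hwe_p(n0, n1, n2),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(hwe_test(c(25, 50, 25)), oracle_hwe_p(25, 50, 25))
  expect_gt(hwe_test(c(25, 50, 25)), 0.99)
  # (50, 0, 50): statistic is exactly 100, far beyond the 1e-4 cut
  expect_equal(epigain:::hwe_chisq(c(50, 0, 50)), 100)
  expect_lt(hwe_test(c(50, 0, 50)), 1e-4)
  expect_equal(hwe_test(c(100, 0, 0)), 1.0)
})

test_that("ld_r2 equals squared Pearson correlation with sensible degenerate cases", {
  x <- c(0L, 0L, 1L, 1L); y <- c(0L, 1L, 0L, 1L)
  expect_equal(ld_r2(x, x), 1.0)
  expect_equal(ld_r2(x, y), 0.0)
  expect_equal(ld_r2(rep(1L, 4), x), 0.0)  # constant column
  set.seed(8)
  a <- sample(0:2, 50, TRUE); b <- as.integer(pmin(2, pmax(0, a + sample(-1:1, 50, TRUE))))
  expect_equal(ld_r2(a, b), cor(a, b)^2)
  expect_equal(ld_r2(c(0L, -1L, 1L), c(-1L, 0L, 1L)), 0)  # < 2 complete pairs
})

test_that("ld_prune keeps the first SNP of a block and honors the window", {
  n <- 60
  set.seed(3)
  base <- sample(0:2, n, TRUE)
  g <- geno_matrix(cbind(base, base, base), snp_ids = c("a", "b", "c"))
  expect_equal(ld_prune(g, qc_params()), 1L)
  # orthogonal columns all retained
  gm <- sapply(1:8, function(j) sample(0:2, n, TRUE))
  storage.mode(gm) <- "integer"
  g2 <- geno_matrix(gm)
  keep <- ld_prune(g2, qc_params(ld_r2_max = 0.99))
  expect_equal(keep, 1:8)
  # planted 5-SNP perfect-LD block inside 100 SNPs -> 96 survivors,
  # replayed against brute-force pairwise r2
  gm3 <- sapply(1:100, function(j) sample(0:2, n, TRUE, prob = c(.3, .5, .2)))
  for (j in 51:54) gm3[, j + 1] <- gm3[, 51]
  storage.mode(gm3) <- "integer"
  g3 <- geno_matrix(gm3)
  keep3 <- ld_prune(g3, qc_params(ld_r2_max = 0.6))
  replay <- integer(0)
  for (j in 1:100) {
    prunable <- any(sapply(replay, function(i) cor(gm3[, i], gm3[, j])^2 > 0.6))
    if (!isTRUE(prunable)) replay <- c(replay, j)
  }
  expect_equal(keep3, replay)
  expect_equal(length(keep3), 96)
  # no retained in-window pair exceeds the threshold
  for (a in seq_along(keep3)) {
    for (b in seq_len(a - 1)) {
      expect_lte(ld_r2(gm3[, keep3[b]], gm3[, keep3[a]]), 0.6)
    }
  }
})

test_that("impute_mode fills the per-SNP modal code and never edits observed calls", {
  gm <- cbind(c(0L, 1L, 1L, -1L), c(2L, 2L, -1L, -1L), c(0L, 0L, 2L, 2L))
  gm2 <- cbind(gm, c(0L, 0L, 2L, -1L))  # tie 0/2 -> smaller code
  g <- impute_mode(geno_matrix(gm2))
  expect_equal(unname(g$genotypes[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(g$genotypes[, 2]), rep(2L, 4))
  expect_equal(unname(g$genotypes[, 4]), c(0L, 0L, 2L, 0L))
  obs <- gm2 != -1L
  expect_identical(g$genotypes[obs], gm2[obs])
  expect_error(impute_mode(geno_matrix(matrix(-1L, 3, 1))), "no observed")
})

test_that("run_qc removes exactly the planted violations and reports them", {
  fx <- qc_fixture()
  res <- run_qc(fx$g, fx$phen, qc_params())
  rep <- res$report
  expect_equal(unname(rep$removed["sample_missingness"]), 2)
  expect_equal(unname(rep$removed["heterozygosity_outlier"]), 2)
  expect_equal(unname(rep$removed["snp_missingness"]), 5)
  expect_equal(unname(rep$removed["snp_maf"]), 5)
  expect_equal(unname(rep$removed["snp_hwe"]), 4)
  expect_equal(unname(rep$removed["snp_ld"]), 6)
  removed_ids <- setdiff(fx$g$snp_ids, res$genotypes$snp_ids)
  expect_setequal(removed_ids,
                  fx$g$snp_ids[unlist(fx$planted)])
  expect_equal(res$report$samples_out, 196)
  expect_false(any(res$genotypes$genotypes == -1L))
})

test_that("run_qc is idempotent and filters are monotone in their thresholds", {
  fx <- qc_fixture()
  res1 <- run_qc(fx$g, fx$phen, qc_params())
  res2 <- run_qc(res1$genotypes, res1$phenotype, qc_params())
  expect_identical(res2$genotypes$genotypes, res1$genotypes$genotypes)
  expect_true(all(unlist(res2$report$removed) == 0))
  # loosening MAF never removes a SNP the stricter run kept
  strict <- maf_filter(fx$g, qc_params(maf_min = 0.10))
  loose <- maf_filter(fx$g, qc_params(maf_min = 0.05))
  expect_true(all(strict %in% loose))
  strict_h <- epigain:::hwe_filter(fx$g, qc_params(hwe_alpha = 1e-2))
  loose_h <- epigain:::hwe_filter(fx$g, qc_params(hwe_alpha = 1e-6))
  expect_true(all(strict_h %in% loose_h))
})

test_that("run_qc fails loudly on empty output or single-class phenotype", {
  fx <- qc_fixture()
  expect_error(run_qc(fx$g, fx$phen, qc_params(maf_min = 0.9)), "every SNP")
  g <- geno_matrix(matrix(rep(c(0L, 1L, 2L, 1L), 25), 20, 5))
  phen <- c(1L, rep(0L, 19))
  gm <- g$genotypes; gm[1, 1:3] <- -1L  # the only case gets dropped
  expect_error(run_qc(geno_matrix(gm), phen,
                      qc_params(sample_missing_max = 0.01)),
               "single-class")
})

test_that("single-SNP chi-square association matches the textbook oracle", {
  # identical distribution in cases and controls -> p ~ 1
  gm <- cbind(rep(c(0L, 1L, 2L), 20), rep(0:2, each = 20))
  phen <- rep(c(0L, 1L), 30)
  res <- single_snp_association(geno_matrix(gm), phen)
  expect_true(all(res$p_value > 0.5))
  # perfect separation
  g2 <- geno_matrix(cbind(c(rep(0L, 50), rep(2L, 50))))
  phen2 <- c(rep(1L, 50), rep(0L, 50))
  expect_lt(single_snp_association(g2, phen2)$p_value, 1e-4)
  # printed 3x2 table vs oracle
  geno <- rep(rep(0:2, each = 2), times = c(30, 10, 20, 20, 10, 30))
  stat <- rep(rep(0:1, 3), times = c(30, 10, 20, 20, 10, 30))
  res3 <- single_snp_association(geno_matrix(cbind(as.integer(geno))),
                                 as.integer(stat))
  tab <- matrix(c(30, 20, 10, 10, 20, 30), 3, 2)
  expect_equal(res3$p_value, oracle_chisq_p(tab), tolerance = 1e-12)
  expect_equal(res3$df, 2)
  # monomorphic SNP -> p = 1
  resm <- single_snp_association(geno_matrix(matrix(1L, 20, 1)),
                                 rep(c(0L, 1L), 10))
  expect_equal(resm$p_value, 1)
})
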