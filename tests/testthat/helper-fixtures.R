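# deterministic QC fixture: 200 samples x 500 SNPs with known planted
# violations. Clean SNPs use exact rounded HWE genotype counts, and their
# heterozygous calls are dealt so that every sample carries the same number
# of heterozygotes across the clean columns — the matrix that survives QC is
# then exactly clean (idempotence holds with no statistical slack).
qc_fixture <- function() {
  n <- 200; p <- 500
  set.seed(42)
  planted <- list(miss = 101:105, maf = 201:205, hwe = 301:304,
                  ld = 400 + 2 * (1:6))
  clean <- setdiff(seq_len(p), unlist(planted))

  q <- runif(p, 0.2, 0.45)
  cnt <- t(sapply(q, function(qq) {
    cc <- round(n * c((1 - qq)^2, 2 * qq * (1 - qq), qq^2))
    cc[1] <- n - cc[2] - cc[3]
    cc
  }))
  # balance: total het count over clean columns divisible by n, so the
  # greedy min-fill deal gives every sample an identical het total
  rem <- sum(cnt[clean, 2]) %% n
  if (rem > 0) {
    for (j in clean[seq_len(rem)]) {
      cnt[j, 2] <- cnt[j, 2] - 1L; cnt[j, 1] <- cnt[j, 1] + 1L
    }
  }
  gm <- matrix(0L, n, p)
  fill <- integer(n)
  for (j in clean) {
    ord <- order(fill, runif(n))          # c_j least-filled samples get the hets
    het_rows <- ord[seq_len(cnt[j, 2])]
    fill[het_rows] <- fill[het_rows] + 1L
    rest <- setdiff(seq_len(n), het_rows)
    gm[het_rows, j] <- 1L
    gm[rest, j] <- sample(rep(c(0L, 2L), cnt[j, c(1, 3)]))
  }
  stopifnot(length(unique(fill)) == 1L)   # construction invariant

  # 5 SNPs with > 5% missing calls (rows 5:24, clear of the bad samples)
  for (j in planted$miss) {
    gm[, j] <- sample(rep(0:2, cnt[j, ])); gm[5:24, j] <- -1L
  }
  # 5 SNPs with MAF below 5% (near-monomorphic, still in HWE)
  for (j in planted$maf) gm[, j] <- sample(c(rep(1L, 4), rep(0L, n - 4)))
  # 4 SNPs violating HWE hard (no heterozygotes at q = 0.5)
  for (j in planted$hwe) gm[, j] <- sample(rep(c(0L, 2L), n / 2))
  # 6 SNPs in perfect LD with their left neighbor (duplicates)
  for (j in planted$ld) gm[, j] <- gm[, j - 1L]
  # 2 heterozygosity-outlier samples and 2 high-missingness samples
  gm[1, ] <- 1L; gm[2, ] <- 1L                          # heterozygosity 1
  gm[3, seq_len(15)] <- -1L; gm[4, seq_len(15)] <- -1L  # 3% missing rows
  phen <- rep(c(0L, 1L), n / 2)
  list(g = geno_matrix(gm), phen = phen, planted = planted,
       bad_samples = 1:4)
}

make_label_data <- function(n = 60, p = 5, seed = 8) {
  set.seed(seed)
  gm <- matrix(sample(0:2, n * p, TRUE), n, p)
  phen <- rep(c(0L, 1L), n / 2)
  gm[, 1] <- phen * 2L  # column 1 encodes the truth
  list(g = geno_matrix(gm), phen = phen)
}
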