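# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: entropies are evaluated cell-by-cell from first
# principles, neighbors are found by exhaustive search, AUC by pair
# counting.

# entropy by explicit cell loop
oracle_entropy <- function(p) {
  p <- as.numeric(p) / sum(p)
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log2(v)
  h
}

# mutual information of a counts table via sum p log2(p / (px * pd))
oracle_mi <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  px <- rowSums(tab) / n
  pd <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) s <- s + p * log2(p / (px[i] * pd[j]))
    }
  }
  s
}

# joint genotype x status count table for arbitrary loci, by explicit loop
oracle_joint_table <- function(geno_cols, phen) {
  k <- length(geno_cols)
  states <- 3^k
  tab <- matrix(0, states, 2)
  n <- length(phen)
  for (i in seq_len(n)) {
    idx <- 1
    for (l in seq_len(k)) idx <- idx + geno_cols[[l]][i] * 3^(l - 1)
    tab[idx, phen[i] + 1] <- tab[idx, phen[i] + 1] + 1
  }
  tab
}

# marginalize a 3^k x 2 table onto a subset of loci (1-based positions)
oracle_marginal <- function(tab, keep, k) {
  g <- expand.grid(rep(list(0:2), k))
  idx <- rep(1, nrow(g))
  for (j in seq_along(keep)) idx <- idx + g[[keep[j]]] * 3^(j - 1)
  out <- matrix(0, 3^length(keep), 2)
  for (r in seq_len(nrow(tab))) {
    out[idx[r], ] <- out[idx[r], ] + tab[r, ]
  }
  out
}

oracle_ig2 <- function(gA, gB, phen) {
  tab <- oracle_joint_table(list(gA, gB), phen)
  i_ab <- oracle_mi(tab)
  i_a <- oracle_mi(oracle_marginal(tab, 1, 2))
  i_b <- oracle_mi(oracle_marginal(tab, 2, 2))
  i_ab - i_a - i_b
}

oracle_ig3 <- function(gA, gB, gC, phen) {
  tab <- oracle_joint_table(list(gA, gB, gC), phen)
  i_abc <- oracle_mi(tab)
  mi1 <- sapply(1:3, function(l) oracle_mi(oracle_marginal(tab, l, 3)))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  ig2 <- sapply(pairs, function(pr) {
    oracle_mi(oracle_marginal(tab, pr, 3)) - mi1[pr[1]] - mi1[pr[2]]
  })
  i_abc - sum(ig2) - sum(mi1)
}

# expected (infinite-n) information gain of a penetrance model at given MAFs:
# enumerate the exact joint genotype x status probability table
oracle_expected_ig <- function(model, mafs) {
  k <- length(model$loci)
  g <- expand.grid(rep(list(0:2), k))
  hw <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  pg <- rep(1, nrow(g))
  for (l in seq_len(k)) pg <- pg * hw(mafs[l])[g[[l]] + 1]
  pcase <- model$table  # cell order matches expand.grid (first locus fastest)
  tab <- cbind(pg * (1 - pcase), pg * pcase)
  if (k == 2) {
    oracle_mi(tab) - oracle_mi(oracle_marginal(tab, 1, 2)) -
      oracle_mi(oracle_marginal(tab, 2, 2))
  } else {
    mi1 <- sapply(1:3, function(l) oracle_mi(oracle_marginal(tab, l, 3)))
    prs <- list(c(1, 2), c(1, 3), c(2, 3))
    ig2 <- sapply(prs, function(pr)
      oracle_mi(oracle_marginal(tab, pr, 3)) - mi1[pr[1]] - mi1[pr[2]])
    oracle_mi(tab) - sum(ig2) - sum(mi1)
  }
}

# AUC by exhaustive concordant/discordant pair counting (ties count 1/2)
oracle_auc <- function(probs, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      s <- s + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
    }
  }
  s / (length(pos) * length(neg))
}

# textbook chi-square test of independence on a counts table
oracle_chisq_p <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  pchisq(stat, df = (nrow(tab) - 1) * (ncol(tab) - 1), lower.tail = FALSE)
}

# brute-force HWE chi-square p-value from first principles
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  q <- (n1 + 2 * n2) / (2 * n)
  if (q == 0 || q == 1) return(1)
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  o <- c(n0, n1, n2)
  pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

# exhaustive ReliefF: nested loops, explicit neighbor sort with index
# tie-break, 0/1 mismatch diff
oracle_relieff <- function(gm, phen, k) {
  n <- nrow(gm); p <- ncol(gm)
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) sum(abs(gm[i, ] - gm[j, ])))
    same <- setdiff(which(phen == phen[i]), i)
    other <- which(phen != phen[i])
    hits <- same[order(d[same], same)][1:k]
    misses <- other[order(d[other], other)][1:k]
    for (a in seq_len(p)) {
      for (hh in hits) w[a] <- w[a] - (gm[i, a] != gm[hh, a]) / (n * k)
      for (mm in misses) w[a] <- w[a] + (gm[i, a] != gm[mm, a]) / (n * k)
    }
  }
  w
}

# exact-count two-locus parity dataset: 16 samples, genotype counts (1,2,1)
# per locus, joint counts proportional, status = parity(gA + gB)
parity2_data <- function() {
  g <- expand.grid(a = 0:2, b = 0:2)
  reps <- c(1, 2, 1)[g$a + 1] * c(1, 2, 1)[g$b + 1]
  gA <- rep(g$a, reps); gB <- rep(g$b, reps)
  list(gA = gA, gB = gB, phen = as.integer((gA + gB) %% 2))
}

# 64-sample three-locus analogue with multinomial-proportional counts
parity3_data <- function() {
  g <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  reps <- c(1, 2, 1)[g$a + 1] * c(1, 2, 1)[g$b + 1] * c(1, 2, 1)[g$c + 1]
  gA <- rep(g$a, reps); gB <- rep(g$b, reps); gC <- rep(g$c, reps)
  list(gA = gA, gB = gB, gC = gC, phen = as.integer((gA + gB + gC) %% 2))
}

# random imputed genotype matrix + balanced phenotype (for property tests)
random_geno <- function(n, p, seed) {
  set.seed(seed)
  gm <- matrix(sample(0:2, n * p, replace = TRUE, prob = c(.36, .48, .16)),
               n, p)
  list(g = geno_matrix(gm), phen = rep(c(0L, 1L), length.out = n))
}
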