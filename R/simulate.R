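#' Penetrance model over 1-3 functional loci
#'
#' A penetrance model maps each multi-locus genotype combination of `k`
#' functional SNPs (k in 1..3, 3^k cells) to the probability of being a case.
#' Cell order: the first locus varies fastest, i.e. for loci (A, B) the cell
#' index of genotypes (gA, gB) is `1 + gA + 3*gB`, and for three loci
#' `1 + gA + 3*gB + 9*gC`.
#'
#' @param loci integer vector of 1-3 functional SNP column indices.
#' @param table numeric vector of length `3^length(loci)` of case
#'   probabilities in \[0, 1\].
#' @param label optional model label stored in the truth record.
#' @return object of class `penetrance_model`.
#' @export
penetrance_model <- function(loci, table, label = "custom") {
  loci <- as.integer(loci)
  k <- length(loci)
  if (k < 1L || k > 3L) stop("a penetrance model uses 1-3 loci")
  if (anyDuplicated(loci)) stop("loci must be distinct")
  if (length(table) != 3^k) stop("table must have 3^k = ", 3^k, " cells")
  if (any(table < 0 | table > 1)) stop("penetrances must lie in [0, 1]")
  structure(list(loci = loci, table = as.numeric(table), label = label),
            class = "penetrance_model")
}

# P(case | genotype rows of the model's loci); geno is an n x k matrix
penetrance_prob <- function(model, geno) {
  k <- length(model$loci)
  idx <- geno[, 1] + 1L
  if (k >= 2L) idx <- idx + 3L * geno[, 2]
  if (k == 3L) idx <- idx + 9L * geno[, 3]
  model$table[idx]
}

#' Two-locus XOR (parity) penetrance model
#'
#' A pure-epistasis benchmark: P(case) = 0.5 + h when the summed genotype
#' g1 + g2 is odd and 0.5 - h when even. At minor allele frequency 0.5 both
#' single-locus marginal penetrances are exactly 0.5, so neither SNP has a
#' main effect while the pair is jointly informative.
#'
#' @param h baseline shift in \[0, 0.5\]; `h = 0.5` makes disease status a
#'   deterministic parity function of the genotypes.
#' @param loci the two functional SNP indices (default `c(1, 2)`).
#' @return a [penetrance_model].
#' @export
xor_penetrance <- function(h, loci = c(1L, 2L)) {
  if (h < 0 || h > 0.5) stop("h must lie in [0, 0.5]")
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  tab <- ifelse((g$g1 + g$g2) %% 2 == 1, 0.5 + h, 0.5 - h)
  penetrance_model(loci, tab, label = "xor")
}

#' Three-locus parity penetrance model
#'
#' Three-way analogue of [xor_penetrance()]: P(case) = 0.5 + h when
#' g1 + g2 + g3 is odd, 0.5 - h when even. At MAF 0.5 every one- and
#' two-locus marginal is flat, so the signal is purely three-way synergistic.
#'
#' @inheritParams xor_penetrance
#' @param loci the three functional SNP indices (default `c(1, 2, 3)`).
#' @return a [penetrance_model].
#' @export
parity3_penetrance <- function(h, loci = c(1L, 2L, 3L)) {
  if (h < 0 || h > 0.5) stop("h must lie in [0, 0.5]")
  g <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  tab <- ifelse((g$g1 + g$g2 + g$g3) %% 2 == 1, 0.5 + h, 0.5 - h)
  penetrance_model(loci, tab, label = "parity3")
}

#' Simulation configuration
#'
#' Defaults mirror a balanced case-control genotyping study: 472 cases and
#' 472 controls, biallelic SNPs with MAF drawn uniformly from
#' `maf_range`, genotypes at Hardy-Weinberg proportions. Disease status is
#' driven by the supplied penetrance models; an empty model list gives a
#' null dataset (status independent of all genotypes).
#'
#' @param n_cases,n_controls sample quotas (defaults 472 / 472).
#' @param n_snps number of SNPs.
#' @param maf_range MAF interval, a subset of (0, 0.5].
#' @param models list of [penetrance_model] objects with non-overlapping
#'   loci, all indices < `n_snps`. Empty list = null model.
#' @param functional_maf optional fixed MAF for every functional locus
#'   (e.g. 0.5 for the pure-parity constructions); `NULL` draws functional
#'   MAFs from `maf_range` like any other SNP.
#' @param missing_rate per-entry missing-call probability in \[0, 1).
#' @param ld_block_spec optional list of `c(size, r2)` pairs; each block is
#'   generated by copy-with-mutation from a seed SNP to reach the target
#'   r-squared in expectation. Blocks never overlap functional loci.
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 472, n_controls = 472, n_snps = 100,
                       maf_range = c(0.05, 0.5), models = list(),
                       functional_maf = NULL, missing_rate = 0,
                       ld_block_spec = NULL, seed = 1) {
  if (inherits(models, "penetrance_model")) models <- list(models)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  loci <- unlist(lapply(models, `[[`, "loci"))
  if (length(loci)) {
    if (anyDuplicated(loci)) stop("functional loci overlap across models")
    if (max(loci) > n_snps) stop("functional locus index exceeds n_snps")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 models = models, functional_maf = functional_maf,
                 missing_rate = missing_rate,
                 ld_block_spec = ld_block_spec, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a case-control genotype dataset
#'
#' Non-functional SNPs are drawn independently under Hardy-Weinberg
#' proportions with per-SNP MAF ~ Uniform(`maf_range`). Disease status is
#' assigned by rejection sampling: full genotype vectors are drawn, each is
#' labelled case with the probability given by the penetrance model(s)
#' (independent risks: P(control) is the product of the per-model
#' non-penetrance), and candidates are accepted until both case and control
#' quotas are filled. A fixed seed gives bit-identical output.
#'
#' @param cfg a [sim_config].
#' @param max_reject_factor abort after `max_reject_factor * (n_cases +
#'   n_controls)` candidate draws (guards penetrance tables incompatible
#'   with the quotas).
#' @return list with `genotypes` ([geno_matrix]), `phenotype` (0/1 vector,
#'   1 = case) and `truth` (functional locus indices, model labels, per-SNP
#'   MAF, seed).
#' @export
simulate_genotypes <- function(cfg, max_reject_factor = 1000) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p <- cfg$n_snps
    maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    func <- sort(unlist(lapply(cfg$models, `[[`, "loci")))
    if (!is.null(cfg$functional_maf)) maf[func] <- cfg$functional_maf

    # LD block layout: consecutive runs of non-functional SNPs, each run led
    # by its seed SNP; members copy the seed with per-genotype mutation
    blocks <- list()
    if (!is.null(cfg$ld_block_spec)) {
      free <- setdiff(seq_len(p), func)
      pos <- 1L
      for (bs in cfg$ld_block_spec) {
        size <- as.integer(bs[1]); r2 <- as.numeric(bs[2])
        if (pos + size - 1L > length(free)) stop("ld_block_spec exceeds available SNPs")
        idx <- free[pos:(pos + size - 1L)]
        blocks[[length(blocks) + 1L]] <- list(seed_snp = idx[1],
                                              members = idx[-1],
                                              mut = 1 - sqrt(r2))
        pos <- pos + size
      }
    }
    in_block_member <- unlist(lapply(blocks, `[[`, "members"))

    n_cases_left <- cfg$n_cases; n_controls_left <- cfg$n_controls
    n_total <- cfg$n_cases + cfg$n_controls
    geno_acc <- matrix(0L, n_total, p)
    phen_acc <- integer(n_total)
    filled <- 0L
    drawn <- 0L
    budget <- max_reject_factor * n_total

    gprob <- rbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)  # 3 x p

    while ((n_cases_left > 0L || n_controls_left > 0L) && drawn < budget) {
      b <- min(max(64L, 2L * (n_cases_left + n_controls_left)), budget - drawn)
      gb <- matrix(0L, b, p)
      for (j in setdiff(seq_len(p), in_block_member)) {
        gb[, j] <- sample.int(3L, b, replace = TRUE, prob = gprob[, j]) - 1L
      }
      for (bl in blocks) {
        for (j in bl$members) {
          gb[, j] <- gb[, bl$seed_snp]
          mut <- stats::runif(b) < bl$mut
          if (any(mut)) {
            gb[mut, j] <- sample.int(3L, sum(mut), replace = TRUE,
                                     prob = gprob[, bl$seed_snp]) - 1L
          }
        }
      }
      pr_case <- if (length(cfg$models) == 0L) rep(0.5, b) else {
        1 - Reduce(`*`, lapply(cfg$models, function(m)
          1 - penetrance_prob(m, gb[, m$loci, drop = FALSE])))
      }
      status <- as.integer(stats::runif(b) < pr_case)
      drawn <- drawn + b
      for (i in seq_len(b)) {
        if (status[i] == 1L && n_cases_left > 0L) {
          filled <- filled + 1L
          geno_acc[filled, ] <- gb[i, ]; phen_acc[filled] <- 1L
          n_cases_left <- n_cases_left - 1L
        } else if (status[i] == 0L && n_controls_left > 0L) {
          filled <- filled + 1L
          geno_acc[filled, ] <- gb[i, ]; phen_acc[filled] <- 0L
          n_controls_left <- n_controls_left - 1L
        }
        if (n_cases_left == 0L && n_controls_left == 0L) break
      }
    }
    if (n_cases_left > 0L || n_controls_left > 0L)
      stop("penetrance model incompatible with case/control quotas: ",
           drawn, " rejection-sampling draws exhausted")

    g <- geno_matrix(geno_acc,
                     snp_ids = sprintf("snp%04d", seq_len(p)),
                     chrom = rep("1", p), pos = seq_len(p) * 1000)
    if (cfg$missing_rate > 0) {
      g <- inject_missing(g, cfg$missing_rate,
                          seed = derive_seed(cfg$seed, "missing"))
    }
    list(genotypes = g, phenotype = phen_acc,
         truth = list(functional = func,
                      models = vapply(cfg$models, `[[`, "", "label"),
                      maf = maf, seed = cfg$seed))
  })
}

#' Inject missing genotype calls
#'
#' Sets each entry of the genotype matrix to missing (-1) independently with
#' probability `rate`; deterministic for a fixed seed.
#'
#' @param g a [geno_matrix].
#' @param rate per-entry missing probability in \[0, 1).
#' @param seed integer seed.
#' @return a [geno_matrix].
#' @export
inject_missing <- function(g, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(g)
  with_seed(seed, {
    mask <- matrix(stats::runif(length(g$genotypes)) < rate,
                   nrow(g$genotypes), ncol(g$genotypes))
    g$genotypes[mask] <- -1L
    g
  })
}

#' Write a simulation truth record as flat text
#'
#' @param truth the `truth` element returned by [simulate_genotypes()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  writeLines(c(
    paste0("functional\t", paste(truth$functional, collapse = ",")),
    paste0("models\t", paste(truth$models, collapse = ",")),
    paste0("seed\t", truth$seed)), path)
  invisible(path)
}
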