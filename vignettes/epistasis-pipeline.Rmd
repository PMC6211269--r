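---
title: "Detecting gene-gene interactions in case-control GWAS with epigain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-gene interactions in case-control GWAS with epigain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP association scans miss risk loci whose effect on a disease is
*epistatic* — visible only through the joint genotype of two or three loci,
with little or no marginal signal at any one of them. `epigain` implements a
staged analysis for balanced case-control genotype data that is designed
around this failure mode:

1. **Quality control** (`run_qc()`): per-sample and per-marker filters,
   linkage-disequilibrium (LD) pruning, mode imputation.
2. **Interaction-aware filtering** (`turf_scores()`): TuRF — iterated
   ReliefF with worst-feature removal — cuts a genome-scale SNP panel down
   to a candidate subset *without* discarding loci whose signal is purely
   interactive.
3. **Dual-ensemble ranking** (`tune()`, `consensus_select()`): a random
   forest and a gradient-boosted machine are tuned by repeated stratified
   cross-validation; their averaged importance scores are combined into a
   consensus set of top SNPs.
4. **Information-gain interaction analysis** (`pairwise_scan()`,
   `threeway_scan()`): plug-in mutual-information decompositions quantify
   the synergy of every candidate pair and trio, with permutation
   significance.

A penetrance-model simulator (`simulate_genotypes()`) generates datasets
with planted truth so every stage is testable end to end.

## The statistics

Write $D$ for the binary disease status and $A, B, C$ for genotype
variables coded 0/1/2 (minor-allele dosage). All entropies are plug-in
(maximum-likelihood) estimates in bits, with $0 \log 0 = 0$ and no
pseudo-counts; `entropy()`, `mutual_info()` expose the primitives.

The *main effect* of a SNP is its mutual information with the phenotype,
$I(A;D) = H(A) + H(D) - H(A,D)$.

The **two-way information gain** of a pair is the synergy left after
removing both main effects from the joint association:

$$IG(A;B;D) = I(AB;D) - I(A;D) - I(B;D),$$

where $AB$ is the 9-state joint genotype. It is positive for synergistic
pairs, negative for redundant ones.

The **three-way information gain** removes all lower-order terms from the
27-state joint association:

$$IG(A;B;C;D) = I(ABC;D) - \sum_{\text{pairs}} IG(\cdot;\cdot;D)
  - \sum_{\text{singles}} I(\cdot;D).$$

By construction $I(ABC;D)$ is exactly the sum of the three mains, the
three pairwise gains and $IG(A;B;C;D)$; the test suite asserts this
conservation to $10^{-10}$ on random data.

Gains are reported both in bits and as `gain_pct` $= 100 \cdot IG / H(D)$.
For a balanced design $H(D) = 1$ bit, so percent and bits $\times 100$
coincide; the $H(D)$ normalization keeps the percent interpretable for
unbalanced cohorts. (For data whose labels are exactly determined by a
parity function of the genotypes, `gain_pct` is exactly 100.)

**Significance** comes from phenotype-label permutation
(`permutation_test()`, and per-result inside the scans): the p-value is the
fraction of `n_permutations` label shuffles whose recomputed gain is
*strictly greater* than the observed one. Strict counting can return an
improper $p = 0$, which should be read as $p < 1/n$; the add-one-corrected
$(b+1)/(N+1)$ value is always reported alongside (`p_value_add1`).
Permutations are drawn fresh per pair/trio from a seeded stream, so scan
results are deterministic for a fixed seed regardless of evaluation order;
sharing one permutation set across tests would be cheaper but correlate
neighbouring p-values, and was not chosen.

## Quality control: rules and direction of the HWE filter

Defaults in `qc_params()`: samples are removed when more than 1% of calls
are missing or when heterozygosity deviates from the cohort mean by more
than 3 sample standard deviations; SNPs are removed for missingness
above 5%, minor allele frequency (MAF) below 5%, or a Hardy-Weinberg
equilibrium (HWE) test p-value below $10^{-4}$; finally a greedy
left-to-right LD scan prunes any SNP with $r^2 > 0.6$ against a retained
SNP among the previous 2,000 retained markers on the same chromosome, and
remaining missing calls are imputed with the SNP's modal genotype.

Three deliberate interpretations:

* **HWE direction.** The filter removes SNPs whose genotype counts
  *deviate* from Hardy-Weinberg proportions (p *below* the threshold),
  the standard PLINK convention — HWE deviation in a genotyping-array
  cohort flags genotyping error. A 1-df chi-square goodness-of-fit test is
  used; the exact test would be preferable below the 5% MAF floor, but
  every SNP at or above that floor is well inside the chi-square regime.
* **Heterozygosity outliers** use a plain $\pm k \cdot SD$ rule on the raw
  per-sample heterozygosity fraction (non-missing denominator), not an
  inbreeding F-statistic; with $SD = 0$ no sample is flagged. Sample SD
  ($n-1$) is used everywhere an SD appears.
* **LD pruning** is a deterministic keep-first greedy scan with the window
  measured in retained SNPs, not the sliding/step window of PLINK's
  `--indep-pairwise`; the greedy rule is order-stable and exactly
  replayable, which the tests exploit. HWE filtering is applied to cases
  and controls jointly.

Filters run in a fixed order (sample missingness, heterozygosity, SNP
missingness, MAF, HWE, LD, imputation), and `run_qc()` is idempotent: a
second pass removes nothing.

## TuRF: interaction-sensitive filtering

`relieff_scores()` uses all $n$ samples as reference instances. For each
sample its $k = 10$ nearest hits (same class) and misses (other class) are
found under Manhattan distance on genotype codes, distance ties broken by
sample index; each attribute's weight moves by $\pm \text{diff}/(n k)$,
where diff is the 0/1 genotype mismatch (genotypes as categories; a
dosage-scaled diff is available via `relief_params(diff = "dosage")`).
Weights therefore lie in $[-1, 1]$. Because neighbourhoods are computed in
the full genotype space, an attribute that only matters jointly with
another still separates hits from misses — the property that makes
Relief-style filters suitable ahead of an interaction analysis, and the
reason a marginal filter (chi-square, logistic) is not used here.

`turf_scores()` iterates ReliefF 10 times, after each round dropping the
worst `max(1, floor(0.1 * current))` SNPs (ties broken toward earlier
columns), so every round makes progress; survivors keep their final-round
score and removed SNPs receive rank-preserving scores strictly below all
survivors (ordered by removal round, then score). The removed-SNP scores
are synthetic — spaced by a tiny epsilon below the survivor minimum — and
only their order is meaningful. ReliefF's $k$, the iteration count and the
drop fraction are not dictated by the method; the defaults (10/10/10%)
follow common TuRF practice and are all configurable.

Selection uses the upper-tail rule `mean_sd_threshold()`: keep SNPs
scoring strictly above mean + 3 SD of the score distribution, the
conventional cut for carving a heavy right tail out of a genome-wide
importance histogram.

## The ensemble-ranking harness

The harness — stratified folds, repeated fitting, per-sample accuracy,
pooled AUC, importance averaging, consensus — is the package's code; the
tree learners are consumed behind the `learner_adapter()` contract
(`fit`/`predict`/`importance`) from established implementations:
`ranger` for the probability forest (impurity/Gini importance) and
`xgboost` for the gradient-boosted machine (binary logistic loss,
improvement-weighted gain importance; `n.trees`, `interaction.depth` and
`shrinkage` map to rounds, depth and learning rate, with subsample 0.5 and
minimum node weight 10 fixed). Re-implementing CART, bagging or boosting
is explicitly out of scope — the scientific content lies in the harness and
the downstream statistics.

`repeated_cv()` fits each fold `repeats` times with distinct derived
seeds; a test sample's accuracy entry is the fraction of its `repeats`
predictions that are correct at the 0.5 probability threshold (balanced
design), so entries lie on the $1/\text{repeats}$ grid. The average CV
accuracy is the mean of those fractions; AUC is the rank-based
(Mann-Whitney, midranks for ties) area computed on the per-sample mean
probabilities pooled across folds — pooling gives a single curve rather
than a fold-average, and the two options differ by one flag in the code.
`tune()` evaluates a parameter grid exhaustively (the genome-scale grids
of `default_rf_grid()` / `default_gbm_grid()`: 15 forest cells, 36 boosted
cells) and picks the accuracy argmax, ties broken by AUC then grid order.

Two design points matter for epistasis specifically. First, the ranking
stage consumes the TuRF-filtered candidate subset, not the full panel —
chaining the stages is not just a speed concern: with the null dimensions
pruned away, ensemble importance noise drops enough that a purely
epistatic pair reliably reaches the consensus corner. Second, the forest's
`mtry` should be far above the classification default $\sqrt{p}$ when
interactions are the target: both interacting loci must be available on
one root-to-leaf path for either to accrue impurity credit, and at desk
scale we use $mtry = p/4$. (`mtry` remains a tuning parameter in the
genome-scale grid.)

All randomness is derived, never global: a Lehmer-style counter mixes the
master seed with the fold, repeat and the *values* of the grid cell, so a
duplicated cell reproduces identical metrics and any single fit can be
re-run in isolation.

`aggregate_importance()` averages importance vectors over all
folds-by-repeats fits and min-max normalizes to $[0,1]$ (normalization
after averaging, so late-round boosted trees are not over-weighted).
`consensus_select()` combines the two learners' normalized scores either
by the *diagonal* rule — select SNPs with $rf + gbm \ge t$, a separating
line across the two-score scatter; when $t$ is unset it is placed so about
1.5% of candidates fall above it, mirroring a visual top-corner cut — or
by the deterministic top-$k$ rank intersection.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults to a balanced 472/472 case-control design.
Non-functional SNPs are drawn independently under Hardy-Weinberg
proportions with MAF $\sim U(0.05, 0.5)$. Disease status comes from
penetrance tables over 1-3 functional loci: `xor_penetrance(h)` sets
$P(\text{case}) = 0.5 \pm h$ by the parity of the two-locus dosage sum —
at MAF 0.5 both marginals are exactly flat, the canonical pure-epistasis
benchmark — and `parity3_penetrance(h)` is its three-locus analogue with
flat one- *and* two-locus marginals.

Status is assigned by **rejection sampling**: full genotype vectors are
drawn, labelled case with the table probability, and accepted until both
quotas fill. This honors arbitrary tables exactly with no prevalence
calibration (a liability-threshold construction would need one); an
all-zero table aborts after a bounded number of draws. With several
models, risks combine independently —
$P(\text{control}) = \prod_m (1 - p_m)$ — the simplest composition that
reduces correctly for one model and keeps non-overlapping truth loci
interpretable. Optional LD blocks are built by copy-with-mutation: block
members copy the block's seed SNP and are re-drawn with probability
$1 - \sqrt{r^2_{\text{target}}}$, hitting the target $r^2$ in expectation
(adequate for exercising the pruner). Functional loci are excluded from
blocks so the planted truth stays unambiguous. Missing calls are injected
independently per entry.

Not emulated: demographic/coalescent structure, realistic LD decay,
genotyping-batch artefacts, covariates, or population stratification. A
pipeline that passes the planted-truth tests is therefore validated for
its *statistical machinery*, not certified against confounding present in
real cohorts.

## Numerical conventions

* Missing sentinel is `-1`; MAF, heterozygosity and missingness always use
  non-missing denominators. Monomorphic SNPs: HWE p-value 1, association
  p-value 1, `ld_r2` 0.
* Modal imputation breaks ties toward the smaller genotype code; neighbor
  and removal ties break by index/input order; `which.max` conventions are
  made explicit in tests.
* Empty contingency cells contribute zero to entropy sums.
* An all-equal importance vector min-max normalizes to all zeros.
* Degenerate permutation statistics (constant under relabeling) give
  $p = 0$ under strict-greater counting; the add-one column is the guard.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core: simulated cohorts of
400-2,000 samples, 10-500 SNPs, ensembles of 100-200 trees with 10-fold
by 2-repeat cross-validation, and 1,000-fold permutation tests where
p-values are asserted. The genome-scale defaults (the full tuning grids,
10-fold by 10-repeat CV, window 2,000 LD pruning) are what
`run_pipeline()` applies when given cohort-sized data; at 186k-SNP scale
the TuRF and scan stages are cluster-sized jobs.

## Known limitations

* Plug-in entropies are upward-biased at small $n$ per cell; three-way
  scans on fewer than ~50 samples per genotype cell rank reliably but the
  absolute `gain_pct` is inflated. Bias-corrected estimators are a noted
  extension, not implemented.
* The 1% sample-missingness default is calibrated to genome-scale panels;
  on simulated panels of a few hundred SNPs it is overly aggressive (1% of
  300 calls is 3), and a looser per-sample threshold is the right choice
  there.
* Binary PLINK (BED/BIM/FAM), reference-panel imputation, sex checks and
  stratification correction are out of scope; autosomal biallelic input is
  assumed.
* The consensus diagonal threshold emulates a judgement call (a line drawn
  across a scatter); it is parameterized and deterministic here, but any
  particular `t` or fraction remains a modelling choice.
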