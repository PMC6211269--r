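#' Pipeline configuration
#'
#' Builds the declarative configuration for [run_pipeline()]: exactly one
#' input source (a file to read or a simulation), plus the per-stage
#' parameter blocks. Any block left `NULL` takes the stage defaults
#' ([qc_params()], [relief_params()], the default tuning grids, 1000
#' permutations, mean + 3 SD selection).
#'
#' @param input_path path to genotype data (TSV or PED/MAP), or `NULL` when
#'   simulating.
#' @param input_format `"tsv"` or `"ped_map"`.
#' @param simulation a [sim_config()], or `NULL` when reading from file.
#' @param qc a [qc_params()].
#' @param relief a [relief_params()].
#' @param rf_grid,gbm_grid tuning grids (data.frames); defaults are
#'   desk-scale single cells, see Details.
#' @param folds,repeats cross-validation shape (defaults 10 and 10).
#' @param consensus_rule `"diagonal"` or `"top_k"`.
#' @param consensus_frac target selected fraction for the diagonal rule.
#' @param consensus_k rank cutoff for the top-k rule.
#' @param min_selected if the mean + k*SD cut selects fewer SNPs than this,
#'   the top `min_selected` TuRF SNPs are carried forward instead (an
#'   interaction scan needs at least a pair).
#' @param n_permutations permutations per interaction test (default 1000).
#' @param max_interaction_snps cap on the number of consensus SNPs entering
#'   the pair/trio scans.
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; all stage seeds are derived from it.
#'
#' @details The full genome-scale tuning grids ([default_rf_grid()],
#' [default_gbm_grid()]) can be passed explicitly; the pipeline default is
#' a single desk-scale cell per learner (forest: `mtry` = p/4 — well above
#' the sqrt classification rule, since both members of an interacting pair
#' must be available on one tree path — and `ntree` = 500; boosted
#' machine: 500 trees, depth 10, shrinkage 0.1) so that an end-to-end run
#' on simulated data finishes in minutes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, input_format = "tsv",
                            simulation = NULL,
                            qc = qc_params(), relief = relief_params(),
                            rf_grid = NULL, gbm_grid = NULL,
                            folds = 10, repeats = 10,
                            consensus_rule = "diagonal",
                            consensus_frac = 0.05, consensus_k = NULL,
                            min_selected = 10, n_permutations = 1000,
                            max_interaction_snps = 44,
                            out_dir = tempfile("epigain_run_"), seed = 1) {
  if (is.null(input_path) == is.null(simulation))
    stop("exactly one input source: input_path or simulation")
  if (is.null(rf_grid))
    rf_grid <- data.frame(mtry = NA_integer_, ntree = 500)  # NA -> p/4 rule
  if (is.null(gbm_grid))
    gbm_grid <- data.frame(n.trees = 500, interaction.depth = 10,
                           shrinkage = 0.1)
  structure(list(input_path = input_path, input_format = input_format,
                 simulation = simulation, qc = qc, relief = relief,
                 rf_grid = rf_grid, gbm_grid = gbm_grid,
                 folds = folds, repeats = repeats,
                 consensus_rule = consensus_rule,
                 consensus_frac = consensus_frac, consensus_k = consensus_k,
                 min_selected = min_selected,
                 n_permutations = n_permutations,
                 max_interaction_snps = max_interaction_snps,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat declarative file with optional sections `input`, `simulation`, `qc`,
#' `relief`, `ensemble`, `consensus`, `interaction`, and top-level `out_dir`
#' and `seed`; unknown keys are rejected. Section keys map one-to-one onto
#' the arguments of [pipeline_config()], [sim_config()], [qc_params()] and
#' [relief_params()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("input", "simulation", "qc", "relief", "ensemble",
             "consensus", "interaction", "out_dir", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    models <- list()
    for (m in s$models %||% list()) {
      models[[length(models) + 1L]] <- switch(
        m$type,
        xor = xor_penetrance(m$h, loci = unlist(m$loci)),
        parity3 = parity3_penetrance(m$h, loci = unlist(m$loci)),
        custom = penetrance_model(unlist(m$loci), unlist(m$table)),
        stop("unknown model type: ", m$type))
    }
    sim <- sim_config(n_cases = s$n_cases %||% 472,
                      n_controls = s$n_controls %||% 472,
                      n_snps = s$n_snps %||% 100,
                      maf_range = unlist(s$maf_range %||% c(0.05, 0.5)),
                      models = models,
                      functional_maf = s$functional_maf,
                      missing_rate = s$missing_rate %||% 0,
                      seed = s$seed %||% (y$seed %||% 1))
  }
  qc <- do.call(qc_params, y$qc %||% list())
  relief <- do.call(relief_params, y$relief %||% list())
  ens <- y$ensemble %||% list()
  cons <- y$consensus %||% list()
  inter <- y$interaction %||% list()
  pipeline_config(
    input_path = y$input$path, input_format = y$input$format %||% "tsv",
    simulation = sim, qc = qc, relief = relief,
    rf_grid = if (!is.null(ens$rf_grid)) as.data.frame(ens$rf_grid) else NULL,
    gbm_grid = if (!is.null(ens$gbm_grid)) as.data.frame(ens$gbm_grid) else NULL,
    folds = ens$folds %||% 10, repeats = ens$repeats %||% 10,
    consensus_rule = cons$rule %||% "diagonal",
    consensus_frac = cons$frac %||% 0.05, consensus_k = cons$k,
    min_selected = cons$min_selected %||% 10,
    n_permutations = inter$n_permutations %||% 1000,
    max_interaction_snps = inter$max_snps %||% 44,
    out_dir = y$out_dir %||% tempfile("epigain_run_"),
    seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full epistasis-analysis pipeline
#'
#' Executes, in order: input (read or simulate), quality control, TuRF
#' filtering with mean + k*SD selection, dual-ensemble ranking with
#' consensus selection, and the pairwise/three-way information-gain scans
#' with permutation testing. Every stage writes its artifact into
#' `cfg$out_dir`; the returned manifest lists each file with an MD5
#' checksum, stage timings and record counts. Re-running with an identical
#' configuration reproduces identical outputs. On stage failure the
#' partial manifest is written and the error names the failing stage.
#'
#' @param cfg a [pipeline_config()] or path to a YAML config file.
#' @return object of class `pipeline_manifest` (invisibly also written to
#'   `manifest.yaml` in the output directory).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, out_dir = cfg$out_dir, stages = list())
  files <- character(0)

  add_stage <- function(name, t0, counts, outputs) {
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      counts = counts, outputs = as.list(outputs))
    files <<- c(files, outputs)
  }
  fail <- function(name, e) {
    manifest$failed_stage <- name
    manifest$error <- conditionMessage(e)
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
    stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  }

  # -- stage 1: input ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dat <- tryCatch({
    if (!is.null(cfg$simulation)) {
      sim <- simulate_genotypes(cfg$simulation)
      write_truth(sim$truth, file.path(cfg$out_dir, "truth.txt"))
      sim
    } else {
      read_genotypes(cfg$input_path, cfg$input_format)
    }
  }, error = function(e) fail("input", e))
  f_in <- file.path(cfg$out_dir, "input.tsv")
  write_genotypes(dat$genotypes, dat$phenotype, f_in, "tsv")
  add_stage("input", t0,
            c(samples = nrow(dat$genotypes$genotypes),
              snps = ncol(dat$genotypes$genotypes)),
            c(f_in, if (!is.null(cfg$simulation)) file.path(cfg$out_dir, "truth.txt")))

  # -- stage 2: qc ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  qc <- tryCatch(run_qc(dat$genotypes, dat$phenotype, cfg$qc),
                 error = function(e) fail("qc", e))
  f_qc <- file.path(cfg$out_dir, "genotypes_qc.tsv")
  f_qcr <- file.path(cfg$out_dir, "qc_report.txt")
  write_genotypes(qc$genotypes, qc$phenotype, f_qc, "tsv")
  write_qc_report(qc$report, f_qcr)
  add_stage("qc", t0,
            c(samples = qc$report$samples_out, snps = qc$report$snps_out),
            c(f_qc, f_qcr))

  # -- stage 3: turf -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sel <- tryCatch({
    turf <- turf_scores(qc$genotypes, qc$phenotype, cfg$relief)
    ids <- mean_sd_threshold(turf, cfg$relief$sd_multiplier)
    if (length(ids) < cfg$min_selected) {
      ord <- turf$snp_id[order(turf$rank)]
      ids <- ord[seq_len(min(cfg$min_selected, length(ord)))]
    }
    list(turf = turf, ids = ids)
  }, error = function(e) fail("turf", e))
  f_turf <- file.path(cfg$out_dir, "turf_scores.tsv")
  write_importance(sel$turf, f_turf)
  add_stage("turf", t0, c(snps_scored = nrow(sel$turf),
                          snps_selected = length(sel$ids)), f_turf)
  g_sel <- subset_geno(qc$genotypes, snps = match(sel$ids, qc$genotypes$snp_ids))

  # -- stage 4: rank -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rank_res <- tryCatch({
    rf_grid <- cfg$rf_grid
    if (any(is.na(rf_grid$mtry)))
      rf_grid$mtry[is.na(rf_grid$mtry)] <- max(2L, floor(ncol(g_sel$genotypes) / 4))
    rf_rep <- tune(g_sel, qc$phenotype, adapter_rf(), rf_grid,
                   k = cfg$folds, repeats = cfg$repeats,
                   seed = derive_seed(cfg$seed, "rank", "rf"))
    gbm_rep <- tune(g_sel, qc$phenotype, adapter_gbm(), cfg$gbm_grid,
                    k = cfg$folds, repeats = cfg$repeats,
                    seed = derive_seed(cfg$seed, "rank", "gbm"))
    rf_imp <- aggregate_importance(rf_rep$details[[rf_rep$winner]]$importances,
                                   g_sel$snp_ids, method = "rf_gini")
    gbm_imp <- aggregate_importance(gbm_rep$details[[gbm_rep$winner]]$importances,
                                    g_sel$snp_ids, method = "gbm")
    cons <- consensus_select(rf_imp, gbm_imp, rule = cfg$consensus_rule,
                             k = cfg$consensus_k, frac = cfg$consensus_frac)
    # the interaction stage needs at least a trio: pad from the combined
    # ranking when the consensus rule selects fewer
    floor_n <- min(3L, length(g_sel$snp_ids))
    if (length(cons) < floor_n) {
      cons <- utils::head(consensus_select(rf_imp, gbm_imp, "diagonal", t = 0),
                          floor_n)
    }
    if (length(cons) > cfg$max_interaction_snps)
      cons <- cons[seq_len(cfg$max_interaction_snps)]
    list(rf = rf_rep, gbm = gbm_rep, rf_imp = rf_imp, gbm_imp = gbm_imp,
         consensus = cons)
  }, error = function(e) fail("rank", e))
  f_rfcv <- file.path(cfg$out_dir, "rf_cv_report.tsv")
  f_gbmcv <- file.path(cfg$out_dir, "gbm_cv_report.tsv")
  f_rfimp <- file.path(cfg$out_dir, "rf_importance.tsv")
  f_gbmimp <- file.path(cfg$out_dir, "gbm_importance.tsv")
  f_cons <- file.path(cfg$out_dir, "consensus_snps.txt")
  write_cv_report(rank_res$rf, f_rfcv)
  write_cv_report(rank_res$gbm, f_gbmcv)
  write_importance(rank_res$rf_imp, f_rfimp)
  write_importance(rank_res$gbm_imp, f_gbmimp)
  writeLines(rank_res$consensus, f_cons)
  add_stage("rank", t0, c(consensus_snps = length(rank_res$consensus)),
            c(f_rfcv, f_gbmcv, f_rfimp, f_gbmimp, f_cons))

  # -- stage 5: interact ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  scans <- tryCatch({
    gi <- subset_geno(qc$genotypes,
                      snps = match(rank_res$consensus, qc$genotypes$snp_ids))
    pcfg <- perm_config(max(1L, cfg$n_permutations),
                        seed = derive_seed(cfg$seed, "interact"))
    pairs <- if (ncol(gi$genotypes) >= 2)
      pairwise_scan(gi, qc$phenotype, pcfg, perms = cfg$n_permutations) else NULL
    trios <- if (ncol(gi$genotypes) >= 3)
      threeway_scan(gi, qc$phenotype, pcfg, perms = cfg$n_permutations) else NULL
    list(pairs = pairs, trios = trios)
  }, error = function(e) fail("interact", e))
  outs <- character(0)
  if (!is.null(scans$pairs)) {
    f <- file.path(cfg$out_dir, "interactions_pairs.tsv")
    write_interactions(scans$pairs, f); outs <- c(outs, f)
  }
  if (!is.null(scans$trios)) {
    f <- file.path(cfg$out_dir, "interactions_trios.tsv")
    write_interactions(scans$trios, f); outs <- c(outs, f)
  }
  add_stage("interact", t0,
            c(pairs = if (is.null(scans$pairs)) 0L else nrow(scans$pairs),
              trios = if (is.null(scans$trios)) 0L else nrow(scans$trios)),
            outs)

  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  structure(manifest, class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline run:", x$out_dir, "(seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %6.2fs  %s\n", nm, st$seconds,
                paste(names(st$counts), unlist(st$counts), sep = "=",
                      collapse = ", ")))
  }
  if (!is.null(x$failed_stage)) cat("  FAILED at stage:", x$failed_stage, "\n")
  invisible(x)
}
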