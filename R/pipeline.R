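#' Default pipeline run configuration
#'
#' Collects every threshold and size the pipeline stages use, with the
#' analysis defaults: 10% gene-representation floor, DE retention at
#' q <= 0.05, screen significance at pFDR < 0.01, SNP QC at 90% call rate /
#' 5% MAF / HWE p < 0.01, and 1000 permutations for both permutation nulls.
#'
#' @param seed Global seed; each stage derives its own substream from it.
#' @param ... Overrides for any configuration entry, including `sim`
#'   (a [simulation_config()]) for the simulate stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              sim = NULL,                 # filled with simulation_config(seed)
              min_fraction = 0.10,
              de_q = 0.05,
              pfdr_alpha = 0.01,
              n_perm_rp = 1000L,
              n_perm_pfdr = 1000L,
              call_rate_min = 0.90,
              maf_min = 0.05,
              hwe_alpha = 0.01,
              max_cold_s = 180,
              transforms = c(heat_c = "identity", cold_thresh_s = "log",
                             cold_tol_s = "log"),
              ordering = "ascending")
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (is.null(cfg$sim)) {
    cfg$sim <- simulation_config(seed = cfg$seed)
  } else if (!inherits(cfg$sim, "sim_config")) {
    # plain list of generator overrides (e.g. from a YAML config file)
    sim_args <- cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim <- do.call(simulation_config, sim_args)
  }
  if (cfg$min_fraction <= 0 || cfg$min_fraction > 1) {
    stop_config("min_fraction must lie in (0, 1]")
  }
  if (cfg$pfdr_alpha <= 0 || cfg$de_q <= 0) {
    stop_config("significance thresholds must be positive")
  }
  structure(cfg, class = "run_config")
}

pipeline_paths <- function(out_dir) {
  list(citations = file.path(out_dir, "citations.tsv"),
       index = file.path(out_dir, "index.tsv"),
       expr_dir = file.path(out_dir, "expression"),
       de_dir = file.path(out_dir, "de"),
       registry = file.path(out_dir, "planted_registry.tsv"),
       gold = file.path(out_dir, "gold_standard.txt"),
       fc_matrix = file.path(out_dir, "fc_matrix.tsv"),
       scores = file.path(out_dir, "gene_scores.tsv"),
       candidates = file.path(out_dir, "candidates.tsv"),
       roc = file.path(out_dir, "roc_curve.tsv"),
       roc_summary = file.path(out_dir, "roc_summary.tsv"),
       phenotypes = file.path(out_dir, "twin_phenotypes.tsv"),
       genotypes = file.path(out_dir, "twin_genotypes.tsv"),
       snp_registry = file.path(out_dir, "snp_registry.tsv"),
       assoc = file.path(out_dir, "association.tsv"),
       qc = file.path(out_dir, "snp_qc.tsv"),
       ld = file.path(out_dir, "ld_r2.tsv"),
       manhattan = file.path(out_dir, "manhattan.tsv"),
       manifest = file.path(out_dir, "manifest.json"))
}

#' Run the discovery pipeline
#'
#' Executes the requested stage (or all of them in order) against the files
#' in `out_dir`: `simulate` writes every synthetic input; `dspi` builds the
#' phenotype index from the citation table; `de` runs the Rank Product
#' differential expression per disease; `correlate` assembles the
#' fold-change matrix and scores genes against the index; `validate`
#' computes the ROC of the prioritization against the gold-standard list;
#' `assoc` runs the twin association scan. A machine-readable manifest
#' (inputs, parameters, seed, counts at each filter) is updated after each
#' stage. Rerunning with the same configuration yields byte-identical
#' outputs.
#'
#' @param stage One of `simulate`, `dspi`, `de`, `correlate`, `validate`,
#'   `assoc`, `all`.
#' @param config A [run_config()].
#' @param out_dir Directory for all pipeline artifacts (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "dspi", "de",
                                   "correlate", "validate", "assoc"),
                         config = run_config(), out_dir) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop_config("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(out_dir)
  stages <- if (stage == "all") {
    c("simulate", "dspi", "de", "correlate", "validate", "assoc")
  } else stage

  manifest <- if (file.exists(p$manifest)) {
    jsonlite::read_json(p$manifest, simplifyVector = TRUE)
  } else {
    list(seed = config$seed,
         parameters = config[setdiff(names(config), c("sim", "transforms"))],
         counts = list())
  }

  for (st in stages) {
    manifest$counts[[st]] <- switch(
      st,
      simulate = stage_simulate(config, p),
      dspi = stage_dspi(config, p),
      de = stage_de(config, p),
      correlate = stage_correlate(config, p),
      validate = stage_validate(config, p),
      assoc = stage_assoc(config, p))
  }
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config, p) {
  sim <- config$sim
  cit <- simulate_citations(sim)
  write_tsv(cit[, c("disease_id", "disease_name", "n_total", "n_phenotype")],
            p$citations, stage = "simulate_citations", seed = sim$seed)
  idx <- build_index(cit, ordering = config$ordering)
  expr <- simulate_expression_studies(sim, idx)
  dir.create(p$expr_dir, showWarnings = FALSE)
  for (st in expr$studies) {
    write_expression_study(st,
                           file.path(p$expr_dir, paste0(st$disease_id, "_expr.tsv")),
                           file.path(p$expr_dir, paste0(st$disease_id, "_design.tsv")),
                           seed = sim$seed)
  }
  write_tsv(expr$registry, p$registry, stage = "simulate_registry",
            seed = sim$seed)
  writeLines(c("# synthetic gold standard: planted gene ids",
               expr$registry$gene_id[expr$registry$planted]), p$gold)
  cohort <- simulate_twin_cohort(sim)
  write_twin_cohort(cohort, p$phenotypes, p$genotypes, seed = sim$seed)
  write_tsv(cohort$registry, p$snp_registry, stage = "simulate_snp_registry",
            seed = sim$seed)
  list(n_diseases = nrow(cit), n_studies = length(expr$studies),
       n_genes = sim$n_genes, n_planted = sum(expr$registry$planted),
       n_individuals = nrow(cohort$individuals), n_snps = sim$n_snps)
}

stage_dspi <- function(config, p) {
  cit <- read_citations(p$citations)
  idx <- build_index(cit, ordering = config$ordering)
  write_index(idx, p$index, seed = config$seed)
  list(n_input = nrow(cit), n_retained = nrow(idx),
       n_excluded = nrow(attr(idx, "excluded")))
}

stage_de <- function(config, p) {
  idx <- read_index(p$index)
  expr_files <- sort(list.files(p$expr_dir, pattern = "_expr\\.tsv$",
                                full.names = TRUE))
  if (length(expr_files) == 0L) {
    stop_data("no expression study found; run the simulate stage or supply studies")
  }
  dir.create(p$de_dir, showWarnings = FALSE)
  n_retained <- 0L
  seed0 <- stage_seed(config$seed, "de")
  for (i in seq_along(expr_files)) {
    disease <- sub("_expr\\.tsv$", "", basename(expr_files[i]))
    study <- read_expression_study(expr_files[i],
                                   file.path(p$expr_dir, paste0(disease, "_design.tsv")),
                                   disease)
    de <- de_analysis(study, n_perm = config$n_perm_rp,
                      seed = (seed0 + i) %% 2147483647,
                      q_threshold = config$de_q)
    n_retained <- n_retained + sum(de$retained)
    write_tsv(as.data.frame(de), file.path(p$de_dir, paste0(disease, "_de.tsv")),
              stage = "de", seed = config$seed,
              extra = list(disease_id = disease))
  }
  list(n_studies = length(expr_files), n_gene_disease_retained = n_retained)
}

stage_correlate <- function(config, p) {
  idx <- read_index(p$index)
  de_files <- sort(list.files(p$de_dir, pattern = "_de\\.tsv$", full.names = TRUE))
  if (length(de_files) == 0L) stop_data("no DE table found; run the de stage")
  de_results <- lapply(de_files, read_tsv,
                       required = c("gene_id", "fold_change"), what = "DE table")
  names(de_results) <- sub("_de\\.tsv$", "", basename(de_files))
  fcm <- assemble_matrix(de_results, idx, min_fraction = config$min_fraction,
                         de_q = config$de_q)
  write_fc_matrix(fcm, p$fc_matrix, seed = config$seed)
  scores <- score_genes(fcm, idx, n_perm = config$n_perm_pfdr,
                        seed = stage_seed(config$seed, "correlate"),
                        alpha = config$pfdr_alpha)
  write_tsv(scores, p$scores, stage = "correlate", seed = config$seed)
  cand <- select_candidates(scores, alpha = config$pfdr_alpha)
  write_tsv(cand, p$candidates, stage = "candidates", seed = config$seed)
  list(n_genes = nrow(fcm), n_diseases = ncol(fcm),
       n_candidates = nrow(cand))
}

stage_validate <- function(config, p) {
  scores <- read_tsv(p$scores, c("gene_id", "rho", "pfdr"), "score table")
  gold <- read_gene_list(p$gold, label = "planted")
  roc <- roc_auc(gene_priority(scores), gold)
  write_tsv(data.frame(threshold = roc$thresholds,
                       sensitivity = roc$sensitivity,
                       specificity = roc$specificity),
            p$roc, stage = "roc_curve", seed = config$seed)
  write_tsv(data.frame(auc = roc$auc,
                       best_sensitivity = roc$best_cutoff[["sensitivity"]],
                       best_specificity = roc$best_cutoff[["specificity"]],
                       n_gold = roc$n_gold, n_background = roc$n_background),
            p$roc_summary, stage = "roc_summary", seed = config$seed)
  list(auc = roc$auc, n_gold_evaluable = roc$n_gold,
       n_background = roc$n_background)
}

stage_assoc <- function(config, p) {
  cohort <- read_twin_cohort(p$phenotypes, p$genotypes)
  scan <- run_association(cohort,
                          transforms = config$transforms,
                          call_rate_min = config$call_rate_min,
                          maf_min = config$maf_min,
                          hwe_alpha = config$hwe_alpha,
                          max_cold_s = config$max_cold_s)
  write_tsv(scan$results, p$assoc, stage = "assoc", seed = config$seed,
            extra = list(m = scan$m))
  write_tsv(scan$qc, p$qc, stage = "snp_qc", seed = config$seed)
  write_tsv(scan$manhattan, p$manhattan, stage = "manhattan", seed = config$seed)
  if (!is.null(scan$ld)) {
    ld_df <- data.frame(snp_id = rownames(scan$ld),
                        as.data.frame(scan$ld, check.names = FALSE),
                        check.names = FALSE)
    write_tsv(ld_df, p$ld, stage = "ld", seed = config$seed)
  }
  list(n_snps_tested = scan$m, n_snps_removed = sum(scan$qc$removed),
       n_tests = nrow(scan$results))
}
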