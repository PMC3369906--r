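#' Simulate per-disease case/control expression studies
#'
#' Generates one log2-scale expression study per disease in the supplied
#' index. A registry of "planted" genes receives a true case-minus-control
#' difference that grows linearly with the disease's index midrank at
#' `planted_slope` per rank step (direction randomized per gene and centred
#' across diseases); all other genes are null. Per-sample noise is scaled so
#' that the fold-change estimate (difference of group means) has standard
#' deviation `noise_sd`. Each gene is independently absent from a study with
#' probability `missing_fraction`, emulating platform coverage differences.
#'
#' @param cfg A [simulation_config()].
#' @param index A [build_index()] result giving the diseases and midranks.
#' @return List with elements `studies` (named list of `expression_study`
#'   objects, one per disease: `disease_id`, `gene_ids`, `case_matrix`,
#'   `control_matrix`) and `registry` (data frame `gene_id`, `planted`,
#'   `sign`, `slope`).
#' @export
simulate_expression_studies <- function(cfg, index) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!inherits(index, "phenotype_index") || nrow(index) == 0L) {
    stop_data("index must be a nonempty phenotype_index")
  }
  if (cfg$planted_slope == 0 && cfg$n_planted_genes > 0L) {
    ps_warn("planted_slope is 0: planted genes are indistinguishable from null")
  }
  set.seed(stage_seed(cfg$seed, "expression"))

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  planted <- sort(sample.int(cfg$n_genes, cfg$n_planted_genes))
  sign_g <- integer(cfg$n_genes)
  sign_g[planted] <- sample(c(-1L, 1L), length(planted), replace = TRUE)

  r_centred <- index$midrank - mean(index$midrank)
  # per-sample noise giving SD(mean(case) - mean(control)) = noise_sd
  sample_sd <- cfg$noise_sd / sqrt(1 / cfg$n_case + 1 / cfg$n_control)
  baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)

  studies <- vector("list", nrow(index))
  names(studies) <- index$disease_id
  for (d in seq_len(nrow(index))) {
    mu <- sign_g * cfg$planted_slope * r_centred[d]
    keep <- stats::runif(cfg$n_genes) >= cfg$missing_fraction
    if (!any(keep)) keep[sample.int(cfg$n_genes, 1L)] <- TRUE
    ng <- sum(keep)
    ctrl <- matrix(baseline[keep], ng, cfg$n_control) +
      matrix(stats::rnorm(ng * cfg$n_control, sd = sample_sd), ng, cfg$n_control)
    case <- matrix(baseline[keep] + mu[keep], ng, cfg$n_case) +
      matrix(stats::rnorm(ng * cfg$n_case, sd = sample_sd), ng, cfg$n_case)
    rownames(case) <- rownames(ctrl) <- genes[keep]
    colnames(case) <- sprintf("case_%d", seq_len(cfg$n_case))
    colnames(ctrl) <- sprintf("ctrl_%d", seq_len(cfg$n_control))
    studies[[d]] <- expression_study(index$disease_id[d], genes[keep],
                                     case, ctrl)
  }

  registry <- data.frame(gene_id = genes,
                         planted = seq_len(cfg$n_genes) %in% planted,
                         sign = sign_g,
                         slope = ifelse(seq_len(cfg$n_genes) %in% planted,
                                        cfg$planted_slope, 0),
                         stringsAsFactors = FALSE)
  list(studies = studies, registry = registry)
}

#' Construct an expression study object
#'
#' A per-disease case/control study on the log2 intensity scale. Both
#' matrices must share row (gene) names and contain at least one sample.
#'
#' @param disease_id Disease identifier.
#' @param gene_ids Character vector of gene identifiers (row order).
#' @param case_matrix,control_matrix Numeric matrices, genes x samples.
#' @return An `expression_study` list.
#' @export
expression_study <- function(disease_id, gene_ids, case_matrix, control_matrix) {
  case_matrix <- as.matrix(case_matrix)
  control_matrix <- as.matrix(control_matrix)
  if (nrow(case_matrix) != length(gene_ids) ||
      nrow(control_matrix) != length(gene_ids)) {
    stop_data("case and control matrices must have one row per gene")
  }
  if (ncol(case_matrix) < 1L || ncol(control_matrix) < 1L) {
    stop_data("each group needs at least one sample")
  }
  structure(list(disease_id = disease_id, gene_ids = as.character(gene_ids),
                 case_matrix = case_matrix, control_matrix = control_matrix),
            class = "expression_study")
}
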