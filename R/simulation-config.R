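#' Configuration for the synthetic data generators
#'
#' Collects and validates every parameter of the synthetic inputs: citation
#' counts with heterogeneous phenotype propensity, case/control expression
#' studies with genes planted to trend with the index, and an MZ/DZ twin
#' cohort with shared-environment correlation, group-specific residual
#' variances and planted (optionally male-specific) SNP effects. The same
#' seed always yields byte-identical outputs.
#'
#' @param seed Integer seed governing all generators.
#' @param n_diseases Number of diseases in the citation table.
#' @param n_genes Genes per expression study.
#' @param n_planted_genes Genes whose fold change trends monotonically with
#'   the index midrank (sign randomized per gene).
#' @param planted_slope Expected change in log2 fold change per index rank
#'   step for planted genes.
#' @param noise_sd Standard deviation of the per-gene, per-disease fold-change
#'   noise (the sampling noise of the case-minus-control mean difference).
#' @param missing_fraction Probability that a gene is absent from a given
#'   disease study, in `[0, 1)`.
#' @param n_case,n_control Samples per group in each expression study.
#' @param citation_mean_total Mean of the (negative-binomial) total citation
#'   count per disease.
#' @param propensity_zero_prob Probability a disease has phenotype propensity
#'   exactly 0 (never co-cited); gives the point mass of near-zero ratios.
#' @param propensity_shape1,propensity_shape2 Beta parameters of the non-zero
#'   phenotype propensity; the default `Beta(0.6, 4)` is right-skewed with
#'   most mass near 0 and occasional values near 1.
#' @param propensity Optional fixed propensity applied to every disease,
#'   overriding the mixture (used to force degenerate ratio distributions).
#' @param n_pairs Number of twin pairs.
#' @param prop_mz Proportion of pairs that are monozygotic.
#' @param singleton_fraction Singleton individuals, as a fraction of the
#'   paired individual count, appended to the cohort.
#' @param n_snps Number of simulated SNPs.
#' @param maf_vector Minor allele frequencies, length `n_snps`, each in
#'   `(0, 0.5]`.
#' @param causal_snps Indices of SNPs carrying a phenotype effect.
#' @param beta_snp Effect per minor allele on the (transformed) causal
#'   phenotype scale.
#' @param sex_specific If `TRUE` the SNP effect applies to males only.
#' @param beta_sex,beta_dep Fixed covariate effects (sex coded -1 male /
#'   1 female; depression per Beck-scale point).
#' @param var_components Named individual-level residual variances for the
#'   pair groups `MZ-M`, `MZ-F`, `DZ-M`, `DZ-F`, `DZ-mixed`.
#' @param pair_env_corr Fraction of residual variance shared within a pair
#'   (common environment), in `[0, 1)`.
#' @param causal_phenotype Which phenotype carries the SNP effect (on its
#'   analysis scale; cold times are modelled on the log scale).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_diseases = 40L,
                              n_genes = 500L,
                              n_planted_genes = 25L,
                              planted_slope = 0.05,
                              noise_sd = 0.3,
                              missing_fraction = 0.1,
                              n_case = 4L,
                              n_control = 4L,
                              citation_mean_total = 200,
                              propensity_zero_prob = 0.3,
                              propensity_shape1 = 0.6,
                              propensity_shape2 = 4,
                              propensity = NULL,
                              n_pairs = 90L,
                              prop_mz = 0.7,
                              singleton_fraction = 0.05,
                              n_snps = 5L,
                              maf_vector = rep(0.3, n_snps),
                              causal_snps = 1L,
                              beta_snp = 0.5,
                              sex_specific = FALSE,
                              beta_sex = 0.3,
                              beta_dep = -0.01,
                              var_components = c("MZ-M" = 0.8, "MZ-F" = 1.0,
                                                 "DZ-M" = 1.2, "DZ-F" = 1.4,
                                                 "DZ-mixed" = 1.3),
                              pair_env_corr = 0.3,
                              causal_phenotype = "cold_thresh_s") {
  cfg <- list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
              n_genes = as.integer(n_genes),
              n_planted_genes = as.integer(n_planted_genes),
              planted_slope = planted_slope, noise_sd = noise_sd,
              missing_fraction = missing_fraction,
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              citation_mean_total = citation_mean_total,
              propensity_zero_prob = propensity_zero_prob,
              propensity_shape1 = propensity_shape1,
              propensity_shape2 = propensity_shape2,
              propensity = propensity,
              n_pairs = as.integer(n_pairs), prop_mz = prop_mz,
              singleton_fraction = singleton_fraction,
              n_snps = as.integer(n_snps), maf_vector = maf_vector,
              causal_snps = as.integer(causal_snps), beta_snp = beta_snp,
              sex_specific = isTRUE(sex_specific),
              beta_sex = beta_sex, beta_dep = beta_dep,
              var_components = var_components,
              pair_env_corr = pair_env_corr,
              causal_phenotype = causal_phenotype)

  chk <- function(ok, msg) if (!ok) stop_config(msg)
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed must be a single integer")
  chk(cfg$n_diseases >= 2L, "n_diseases must be >= 2")
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(cfg$n_planted_genes >= 0L && cfg$n_planted_genes <= cfg$n_genes,
      "n_planted_genes must lie in [0, n_genes]")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$missing_fraction >= 0 && cfg$missing_fraction < 1,
      "missing_fraction must lie in [0, 1)")
  chk(cfg$n_case >= 1L && cfg$n_control >= 1L,
      "n_case and n_control must be >= 1")
  chk(cfg$citation_mean_total > 1, "citation_mean_total must exceed 1")
  chk(cfg$propensity_zero_prob >= 0 && cfg$propensity_zero_prob < 1,
      "propensity_zero_prob must lie in [0, 1)")
  chk(cfg$propensity_shape1 > 0 && cfg$propensity_shape2 > 0,
      "propensity Beta shapes must be positive")
  if (!is.null(cfg$propensity)) {
    chk(all(cfg$propensity >= 0 & cfg$propensity <= 1),
        "fixed propensity must lie in [0, 1]")
  }
  chk(cfg$n_pairs >= 1L, "n_pairs must be >= 1")
  chk(cfg$prop_mz >= 0 && cfg$prop_mz <= 1, "prop_mz must lie in [0, 1]")
  chk(cfg$singleton_fraction >= 0 && cfg$singleton_fraction < 1,
      "singleton_fraction must lie in [0, 1)")
  chk(length(cfg$maf_vector) == cfg$n_snps,
      "maf_vector length must equal n_snps")
  chk(all(cfg$maf_vector > 0 & cfg$maf_vector <= 0.5),
      "minor allele frequencies must lie in (0, 0.5]")
  chk(all(cfg$causal_snps >= 1L & cfg$causal_snps <= cfg$n_snps),
      "causal_snps must index into 1..n_snps")
  need <- c("MZ-M", "MZ-F", "DZ-M", "DZ-F", "DZ-mixed")
  chk(all(need %in% names(cfg$var_components)) &&
        all(cfg$var_components > 0),
      "var_components must name positive variances for MZ-M, MZ-F, DZ-M, DZ-F, DZ-mixed")
  chk(cfg$pair_env_corr >= 0 && cfg$pair_env_corr < 1,
      "pair_env_corr must lie in [0, 1)")
  chk(cfg$causal_phenotype %in% c("heat_c", "cold_thresh_s", "cold_tol_s"),
      "causal_phenotype must be one of heat_c, cold_thresh_s, cold_tol_s")

  structure(cfg, class = "sim_config")
}

#' Closed-form mean of the configured phenotype-propensity mixture
#'
#' The propensity is 0 with probability `propensity_zero_prob` and otherwise
#' `Beta(shape1, shape2)`, so the mean is
#' `(1 - p0) * shape1 / (shape1 + shape2)` (or the fixed propensity mean when
#' one is forced). Used as the analytic reference for the simulated
#' citation-ratio distribution.
#'
#' @param cfg A `sim_config`.
#' @return Expected phenotype propensity (= expected co-citation ratio).
#' @export
propensity_mean <- function(cfg) {
  if (!is.null(cfg$propensity)) return(mean(cfg$propensity))
  (1 - cfg$propensity_zero_prob) *
    cfg$propensity_shape1 / (cfg$propensity_shape1 + cfg$propensity_shape2)
}

# Derive a reproducible sub-seed for a named stage from the global seed, kept
# within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(citations = 101L, expression = 211L, twins = 307L,
               de = 401L, correlate = 503L, validate = 601L, assoc = 701L)
  off <- unname(offsets[stage])
  if (is.na(off)) off <- 997L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}
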