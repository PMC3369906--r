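#' Simulate disease citation-count records
#'
#' Emulates the raw material of the phenotype index: per-disease total
#' citation counts and the number co-annotated with the phenotype heading.
#' Each disease draws a latent phenotype propensity from a zero-inflated
#' Beta mixture (a point mass at 0 plus a right-skewed Beta), so that
#' co-citation ratios span `[0, 1]` with most mass near 0, a tail of highly
#' phenotype-specific diseases, and some diseases with no co-citation at all
#' (which the index-building inclusion rule must drop).
#'
#' @param cfg A [simulation_config()].
#' @return Data frame with columns `disease_id`, `disease_name`, `n_total`,
#'   `n_phenotype` and the latent `propensity` (kept for test oracles).
#' @export
simulate_citations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_diseases
  set.seed(stage_seed(cfg$seed, "citations"))
  n_total <- 1L + stats::rnbinom(n, size = 0.5, mu = cfg$citation_mean_total - 1)
  if (is.null(cfg$propensity)) {
    zero <- stats::runif(n) < cfg$propensity_zero_prob
    prop <- ifelse(zero, 0,
                   stats::rbeta(n, cfg$propensity_shape1, cfg$propensity_shape2))
  } else {
    prop <- rep_len(cfg$propensity, n)
  }
  n_phenotype <- stats::rbinom(n, n_total, prop)
  data.frame(
    disease_id = sprintf("D%04d", seq_len(n)),
    disease_name = sprintf("synthetic disease %d", seq_len(n)),
    n_total = n_total,
    n_phenotype = n_phenotype,
    propensity = prop,
    stringsAsFactors = FALSE
  )
}
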