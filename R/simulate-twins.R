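#' Simulate a twin cohort with genotypes and pain phenotypes
#'
#' Generates MZ/DZ twin pairs (plus optional singletons) with SNP genotypes
#' drawn under Hardy-Weinberg equilibrium by explicit parental-haplotype
#' transmission: MZ co-twins share one genotype draw, DZ co-twins each
#' inherit one allele from each simulated parent, giving the expected 0.5
#' genotype correlation with exactly valid 0/1/2 dosages. Phenotypes follow
#' the heteroscedastic pair-group model used by the association stage:
#' on the analysis scale (log seconds for cold times, degrees C for heat),
#'
#' \code{y = intercept + beta_snp * dosage (* male indicator if sex-specific)
#'        + beta_sex * sex + beta_dep * depression + pair-shared env + resid}
#'
#' with individual-level residual variance taken from `var_components` for
#' the pair's zygosity-sex group, split into a pair-shared component
#' (`pair_env_corr` of the variance) and an individual remainder. Cold pain
#' threshold times are censored at the 180 s test ceiling, which exercises
#' the downstream outlier rule.
#'
#' @param cfg A [simulation_config()].
#' @return A `twin_cohort` list: `individuals` (data frame: `individual_id`,
#'   `pair_id`, `zygosity`, `sex`, `heat_c`, `cold_thresh_s`, `cold_tol_s`,
#'   `depression`), `genotypes` (SNP x individual dosage matrix of the minor
#'   allele), `snp_info` (data frame: `snp_id`, `position`, `maf`), and
#'   `registry` (data frame of causal SNPs: `snp_id`, `beta`, `phenotype`,
#'   `sex_specific`).
#' @export
simulate_twin_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "twins"))
  np <- cfg$n_pairs
  ns <- round(2 * np * cfg$singleton_fraction)
  n_ind <- 2L * np + ns

  zyg_pair <- ifelse(stats::runif(np) < cfg$prop_mz, "MZ", "DZ")
  sex_pair1 <- ifelse(stats::runif(np) < 0.5, "M", "F")
  sex_pair2 <- ifelse(zyg_pair == "MZ", sex_pair1,
                      ifelse(stats::runif(np) < 0.5, "M", "F"))
  sex_single <- ifelse(stats::runif(ns) < 0.5, "M", "F")

  individual_id <- c(sprintf("T%03d_%d", rep(seq_len(np), each = 2L), 1:2),
                     if (ns > 0) sprintf("S%03d", seq_len(ns)))
  pair_id <- c(sprintf("P%03d", rep(seq_len(np), each = 2L)),
               if (ns > 0) rep(NA_character_, ns))
  zygosity <- c(rep(zyg_pair, each = 2L), if (ns > 0) rep(NA_character_, ns))
  sex <- c(as.vector(rbind(sex_pair1, sex_pair2)), sex_single)

  # genotypes: parental transmission per pair, HWE draw for singletons
  G <- matrix(NA_integer_, cfg$n_snps, n_ind)
  for (j in seq_len(cfg$n_snps)) {
    maf <- cfg$maf_vector[j]
    fa <- matrix(stats::rbinom(2L * np, 1L, maf), np, 2L)
    mo <- matrix(stats::rbinom(2L * np, 1L, maf), np, 2L)
    pick <- function(hap, n) hap[cbind(seq_len(n), stats::rbinom(n, 1L, 0.5) + 1L)]
    g1 <- pick(fa, np) + pick(mo, np)
    g2 <- ifelse(zyg_pair == "MZ", g1, pick(fa, np) + pick(mo, np))
    g_single <- if (ns > 0) stats::rbinom(ns, 2L, maf) else integer(0)
    G[j, ] <- c(as.vector(rbind(g1, g2)), g_single)
  }
  rownames(G) <- sprintf("rs%05d", seq_len(cfg$n_snps))
  colnames(G) <- individual_id

  depression <- pmin(63L, stats::rnbinom(n_ind, size = 2, mu = 8))
  sex_code <- ifelse(sex == "M", -1, 1)

  pair_group <- function(zyg, s1, s2) {
    ifelse(zyg == "MZ", paste0("MZ-", s1),
           ifelse(s1 == s2, paste0("DZ-", s1), "DZ-mixed"))
  }
  grp_pair <- pair_group(zyg_pair, sex_pair1, sex_pair2)
  # individual-level residual variance by pair group; singletons use the
  # same-sex DZ component (no co-twin to share environment with)
  v_ind <- c(rep(cfg$var_components[grp_pair], each = 2L),
             if (ns > 0) cfg$var_components[paste0("DZ-", sex_single)])
  rho <- cfg$pair_env_corr
  shared_pair <- stats::rnorm(np, sd = sqrt(rho * cfg$var_components[grp_pair]))
  shared <- c(rep(shared_pair, each = 2L),
              if (ns > 0) stats::rnorm(ns, sd = sqrt(rho * v_ind[2L * np + seq_len(ns)])))
  resid <- stats::rnorm(n_ind, sd = sqrt((1 - rho) * v_ind))

  male_ind <- as.numeric(sex == "M")
  snp_effect <- numeric(n_ind)
  for (j in cfg$causal_snps) {
    eff <- cfg$beta_snp * G[j, ]
    if (cfg$sex_specific) eff <- eff * male_ind
    snp_effect <- snp_effect + eff
  }
  lin <- cfg$beta_sex * sex_code + cfg$beta_dep * depression + shared + resid

  intercepts <- c(heat_c = 46, cold_thresh_s = log(12), cold_tol_s = log(45))
  mk <- function(pheno) {
    base <- intercepts[[pheno]] + lin +
      if (cfg$causal_phenotype == pheno) snp_effect else 0
    switch(pheno,
           heat_c = base,
           cold_thresh_s = pmin(exp(base), 180),
           cold_tol_s = exp(base))
  }

  individuals <- data.frame(
    individual_id = individual_id, pair_id = pair_id,
    zygosity = zygosity, sex = sex,
    heat_c = mk("heat_c"),
    cold_thresh_s = mk("cold_thresh_s"),
    cold_tol_s = mk("cold_tol_s"),
    depression = as.integer(depression),
    stringsAsFactors = FALSE
  )
  registry <- data.frame(snp_id = rownames(G)[cfg$causal_snps],
                         beta = cfg$beta_snp,
                         phenotype = cfg$causal_phenotype,
                         sex_specific = cfg$sex_specific,
                         stringsAsFactors = FALSE)
  twin_cohort(individuals, G,
              snp_info = data.frame(snp_id = rownames(G),
                                    position = 1000L * seq_len(cfg$n_snps),
                                    maf = cfg$maf_vector,
                                    stringsAsFactors = FALSE),
              registry = registry)
}

#' Construct a twin cohort object
#'
#' @param individuals Data frame with columns `individual_id`, `pair_id`,
#'   `zygosity` (`MZ`/`DZ`/`NA`), `sex` (`M`/`F`), phenotypes and
#'   `depression`.
#' @param genotypes SNP x individual matrix of dosages in `{0, 1, 2, NA}`;
#'   column names must match `individual_id`.
#' @param snp_info Optional data frame with `snp_id` and `position`.
#' @param registry Optional data frame of simulated causal SNPs.
#' @return A `twin_cohort` list.
#' @export
twin_cohort <- function(individuals, genotypes, snp_info = NULL,
                        registry = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(colnames(genotypes) == individuals$individual_id)) {
    stop_data("genotype columns must match individuals$individual_id")
  }
  tab <- table(individuals$pair_id)
  if (any(tab > 2L)) stop_data("pair_id groups must have size <= 2")
  structure(list(individuals = individuals, genotypes = genotypes,
                 snp_info = snp_info, registry = registry),
            class = "twin_cohort")
}
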