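test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_diseases = 1), class = "painscreen_config_error")
  expect_error(simulation_config(n_planted_genes = 1000, n_genes = 10),
               class = "painscreen_config_error")
  expect_error(simulation_config(missing_fraction = 1), class = "painscreen_config_error")
  expect_error(simulation_config(maf_vector = c(0.3, 0.6), n_snps = 2),
               class = "painscreen_config_error")
  expect_error(simulation_config(pair_env_corr = 1), class = "painscreen_config_error")
})

test_that("identical seeds give identical synthetic outputs", {
  cfg <- simulation_config(seed = 7, n_diseases = 30, n_genes = 50,
                           n_planted_genes = 5, n_pairs = 20, n_snps = 3,
                           maf_vector = rep(0.3, 3))
  c1 <- simulate_citations(cfg)
  c2 <- simulate_citations(cfg)
  expect_identical(c1, c2)
  idx <- build_index(c1)
  e1 <- simulate_expression_studies(cfg, idx)
  e2 <- simulate_expression_studies(cfg, idx)
  expect_identical(e1, e2)
  t1 <- simulate_twin_cohort(cfg)
  t2 <- simulate_twin_cohort(cfg)
  expect_identical(t1, t2)
})

test_that("citation counts respect bounds and the propensity mixture shape", {
  cfg <- simulation_config(seed = 1, n_diseases = 200)
  cit <- simulate_citations(cfg)
  expect_true(all(cit$n_total >= 1))
  expect_true(all(cit$n_phenotype >= 0 & cit$n_phenotype <= cit$n_total))
  expect_gt(sum(cit$n_phenotype == 0), 0)       # inclusion rule exercised
  # forced propensity 1 makes every ratio 1
  all1 <- simulate_citations(simulation_config(seed = 2, n_diseases = 50,
                                               propensity = 1))
  expect_true(all(all1$n_phenotype == all1$n_total))
})

test_that("empirical ratio mean matches the closed-form mixture mean", {
  cfg <- simulation_config(seed = 7, n_diseases = 1000)
  cit <- simulate_citations(cfg)
  ratio <- cit$n_phenotype / cit$n_total
  mc_se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - propensity_mean(cfg)), 3 * mc_se)
})

test_that("planted fold changes are monotone in rank in the noiseless limit", {
  cfg <- simulation_config(seed = 3, n_diseases = 15, n_genes = 40,
                           n_planted_genes = 8, noise_sd = 0,
                           missing_fraction = 0)
  idx <- tiny_index(15)
  sim <- simulate_expression_studies(cfg, idx)
  fc <- sapply(sim$studies, fold_change)     # genes x diseases, index order
  reg <- sim$registry
  for (g in which(reg$planted)) {
    expect_equal(abs(cor(fc[g, ], idx$midrank, method = "spearman")), 1)
  }
  # null genes carry no rank signal at noise 0: constant zero fold change
  expect_equal(max(abs(fc[!reg$planted, ])), 0)
})

test_that("planted genes out-correlate null genes at moderate signal-to-noise", {
  cfg <- simulation_config(seed = 11, n_genes = 500, n_planted_genes = 25)
  idx <- tiny_index(cfg$n_diseases)
  sim <- simulate_expression_studies(cfg, idx)
  genes <- sim$registry$gene_id
  fc <- sapply(sim$studies, function(s) {
    v <- setNames(rep(NA_real_, length(genes)), genes)
    f <- fold_change(s)
    v[names(f)] <- f
    v
  })
  rho <- apply(fc, 1L, function(v) {
    obs <- !is.na(v)
    cor(v[obs], idx$midrank[obs], method = "spearman")
  })
  reg <- sim$registry
  expect_gt(mean(abs(rho[reg$planted]), na.rm = TRUE),
            mean(abs(rho[!reg$planted]), na.rm = TRUE))
  expect_warning(simulate_expression_studies(
    simulation_config(seed = 1, planted_slope = 0, n_genes = 20,
                      n_planted_genes = 2), idx),
    class = "painscreen_warning")
})

test_that("twin genotypes have MZ identity, DZ half-sharing and HWE frequencies", {
  cfg <- simulation_config(seed = 5, n_pairs = 300, n_snps = 20,
                           maf_vector = runif(20, 0.1, 0.5),
                           singleton_fraction = 0)
  co <- simulate_twin_cohort(cfg)
  ind <- co$individuals
  first <- !duplicated(ind$pair_id)
  mz <- ind$zygosity == "MZ"
  id1 <- ind$individual_id[first & mz]
  id2 <- ind$individual_id[!first & mz]
  expect_true(all(co$genotypes[, id1] == co$genotypes[, id2]))
  d1 <- ind$individual_id[first & !mz]
  d2 <- ind$individual_id[!first & !mz]
  r_dz <- cor(as.vector(co$genotypes[, d1]), as.vector(co$genotypes[, d2]))
  expect_lt(abs(r_dz - 0.5), 0.1)
  # per-SNP HWE consistency on deduplicated genomes over replicates
  pvals <- unlist(lapply(1:5, function(s) {
    cc <- simulate_twin_cohort(simulation_config(
      seed = 100 + s, n_pairs = 250, n_snps = 20,
      maf_vector = runif(20, 0.1, 0.5), singleton_fraction = 0))
    g <- cc$genotypes[, !duplicated(cc$individuals$pair_id) |
                        cc$individuals$zygosity != "MZ"]
    apply(g, 1L, function(x) hwe_test(sum(x == 0), sum(x == 1), sum(x == 2)))
  }))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("a planted SNP effect is detected at the analytically predicted power", {
  # normal-approximation oracle: GLS information from group mixture
  maf <- 0.3
  rho <- 0.3
  vc <- c("MZ-M" = 0.8, "MZ-F" = 1.0, "DZ-M" = 1.2, "DZ-F" = 1.4,
          "DZ-mixed" = 1.3)
  prop <- c("MZ-M" = 0.35, "MZ-F" = 0.35, "DZ-M" = 0.075, "DZ-F" = 0.075,
            "DZ-mixed" = 0.15)
  v_pair <- rho * vc + (1 - rho) * vc / 2
  var_gbar <- ifelse(grepl("MZ", names(vc)), 2 * maf * (1 - maf),
                     1.5 * maf * (1 - maf))
  n_pairs <- 200
  info <- n_pairs * sum(prop * var_gbar / v_pair)
  se <- 1 / sqrt(info)
  beta <- (qnorm(0.975) + qnorm(0.80)) * se   # ~80% power at alpha 0.05
  power_analytic <- pnorm(beta / se - qnorm(0.975)) +
    pnorm(-beta / se - qnorm(0.975))

  n_rep <- 500
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 20000 + i, n_pairs = n_pairs, n_snps = 1,
                             maf_vector = maf, beta_snp = beta,
                             causal_phenotype = "heat_c",
                             singleton_fraction = 0)
    co <- simulate_twin_cohort(cfg)
    u <- encode_units(co, "heat_c", "identity")
    rej[i] <- gls_fit(u, "rs00001")$p_raw < 0.05
  }
  # binomial MC band plus an allowance for the normal approximation and the
  # finite-sample SE correction, both of which shave a little power
  half_width <- 1.96 * sqrt(power_analytic * (1 - power_analytic) / n_rep)
  expect_lt(abs(mean(rej) - power_analytic), half_width + 0.04)
})
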