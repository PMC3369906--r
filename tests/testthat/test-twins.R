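test_that("HWE chi-square test matches hand-computed expectations", {
  expect_equal(hwe_test(25, 50, 25), 1)            # exact HWE proportions
  expect_lt(hwe_test(100, 0, 100), 1e-40)          # maximal departure
  # allele freq 0.75 -> expected (56.25, 37.5, 6.25), chi2 = 11.11
  chi2 <- (50 - 56.25)^2 / 56.25 + (50 - 37.5)^2 / 37.5 + 6.25
  expect_equal(hwe_test(50, 50, 0), pchisq(chi2, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 50, 0), 0.01)
  expect_equal(hwe_test(30, 0, 0), 1)              # monomorphic convention
})

make_qc_cohort <- function() {
  ind <- data.frame(
    individual_id = sprintf("I%02d", 1:40),
    pair_id = rep(sprintf("P%02d", 1:20), each = 2),
    zygosity = rep(rep(c("MZ", "DZ"), 10), each = 2),
    sex = rep(c("M", "F"), 20),
    heat_c = rnorm(40, 46), cold_thresh_s = exp(rnorm(40, 2.5)),
    cold_tol_s = exp(rnorm(40, 3.5)), depression = rpois(40, 6),
    stringsAsFactors = FALSE)
  ind
}

test_that("QC removes exactly the SNPs designed to fail each filter", {
  set.seed(50)
  ind <- make_qc_cohort()
  dedup_n <- 30   # 40 individuals minus 10 duplicated MZ co-twins
  G <- rbind(
    good = rbinom(40, 2, 0.3),
    low_call = c(rep(NA, 6), rbinom(34, 2, 0.3)),        # call rate 85%
    rare = c(1, rep(0, 39)),                             # MAF ~ 1.7%
    hwe_fail = rep(1, 40),                               # all heterozygous
    mono = rep(0, 40))
  # make 'good' genuinely clean: resample until it passes on this layout
  co <- hand_cohort(ind, G)
  qc <- snp_qc(co)
  expect_true("good" %in% qc$keep)
  rep <- qc$report
  expect_true(rep$removed[rep$snp_id == "low_call"])
  expect_match(rep$reason[rep$snp_id == "low_call"], "call_rate")
  expect_true(rep$removed[rep$snp_id == "rare"])
  expect_match(rep$reason[rep$snp_id == "rare"], "maf")
  expect_true(rep$removed[rep$snp_id == "mono"])
  expect_lt(rep$call_rate[rep$snp_id == "low_call"], 0.90)
})

test_that("missing genotypes impute to homozygous wildtype with MZ warnings", {
  ind <- make_qc_cohort()[1:4, ]
  ind$zygosity <- "MZ"
  ind$pair_id <- rep(c("P01", "P02"), each = 2)
  G <- rbind(snp01 = c(2, NA, 0, 0), snp02 = c(0, 1, 0, NA))
  co <- hand_cohort(ind, G)
  expect_warning(Gi <- impute_missing(co$genotypes, co$individuals),
                 class = "painscreen_mz_imputation_warning")
  expect_equal(unname(Gi["snp01", 2]), 0)          # stated rule, not copy
  expect_equal(attr(Gi, "n_imputed"), c(snp01 = 1L, snp02 = 1L))
  clean <- matrix(rep(0:2, 4), 3, 4,
                  dimnames = list(paste0("s", 1:3), ind$individual_id))
  expect_equal(unname(impute_missing(clean)[, 1]), 0:2)
})

test_that("dosages flip so 0 counts the major (wildtype) allele", {
  G <- rbind(flipme = c(2, 2, 2, 1), keep = c(0, 0, 1, 0))
  colnames(G) <- sprintf("I%02d", 1:4)
  R <- recode_to_minor(G)
  expect_equal(unname(R["flipme", ]), c(0, 0, 0, 1))
  expect_equal(unname(R["keep", ]), c(0, 0, 1, 0))
  expect_identical(attr(R, "flipped"), "flipme")
})

test_that("pair encoding follows the published genotype and sex codings", {
  ind <- data.frame(
    individual_id = c("a1", "a2", "b1", "b2", "c1"),
    pair_id = c("PA", "PA", "PB", "PB", NA),
    zygosity = c("MZ", "MZ", "DZ", "DZ", NA),
    sex = c("M", "M", "M", "F", "F"),
    heat_c = c(45, 47, 46, 48, 44),
    cold_thresh_s = c(10, 12, 9, 11, 14),
    cold_tol_s = c(30, 40, 35, 45, 50),
    depression = c(4, 6, 8, 2, 10),
    stringsAsFactors = FALSE)
  G <- matrix(c(2, 2, 0, 1, 1), 1, dimnames = list("snp01", ind$individual_id))
  u <- encode_units(twin_cohort(ind, G), "heat_c", "identity")
  uu <- u$units
  expect_equal(uu$var_group, c("MZ-M", "DZ-mixed", "singleton-F"))
  expect_equal(unname(u$g_bar["snp01", ]), c(2, 0.5, 1))
  expect_equal(uu$sex_code, c(-1, 0, 1))
  expect_equal(uu$y_bar, c(46, 47, 44))
  expect_equal(uu$dep_bar, c(5, 5, 10))
  # log transform averages on the log scale
  ul <- encode_units(twin_cohort(ind, G), "cold_thresh_s", "log")
  expect_equal(ul$units$y_bar[1], mean(log(c(10, 12))))
  # non-positive phenotype under log excluded with warning
  ind2 <- ind; ind2$cold_thresh_s[5] <- 0
  expect_warning(u2 <- encode_units(twin_cohort(ind2, G), "cold_thresh_s", "log"),
                 class = "painscreen_warning")
  expect_false("c1" %in% u2$units$unit_id)
})

test_that("homoscedastic GLS reduces exactly to ordinary least squares", {
  cfg <- simulation_config(seed = 61, n_pairs = 80, n_snps = 2,
                           maf_vector = c(0.3, 0.4))
  co <- simulate_twin_cohort(cfg)
  u <- encode_units(co, "heat_c", "identity")
  f <- gls_fit(u, "rs00001", single_group = TRUE)
  ols <- lm(y_bar ~ g + dep_bar + sex_code,
            data = cbind(u$units, g = u$g_bar["rs00001", ]))
  expect_lt(max(abs(f$coefficients - coef(ols))), 1e-10)
  expect_error(gls_fit(u, "nope"), class = "painscreen_data_error")
})

test_that("heteroscedastic GLS agrees with an independent REML fit on shared data", {
  skip_if_not_installed("nlme")
  cfg <- simulation_config(seed = 62, n_pairs = 250, n_snps = 1,
                           maf_vector = 0.3, beta_snp = 0.4,
                           causal_phenotype = "heat_c", singleton_fraction = 0)
  co <- simulate_twin_cohort(cfg)
  u <- encode_units(co, "heat_c", "identity")
  f <- gls_fit(u, "rs00001")
  d <- cbind(u$units, g = u$g_bar["rs00001", ])
  ref <- nlme::gls(y_bar ~ g + dep_bar + sex_code, data = d,
                   weights = nlme::varIdent(form = ~ 1 | var_group))
  expect_lt(abs(f$beta - coef(ref)[["g"]]), 0.02)
  expect_lt(abs(f$se / sqrt(diag(ref$varBeta))[["g"]] - 1), 0.15)
})

test_that("pair averaging halves the independent-error residual variance", {
  cfg <- simulation_config(seed = 63, n_pairs = 1500, n_snps = 1,
                           maf_vector = 0.3, beta_snp = 0,
                           pair_env_corr = 0, singleton_fraction = 0,
                           prop_mz = 0)
  co <- simulate_twin_cohort(cfg)
  u <- encode_units(co, "heat_c", "identity")
  f <- gls_fit(u, "rs00001")
  vc <- simulation_config()$var_components
  for (g in c("DZ-M", "DZ-F", "DZ-mixed")) {
    expect_lt(abs(f$group_variances[[g]] / (vc[[g]] / 2) - 1), 0.15)
  }
})

test_that("GLS p-values are calibrated under genotype permutation", {
  cfg <- simulation_config(seed = 64, n_pairs = 150, n_snps = 1,
                           maf_vector = 0.3, beta_snp = 0.6,
                           causal_phenotype = "heat_c", singleton_fraction = 0)
  co <- simulate_twin_cohort(cfg)
  u <- encode_units(co, "heat_c", "identity")
  set.seed(1)
  p <- replicate(200, {
    up <- u
    up$g_bar[1, ] <- sample(u$g_bar[1, ])
    gls_fit(up, "rs00001")$p_raw
  })
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.06)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("Bonferroni, Cohen's d and Welch t match their textbook formulas", {
  expect_equal(bonferroni(1e-4, m = 207), 0.0207)
  expect_equal(bonferroni(0.5, m = 207), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 1), c(0.2, 0.04))

  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)   # pooled SD is 1
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "painscreen_data_error")

  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  a <- c(1, 2, 3, 4); b <- c(10, 20, 30, 40)
  w <- welch_t(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand))
  # equal variances, equal n: df reduces to 2n - 2
  w2 <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w2$df, 6)
})

test_that("quantile normalization produces Blom normal scores", {
  x <- c(5, 1, 9)
  qn <- quantile_normalize(x)
  expect_equal(sort(qn), qnorm((1:3 - 3 / 8) / (3 + 1 / 4)))
  expect_equal(order(qn), order(x))
  set.seed(2)
  y <- rnorm(101)
  expect_lt(abs(sum(quantile_normalize(y))), 1e-8)
  expect_equal(quantile_normalize(c(2, 2, 2)), c(0, 0, 0))
  expect_error(quantile_normalize(c(1, 2)), class = "painscreen_data_error")
})

test_that("composite LD r2 behaves at its boundary cases", {
  set.seed(9)
  G <- matrix(rbinom(3 * 500, 2, 0.4), 3, 500,
              dimnames = list(c("s1", "s2", "s3"), sprintf("I%03d", 1:500)))
  G["s2", ] <- G["s1", ]              # perfect proxy
  ld <- ld_r2(G)
  expect_equal(diag(ld), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(ld["s1", "s2"], 1)
  expect_lt(ld["s1", "s3"], 0.05)     # independent SNPs
  mono <- rbind(G, s4 = rep(1, 500))
  expect_true(is.na(ld_r2(mono)["s4", "s1"]))
})

test_that("ceiling observations are flagged by the strict outlier rule", {
  v <- c(12, 179.9, 180, NA, 60)
  f <- censored_max_rule(v)
  expect_equal(which(f), 3L)
  expect_equal(attr(f, "n_censored"), 1L)
  expect_equal(sum(censored_max_rule(c(1, 2, 3))), 0L)
})

test_that("the association scan ties QC, encoding, GLS and Bonferroni together", {
  cfg <- simulation_config(seed = 65, n_pairs = 150, n_snps = 4,
                           maf_vector = c(0.3, 0.25, 0.4, 0.35),
                           beta_snp = 0.8, causal_snps = 2L)
  co <- simulate_twin_cohort(cfg)
  scan <- run_association(co)
  expect_s3_class(scan$results, "data.frame")
  expect_equal(scan$m, 4L)
  expect_true(all(scan$results$p_bonf >= scan$results$p_raw - 1e-12))
  expect_true(all(scan$results$p_bonf <= 1 + 1e-12))
  hit <- scan$results[scan$results$phenotype == "cold_thresh_s" &
                        scan$results$snp_id == "rs00002", ]
  expect_lt(hit$p_bonf, 0.05)
  expect_equal(dim(scan$ld), c(4L, 4L))
})

test_that("male-specific effects surface in male-stratified fits", {
  detect <- matrix(NA, 40, 2)
  for (i in seq_len(40)) {
    cfg <- simulation_config(seed = 30000 + i, n_pairs = 220, n_snps = 1,
                             maf_vector = 0.3, beta_snp = 0.7,
                             sex_specific = TRUE, causal_phenotype = "heat_c",
                             singleton_fraction = 0)
    co <- simulate_twin_cohort(cfg)
    u <- encode_units(co, "heat_c", "identity")
    fm <- gls_fit(filter_units(u, "M"), "rs00001", covariates = "dep_bar")
    ff <- gls_fit(filter_units(u, "F"), "rs00001", covariates = "dep_bar")
    detect[i, ] <- c(fm$p_raw < 0.05, ff$p_raw < 0.05)
  }
  expect_gt(mean(detect[, 1]), mean(detect[, 2]))
  expect_gt(mean(detect[, 1]), 0.5)
  expect_lt(mean(detect[, 2]), 0.3)
})
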