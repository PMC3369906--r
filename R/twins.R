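#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the `p^2, 2pq, q^2` expectation, with the allele frequency estimated from
#' the counts. A monomorphic SNP returns p = 1 by convention (no departure
#' is testable).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (AA = dosage 0, Aa = 1, aa = 2).
#' @return The chi-square p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_data("HWE test needs at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# one representative individual per MZ pair (first by column order), all
# DZ/singleton individuals kept; avoids double-counting duplicated genomes
# in allele-frequency, HWE and LD computations
mz_dedup_ids <- function(individuals) {
  mz <- !is.na(individuals$zygosity) & individuals$zygosity == "MZ" &
    !is.na(individuals$pair_id)
  dup <- mz & duplicated(ifelse(mz, individuals$pair_id, individuals$individual_id))
  individuals$individual_id[!dup]
}

#' SNP quality control
#'
#' Removes SNPs failing any of three filters: call rate below
#' `call_rate_min` (computed over all individuals), minor allele frequency
#' below `maf_min`, or Hardy-Weinberg departure at `hwe_alpha`. Allele
#' frequencies and HWE use one member per MZ pair so duplicated genomes do
#' not bias either.
#'
#' @param cohort A [twin_cohort()].
#' @param call_rate_min Minimum fraction of non-missing genotypes (default 0.90).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_alpha HWE rejection level (default 0.01).
#' @return List: `keep` (SNP ids passing), `report` (data frame: `snp_id`,
#'   `call_rate`, `maf`, `hwe_p`, `removed`, `reason`).
#' @export
snp_qc <- function(cohort, call_rate_min = 0.90, maf_min = 0.05,
                   hwe_alpha = 0.01) {
  stopifnot(inherits(cohort, "twin_cohort"))
  G <- cohort$genotypes
  if (nrow(G) == 0L) stop_data("empty genotype table")
  ded <- G[, mz_dedup_ids(cohort$individuals), drop = FALSE]

  call_rate <- rowMeans(!is.na(G))
  af <- rowMeans(ded, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hwe_p <- apply(ded, 1L, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })

  fail <- cbind(call_rate = call_rate < call_rate_min,
                maf = maf < maf_min,
                hwe = hwe_p < hwe_alpha)
  reason <- apply(fail, 1L, function(f) paste(colnames(fail)[f], collapse = ";"))
  removed <- rowSums(fail) > 0
  if (all(removed)) stop_data("all SNPs removed by QC")
  list(keep = rownames(G)[!removed],
       report = data.frame(snp_id = rownames(G), call_rate = call_rate,
                           maf = maf, hwe_p = hwe_p, removed = removed,
                           reason = reason, stringsAsFactors = FALSE,
                           row.names = NULL))
}

#' Impute missing genotypes with the homozygous wildtype
#'
#' Missing dosages are set to 0, i.e. homozygous for the population
#' wildtype (major) allele — the stated imputation rule of the association
#' stage. When pair metadata is supplied, an MZ co-twin whose observed
#' genotype is non-zero while its partner is imputed to 0 triggers a
#' warning, since the rule then contradicts MZ genotype identity.
#'
#' @param genotypes SNP x individual dosage matrix (0/1/2/NA), oriented so 0
#'   is homozygous wildtype (see [recode_to_minor()]).
#' @param individuals Optional individuals data frame (for MZ-consistency
#'   warnings).
#' @return The completed matrix, with attribute `n_imputed` (per-SNP counts).
#' @export
impute_missing <- function(genotypes, individuals = NULL) {
  G <- genotypes
  n_imputed <- rowSums(is.na(G))
  if (!is.null(individuals) && any(is.na(G))) {
    mz <- individuals[!is.na(individuals$zygosity) &
                        individuals$zygosity == "MZ" &
                        !is.na(individuals$pair_id), ]
    for (pid in unique(mz$pair_id)) {
      ids <- mz$individual_id[mz$pair_id == pid]
      if (length(ids) != 2L) next
      g <- G[, ids, drop = FALSE]
      bad <- rowSums(is.na(g)) == 1L & apply(g, 1L, max, na.rm = TRUE) > 0
      if (any(bad)) {
        ps_warn(sprintf(
          "MZ pair %s: %d missing genotype(s) imputed to wildtype despite a non-wildtype co-twin",
          pid, sum(bad)), class = "painscreen_mz_imputation_warning")
      }
    }
  }
  G[is.na(G)] <- 0
  attr(G, "n_imputed") <- n_imputed
  G
}

#' Orient dosages so 0 counts the wildtype (major) allele
#'
#' The association encoding requires 0/1/2 = homozygous wildtype /
#' heterozygous / homozygous rare. Genotypes read from a VCF count the ALT
#' allele, which need not be the rare one: SNPs whose counted-allele
#' frequency exceeds 0.5 in the cohort are flipped (`2 - g`). At frequency
#' exactly 0.5 the orientation is kept as supplied (the reference allele
#' stays wildtype).
#'
#' @param genotypes SNP x individual dosage matrix.
#' @param individuals Optional individuals data frame; when supplied, allele
#'   frequencies are computed on one member per MZ pair.
#' @return The matrix, flipped where needed; attribute `flipped` names the
#'   recoded SNPs.
#' @export
recode_to_minor <- function(genotypes, individuals = NULL) {
  base <- if (is.null(individuals)) genotypes else
    genotypes[, mz_dedup_ids(individuals), drop = FALSE]
  af <- rowMeans(base, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  genotypes[flip, ] <- 2 - genotypes[flip, , drop = FALSE]
  attr(genotypes, "flipped") <- rownames(genotypes)[flip]
  genotypes
}

#' Flag phenotype values at the test ceiling
#'
#' Observations that reached the maximum allowed time of the cold test are
#' treated as outliers and excluded from association runs.
#'
#' @param values Numeric phenotype values (seconds).
#' @param max_allowed Ceiling (default 180 s, the 3-minute limit).
#' @return Logical vector, `TRUE` where the value is at (or beyond) the
#'   ceiling; attribute `n_censored` carries the count.
#' @export
censored_max_rule <- function(values, max_allowed = 180) {
  if (max_allowed <= 0) stop_config("max_allowed must be positive")
  flag <- !is.na(values) & values >= max_allowed
  attr(flag, "n_censored") <- sum(flag)
  flag
}

#' Rank-based inverse-normal (quantile) transformation
#'
#' Replaces values by normal scores of their midranks with the Blom offset,
#' `qnorm((rank - 3/8) / (n + 1/4))`. Order-preserving; tied values share a
#' score; missing values stay missing. A fully tied vector maps to all
#' zeros.
#'
#' @param values Numeric vector (>= 3 non-missing values).
#' @return Numeric vector of normal scores.
#' @export
quantile_normalize <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3L) stop_data("quantile normalization needs >= 3 non-missing values")
  out <- rep(NA_real_, length(values))
  if (stats::sd(values[ok]) == 0) {
    out[ok] <- 0
    return(out)
  }
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

# map a phenotype transform name to its function
pheno_transform <- function(transform) {
  switch(transform,
         identity = identity,
         log = log,
         `quantile-normal` = quantile_normalize,
         stop_config(sprintf("unknown transform '%s'", transform)))
}

#' Collapse a twin cohort to pair-averaged observations
#'
#' Each complete twin pair becomes a single observation: the phenotype is
#' transformed per individual (identity, log, or quantile-normal) and then
#' averaged within the pair, genotype dosages are averaged (so MZ pairs
#' keep integer dosages and DZ pairs may take half-integer values), the
#' depression covariate is averaged, and sex is coded -1 (male) / 1
#' (female) and averaged, giving 0 for mixed-sex DZ pairs. Singletons pass
#' through unchanged. Each unit carries a variance-group label
#' (`MZ-M`, `MZ-F`, `DZ-M`, `DZ-F`, `DZ-mixed`, `singleton-M`,
#' `singleton-F`) used by the heteroscedastic GLS.
#'
#' Individuals with a non-positive value under the log transform are
#' excluded with a warning; a pair member without a usable phenotype drops
#' out and the remaining member contributes alone.
#'
#' @param cohort A [twin_cohort()] (genotypes should already be imputed and
#'   wildtype-oriented).
#' @param phenotype Column name: `heat_c`, `cold_thresh_s` or `cold_tol_s`.
#' @param transform `"identity"`, `"log"` or `"quantile-normal"`.
#' @param exclude_ids Individual ids to drop beforehand (e.g. ceiling
#'   outliers from [censored_max_rule()]).
#' @return List of class `pair_units`: `units` (data frame: `unit_id`,
#'   `pair_id`, `y_bar`, `sex_code`, `dep_bar`, `var_group`, `n_members`)
#'   and `g_bar` (SNP x unit matrix of averaged dosages).
#' @export
encode_units <- function(cohort, phenotype, transform = "identity",
                         exclude_ids = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  ind <- cohort$individuals
  if (!phenotype %in% names(ind)) {
    stop_config(sprintf("phenotype '%s' not present", phenotype))
  }
  keep <- !(ind$individual_id %in% exclude_ids)
  ind <- ind[keep, , drop = FALSE]
  G <- cohort$genotypes[, ind$individual_id, drop = FALSE]

  y <- ind[[phenotype]]
  if (transform == "log") {
    bad <- !is.na(y) & y <= 0
    if (any(bad)) {
      ps_warn(sprintf("%d unit(s) excluded: non-positive value under log", sum(bad)))
      y[bad] <- NA
    }
  }
  f <- pheno_transform(transform)
  y <- if (transform == "quantile-normal") f(y) else
    ifelse(is.na(y), NA_real_, f(y))
  usable <- !is.na(y)
  ind <- ind[usable, , drop = FALSE]
  y <- y[usable]
  G <- G[, usable, drop = FALSE]
  if (nrow(ind) == 0L) stop_data("no usable observation for this phenotype")

  sex_code <- ifelse(ind$sex == "M", -1, 1)
  unit_key <- ifelse(is.na(ind$pair_id), ind$individual_id, ind$pair_id)
  units <- unique(unit_key)

  n_members <- integer(length(units))
  y_bar <- dep_bar <- sc <- numeric(length(units))
  vg <- character(length(units))
  g_bar <- matrix(NA_real_, nrow(G), length(units),
                  dimnames = list(rownames(G), units))
  for (u in seq_along(units)) {
    sel <- unit_key == units[u]
    n_members[u] <- sum(sel)
    y_bar[u] <- mean(y[sel])
    dep_bar[u] <- mean(ind$depression[sel])
    sc[u] <- mean(sex_code[sel])
    g_bar[, u] <- rowMeans(G[, sel, drop = FALSE])
    zyg <- ind$zygosity[sel][1L]
    sexes <- ind$sex[sel]
    vg[u] <- if (is.na(ind$pair_id[sel][1L])) {
      paste0("singleton-", sexes[1L])
    } else if (!is.na(zyg) && zyg == "MZ") {
      paste0("MZ-", sexes[1L])
    } else if (length(unique(sexes)) > 1L) {
      "DZ-mixed"
    } else {
      paste0("DZ-", sexes[1L])
    }
  }
  structure(list(units = data.frame(unit_id = units,
                                    y_bar = y_bar, sex_code = sc,
                                    dep_bar = dep_bar, var_group = vg,
                                    n_members = n_members,
                                    stringsAsFactors = FALSE),
                 g_bar = g_bar),
            class = "pair_units")
}

# merge variance groups with fewer than min_units units into their
# zygosity-level pool; a still-small pool merges into "all"
merge_small_groups <- function(var_group, min_units = 2L) {
  g <- var_group
  repeat {
    tab <- table(g)
    small <- names(tab)[tab < min_units]
    if (length(small) == 0L) break
    lab <- small[1L]
    parent <- sub("-.*$", "", lab)
    g[g == lab] <- if (parent != lab) parent else "all"
    if (lab == "all") break
  }
  if (length(unique(g)) == 1L) g[] <- "all"
  g
}

#' Heteroscedastic GLS association fit for one SNP
#'
#' Regresses the pair-averaged phenotype on the averaged dosage plus
#' covariates,
#' \code{y_bar = b0 + b_g * g_bar + b_sex * sex_code + b_dep * dep_bar + e},
#' with a diagonal error covariance that is constant within variance group
#' (zygosity x sex at the pair level), estimated by iterated feasible GLS:
#' ordinary least squares start, residual-based group variances (residual
#' sums of squares over leverage-adjusted group degrees of freedom, with a
#' small floor), reweighting, iterated to a relative coefficient change
#' below `tol`. Groups with fewer than 2 units are merged into their
#' zygosity pool.
#'
#' Because the weights are estimated, the model-based GLS covariance
#' understates the sampling variance of the coefficients in small samples.
#' The reported standard error therefore carries a first-order
#' Kackar-Harville-type correction,
#' \deqn{Var(\hat\beta) \approx \Phi + 2 \sum_k \Phi X_k' X_k \Phi /
#'   (\nu_k \hat\sigma^2_k),}
#' where \eqn{\Phi} is the model-based covariance and \eqn{\nu_k} the
#' group's residual degrees of freedom; without it, null rejection rates
#' run visibly above nominal at cohort-scale unit counts. The Wald p-value
#' uses a t reference with `n - p` degrees of freedom.
#'
#' @param units A [encode_units()] result.
#' @param snp SNP id (row of `units$g_bar`).
#' @param covariates Columns of `units$units` entering the model (default
#'   depression and sex, the quoted covariate set).
#' @param tol Relative coefficient-change convergence tolerance.
#' @param max_iter Maximum FGLS iterations.
#' @param single_group Force one variance group (homoscedastic fit; then the
#'   coefficient estimates equal ordinary least squares).
#' @return List of class `gls_fit`: `snp_id`, `beta` (genotype effect),
#'   `se`, `statistic`, `p_raw`, `n_units`, `coefficients`,
#'   `group_variances`, `iterations`, `converged`.
#' @export
gls_fit <- function(units, snp, covariates = c("dep_bar", "sex_code"),
                    tol = 1e-8, max_iter = 50L, single_group = FALSE) {
  stopifnot(inherits(units, "pair_units"))
  if (!snp %in% rownames(units$g_bar)) {
    stop_data(sprintf("SNP '%s' not present", snp))
  }
  u <- units$units
  g <- units$g_bar[snp, ]
  if (length(unique(g)) < 2L) {
    stop_data(sprintf("SNP '%s' has constant averaged dosage: degenerate design", snp))
  }
  X <- cbind(`(Intercept)` = 1, g_bar = g)
  for (cv in covariates) X <- cbind(X, u[[cv]])
  colnames(X) <- c("(Intercept)", "g_bar", covariates)
  y <- u$y_bar
  n <- length(y)
  p_dim <- ncol(X)
  grp <- if (single_group) rep("all", n) else merge_small_groups(u$var_group)
  glev <- unique(grp)
  if (n < p_dim + length(glev)) {
    stop_data("too few units for the number of predictors and variance groups")
  }

  floor_var <- 1e-10 * max(stats::var(y), .Machine$double.eps)
  group_var <- function(res, w) {
    # RSS over leverage-adjusted group df
    Xw <- X * sqrt(w)
    H <- rowSums((Xw %*% solve(crossprod(Xw))) * Xw)
    vapply(glev, function(k) {
      sel <- grp == k
      max(sum(res[sel]^2) / max(sum(sel) - sum(H[sel]), 0.5), floor_var)
    }, numeric(1))
  }

  w <- rep(1, n)
  beta <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    b <- fit$coefficients
    res <- y - X %*% b
    s2 <- group_var(res, w)
    w_new <- 1 / s2[match(grp, glev)]
    if (!is.null(beta) &&
        max(abs(b - beta)) < tol * max(1, max(abs(b)))) {
      converged <- TRUE
      beta <- b
      w <- w_new
      break
    }
    beta <- b
    w <- w_new
  }
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  Phi <- solve(crossprod(X * sqrt(w)))
  res <- y - X %*% beta
  s2 <- group_var(res, w)
  names(s2) <- glev

  # estimated-weight correction to the covariance
  Xw <- X * sqrt(w)
  H <- rowSums((Xw %*% Phi) * Xw)
  covb <- Phi
  for (k in glev) {
    sel <- grp == k
    nu <- max(sum(sel) - sum(H[sel]), 0.5)
    Mk <- crossprod(X[sel, , drop = FALSE])
    covb <- covb + 2 / (nu * s2[[k]]) * Phi %*% Mk %*% Phi
  }
  se <- sqrt(diag(covb))
  tstat <- beta / se
  df <- n - p_dim
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(snp_id = snp,
                 beta = unname(beta["g_bar"]), se = unname(se["g_bar"]),
                 statistic = unname(tstat["g_bar"]),
                 p_raw = unname(p["g_bar"]),
                 n_units = n, coefficients = beta,
                 group_variances = s2, iterations = it,
                 converged = converged),
            class = "gls_fit")
}

#' Restrict pair-averaged units to one sex
#'
#' Keeps only units whose members are all of the given sex (mixed-sex DZ
#' pairs are dropped), for sex-stratified association fits.
#'
#' @param units A [encode_units()] result.
#' @param sex `"M"` or `"F"`.
#' @return A `pair_units` object on the subset.
#' @export
filter_units <- function(units, sex = c("M", "F")) {
  stopifnot(inherits(units, "pair_units"))
  sex <- match.arg(sex)
  code <- if (sex == "M") -1 else 1
  sel <- units$units$sex_code == code
  if (!any(sel)) stop_data(sprintf("no %s-only unit", sex))
  structure(list(units = units$units[sel, , drop = FALSE],
                 g_bar = units$g_bar[, sel, drop = FALSE]),
            class = "pair_units")
}

#' Bonferroni correction
#'
#' @param p_raw Vector of raw p-values.
#' @param m Number of tests (default: length of `p_raw`).
#' @return `min(1, m * p)` per element.
#' @export
bonferroni <- function(p_raw, m = length(p_raw)) {
  if (m < 1) stop_config("m must be >= 1")
  pmin(1, m * p_raw)
}

#' Cohen's d standardized mean difference
#'
#' Mean difference over the sample-size-weighted pooled standard deviation;
#' positive values mean the first group is larger. Benchmarks: 0.2 small,
#' 0.5 medium, 0.8 large.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return Cohen's d.
#' @export
cohens_d <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop_data("each group needs >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop_data("zero pooled standard deviation: effect size undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each, positive
#'   variance in at least one).
#' @return List: `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop_data("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop_data("both group variances are zero")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pairwise composite LD (r-squared of dosages)
#'
#' Squared Pearson correlation between dosage vectors (phase-free composite
#' linkage disequilibrium), computed on one member per MZ pair with pairwise
#' complete observations. Monomorphic SNPs give missing entries.
#'
#' @param cohort A [twin_cohort()], or a SNP x individual dosage matrix.
#' @param snps Optional subset of SNP ids (default: all).
#' @return Symmetric matrix of r-squared values.
#' @export
ld_r2 <- function(cohort, snps = NULL) {
  if (inherits(cohort, "twin_cohort")) {
    G <- cohort$genotypes[, mz_dedup_ids(cohort$individuals), drop = FALSE]
  } else {
    G <- as.matrix(cohort)
  }
  if (!is.null(snps)) G <- G[snps, , drop = FALSE]
  if (ncol(G) < 2L) stop_data("need >= 2 individuals for LD")
  r <- suppressWarnings(stats::cor(t(G), use = "pairwise.complete.obs"))
  r^2
}

#' Candidate-SNP association scan over a twin cohort
#'
#' Full association stage: wildtype orientation, SNP QC, homozygous-wildtype
#' imputation, ceiling-outlier removal for the cold threshold, pair-averaged
#' encoding with the requested transform per phenotype, heteroscedastic GLS
#' per SNP, and per-phenotype Bonferroni correction with `m` = SNPs passing
#' QC.
#'
#' @param cohort A [twin_cohort()].
#' @param phenotypes Phenotype columns to test.
#' @param transforms Named character vector mapping phenotype to transform
#'   (default: heat on its raw scale, cold times on the log scale).
#' @param call_rate_min,maf_min,hwe_alpha QC thresholds (see [snp_qc()]).
#' @param max_cold_s Ceiling for the cold-threshold outlier rule.
#' @return List of class `association_scan`: `results` (data frame: `snp_id`,
#'   `phenotype`, `beta`, `se`, `p_raw`, `p_bonf`, `n_units`), `qc`
#'   (QC report), `m` (tests per phenotype), `ld` (r-squared matrix of
#'   passing SNPs), `manhattan` (data frame: `snp_id`, `position`,
#'   `phenotype`, `neg_log10_p`).
#' @export
run_association <- function(cohort,
                            phenotypes = c("heat_c", "cold_thresh_s", "cold_tol_s"),
                            transforms = c(heat_c = "identity",
                                           cold_thresh_s = "log",
                                           cold_tol_s = "log"),
                            call_rate_min = 0.90, maf_min = 0.05,
                            hwe_alpha = 0.01, max_cold_s = 180) {
  stopifnot(inherits(cohort, "twin_cohort"))
  G <- recode_to_minor(cohort$genotypes, cohort$individuals)
  cohort$genotypes <- G
  qc <- snp_qc(cohort, call_rate_min = call_rate_min, maf_min = maf_min,
               hwe_alpha = hwe_alpha)
  cohort$genotypes <- impute_missing(G[qc$keep, , drop = FALSE],
                                     cohort$individuals)
  m <- length(qc$keep)

  rows <- list()
  for (ph in phenotypes) {
    excl <- character(0)
    if (ph == "cold_thresh_s") {
      flag <- censored_max_rule(cohort$individuals[[ph]], max_cold_s)
      excl <- cohort$individuals$individual_id[flag]
    }
    units <- encode_units(cohort, ph, transform = transforms[[ph]],
                          exclude_ids = excl)
    for (snp in qc$keep) {
      fit <- try(gls_fit(units, snp), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, phenotype = ph, beta = fit$beta, se = fit$se,
        p_raw = fit$p_raw, n_units = fit$n_units, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_data("no SNP could be tested")
  res$p_bonf <- NA_real_
  for (ph in unique(res$phenotype)) {
    sel <- res$phenotype == ph
    res$p_bonf[sel] <- bonferroni(res$p_raw[sel], m = m)
  }
  pos <- if (!is.null(cohort$snp_info)) {
    cohort$snp_info$position[match(res$snp_id, cohort$snp_info$snp_id)]
  } else {
    match(res$snp_id, rownames(G))
  }
  manhattan <- data.frame(snp_id = res$snp_id, position = pos,
                          phenotype = res$phenotype,
                          neg_log10_p = -log10(res$p_raw),
                          stringsAsFactors = FALSE)
  structure(list(results = res, qc = qc$report, m = m,
                 ld = if (m >= 2L) ld_r2(cohort) else NULL,
                 manhattan = manhattan),
            class = "association_scan")
}
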