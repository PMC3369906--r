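#' Per-gene signed log2 fold change
#'
#' Difference of group means on the log2 scale, `mean(case) - mean(control)`,
#' per gene. Samples with missing intensities are dropped per gene; a gene
#' with no non-missing sample in either group gets a missing fold change.
#'
#' @param study An [expression_study()].
#' @return Named numeric vector of signed log2 fold changes.
#' @export
fold_change <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  fc <- rowMeans(study$case_matrix, na.rm = TRUE) -
    rowMeans(study$control_matrix, na.rm = TRUE)
  fc[!is.finite(fc)] <- NA_real_
  names(fc) <- study$gene_ids
  fc
}

# All permutations of 1..n as a matrix (n! rows); used by the exhaustive
# modes. Guarded to small n.
all_permutations <- function(n) {
  if (n > 8L) stop_config("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Rank Product differential-expression statistic
#'
#' Computes the Rank Product of Breitling's rank-based meta-statistic over
#' all pairwise case-vs-control comparisons: within each comparison genes
#' are ranked by their expression difference (descending for up-regulation,
#' ascending for down-regulation) and the statistic is the geometric mean of
#' a gene's ranks across comparisons. Significance comes from a permutation
#' null in which each comparison's rank vector is replaced by a uniformly
#' random permutation; the p-value pools null statistics over genes and
#' permutations,
#' `p = (#\{null RP <= observed\} + 1) / (n_genes * n_perm + 1)`.
#' With `exhaustive = TRUE` all `(n_genes!)^n_comparisons` rank assignments
#' are enumerated instead of sampled (tiny problems only).
#'
#' Genes with any missing intensity are excluded from ranking and returned
#' with missing statistics.
#'
#' @param study An [expression_study()].
#' @param n_perm Number of sampled rank permutations (default 1000).
#' @param seed Optional integer seed for the permutation draw.
#' @param exhaustive Enumerate all rank assignments exactly instead of
#'   sampling (requires tiny gene and comparison counts).
#' @return Data frame: `gene_id`, `rp_up`, `rp_down`, `p_up`, `p_down`.
#' @export
rank_product <- function(study, n_perm = 1000L, seed = NULL,
                         exhaustive = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  nc <- ncol(study$case_matrix)
  nk <- ncol(study$control_matrix)
  if (nc * nk < 1L) stop_data("no case-control comparison can be formed")

  complete <- stats::complete.cases(study$case_matrix) &
    stats::complete.cases(study$control_matrix)
  G <- sum(complete)
  if (G < 2L) stop_data("need at least 2 genes with complete data")

  # genes x comparisons matrix of log differences
  diffs <- matrix(NA_real_, G, nc * nk)
  k <- 0L
  for (i in seq_len(nc)) for (j in seq_len(nk)) {
    k <- k + 1L
    diffs[, k] <- study$case_matrix[complete, i] - study$control_matrix[complete, j]
  }
  K <- ncol(diffs)
  ranks_up <- apply(diffs, 2L, function(d) rank(-d))
  ranks_down <- apply(diffs, 2L, function(d) rank(d))
  rp <- function(r) exp(rowMeans(log(r)))
  rp_up <- rp(ranks_up)
  rp_down <- rp(ranks_down)

  if (exhaustive) {
    if (factorial(G)^K > 2e5) {
      stop_config("exhaustive rank-product enumeration is infeasible at this size")
    }
    perm <- all_permutations(G)
    combo <- rep(list(seq_len(nrow(perm))), K)
    grid <- as.matrix(expand.grid(combo))
    null_rp <- numeric(nrow(grid) * G)
    for (b in seq_len(nrow(grid))) {
      r <- vapply(seq_len(K), function(k) perm[grid[b, k], ], integer(G))
      null_rp[(b - 1L) * G + seq_len(G)] <- rp(matrix(r, G, K))
    }
    denom <- nrow(grid) * G
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    null_rp <- numeric(n_perm * G)
    for (b in seq_len(n_perm)) {
      r <- vapply(seq_len(K), function(k) sample.int(G), integer(G))
      null_rp[(b - 1L) * G + seq_len(G)] <- rp(matrix(r, G, K))
    }
    denom <- n_perm * G
  }
  null_sorted <- sort(null_rp)
  pval <- function(obs) {
    cnt <- findInterval(obs + 1e-9, null_sorted)
    (cnt + 1) / (denom + 1)
  }

  out <- data.frame(gene_id = study$gene_ids,
                    rp_up = NA_real_, rp_down = NA_real_,
                    p_up = NA_real_, p_down = NA_real_,
                    stringsAsFactors = FALSE)
  out$rp_up[complete] <- rp_up
  out$rp_down[complete] <- rp_down
  out$p_up[complete] <- pval(rp_up)
  out$p_down[complete] <- pval(rp_down)
  out
}

#' Storey q-values
#'
#' Converts p-values to gene-specific false-discovery-rate estimates
#' (q-values). The proportion of true nulls `pi0` is estimated on the
#' lambda grid 0.05-0.95 (step 0.05) with a cubic smoothing spline
#' extrapolated at the grid maximum, clipped to `(0, 1]`; with fewer than
#' 100 p-values (where the smoother is unstable) `pi0` falls back to 1,
#' which reduces to Benjamini-Hochberg. Step-up enforcement makes q
#' monotone nondecreasing in p.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion, overriding estimation.
#' @param lambda Grid for `pi0` estimation.
#' @return Numeric vector of q-values, same order as the input.
#' @export
qvalues <- function(pvalues, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- pvalues
  if (length(p) == 0L) stop_data("empty p-value vector")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_data("p-values must lie in [0, 1]")
  m <- sum(ok)
  if (is.null(pi0)) {
    if (m >= 100L) {
      pi0_l <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1))
      fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
      pi0 <- if (inherits(fit, "try-error")) 1 else
        stats::predict(fit, x = max(lambda))$y
    } else {
      pi0 <- 1
    }
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  q <- rep(NA_real_, length(p))
  ord <- order(p[ok])
  po <- p[ok][ord]
  qo <- pi0 * m * po / seq_len(m)
  qo <- rev(cummin(rev(qo)))
  qo <- pmin(qo, 1)
  qi <- numeric(m)
  qi[ord] <- qo
  q[ok] <- qi
  q
}

#' Full per-disease differential-expression analysis
#'
#' Combines [fold_change()], two one-sided [rank_product()] runs (up and
#' down) and [qvalues()] per direction; a gene is retained when either
#' direction reaches `q <= q_threshold`, with the signed fold change
#' carrying the direction.
#'
#' @param study An [expression_study()].
#' @param n_perm Rank-product permutations.
#' @param seed Optional seed for the permutation draw.
#' @param q_threshold Retention threshold on the smaller of the two
#'   directional q-values (default 0.05).
#' @return Data frame of class `de_result`: `gene_id`, `fold_change`,
#'   `rp_up`, `rp_down`, `p_up`, `p_down`, `q`, `retained`, with the
#'   `disease_id` as an attribute.
#' @export
de_analysis <- function(study, n_perm = 1000L, seed = NULL,
                        q_threshold = 0.05) {
  fc <- fold_change(study)
  rp <- rank_product(study, n_perm = n_perm, seed = seed)
  q_up <- qvalues(rp$p_up)
  q_down <- qvalues(rp$p_down)
  q <- pmin(q_up, q_down)
  out <- data.frame(gene_id = study$gene_ids,
                    fold_change = unname(fc),
                    rp_up = rp$rp_up, rp_down = rp$rp_down,
                    p_up = rp$p_up, p_down = rp$p_down,
                    q = q,
                    retained = !is.na(q) & q <= q_threshold,
                    stringsAsFactors = FALSE)
  structure(out, disease_id = study$disease_id,
            class = c("de_result", "data.frame"))
}
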