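#' Assemble the gene x disease fold-change matrix
#'
#' Collects per-disease differential-expression tables into a single matrix
#' of signed fold changes with diseases as columns in index order and genes
#' as rows. Diseases absent from the index are ignored (and logged in the
#' `dropped_diseases` attribute). Genes must be represented (non-missing) in
#' at least `ceiling(min_fraction * n_diseases)` of the retained disease
#' columns; "at least 10%" is the default floor.
#'
#' @param de_results Named list of per-disease tables (names = disease ids),
#'   each with columns `gene_id`, `fold_change` and optionally `retained`
#'   and/or `q`; when present, only rows with `retained == TRUE` (or
#'   `q <= de_q`) contribute. [de_analysis()] outputs work directly.
#' @param index A [build_index()] result.
#' @param min_fraction Minimum fraction of disease columns in which a gene
#'   must be observed (default 0.10).
#' @param de_q Retention threshold applied when a `q` column is present but
#'   no `retained` flag (default 0.05).
#' @return Matrix of class `fold_change_matrix` (genes x diseases, `NA` for
#'   missing) with attributes `index_ordering` and `dropped_diseases`.
#' @export
assemble_matrix <- function(de_results, index, min_fraction = 0.10,
                            de_q = 0.05) {
  if (!inherits(index, "phenotype_index")) stop_data("index must be a phenotype_index")
  if (is.null(names(de_results)) || any(names(de_results) == "")) {
    stop_data("de_results must be a named list keyed by disease_id")
  }
  if (min_fraction <= 0 || min_fraction > 1) {
    stop_config("min_fraction must lie in (0, 1]")
  }
  dropped <- setdiff(names(de_results), index$disease_id)
  diseases <- index$disease_id[index$disease_id %in% names(de_results)]
  if (length(diseases) == 0L) stop_data("no disease overlaps the index")

  tabs <- lapply(de_results[diseases], function(tab) {
    if (!all(c("gene_id", "fold_change") %in% names(tab))) {
      stop_data("each DE table needs gene_id and fold_change columns")
    }
    if ("retained" %in% names(tab)) {
      tab <- tab[!is.na(tab$retained) & tab$retained, , drop = FALSE]
    } else if ("q" %in% names(tab)) {
      tab <- tab[!is.na(tab$q) & tab$q <= de_q, , drop = FALSE]
    }
    tab[!is.na(tab$fold_change), c("gene_id", "fold_change")]
  })
  genes <- sort(unique(unlist(lapply(tabs, `[[`, "gene_id"))))
  if (length(genes) == 0L) stop_data("no gene survives assembly")

  mat <- matrix(NA_real_, length(genes), length(diseases),
                dimnames = list(genes, diseases))
  for (d in diseases) {
    tab <- tabs[[d]]
    mat[tab$gene_id, d] <- tab$fold_change
  }
  need <- ceiling(min_fraction * length(diseases))
  keep <- rowSums(!is.na(mat)) >= need
  if (!any(keep)) stop_data("no gene passes the representation filter")
  mat <- mat[keep, , drop = FALSE]
  structure(mat,
            index_ordering = attr(index, "ordering"),
            dropped_diseases = dropped,
            class = c("fold_change_matrix", "matrix", "array"))
}

# midranks of the index aligned to the matrix columns
index_ranks_for <- function(matrix, index) {
  pos <- match(colnames(matrix), index$disease_id)
  if (anyNA(pos)) stop_data("matrix columns must all be present in the index")
  index$midrank[pos]
}

# Spearman rho of each gene's non-missing fold changes against the supplied
# disease-rank values, pairwise complete, with tie-corrected handling via
# Pearson correlation of midranks. Genes observed in fewer than `min_obs`
# diseases get NA.
spearman_by_gene <- function(mat, rank_values, min_obs = 3L) {
  vapply(seq_len(nrow(mat)), function(g) {
    obs <- !is.na(mat[g, ])
    n <- sum(obs)
    if (n < min_obs) return(NA_real_)
    x <- rank(mat[g, obs])
    y <- rank(rank_values[obs])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}

#' Per-gene Spearman correlation with the phenotype index
#'
#' For each gene, the Spearman rank correlation between its non-missing
#' fold changes and the index midranks of the corresponding diseases
#' (pairwise complete; ties tie-corrected by computing the Pearson
#' correlation of midranks). The raw p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Genes observed in fewer than 3 diseases are excluded (NA, flagged).
#'
#' @param matrix A [assemble_matrix()] result.
#' @param index The [build_index()] result whose diseases form the columns.
#' @return Data frame: `gene_id`, `rho`, `n_obs`, `p_raw`.
#' @export
gene_index_correlation <- function(matrix, index) {
  rk <- index_ranks_for(matrix, index)
  n_obs <- rowSums(!is.na(unclass(matrix)))
  rho <- spearman_by_gene(unclass(matrix), rk)
  tstat <- rho * sqrt((n_obs - 2) / pmax(1 - rho^2, 0))
  p <- ifelse(is.na(rho), NA_real_,
              ifelse(abs(rho) >= 1, 0, 2 * stats::pt(-abs(tstat), n_obs - 2)))
  data.frame(gene_id = rownames(matrix), rho = rho,
             n_obs = as.integer(n_obs), p_raw = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Null |rho| matrix: for each permutation of the disease ranks, recompute
# every gene's correlation on its own missingness pattern. Genes are grouped
# by missingness pattern so each pattern re-ranks the permuted values once.
null_abs_rho <- function(mat, rank_values, perms) {
  G <- nrow(mat)
  B <- nrow(perms)
  pat_key <- apply(!is.na(mat), 1L, paste, collapse = "")
  out <- matrix(NA_real_, G, B)
  for (key in unique(pat_key)) {
    rows <- which(pat_key == key)
    obs <- !is.na(mat[rows[1L], ])
    n <- sum(obs)
    if (n < 3L) next
    xr <- t(apply(mat[rows, obs, drop = FALSE], 1L, rank))
    xc <- xr - rowMeans(xr)
    xn <- sqrt(rowSums(xc^2))
    sub <- perms[, obs, drop = FALSE]
    for (b in seq_len(B)) {
      y <- rank(sub[b, ])
      yc <- y - mean(y)
      yn <- sqrt(sum(yc^2))
      if (yn == 0 || any(xn == 0)) next
      out[rows, b] <- abs((xc %*% yc) / (xn * yn))
    }
  }
  out
}

#' Permutation-based positive false discovery rate for the screen
#'
#' Estimates a per-gene pFDR by permuting the disease ranks and recomputing
#' every gene's Spearman correlation on its own missingness pattern. For a
#' gene with observed `|rho_g|`, `R` counts observed genes at or above that
#' threshold and `E[V]` is the average number of null correlations (pooled
#' over genes) at or above it per permutation; `pfdr = E[V] / R`, clipped to
#' 1 and then enforced monotone nonincreasing in `|rho|`. With
#' `exhaustive = TRUE` all permutations of the disease ranks are enumerated
#' (at most 8 diseases) instead of sampled.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param index The matching [build_index()] result.
#' @param n_perm Number of sampled rank permutations (>= 100 recommended;
#'   fewer triggers a warning).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all disease-rank permutations exactly.
#' @return Data frame: `gene_id`, `rho`, `n_obs`, `pfdr`.
#' @export
permutation_pfdr <- function(matrix, index, n_perm = 1000L, seed = NULL,
                             exhaustive = FALSE) {
  rk <- index_ranks_for(matrix, index)
  mat <- unclass(matrix)
  if (nrow(mat) == 0L) stop_data("empty fold-change matrix")
  if (!exhaustive && n_perm < 100L) {
    ps_warn("n_perm < 100 gives unstable pFDR estimates")
  }
  obs_rho <- spearman_by_gene(mat, rk)
  scored <- !is.na(obs_rho)
  abs_obs <- abs(obs_rho[scored])

  if (exhaustive) {
    if (ncol(mat) > 8L) {
      stop_config("exhaustive pFDR limited to 8 diseases")
    }
    perm_idx <- all_permutations(ncol(mat))
    perms <- matrix(rk[perm_idx], nrow(perm_idx), ncol(mat))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_perm), function(b) sample(rk), numeric(length(rk))))
  }
  nullr <- null_abs_rho(mat[scored, , drop = FALSE], rk, perms)
  pool <- sort(nullr[!is.na(nullr)])
  n_b <- nrow(perms)

  eps <- 1e-12
  cnt_ge <- function(a, sorted) length(sorted) - findInterval(a - eps, sorted)
  sorted_obs <- sort(abs_obs)
  R <- vapply(abs_obs, cnt_ge, numeric(1), sorted = sorted_obs)
  EV <- vapply(abs_obs, cnt_ge, numeric(1), sorted = pool) / n_b
  pfdr <- pmin(EV / R, 1)

  # monotone nonincreasing in |rho|: in descending-|rho| order the enforced
  # values must be nondecreasing
  ord <- order(abs_obs, decreasing = TRUE)
  enforced <- pfdr[ord]
  for (i in seq(length(enforced) - 1L, 1L)) {
    if (length(enforced) < 2L) break
    enforced[i] <- min(enforced[i], enforced[i + 1L])
  }
  pfdr[ord] <- enforced

  out <- data.frame(gene_id = rownames(mat), rho = obs_rho,
                    n_obs = as.integer(rowSums(!is.na(mat))),
                    pfdr = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$pfdr[scored] <- pfdr
  out
}

#' Score genes against the phenotype index
#'
#' Convenience wrapper running [gene_index_correlation()] and
#' [permutation_pfdr()] on the same matrix and index.
#'
#' @inheritParams permutation_pfdr
#' @param alpha Significance threshold on the pFDR (default 0.01).
#' @return Data frame of gene scores: `gene_id`, `rho`, `n_obs`, `p_raw`,
#'   `pfdr`, `significant`.
#' @export
score_genes <- function(matrix, index, n_perm = 1000L, seed = NULL,
                        alpha = 0.01, exhaustive = FALSE) {
  corr <- gene_index_correlation(matrix, index)
  pf <- permutation_pfdr(matrix, index, n_perm = n_perm, seed = seed,
                         exhaustive = exhaustive)
  out <- merge(corr, pf[, c("gene_id", "pfdr")], by = "gene_id", sort = FALSE)
  out$significant <- !is.na(out$pfdr) & out$pfdr < alpha
  out
}

#' Select significant candidate genes
#'
#' Filters gene scores at `pfdr < alpha` and orders candidates by `|rho|`
#' descending, with a `direction` column separating positively and
#' negatively index-correlated genes.
#'
#' @param scores Output of [score_genes()] (or any table with `gene_id`,
#'   `rho`, `pfdr`).
#' @param alpha pFDR threshold (default 0.01).
#' @return Data frame of candidates: `gene_id`, `rho`, `n_obs` (if present),
#'   `p_raw` (if present), `pfdr`, `direction` (`"positive"`/`"negative"`).
#' @export
select_candidates <- function(scores, alpha = 0.01) {
  if (nrow(scores) == 0L) stop_data("empty score table")
  sel <- scores[!is.na(scores$pfdr) & scores$pfdr < alpha, , drop = FALSE]
  sel$direction <- ifelse(sel$rho >= 0, "positive", "negative")
  sel <- sel[order(-abs(sel$rho), sel$gene_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Priority score for ROC evaluation
#'
#' Turns gene scores into a single priority value, higher meaning a stronger
#' candidate: genes are ordered by pFDR ascending with `|rho|` descending as
#' tie-break, and the reversed (mid)rank of that ordering is returned, so
#' fully tied genes share a value.
#'
#' @param scores Output of [score_genes()].
#' @return Named numeric vector of priorities (names = gene ids).
#' @export
gene_priority <- function(scores) {
  ok <- !is.na(scores$pfdr) & !is.na(scores$rho)
  s <- scores[ok, , drop = FALSE]
  key <- rank(s$pfdr, ties.method = "average") * (nrow(s) + 1) -
    rank(abs(s$rho), ties.method = "average")
  pr <- -rank(key, ties.method = "average")
  names(pr) <- s$gene_id
  pr
}
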