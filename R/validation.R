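#' Gold-standard gene set
#'
#' @param gene_ids Character vector of gene symbols (uppercased, deduplicated).
#' @param label Free-text label for reporting (e.g. the source database).
#' @return A `gold_standard` list.
#' @export
gold_standard <- function(gene_ids, label = "gold") {
  ids <- unique(toupper(trimws(as.character(gene_ids))))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop_data("gold standard is empty")
  structure(list(gene_ids = ids, label = label), class = "gold_standard")
}

#' Evaluable intersection of a score list and a gold standard
#'
#' The ROC can only use gold genes that were actually scored; this reports
#' the intersection sizes for transparency (e.g. when only a subset of the
#' reference genes were measurable on the assembled matrix).
#'
#' @param scores Named numeric priority vector, or a data frame with a
#'   `gene_id` column.
#' @param gold A [gold_standard()] (or character vector of symbols).
#' @return List: `n_gold_evaluable`, `n_background`, `gold_evaluable` ids.
#' @export
evaluable_subset <- function(scores, gold) {
  ids <- if (is.data.frame(scores)) scores$gene_id else names(scores)
  ids <- toupper(ids)
  gids <- if (inherits(gold, "gold_standard")) gold$gene_ids else
    gold_standard(gold)$gene_ids
  inter <- intersect(ids, gids)
  list(n_gold_evaluable = length(inter),
       n_background = length(ids) - length(inter),
       gold_evaluable = inter)
}

#' ROC curve and AUC of a gene prioritization against a gold standard
#'
#' Genes are ranked by priority (higher = stronger candidate). The AUC is
#' the Mann-Whitney concordance probability with the usual midrank tie
#' correction; the curve sweeps thresholds over the distinct priority
#' values, and the reported best cutoff maximizes Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores Named numeric vector of priorities (names = gene ids), or a
#'   [score_genes()] data frame (converted via [gene_priority()]).
#' @param gold A [gold_standard()] or character vector of gold symbols.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `best_cutoff` (named vector: threshold,
#'   sensitivity, specificity), `n_gold`, `n_background`.
#' @export
roc_auc <- function(scores, gold) {
  if (is.data.frame(scores)) scores <- gene_priority(scores)
  if (is.null(names(scores))) stop_data("scores must be named by gene id")
  gids <- if (inherits(gold, "gold_standard")) gold$gene_ids else
    gold_standard(gold)$gene_ids
  scores <- scores[!is.na(scores)]
  label <- toupper(names(scores)) %in% gids
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) {
    stop_data("evaluable set needs at least one gold and one background gene")
  }
  r <- rank(scores)
  auc <- (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- label[ord]
  grp <- !duplicated(s)              # threshold blocks over tied priorities
  tp <- cumsum(l)
  fp <- cumsum(!l)
  at <- which(c(grp[-1L], TRUE))     # last element of each tie block
  sens <- c(0, tp[at] / n1)
  spec <- c(1, 1 - fp[at] / n0)
  thr <- c(Inf, s[at])
  j <- which.max(sens + spec)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 best_cutoff = c(threshold = unname(thr[j]),
                                 sensitivity = unname(sens[j]),
                                 specificity = unname(spec[j])),
                 n_gold = n1, n_background = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d gold vs %d background genes)\n",
              x$auc, x$n_gold, x$n_background))
  cat(sprintf("best cutoff (Youden): sensitivity %.3f, specificity %.3f\n",
              x$best_cutoff[["sensitivity"]], x$best_cutoff[["specificity"]]))
  invisible(x)
}

#' Resampling confidence band for the ROC curve
#'
#' Repeatedly reruns the prioritization on random subsets of the diseases
#' (delete-d resampling keeping `fraction` of the diseases per replicate),
#' recomputes the ROC against the same gold standard, and summarizes the
#' replicate curves pointwise on a fixed false-positive-rate grid. Both a
#' standard-error envelope and empirical quantile bands are returned, along
#' with the replicate AUC spread. Replicates whose rerun fails (e.g. an
#' empty matrix after subsetting) are skipped and counted.
#'
#' @param pipeline_rerun Function taking a character vector of disease ids
#'   and returning a named priority vector (or scores data frame) for that
#'   subset.
#' @param diseases Character vector of all disease ids.
#' @param gold Gold standard passed to [roc_auc()].
#' @param fraction Fraction of diseases kept per replicate (default 0.9).
#' @param B Number of replicates (>= 20 recommended).
#' @param seed Optional integer seed.
#' @return List of class `roc_band`: `fpr_grid`, `mean_sens`, `se_sens`,
#'   `band_se_lo`, `band_se_hi`, `band_q_lo`, `band_q_hi`, `aucs`,
#'   `n_skipped`.
#' @export
resampling_band <- function(pipeline_rerun, diseases, gold, fraction = 0.9,
                            B = 50L, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop_config("fraction must lie in (0, 1]")
  if (B < 2L) stop_config("need at least 2 replicates")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(diseases)
  n_keep <- max(1L, round(fraction * n))
  grid <- seq(0, 1, by = 0.01)
  sens_mat <- matrix(NA_real_, B, length(grid))
  aucs <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    keep <- if (n_keep == n) diseases else sort(sample(diseases, n_keep))
    res <- try({
      pr <- pipeline_rerun(keep)
      roc_auc(pr, gold)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      skipped <- skipped + 1L
      next
    }
    fpr <- 1 - res$specificity
    # step-function interpolation of sensitivity at the grid
    sens_mat[b, ] <- stats::approx(fpr, res$sensitivity, xout = grid,
                                   method = "constant", ties = max,
                                   rule = 2)$y
    aucs[b] <- res$auc
  }
  ok <- !is.na(aucs)
  if (!any(ok)) stop_data("all resampling replicates failed")
  m <- colMeans(sens_mat[ok, , drop = FALSE])
  se <- apply(sens_mat[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
  ql <- apply(sens_mat[ok, , drop = FALSE], 2L, stats::quantile, probs = 0.025)
  qh <- apply(sens_mat[ok, , drop = FALSE], 2L, stats::quantile, probs = 0.975)
  structure(list(fpr_grid = grid, mean_sens = m, se_sens = se,
                 band_se_lo = pmax(m - 1.96 * se, 0),
                 band_se_hi = pmin(m + 1.96 * se, 1),
                 band_q_lo = ql, band_q_hi = qh,
                 aucs = aucs[ok], n_skipped = skipped),
            class = "roc_band")
}
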