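#' Disease--phenotype co-citation ratio
#'
#' The fraction of a disease's literature citations that are co-annotated
#' with a phenotype subject heading (e.g. "pain"). This ratio is the building
#' block of the disease-specific phenotype index: a disease whose every
#' citation also carries the pain heading has ratio 1, a disease never
#' studied in the context of pain has ratio 0.
#'
#' @param n_phenotype Number of citations for the disease that are also
#'   annotated with the phenotype heading. Non-negative integer.
#' @param n_total Total number of citations for the disease. Must be >= 1.
#' @return The ratio `n_phenotype / n_total`, a value in `[0, 1]`.
#' @examples
#' disease_phenotype_ratio(12, 12) # 1
#' disease_phenotype_ratio(31, 50) # 0.62
#' @export
disease_phenotype_ratio <- function(n_phenotype, n_total) {
  if (any(n_total < 1)) {
    stop_data("ratio undefined: n_total must be >= 1")
  }
  if (any(n_phenotype < 0) || any(n_phenotype > n_total)) {
    stop_data("n_phenotype must lie in [0, n_total]")
  }
  n_phenotype / n_total
}

#' Build a disease-specific phenotype index from citation records
#'
#' Ranks diseases by their phenotype co-citation ratio. Diseases with no
#' phenotype co-citation are excluded (the inclusion rule is at least one
#' co-citation), as are diseases on an optional caller-supplied blocklist
#' (e.g. veterinary diseases). Tied ratios receive midranks (the average of
#' the tied rank positions), the standard Spearman convention, so the index
#' can be correlated against downstream without an arbitrary tie order.
#'
#' @param records Data frame with columns `disease_id`, `n_total`,
#'   `n_phenotype` and optionally `disease_name`.
#' @param ordering `"ascending"` (default; lowest ratio gets midrank 1, so the
#'   index runs from least to most phenotype-associated) or `"descending"`.
#' @param blocklist Optional character vector of `disease_id`s to drop before
#'   ranking.
#' @return A data frame of class `phenotype_index` with columns `disease_id`,
#'   (`disease_name`,) `ratio` and `midrank`, sorted for presentation by
#'   ratio, then `n_total` descending, then `disease_id`. Attributes:
#'   `ordering`, and `excluded` (data frame of dropped diseases with reasons).
#' @export
build_index <- function(records, ordering = c("ascending", "descending"),
                        blocklist = NULL) {
  ordering <- match.arg(ordering)
  req <- c("disease_id", "n_total", "n_phenotype")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop_data("records must contain columns disease_id, n_total, n_phenotype")
  }
  if (nrow(records) == 0L) stop_data("records is empty")
  if (anyDuplicated(records$disease_id)) {
    stop_data("duplicate disease_id in citation records")
  }

  excluded <- data.frame(disease_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(blocklist)) {
    drop <- records$disease_id %in% blocklist
    if (any(drop)) {
      excluded <- rbind(excluded, data.frame(
        disease_id = records$disease_id[drop], reason = "blocklist",
        stringsAsFactors = FALSE))
      records <- records[!drop, , drop = FALSE]
    }
  }
  zero <- records$n_phenotype == 0
  if (any(zero)) {
    excluded <- rbind(excluded, data.frame(
      disease_id = records$disease_id[zero], reason = "no_cocitation",
      stringsAsFactors = FALSE))
    records <- records[!zero, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop_data("all diseases excluded; index would be empty")
  }

  ratio <- disease_phenotype_ratio(records$n_phenotype, records$n_total)
  midrank <- if (ordering == "ascending") rank(ratio) else rank(-ratio)

  idx <- data.frame(disease_id = records$disease_id,
                    ratio = ratio, midrank = midrank,
                    stringsAsFactors = FALSE)
  if ("disease_name" %in% names(records)) {
    idx$disease_name <- records$disease_name
    idx <- idx[, c("disease_id", "disease_name", "ratio", "midrank")]
  }
  # deterministic presentation order; midranks are order-independent
  sgn <- if (ordering == "ascending") 1 else -1
  ord <- order(sgn * idx$ratio, -records$n_total, idx$disease_id)
  idx <- idx[ord, , drop = FALSE]
  rownames(idx) <- NULL
  structure(idx,
            ordering = ordering,
            excluded = excluded,
            class = c("phenotype_index", "data.frame"))
}

#' @export
print.phenotype_index <- function(x, ...) {
  cat(sprintf("Disease-specific phenotype index: %d diseases (%s ratio order), %d excluded\n",
              nrow(x), attr(x, "ordering"), nrow(attr(x, "excluded"))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more diseases\n", nrow(x) - 10L))
  invisible(x)
}
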