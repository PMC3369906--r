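# Small in-code fixtures shared across test files.

# citation records with given ratios (scaled to integer counts)
records_with_ratios <- function(ratios, n_total = 100L) {
  data.frame(disease_id = sprintf("D%02d", seq_along(ratios)),
             disease_name = sprintf("disease %d", seq_along(ratios)),
             n_total = n_total,
             n_phenotype = as.integer(round(ratios * n_total)),
             stringsAsFactors = FALSE)
}

# index over n diseases with strictly increasing ratios (no ties)
tiny_index <- function(n) {
  build_index(records_with_ratios(seq(0.05, 0.9, length.out = n)))
}

# fold-change matrix built through assemble_matrix from a plain gene x
# disease value matrix (NA = missing)
fcm_from_values <- function(values, index, min_fraction = 0.01) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  de <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    data.frame(gene_id = rownames(values)[!is.na(v)],
               fold_change = v[!is.na(v)], stringsAsFactors = FALSE)
  })
  names(de) <- index$disease_id[seq_len(ncol(values))]
  assemble_matrix(de, index, min_fraction = min_fraction)
}

# a two-group expression study from case/control matrices
study_from_matrices <- function(case, control, disease_id = "Dtest") {
  if (is.null(rownames(case))) {
    rownames(case) <- rownames(control) <- sprintf("G%03d", seq_len(nrow(case)))
  }
  expression_study(disease_id, rownames(case), case, control)
}

# minimal hand-built twin cohort; genotypes is SNP x individual
hand_cohort <- function(individuals, genotypes) {
  colnames(genotypes) <- individuals$individual_id
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("snp%02d", seq_len(nrow(genotypes)))
  }
  twin_cohort(individuals, genotypes)
}

# independent permutation enumerator used as oracle (distinct from the
# package's internal generator on purpose: iterative insertion vs recursion)
oracle_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) {
      for (pos in 0:(k - 1L)) {
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
      }
    }
    out <- nxt
  }
  do.call(rbind, out)
}

# read a pipeline output table, skipping provenance comment lines
read_out <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# a small configuration so the chained pipeline runs in seconds
small_config <- function(seed = 1L) {
  run_config(seed = seed,
             sim = simulation_config(seed = seed, n_diseases = 12,
                                     n_genes = 80, n_planted_genes = 8,
                                     planted_slope = 0.12, noise_sd = 0.2,
                                     missing_fraction = 0.05,
                                     n_case = 3L, n_control = 3L,
                                     n_pairs = 60, n_snps = 3,
                                     maf_vector = rep(0.3, 3),
                                     beta_snp = 0.8),
             n_perm_rp = 120L, n_perm_pfdr = 250L,
             # lenient DE retention so null genes populate the matrix and
             # the ROC has a background set at this small scale
             de_q = 0.5)
}
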