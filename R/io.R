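# Tab-delimited readers/writers with required-header validation and a
# provenance comment header. Provenance lines start with '#' and record the
# stage, seed and parameter hash only (no timestamps, so reruns with the
# same configuration are byte-identical).

provenance_header <- function(stage, seed = NA, extra = NULL) {
  c(sprintf("# painscreen %s", stage),
    sprintf("# seed: %s", seed),
    if (!is.null(extra)) sprintf("# %s: %s", names(extra), unlist(extra)))
}

write_tsv <- function(df, path, stage = "table", seed = NA, extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(stage, seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_data(sprintf("cannot parse %s '%s': %s",
                                          what, path, conditionMessage(e))))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop_data(sprintf("%s '%s' lacks required column(s): %s",
                        what, path, paste(missing, collapse = ", ")))
    }
  }
  df
}

#' Read a disease citation-count table
#'
#' Tab-delimited with header columns `disease_id`, `disease_name`,
#' `n_total`, `n_phenotype`. Duplicate disease ids are rejected with their
#' line numbers; counts must be non-negative integers with
#' `n_phenotype <= n_total`.
#'
#' @param path File path.
#' @return Validated data frame of citation records.
#' @export
read_citations <- function(path) {
  df <- read_tsv(path, c("disease_id", "disease_name", "n_total", "n_phenotype"),
                 "citation table")
  if (anyDuplicated(df$disease_id)) {
    dup <- df$disease_id[duplicated(df$disease_id)][1L]
    lines <- which(df$disease_id == dup)
    stop_data(sprintf("duplicate disease_id '%s' at data rows %s of %s",
                      dup, paste(lines, collapse = " and "), path))
  }
  if (!is.numeric(df$n_total) || !is.numeric(df$n_phenotype) ||
      any(df$n_total < 0) || any(df$n_phenotype < 0) ||
      any(df$n_phenotype > df$n_total)) {
    stop_data(sprintf("invalid citation counts in %s", path))
  }
  df
}

#' Write / read a phenotype index
#'
#' @param index A [build_index()] result.
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @return `write_index` returns the path; `read_index` the
#'   `phenotype_index`.
#' @export
write_index <- function(index, path, seed = NA) {
  write_tsv(as.data.frame(index), path, stage = "dspi", seed = seed,
            extra = list(ordering = attr(index, "ordering"),
                         n_excluded = nrow(attr(index, "excluded"))))
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  df <- read_tsv(path, c("disease_id", "ratio", "midrank"), "index table")
  hdr <- grep("^# ordering:", readLines(path, n = 10L), value = TRUE)
  ordering <- if (length(hdr) > 0L) sub("^# ordering: *", "", hdr[1L]) else "ascending"
  structure(df, ordering = ordering,
            excluded = data.frame(disease_id = character(0),
                                  reason = character(0)),
            class = c("phenotype_index", "data.frame"))
}

#' Write / read a fold-change matrix
#'
#' Genes as rows, diseases as columns, `NA` for missing entries; the column
#' order is the index order. Round-trips exactly.
#'
#' @param matrix A [assemble_matrix()] result.
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @export
write_fc_matrix <- function(matrix, path, seed = NA) {
  df <- data.frame(gene_id = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, stage = "fc_matrix", seed = seed,
            extra = list(ordering = attr(matrix, "index_ordering") %||% "ascending"))
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  df <- read_tsv(path, "gene_id", "fold-change matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  structure(m, class = c("fold_change_matrix", "matrix", "array"))
}

#' Read a gold-standard gene list (one symbol per line)
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @param label Label for the resulting [gold_standard()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  gold_standard(x, label = label)
}

#' Read an expression study from delimited files
#'
#' @param expr_path Gene x sample table (first column `gene_id`).
#' @param design_path Design table with columns `sample_id` and `group`
#'   (values `case`/`control`).
#' @param disease_id Disease identifier for the study.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expr_path, design_path, disease_id) {
  expr <- read_tsv(expr_path, "gene_id", "expression table")
  design <- read_tsv(design_path, c("sample_id", "group"), "design table")
  if (!all(design$group %in% c("case", "control"))) {
    stop_data(sprintf("design groups must be case/control in %s", design_path))
  }
  missing <- setdiff(design$sample_id, names(expr))
  if (length(missing) > 0L) {
    stop_data(sprintf("samples %s absent from %s",
                      paste(missing, collapse = ", "), expr_path))
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  expression_study(disease_id, expr$gene_id,
                   m[, design$sample_id[design$group == "case"], drop = FALSE],
                   m[, design$sample_id[design$group == "control"], drop = FALSE])
}

#' Write an expression study to delimited files
#'
#' @param study An [expression_study()].
#' @param expr_path,design_path Output paths.
#' @param seed Seed recorded in the provenance header.
#' @export
write_expression_study <- function(study, expr_path, design_path, seed = NA) {
  m <- cbind(study$case_matrix, study$control_matrix)
  df <- data.frame(gene_id = study$gene_ids, as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expr_path, stage = "expression", seed = seed,
            extra = list(disease_id = study$disease_id))
  design <- data.frame(sample_id = colnames(m),
                       group = rep(c("case", "control"),
                                   c(ncol(study$case_matrix),
                                     ncol(study$control_matrix))),
                       stringsAsFactors = FALSE)
  write_tsv(design, design_path, stage = "design", seed = seed)
  invisible(expr_path)
}

#' Read a SNP x individual dosage table
#'
#' Tab-delimited: first column `snp_id`, remaining columns one per
#' individual, values in `{0, 1, 2, NA}`.
#'
#' @param path File path.
#' @return Dosage matrix (SNPs x individuals).
#' @export
read_dosage_table <- function(path) {
  df <- read_tsv(path, "snp_id", "dosage table")
  if (anyDuplicated(df$snp_id)) {
    dup <- df$snp_id[duplicated(df$snp_id)][1L]
    stop_data(sprintf("duplicate snp_id '%s' in %s", dup, path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(is.na(m) | m %in% 0:2)) {
    stop_data(sprintf("dosages must be 0/1/2/NA in %s", path))
  }
  rownames(m) <- df$snp_id
  m
}

#' @rdname read_dosage_table
#' @param genotypes SNP x individual matrix to write.
#' @param seed Seed recorded in the provenance header.
#' @export
write_dosage_table <- function(genotypes, path, seed = NA) {
  df <- data.frame(snp_id = rownames(genotypes),
                   as.data.frame(genotypes, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, stage = "genotypes", seed = seed)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field into dosages of the non-reference (ALT) allele;
#' `./.` becomes missing. Positions are 1-based per the VCF standard.
#'
#' @param path Path to an (uncompressed) VCF.
#' @return List: `genotypes` (SNP x individual ALT-dosage matrix),
#'   `snp_info` (data frame: `snp_id`, `chrom`, `position`, `ref`, `alt`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  })
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  rownames(dos) <- ids
  list(genotypes = dos,
       snp_info = data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                             position = as.integer(fix[, "POS"]),
                             ref = fix[, "REF"], alt = fix[, "ALT"],
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Write genotypes as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only genotype fields, dosages
#' mapped to `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param genotypes SNP x individual dosage matrix.
#' @param path Output path.
#' @param snp_info Optional data frame with `snp_id`, `chrom`, `position`,
#'   `ref`, `alt`.
#' @export
write_genotypes_vcf <- function(genotypes, path, snp_info = NULL) {
  ids <- rownames(genotypes)
  info <- data.frame(snp_id = ids,
                     chrom = "1",
                     position = seq_along(ids) * 1000L,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  if (!is.null(snp_info)) {
    m <- match(ids, snp_info$snp_id)
    for (col in intersect(c("chrom", "position", "ref", "alt"), names(snp_info))) {
      info[[col]][!is.na(m)] <- snp_info[[col]][m[!is.na(m)]]
    }
  }
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(ids), function(i) {
    g <- genotypes[i, ]
    gt <- ifelse(is.na(g), "./.", gt_map[as.character(g)])
    paste(c(info$chrom[i], info$position[i], ids[i], info$ref[i], info$alt[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=painscreen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read twin phenotype/metadata and genotypes into a cohort
#'
#' The phenotype file is tab-delimited with header `individual_id`,
#' `pair_id`, `zygosity`, `sex`, `heat_c`, `cold_thresh_s`, `cold_tol_s`,
#' `depression`. Genotypes come from a dosage table or a VCF (by file
#' extension).
#'
#' @param phenotype_path Path to the phenotype/metadata table.
#' @param genotype_path Path to a dosage `.tsv` or a `.vcf`.
#' @return A [twin_cohort()].
#' @export
read_twin_cohort <- function(phenotype_path, genotype_path) {
  ind <- read_tsv(phenotype_path,
                  c("individual_id", "pair_id", "zygosity", "sex", "heat_c",
                    "cold_thresh_s", "cold_tol_s", "depression"),
                  "phenotype table")
  if (anyDuplicated(ind$individual_id)) {
    stop_data(sprintf("duplicate individual_id in %s", phenotype_path))
  }
  ind$pair_id[ind$pair_id %in% c("", "NA")] <- NA
  ind$zygosity[ind$zygosity %in% c("", "NA")] <- NA
  if (grepl("\\.vcf$", genotype_path, ignore.case = TRUE)) {
    v <- read_genotypes_vcf(genotype_path)
    G <- v$genotypes
    snp_info <- v$snp_info
  } else {
    G <- read_dosage_table(genotype_path)
    snp_info <- NULL
  }
  missing <- setdiff(ind$individual_id, colnames(G))
  if (length(missing) > 0L) {
    stop_data(sprintf("individuals without genotypes: %s",
                      paste(utils::head(missing, 5L), collapse = ", ")))
  }
  twin_cohort(ind, G[, ind$individual_id, drop = FALSE], snp_info = snp_info)
}

#' @rdname read_twin_cohort
#' @param cohort A [twin_cohort()] to write.
#' @param seed Seed recorded in the provenance header.
#' @export
write_twin_cohort <- function(cohort, phenotype_path, genotype_path, seed = NA) {
  write_tsv(cohort$individuals, phenotype_path, stage = "twin_phenotypes",
            seed = seed)
  if (grepl("\\.vcf$", genotype_path, ignore.case = TRUE)) {
    write_genotypes_vcf(cohort$genotypes, genotype_path, cohort$snp_info)
  } else {
    write_dosage_table(cohort$genotypes, genotype_path, seed = seed)
  }
  invisible(phenotype_path)
}
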