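# TSV readers/writers and network export.
#
# Native tabular dialect is TSV, UTF-8, LF; first column = feature id,
# header row = sample ids. Writers are deterministic so outputs are
# byte-identical across runs with the same config and seed.

read_feature_tsv <- function(path, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop(sprintf("%s: need an id column plus >= 2 sample columns", what))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("%s: non-numeric value at row '%s', column '%s'",
                   what, ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    m <- matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix from TSV
#'
#' @param path TSV file: first column gene id, remaining columns one per
#'   sample with sample ids in the header.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  m <- read_feature_tsv(path, "read_expression")
  expression_matrix(m, rownames(m), colnames(m))
}

#' Read a genotype matrix from TSV
#'
#' Entries must be coded `{1, 2, 3}` (minor-allele count + 1).
#'
#' @param path TSV file, same layout as [read_expression()].
#' @return Numeric matrix, SNPs x samples, with dimnames.
#' @export
read_genotypes <- function(path) {
  m <- read_feature_tsv(path, "read_genotypes")
  genotype_matrix(m, rownames(m), colnames(m))
}

#' Import genotypes from a VCF file
#'
#' Reads diploid GT fields and maps alternate-allele dosage 0/1/2 to
#' the native `{1, 2, 3}` coding. Requires the vcfR package.
#'
#' @param path path to a VCF file.
#' @return Genotype matrix, variants x samples, coded `{1, 2, 3}`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    sum(alleles != "0" & alleles != ".")
  })
  if (anyNA(dosage)) {
    stop("read_genotypes_vcf: missing genotypes are not supported")
  }
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("var", seq_len(nrow(dosage)))
  genotype_matrix(dosage + 1, ids, colnames(dosage))
}

#' Align expression and genotype matrices on shared samples
#'
#' Restricts both matrices to the sample ids they share, in
#' expression-file order.
#'
#' @param Y expression matrix with sample ids as colnames.
#' @param X genotype matrix with sample ids as colnames.
#' @return List with aligned `Y` and `X`.
#' @export
align_samples <- function(Y, X) {
  shared <- intersect(colnames(Y), colnames(X))
  if (length(shared) < 2L) {
    stop("align_samples: fewer than 2 shared sample ids")
  }
  list(Y = Y[, shared, drop = FALSE], X = X[, shared, drop = FALSE])
}

fit_edge_table <- function(fit, zero_tol = NULL) {
  if (is.null(zero_tol)) zero_tol <- fit$config$zero_tol
  gid <- fit$gene_ids
  if (is.null(gid)) gid <- paste0("g", seq_len(nrow(fit$B)))
  sid <- fit$snp_ids
  if (is.null(sid)) sid <- paste0("snp", seq_len(ncol(fit$F)))
  sb <- support_indices(fit$B, zero_tol)
  sf <- support_indices(fit$F, zero_tol)
  edges <- rbind(
    if (nrow(sb) > 0L)
      data.frame(source_id = gid[sb[, "col"]],
                 target_id = gid[sb[, "row"]],
                 weight = fit$B[sb], source_kind = "gene"),
    if (nrow(sf) > 0L)
      data.frame(source_id = sid[sf[, "col"]],
                 target_id = gid[sf[, "row"]],
                 weight = fit$F[sf], source_kind = "snp"))
  if (is.null(edges)) {
    edges <- data.frame(source_id = character(0),
                        target_id = character(0), weight = numeric(0),
                        source_kind = character(0))
  }
  edges[order(edges$target_id, edges$source_id), , drop = FALSE]
}

#' Write an inferred network to disk
#'
#' `"edgelist"` writes a TSV with columns `source_id`, `target_id`,
#' `weight`, `source_kind`; `"sif"` writes simple-interaction format
#' with relation `regulates` for gene sources and `eqtl_of` for SNP
#' sources. Row order is deterministic (targets ascending, then
#' sources). SNPs only ever appear as sources.
#'
#' @param fit an `sgrn_fit` from [ial()].
#' @param path output file path.
#' @param format `"edgelist"` or `"sif"`.
#' @return The edge table, invisibly.
#' @export
write_network <- function(fit, path, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  edges <- fit_edge_table(fit)
  if (format == "edgelist") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  } else {
    rel <- ifelse(edges$source_kind == "gene", "regulates", "eqtl_of")
    sif <- data.frame(source = edges$source_id, relation = rel,
                      target = edges$target_id)
    utils::write.table(sif, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(edges)
}

#' Read a written edge list back
#'
#' @param path an edgelist TSV written by [write_network()].
#' @return Data frame with `source_id`, `target_id`, `weight`,
#'   `source_kind`.
#' @export
read_network <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

#' Write a simulated dataset with ground truth
#'
#' Emits `expression.tsv` and `genotypes.tsv` (features x samples),
#' `true_gene_edges.tsv` (regulator, target, weight),
#' `true_eqtls.tsv` (gene, snp, weight), and `provenance.json`
#' recording the full simulation configuration including the seed.
#'
#' @param sim an `sgrn_sim` from [sgrn_simulate()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sgrn_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$Y, file.path(dir, "expression.tsv"), "gene_id")
  write_matrix_tsv(sim$X, file.path(dir, "genotypes.tsv"), "snp_id")
  gid <- rownames(sim$Y)
  sid <- rownames(sim$X)
  sb <- support_indices(sim$model$B)
  edges <- data.frame(regulator_gene = gid[sb[, "col"]],
                      target_gene = gid[sb[, "row"]],
                      weight = sim$model$B[sb])
  utils::write.table(edges[order(edges$target_gene,
                                 edges$regulator_gene), ],
                     file.path(dir, "true_gene_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  sf <- support_indices(sim$model$F)
  eq <- data.frame(gene = gid[sf[, "row"]], snp = sid[sf[, "col"]],
                   weight = sim$model$F[sf])
  utils::write.table(eq[order(eq$gene), ],
                     file.path(dir, "true_eqtls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  jsonlite::write_json(unclass(sim$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Field names mirror [ial_config()] arguments; unknown fields are an
#' error. Files ending in `.json` are parsed as JSON, otherwise YAML
#' (requires the yaml package).
#'
#' @param path config file path.
#' @return An `ial_config`.
#' @export
read_ial_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_ial_config: YAML configs require the yaml package")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(ial_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("read_ial_config: unknown fields: %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(ial_config, vals)
}
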