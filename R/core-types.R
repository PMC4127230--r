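#' Row mean-centering
#'
#' Subtracts each row's mean, so that per-row intercepts (the model bias
#' term) vanish from all downstream regressions. Idempotent.
#'
#' @param m numeric matrix with at least one column.
#' @return A matrix of the same shape whose rows all have mean zero.
#' @examples
#' center_rows(matrix(1:3, nrow = 1))  # -1 0 1
#' @export
center_rows <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0L || ncol(m) < 1L) {
    stop("center_rows: 'm' must be a non-empty numeric matrix")
  }
  m - rowMeans(m)
}

#' Support (nonzero index pairs) of a matrix
#'
#' Indices of entries exceeding `zero_tol` in absolute value, the
#' convention used throughout to decide whether an edge is selected.
#'
#' @param m numeric matrix.
#' @param zero_tol nonnegative numeric-zero threshold (default `1e-8`).
#' @return Integer matrix with columns `row`, `col`, one row per
#'   above-tolerance entry, ordered column-major.
#' @export
support_indices <- function(m, zero_tol = 1e-8) {
  stopifnot(is.matrix(m), is.numeric(zero_tol), zero_tol >= 0)
  idx <- which(abs(m) > zero_tol, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  # drop dimnames inherited from m so supports compare by position
  rownames(idx) <- NULL
  idx
}

#' Validate and label an expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional identifier vectors; defaults are
#'   `g1..gM` and `s1..sN`.
#' @return The matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression_matrix: 'values' must be a numeric matrix")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("expression_matrix: need at least 2 genes and 2 samples")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  stopifnot(length(gene_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Validate and label a genotype matrix
#'
#' Genotypes are coded 1, 2, 3 = minor-allele count plus one. The raw
#' coding is preserved; regressions center rows themselves, which makes
#' the offset immaterial.
#'
#' @param values integer-valued matrix, SNPs in rows, samples in columns,
#'   entries in `{1, 2, 3}`.
#' @param snp_ids,sample_ids optional identifier vectors.
#' @return The matrix with dimnames set.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("genotype_matrix: 'values' must be a numeric matrix")
  }
  if (!all(values %in% c(1, 2, 3))) {
    bad <- arrayInd(which(!(values %in% c(1, 2, 3)))[1], dim(values))
    stop(sprintf(
      "genotype_matrix: entry at row %d, column %d is not in {1,2,3} (minor-allele count + 1 coding)",
      bad[1], bad[2]))
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  stopifnot(length(snp_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  dimnames(values) <- list(snp_ids, sample_ids)
  values
}

# run expr with the global RNG seeded to `seed`, restoring prior state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
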