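#' Configuration for the synthetic SEM benchmark generator
#'
#' The generator emulates the benchmark conditions used to characterize
#' the method: random directed acyclic gene networks with an expected
#' `edges_per_gene` regulators per gene, regulatory and eQTL coefficients
#' drawn uniformly from \eqn{[0.5, 1] \cup [-1, -0.5]}, one true eQTL per
#' gene (diagonal eQTL matrix, so the number of SNPs equals the number of
#' genes), genotypes i.i.d. over `{1,2,3}` with probabilities
#' (0.25, 0.5, 0.25), and Gaussian noise with variance 0.01.
#'
#' @param n_genes number of genes (and SNPs), M.
#' @param n_samples number of samples, N.
#' @param edges_per_gene expected number of gene-gene edges per gene, Eg.
#' @param coef_range magnitude range of nonzero coefficients.
#' @param noise_variance variance of the Gaussian residual.
#' @param genotype_probs probabilities of genotype codes 1, 2, 3.
#' @param seed integer seed making the dataset reproducible.
#' @return A list of class `sgrn_sim_config`.
#' @export
sgrn_sim_config <- function(n_genes, n_samples, edges_per_gene = 1,
                            coef_range = c(0.5, 1), noise_variance = 0.01,
                            genotype_probs = c(0.25, 0.5, 0.25), seed = 1L) {
  stopifnot(n_genes >= 2, n_samples >= 2, edges_per_gene > 0,
            length(coef_range) == 2L, coef_range[1] < coef_range[2],
            coef_range[1] > 0, noise_variance >= 0,
            length(genotype_probs) == 3L, all(genotype_probs >= 0))
  if (abs(sum(genotype_probs) - 1) > 1e-12) {
    stop("sgrn_sim_config: genotype_probs must sum to 1")
  }
  if (edges_per_gene * n_genes > n_genes * (n_genes - 1) / 2) {
    stop("sgrn_sim_config: edge budget Eg*M exceeds the M(M-1)/2 acyclic slots")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 edges_per_gene = edges_per_gene,
                 eqtls_per_gene = 1L,
                 coef_range = as.numeric(coef_range),
                 noise_variance = noise_variance,
                 genotype_probs = as.numeric(genotype_probs),
                 seed = as.integer(seed)),
            class = "sgrn_sim_config")
}

# coefficient law: uniform magnitude in coef_range, random sign
sample_coefs <- function(n, coef_range) {
  sample(c(-1, 1), n, replace = TRUE) *
    runif(n, coef_range[1], coef_range[2])
}

#' Draw a random acyclic SEM network
#'
#' Draws a uniform random permutation as topological order and includes
#' each of the M(M-1)/2 order-respecting gene-gene slots independently
#' with probability `2*Eg/(M-1)`, so the expected edge count is `Eg*M`.
#' The eQTL matrix F is diagonal with a nonzero entry for every gene
#' (one true eQTL per gene); all nonzero coefficients follow the
#' configured uniform-magnitude law. Uses the current RNG state.
#'
#' @param config a [sgrn_sim_config()].
#' @return A list of class `sem_model` with elements `B` (gene adjacency,
#'   `B[i, j]` nonzero means gene j regulates gene i, zero diagonal,
#'   acyclic), `F` (diagonal eQTL matrix), `noise_variance`, and `order`
#'   (the generating topological order).
#' @export
sample_network <- function(config) {
  stopifnot(inherits(config, "sgrn_sim_config"))
  M <- config$n_genes
  p_edge <- 2 * config$edges_per_gene / (M - 1)
  ord <- sample.int(M)  # ord[k] = gene at topological position k
  B <- matrix(0, M, M)
  # regulator at earlier position -> target at later position
  for (l in 2:M) {
    on <- runif(l - 1) < p_edge
    if (any(on)) {
      regs <- ord[seq_len(l - 1)][on]
      B[ord[l], regs] <- sample_coefs(sum(on), config$coef_range)
    }
  }
  Fm <- diag(sample_coefs(M, config$coef_range), M, M)
  structure(list(B = B, F = Fm,
                 noise_variance = config$noise_variance, order = ord),
            class = "sem_model")
}

#' Draw a genotype matrix
#'
#' Entries i.i.d. over `{1, 2, 3}` with the configured probabilities
#' (defaults 0.25, 0.5, 0.25, i.e. Hardy-Weinberg at allele frequency
#' one half, shifted by one). Uses the current RNG state.
#'
#' @param config a [sgrn_sim_config()].
#' @return A genotype matrix (SNPs x samples) with dimnames.
#' @export
sample_genotypes <- function(config) {
  stopifnot(inherits(config, "sgrn_sim_config"))
  M <- config$n_genes
  N <- config$n_samples
  vals <- sample(c(1, 2, 3), M * N, replace = TRUE,
                 prob = config$genotype_probs)
  genotype_matrix(matrix(vals, M, N))
}

#' Generate expression data from a SEM
#'
#' Solves the structural equations for the observed expression,
#' \eqn{Y = (I - B)^{-1} (F X + E)}, with \eqn{E_{ij}} i.i.d. Gaussian
#' with mean zero and the model's noise variance. Uses the current RNG
#' state for E unless an `E` realization is supplied.
#'
#' @param model a `sem_model`.
#' @param X genotype matrix (SNPs x samples).
#' @param E optional noise matrix realization (genes x samples).
#' @return List with `Y` (expression matrix, genes x samples) and `E`
#'   (the noise realization used).
#' @export
generate_expression <- function(model, X, E = NULL) {
  stopifnot(inherits(model, "sem_model"), is.matrix(X))
  M <- nrow(model$B)
  N <- ncol(X)
  if (is.null(E)) {
    E <- matrix(rnorm(M * N, sd = sqrt(model$noise_variance)), M, N)
  }
  stopifnot(nrow(E) == M, ncol(E) == N)
  ImB <- diag(M) - model$B
  rc <- rcond(ImB)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("generate_expression: (I - B) is numerically singular; the SEM has no unique solution")
  }
  Y <- solve(ImB, model$F %*% X + E)
  list(Y = expression_matrix(unname(Y)), E = E)
}

#' Simulate a complete benchmark dataset
#'
#' Seeds the RNG from the configuration, draws a random acyclic network,
#' genotypes, and noise, and returns data plus ground truth. The noise
#' realization is stored so the structural residual \eqn{(I-B)Y - FX}
#' can be recovered exactly in tests.
#'
#' @param config a [sgrn_sim_config()].
#' @return A list of class `sgrn_sim` with `model`, `Y`, `X`, `E`,
#'   `config`.
#' @export
sgrn_simulate <- function(config) {
  stopifnot(inherits(config, "sgrn_sim_config"))
  with_seed(config$seed, {
    model <- sample_network(config)
    X <- sample_genotypes(config)
    gen <- generate_expression(model, X)
    structure(list(model = model, Y = gen$Y, X = X, E = gen$E,
                   config = config),
              class = "sgrn_sim")
  })
}

#' @export
print.sgrn_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated SGRN dataset: %d genes/SNPs, %d samples, %d true gene edges, Eg = %g, seed = %d\n",
    x$config$n_genes, x$config$n_samples,
    nrow(support_indices(x$model$B)), x$config$edges_per_gene,
    x$config$seed))
  invisible(x)
}
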