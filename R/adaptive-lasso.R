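#' Adaptive-lasso penalty weights from a previous estimate
#'
#' Weights are \eqn{w^b_{ij} = |\hat b_{ij}|^{-\alpha}} and
#' \eqn{w^f_{ij} = |\hat f_{ij}|^{-\beta}}, so coefficients that were
#' large in the previous estimate are penalized lightly and small ones
#' heavily. Coefficients estimated as zero get infinite weight and are
#' permanently excluded (a zeroed coefficient can never return). The
#' special case \eqn{\alpha = 0} (resp. \eqn{\beta = 0}) keeps weight 1
#' on every surviving coefficient and infinity on the rest, i.e. pure
#' support freezing without magnitude re-weighting.
#'
#' @param b_hat,f_hat previous coefficient estimates (rows of B and F).
#' @param alpha,beta nonnegative weight exponents.
#' @param zero_tol threshold below which an estimate counts as zero.
#' @return List with numeric vectors `w_b`, `w_f` (entries in
#'   \eqn{(0, \infty]}) and the exponents used.
#' @export
make_weights <- function(b_hat, f_hat, alpha, beta, zero_tol = 1e-8) {
  if (alpha < 0 || beta < 0) {
    stop("make_weights: alpha and beta must be nonnegative")
  }
  wfun <- function(v, expnt) {
    w <- rep(Inf, length(v))
    nz <- abs(v) > zero_tol
    w[nz] <- if (expnt == 0) 1 else abs(v[nz])^(-expnt)
    w
  }
  list(w_b = wfun(b_hat, alpha), w_f = wfun(f_hat, beta),
       alpha = alpha, beta = beta)
}

#' Weighted-l1 (adaptive lasso) fit for one gene
#'
#' Minimizes
#' \deqn{\tfrac12 \|y_i - b_i Y - f_i X\|_2^2
#'       + \lambda_1 \sum_j w^b_{ij} |b_{ij}|
#'       + \lambda_2 \sum_j w^f_{ij} |f_{ij}|}
#' by joint coordinate descent over both blocks; each update is a
#' soft-threshold at the coordinate's weighted penalty divided by its
#' curvature (\eqn{y_j y_j'} for gene coordinates, \eqn{x_j x_j'} for
#' SNP coordinates), with every accepted update immediately visible to
#' subsequent coordinates. Infinite-weight coordinates (including the
#' diagonal \eqn{b_{ii}}) are frozen at zero and never touched.
#'
#' @param i target gene index.
#' @param Y,X data matrices (centered internally).
#' @param weights a [make_weights()] result; `w_b` must have length M
#'   and `w_f` length Ms.
#' @param lambda1,lambda2 nonnegative penalty levels for the two blocks.
#' @param init_b,init_f warm-start vectors (default zero); must be zero
#'   wherever the weight is infinite.
#' @param tol,max_sweeps convergence controls.
#' @param trace_objective record the objective after every sweep.
#' @return List with `b`, `f`, `objective`, `sweeps`, `converged`, and
#'   optionally `objective_trace`.
#' @export
adaptive_lasso_fit_gene <- function(i, Y, X, weights, lambda1, lambda2,
                                    init_b = NULL, init_f = NULL,
                                    tol = 1e-6, max_sweeps = 10000,
                                    trace_objective = FALSE) {
  ctx <- xprod_context(center_rows(Y), center_rows(X))
  adaptive_lasso_fit_gene_ctx(ctx, NULL, i, weights, lambda1, lambda2,
                              init_b = init_b, init_f = init_f,
                              tol = tol, max_sweeps = max_sweeps,
                              trace_objective = trace_objective)
}

adaptive_lasso_fit_gene_ctx <- function(ctx, G, i, weights, lambda1,
                                        lambda2, init_b = NULL,
                                        init_f = NULL, tol = 1e-6,
                                        max_sweeps = 10000,
                                        trace_objective = FALSE) {
  M <- ctx$M
  Ms <- ctx$Ms
  stopifnot(length(weights$w_b) == M, length(weights$w_f) == Ms)
  if (is.null(G)) G <- stacked_gram(ctx)
  if (is.null(init_b)) init_b <- numeric(M)
  if (is.null(init_f)) init_f <- numeric(Ms)
  w_b <- weights$w_b
  w_b[i] <- Inf  # no self-loop
  penalty <- c(lambda1 * w_b, lambda2 * weights$w_f)
  # lambda = 0 on an infinite weight must still freeze the coordinate
  penalty[is.nan(penalty)] <- Inf
  beta0 <- c(init_b, init_f)
  beta0[!is.finite(penalty)] <- 0
  sol <- cd_penalized_gram(G, stacked_q(ctx, i), ctx$Cyy[i, i], penalty,
                           beta0, tol = tol, max_sweeps = max_sweeps,
                           trace_objective = trace_objective)
  beta <- drop(sol$beta)
  list(b = beta[seq_len(M)], f = beta[M + seq_len(Ms)],
       objective = sol$objective, sweeps = sol$sweeps,
       converged = sol$converged,
       objective_trace = drop(sol$objective_trace))
}

# joint per-gene CV of (lambda1, lambda2) for adaptive lasso at fixed
# weights; lambda2 is skipped when no SNP coordinate is free
adaptive_lasso_cv_gene <- function(fc, i, weights,
                                   grid1 = lambda_grid_default(),
                                   grid2 = lambda_grid_default(),
                                   tol = 1e-6, max_sweeps = 10000) {
  f_free <- any(is.finite(weights$w_f))
  if (!f_free) grid2 <- grid2[1]
  err <- matrix(0, length(grid1), length(grid2))
  w_b <- weights$w_b
  w_b[i] <- Inf
  for (fold in fc) {
    ctx <- fold$train
    err <- err + cd_cv_grid(stacked_gram(ctx), stacked_q(ctx, i),
                            w_b, weights$w_f, grid1, grid2,
                            fold$G_val, stacked_q(fold$val, i),
                            fold$val$Cyy[i, i], tol = tol,
                            max_sweeps = max_sweeps)
  }
  best <- arrayInd(which.min(err), dim(err))
  list(lambda1 = grid1[best[1]], lambda2 = grid2[best[2]])
}
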