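#' Elastic-net SNP screen for one gene
#'
#' Minimizes the mixed-penalty objective
#' \deqn{\min_{b_i, f_i} \tfrac12\left(\|y_i - b_i Y_{(-i)} - f_i X\|_2^2
#'       + \lambda_1 \|b_i\|_2^2\right) + \lambda_2 \|f_i\|_1}
#' by coordinate descent over \eqn{f_i} with the gene block profiled out
#' through its ridge closed form. Profiling reduces the problem to a
#' weighted lasso under the positive-definite sample metric
#' \eqn{H = I - Y'(YY' + \lambda_1 I)^{-1} Y}: each coordinate update is
#' the soft-threshold rule \eqn{f_{ij} \gets S(C_j, \lambda_2) / a_j}
#' with curvature \eqn{a_j = x_j H x_j'} and partial-residual
#' correlation \eqn{C_j = (y_i - f_{i(-j)} X_{(-j)}) H x_j'}. SNPs with
#' nonzero coefficients are the candidate eQTLs passed to the lasso-path
#' finalization.
#'
#' @inheritParams ridge_fit_gene
#' @param tol convergence tolerance on the largest coordinate change per
#'   sweep.
#' @param max_sweeps sweep cap; non-convergence is flagged, not fatal.
#' @return List with `f` (sparse SNP coefficients), `b` (profiled gene
#'   coefficients, `b[i] == 0`), `objective`, `sweeps`, `converged`.
#' @export
elastic_net_fit_gene <- function(i, Y, X, lambda1, lambda2,
                                 tol = 1e-6, max_sweeps = 10000) {
  stopifnot(lambda1 > 0, lambda2 > 0, ncol(Y) == ncol(X))
  ctx <- xprod_context(center_rows(Y), center_rows(X))
  elastic_net_fit_gene_ctx(ctx, i, lambda1, lambda2, tol = tol,
                           max_sweeps = max_sweeps)
}

elastic_net_fit_gene_ctx <- function(ctx, i, lambda1, lambda2,
                                     f0 = NULL, prof = NULL,
                                     tol = 1e-6, max_sweeps = 10000,
                                     trace_objective = FALSE) {
  if (is.null(prof)) prof <- profile_gene(ctx, i, lambda1)
  if (is.null(f0)) f0 <- numeric(ctx$Ms)
  sol <- cd_penalized_gram(prof$G, prof$q, prof$yty,
                           rep(lambda2, ctx$Ms), f0,
                           tol = tol, max_sweeps = max_sweeps,
                           trace_objective = trace_objective)
  if (!sol$converged) {
    warning(sprintf(
      "elastic_net_fit_gene: gene %d not converged after %d sweeps", i,
      sol$sweeps))
  }
  f <- drop(sol$beta)
  b_mi <- drop(prof$u1 - f %*% prof$W)
  list(f = f, b = expand_b(b_mi, prof$mi, ctx$M),
       objective = sol$objective, sweeps = sol$sweeps,
       converged = sol$converged,
       objective_trace = drop(sol$objective_trace))
}

# per-gene CV of the elastic-net l1 penalty; lambda1 is carried over
# from the ridge stage (one value per gene). Selection uses the
# one-standard-error rule: the largest lambda2 whose mean held-out
# error is within one SE of the minimum. The screen's job is to keep
# plausible eQTL candidates, and the CV-minimum notoriously
# over-selects; the 1-SE choice prunes near-collinear bystanders (a
# parent gene's SNP tracking the parent's expression) that would later
# contaminate the path race.
elastic_net_cv_gene <- function(fc, i, lambda1,
                                lambda_grid = lambda_grid_default(),
                                tol = 1e-6, max_sweeps = 10000) {
  k <- length(fc)
  errs <- matrix(0, k, length(lambda_grid))
  for (kf in seq_len(k)) {
    fold <- fc[[kf]]
    prof <- profile_gene(fold$train, i, lambda1)
    f_warm <- numeric(length(prof$q))
    for (a in seq_along(lambda_grid)) {  # descending grid, warm starts
      sol <- cd_penalized_gram(prof$G, prof$q, prof$yty,
                               rep(lambda_grid[a], length(prof$q)),
                               f_warm, tol = tol,
                               max_sweeps = max_sweeps)
      f_warm <- drop(sol$beta)
      b_mi <- drop(prof$u1 - f_warm %*% prof$W)
      errs[kf, a] <- val_sse(fold, i,
                             expand_b(b_mi, prof$mi, fold$train$M),
                             f_warm)
    }
  }
  m <- colMeans(errs)
  se <- apply(errs, 2, stats::sd) / sqrt(k)
  thr <- min(m) + se[which.min(m)]
  # grid is descending, so the first qualifying index is the sparsest
  lambda_grid[min(which(m <= thr))]
}
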