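#' Ridge initialization for one gene
#'
#' Solves the doubly l2-penalized structural regression
#' \deqn{\min_{b_i, f_i} \|y_i - b_i Y_{(-i)} - f_i X\|_2^2
#'       + \lambda_1 \|b_i\|_2^2 + \lambda_2 \|f_i\|_2^2}
#' in closed form: \eqn{f_i = y_i S_1 (X S_1 + \lambda_2 I)^{-1}} with
#' \eqn{S_1 = X' - Y'(YY' + \lambda_1 I)^{-1} Y X'} (gene i's own row
#' excluded from Y so that \eqn{b_{ii} = 0}), then
#' \eqn{b_i = (y_i - f_i X) Y' (YY' + \lambda_1 I)^{-1}}.
#'
#' @param i target gene index.
#' @param Y expression matrix (genes x samples); centered internally.
#' @param X genotype matrix (SNPs x samples); centered internally.
#' @param lambda1,lambda2 positive ridge penalties on gene and SNP
#'   coefficients.
#' @return List with `b` (length M, `b[i] == 0`) and `f` (length Ms).
#' @export
ridge_fit_gene <- function(i, Y, X, lambda1, lambda2) {
  stopifnot(lambda1 > 0, lambda2 > 0, ncol(Y) == ncol(X))
  ctx <- xprod_context(center_rows(Y), center_rows(X))
  ridge_fit_gene_ctx(ctx, i, lambda1, lambda2)
}

ridge_fit_gene_ctx <- function(ctx, i, lambda1, lambda2, prof = NULL) {
  if (is.null(prof)) prof <- profile_gene(ctx, i, lambda1)
  f <- drop(solve(prof$G + diag(lambda2, ctx$Ms), prof$q))
  b_mi <- drop(prof$u1 - f %*% prof$W)
  list(b = expand_b(b_mi, prof$mi, ctx$M), f = f)
}

#' Per-gene cross-validation of the ridge penalties
#'
#' K-fold cross-validation (default K = 5) of held-out squared
#' prediction error over a joint log-spaced grid for
#' \eqn{(\lambda_1, \lambda_2)}, one pair selected per gene. Fold
#' assignment is drawn from the current RNG state.
#'
#' @param Y,X data matrices (centered internally).
#' @param lambda_grid descending vector of candidate penalties (used for
#'   both \eqn{\lambda_1} and \eqn{\lambda_2}).
#' @param k_folds number of folds.
#' @param folds optional explicit fold assignment (length N).
#' @return List with per-gene vectors `lambda1`, `lambda2`, and the
#'   `folds` used.
#' @export
ridge_cv <- function(Y, X, lambda_grid = lambda_grid_default(),
                     k_folds = 5, folds = NULL) {
  if (length(lambda_grid) == 0L) stop("ridge_cv: empty lambda grid")
  Yc <- center_rows(Y)
  Xc <- center_rows(X)
  if (is.null(folds)) folds <- make_folds(ncol(Yc), k_folds)
  fc <- fold_contexts(Yc, Xc, folds)
  M <- nrow(Yc)
  n1 <- length(lambda_grid)
  l1 <- l2 <- numeric(M)
  for (i in seq_len(M)) {
    err <- matrix(0, n1, n1)  # lambda1 x lambda2
    for (fold in fc) {
      qv_val <- stacked_q(fold$val, i)
      yv <- fold$val$Cyy[i, i]
      for (a in seq_len(n1)) {
        prof <- profile_gene(fold$train, i, lambda_grid[a])
        eg <- eigen(prof$G, symmetric = TRUE)
        qrot <- drop(crossprod(eg$vectors, prof$q))
        # all lambda2 solutions at once: f(l2) = V (qrot / (d + l2))
        Fmat <- eg$vectors %*% (qrot / outer(eg$values, lambda_grid, "+"))
        Bmat <- matrix(prof$u1, n1, M - 1, byrow = TRUE) -
          crossprod(Fmat, prof$W)
        Ms <- nrow(Fmat)
        Beta <- matrix(0, n1, M + Ms)
        Beta[, prof$mi] <- Bmat
        Beta[, M + seq_len(Ms)] <- t(Fmat)
        err[a, ] <- err[a, ] + yv - 2 * drop(Beta %*% qv_val) +
          rowSums((Beta %*% fold$G_val) * Beta)
      }
    }
    best <- arrayInd(which.min(err), dim(err))
    l1[i] <- lambda_grid[best[1]]
    l2[i] <- lambda_grid[best[2]]
  }
  list(lambda1 = l1, lambda2 = l2, folds = folds)
}

#' Restricted ridge refit on a fixed eQTL support
#'
#' Per-gene ridge refit used to initialize the iterative adaptive lasso:
#' the gene block keeps its l2 penalty \eqn{\lambda_1} while the single
#' retained SNP coefficient is left unpenalized (\eqn{\lambda_2 = 0});
#' all other SNP coefficients are fixed at zero. Genes with no retained
#' SNP get an all-zero f row and a plain ridge fit for b.
#'
#' @param Y,X data matrices (centered internally).
#' @param snp_of_gene integer vector, length M: retained SNP index per
#'   gene, `NA` for genes with no eQTL candidate.
#' @param lambda1_vec per-gene ridge penalty for the gene block.
#' @return List with matrices `B` (M x M, zero diagonal) and `F`
#'   (M x Ms, at most one nonzero per row).
#' @export
refit_ridge_restricted <- function(Y, X, snp_of_gene, lambda1_vec) {
  Yc <- center_rows(Y)
  Xc <- center_rows(X)
  ctx <- xprod_context(Yc, Xc)
  refit_ridge_restricted_ctx(ctx, snp_of_gene, lambda1_vec)
}

refit_ridge_restricted_ctx <- function(ctx, snp_of_gene, lambda1_vec) {
  M <- ctx$M
  stopifnot(length(snp_of_gene) == M, length(lambda1_vec) == M)
  B <- matrix(0, M, M)
  Fm <- matrix(0, M, ctx$Ms)
  for (i in seq_len(M)) {
    mi <- setdiff(seq_len(M), i)
    k <- snp_of_gene[i]
    if (is.na(k)) {
      A <- solve(ctx$Cyy[mi, mi, drop = FALSE] +
                   diag(lambda1_vec[i], M - 1))
      B[i, mi] <- drop(ctx$Cyy[i, mi, drop = FALSE] %*% A)
      next
    }
    G <- rbind(cbind(ctx$Cyy[mi, mi, drop = FALSE],
                     ctx$Cyx[mi, k, drop = FALSE]),
               cbind(t(ctx$Cyx[mi, k, drop = FALSE]),
                     ctx$Cxx[k, k, drop = FALSE]))
    D <- diag(c(rep(lambda1_vec[i], M - 1), 0), M)
    q <- c(ctx$Cyy[i, mi], ctx$Cyx[i, k])
    beta <- drop(solve(G + D, q))
    B[i, mi] <- beta[seq_len(M - 1)]
    Fm[i, k] <- beta[M]
  }
  list(B = B, F = Fm)
}

# CV of lambda1 for the restricted ridge (IAL1 entry point: the
# screening stages are skipped but Step 3's initialization still needs a
# per-gene lambda1)
ridge_cv_restricted <- function(Yc, Xc, snp_of_gene,
                                lambda_grid = lambda_grid_default(),
                                k_folds = 5, folds = NULL) {
  if (is.null(folds)) folds <- make_folds(ncol(Yc), k_folds)
  fc <- fold_contexts(Yc, Xc, folds)
  M <- nrow(Yc)
  l1 <- numeric(M)
  for (i in seq_len(M)) {
    err <- numeric(length(lambda_grid))
    for (fold in fc) {
      for (a in seq_along(lambda_grid)) {
        fit <- refit_ridge_restricted_ctx_gene(fold$train, i,
                                               snp_of_gene[i],
                                               lambda_grid[a])
        err[a] <- err[a] + val_sse(fold, i, fit$b, fit$f)
      }
    }
    l1[i] <- lambda_grid[which.min(err)]
  }
  list(lambda1 = l1, folds = folds)
}

refit_ridge_restricted_ctx_gene <- function(ctx, i, k, lambda1) {
  M <- ctx$M
  mi <- setdiff(seq_len(M), i)
  b <- numeric(M)
  f <- numeric(ctx$Ms)
  if (is.na(k)) {
    A <- solve(ctx$Cyy[mi, mi, drop = FALSE] + diag(lambda1, M - 1))
    b[mi] <- drop(ctx$Cyy[i, mi, drop = FALSE] %*% A)
  } else {
    G <- rbind(cbind(ctx$Cyy[mi, mi, drop = FALSE],
                     ctx$Cyx[mi, k, drop = FALSE]),
               cbind(t(ctx$Cyx[mi, k, drop = FALSE]),
                     ctx$Cxx[k, k, drop = FALSE]))
    D <- diag(c(rep(lambda1, M - 1), 0), M)
    q <- c(ctx$Cyy[i, mi], ctx$Cyx[i, k])
    beta <- drop(solve(G + D, q))
    b[mi] <- beta[seq_len(M - 1)]
    f[k] <- beta[M]
  }
  list(b = b, f = f)
}
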