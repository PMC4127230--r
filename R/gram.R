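# Internal cross-product ("Gram") contexts.
#
# Every per-gene subproblem in the pipeline depends on the data only
# through the cross-products YY', YX', XX' (and their restrictions to a
# training fold), so these are computed once per dataset/fold and all
# fits, profiled objectives and held-out errors are evaluated at O(M^2)
# cost, independent of the sample count.

xprod_context <- function(Yc, Xc) {
  list(Cyy = tcrossprod(Yc),
       Cyx = tcrossprod(Yc, Xc),
       Cxx = tcrossprod(Xc),
       M = nrow(Yc), Ms = nrow(Xc), N = ncol(Yc))
}

# full stacked Gram of [Y; X] and its q-vector for gene i
stacked_gram <- function(ctx) {
  rbind(cbind(ctx$Cyy, ctx$Cyx),
        cbind(t(ctx$Cyx), ctx$Cxx))
}

stacked_q <- function(ctx, i) {
  c(ctx$Cyy[i, ], ctx$Cyx[i, ])
}

# deterministic fold assignment: permuted, balanced
make_folds <- function(n, k) {
  stopifnot(k >= 2, n >= k)
  sample(rep_len(seq_len(k), n))
}

# per-fold train/validation contexts (data already centered globally)
fold_contexts <- function(Yc, Xc, folds) {
  k <- max(folds)
  lapply(seq_len(k), function(f) {
    tr <- folds != f
    ctx_tr <- xprod_context(Yc[, tr, drop = FALSE], Xc[, tr, drop = FALSE])
    ctx_va <- xprod_context(Yc[, !tr, drop = FALSE], Xc[, !tr, drop = FALSE])
    list(train = ctx_tr, val = ctx_va,
         G_val = stacked_gram(ctx_va))
  })
}

# held-out squared prediction error of y_i ~ b Y + f X, Gram form
val_sse <- function(fold, i, b, f) {
  beta <- c(b, f)
  qv <- stacked_q(fold$val, i)
  drop(fold$val$Cyy[i, i] - 2 * sum(beta * qv) +
         beta %*% fold$G_val %*% beta)
}

# log-spaced penalty grid, descending
lambda_grid_default <- function(n = 20, lo = 1e-3, hi = 1e3) {
  exp(seq(log(hi), log(lo), length.out = n))
}

# profiled-gene quantities for gene i at ridge penalty lambda1:
#  A    = (Y_(-i) Y_(-i)' + lambda1 I)^-1
#  G    = X H X'   with H = I - Y_(-i)' A Y_(-i)   (PSD sample metric)
#  q    = X H y_i'
#  yty  = y_i H y_i'
#  u1, W: pieces of the profiled b_i = (y_i - f X) Y_(-i)' A = u1 - f W
profile_gene <- function(ctx, i, lambda1) {
  mi <- setdiff(seq_len(ctx$M), i)
  A <- solve(ctx$Cyy[mi, mi, drop = FALSE] +
               diag(lambda1, length(mi)))
  Cyx_mi <- ctx$Cyx[mi, , drop = FALSE]
  u1 <- drop(ctx$Cyy[i, mi, drop = FALSE] %*% A)       # 1 x (M-1)
  W <- crossprod(Cyx_mi, A)                            # Ms x (M-1)
  G <- ctx$Cxx - W %*% Cyx_mi                          # X H X'
  q <- drop(ctx$Cyx[i, ] - u1 %*% Cyx_mi)              # X H y'
  yty <- drop(ctx$Cyy[i, i] - ctx$Cyy[i, mi, drop = FALSE] %*% A %*%
                ctx$Cyy[mi, i, drop = FALSE])
  list(A = A, G = G, q = q, yty = yty, u1 = u1, W = W, mi = mi)
}

# expand a b-vector over genes != i to the full M-vector with b[i] = 0
expand_b <- function(b_mi, mi, M) {
  b <- numeric(M)
  b[mi] <- b_mi
  b
}
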