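# Independent convex-solver oracle: accelerated proximal gradient
# (FISTA) on the exact objective
#
#   0.5 * || y - beta R ||^2 + 0.5 * sum_j l2pen_j beta_j^2
#                            + sum_j l1pen_j |beta_j|
#
# where R holds regressors in rows. An l1pen of +Inf freezes a
# coordinate at zero. Algorithmically unrelated to the coordinate
# descent under test; run to high precision and compared on objective
# values.

fista_solve <- function(R, y, l1pen, l2pen = rep(0, nrow(R)),
                        iters = 50000, tol = 1e-12) {
  G <- tcrossprod(R)
  q <- drop(R %*% y)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    max(l2pen, 0)
  frozen <- !is.finite(l1pen)
  l1 <- ifelse(frozen, 0, l1pen)
  beta <- z <- numeric(nrow(R))
  tk <- 1
  obj_old <- Inf
  for (it in seq_len(iters)) {
    grad <- drop(G %*% z) - q + l2pen * z
    bn <- z - grad / L
    bn <- sign(bn) * pmax(abs(bn) - l1 / L, 0)
    bn[frozen] <- 0
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + ((tk - 1) / tn) * (bn - beta)
    beta <- bn
    tk <- tn
    if (it %% 200 == 0) {
      obj <- pls_objective(R, y, beta, l1pen, l2pen)
      if (abs(obj_old - obj) < tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  beta
}

pls_objective <- function(R, y, beta, l1pen, l2pen = rep(0, nrow(R))) {
  r <- y - drop(crossprod(R, beta))
  pen1 <- sum(ifelse(beta == 0, 0, l1pen * abs(beta)))
  0.5 * sum(r^2) + 0.5 * sum(l2pen * beta^2) + pen1
}

# small dense centered test instances with a planted sparse signal
make_instance <- function(m_g, m_s, n, seed) {
  set.seed(seed)
  X <- matrix(sample(c(1, 2, 3), m_s * n, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), m_s, n)
  B <- matrix(0, m_g, m_g)
  B[lower.tri(B)] <- rbinom(sum(lower.tri(B)), 1, 0.4) *
    runif(sum(lower.tri(B)), 0.5, 1)
  Fm <- diag(runif(m_g, 0.5, 1), m_g, m_s)
  E <- matrix(rnorm(m_g * n, sd = 0.1), m_g, n)
  Y <- solve(diag(m_g) - B, Fm %*% X + E)
  list(Y = center_rows(Y), X = center_rows(X), B = B, F = Fm)
}

# objective of the mixed elastic-net problem (l2 on genes, l1 on SNPs)
# in the (b, f) parameterization used by the screening stage
en_objective <- function(i, Y, X, b, f, lambda1, lambda2) {
  mi <- setdiff(seq_len(nrow(Y)), i)
  r <- Y[i, ] - drop(crossprod(Y[mi, , drop = FALSE], b[mi])) -
    drop(crossprod(X, f))
  0.5 * (sum(r^2) + lambda1 * sum(b^2)) + lambda2 * sum(abs(f))
}

# objective of the weighted two-block lasso in (b, f)
al_objective <- function(i, Y, X, b, f, weights, lambda1, lambda2) {
  r <- Y[i, ] - drop(crossprod(Y, b)) - drop(crossprod(X, f))
  pb <- ifelse(b == 0, 0, lambda1 * weights$w_b * abs(b))
  pf <- ifelse(f == 0, 0, lambda2 * weights$w_f * abs(f))
  0.5 * sum(r^2) + sum(pb) + sum(pf)
}
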