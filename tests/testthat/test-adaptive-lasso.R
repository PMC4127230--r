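test_that("penalty weights follow the inverse-power law with freezing", {
  expect_equal(make_weights(1, 1, 2, 2)$w_b, 1)        # 1^(-a) = 1
  expect_equal(make_weights(0.5, 0.5, 1, 1)$w_b, 2)    # 0.5^(-1)
  w <- make_weights(c(0.3, 0), c(0.3, 0), 0, 0)
  expect_equal(w$w_f, c(1, Inf))                       # a = b = 0 case
  expect_equal(w$w_b, c(1, Inf))
  w2 <- make_weights(c(0.25, 1e-12), c(2, 0.5), 0.5, 0.5)
  expect_equal(w2$w_b, c(2, Inf))
  expect_equal(w2$w_f, c(1 / sqrt(2), sqrt(2)))
  expect_error(make_weights(1, 1, -1, 0), "nonnegative")
})

test_that("adaptive lasso obeys the dead zone and frozen coordinates", {
  ins <- make_instance(4, 4, 25, seed = 51)
  i <- 2
  # enormous lambda1: every finite-weight b lands in the dead zone
  w <- make_weights(rep(1, 4), rep(1, 4), 0, 0)
  fit <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w, 1e9, 0.1)
  expect_true(all(fit$b == 0))

  # all-infinite f weights: f stays exactly zero, genes still fit
  w2 <- make_weights(rep(1, 4), rep(0, 4), 0, 0.5)
  fit2 <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w2, 0.05, 0.05)
  expect_true(all(fit2$f == 0))
  expect_true(any(fit2$b != 0))
  expect_identical(fit2$b[i], 0)
})

test_that("adaptive lasso matches the convex oracle with finite weights", {
  ins <- make_instance(4, 4, 25, seed = 52)
  set.seed(52)
  for (i in c(1, 4)) {
    w <- make_weights(runif(4, 0.3, 2), runif(4, 0.3, 2), 1, 0.5)
    l1 <- 0.4
    l2 <- 0.6
    fit <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w, l1, l2)
    R <- rbind(ins$Y, ins$X)
    l1pen <- c(l1 * w$w_b, l2 * w$w_f)
    l1pen[i] <- Inf  # no self-loop
    beta_o <- fista_solve(R, ins$Y[i, ], l1pen = l1pen)
    obj_cd <- al_objective(i, ins$Y, ins$X, fit$b, fit$f, w, l1, l2)
    obj_or <- al_objective(i, ins$Y, ins$X, beta_o[1:4], beta_o[5:8],
                           w, l1, l2)
    expect_lt(abs(obj_cd - obj_or), 1e-6)
  }
})

test_that("adaptive-lasso objective is non-increasing across sweeps", {
  ins <- make_instance(5, 5, 30, seed = 53)
  for (i in c(2, 3)) {
    w <- make_weights(rep(0.8, 5), rep(0.8, 5), 1, 0.5)
    fit <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w, 0.2, 0.2,
                                   trace_objective = TRUE)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("unit weights at equal lambdas reduce to the plain joint lasso", {
  ins <- make_instance(4, 4, 25, seed = 54)
  i <- 3
  lam <- 1.5
  w <- make_weights(rep(1, 4), rep(1, 4), 0, 0)
  fit <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w, lam, lam)
  # same problem through the generic kernel on [Y_(-i); X]
  mi <- setdiff(1:4, i)
  R <- rbind(ins$Y[mi, , drop = FALSE], ins$X)
  cd <- ialnet:::cd_penalized_gram(tcrossprod(R),
                                   drop(R %*% ins$Y[i, ]),
                                   sum(ins$Y[i, ]^2),
                                   rep(lam, 7), numeric(7))
  expect_equal(fit$b[mi], drop(cd$beta)[1:3], tolerance = 1e-5)
  expect_equal(fit$f, drop(cd$beta)[4:7], tolerance = 1e-5)
})

test_that("stronger weight exponents only prune sub-unit coefficients", {
  ins <- make_instance(5, 5, 40, seed = 55)
  i <- 2
  b_hat <- c(0.9, 0.04, 0, 0.3, 0.6)
  f_hat <- c(0, 0.8, 0, 0, 0)
  supp_prev <- NULL
  for (a in c(0.5, 1.5, 3)) {
    w <- make_weights(b_hat, f_hat, a, 0.5)
    fit <- adaptive_lasso_fit_gene(i, ins$Y, ins$X, w, 0.3, 0.3)
    supp <- which(abs(fit$b) > 1e-8)
    if (!is.null(supp_prev)) expect_true(all(supp %in% supp_prev))
    supp_prev <- supp
  }
})
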