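test_that("sampled networks are acyclic with the configured edge law", {
  cfg <- sgrn_sim_config(10, 50, edges_per_gene = 1, seed = 3)
  set.seed(3)
  counts <- numeric(200)
  for (r in seq_len(200)) {
    mod <- sample_network(cfg)
    expect_true(all(diag(mod$B) == 0))
    # permuting by the generating order gives strict lower-triangularity
    P <- mod$B[mod$order, mod$order]
    expect_true(all(P[upper.tri(P, diag = TRUE)] == 0))
    nz <- mod$B[mod$B != 0]
    if (length(nz) > 0) {
      expect_true(all(abs(nz) >= 0.5 & abs(nz) <= 1))
    }
    # one eQTL per gene, diagonal, same coefficient law
    expect_true(all(abs(diag(mod$F)) >= 0.5 & abs(diag(mod$F)) <= 1))
    expect_equal(nrow(support_indices(mod$F)), 10L)
    counts[r] <- sum(mod$B != 0)
  }
  # expected edge count Eg * M = 10; 200 draws give a tight mean
  expect_gt(mean(counts), 10 * 0.85)
  expect_lt(mean(counts), 10 * 1.15)
  expect_error(sgrn_sim_config(4, 50, edges_per_gene = 3), "budget")
})

test_that("genotype draws follow the 0.25/0.5/0.25 law", {
  cfg <- sgrn_sim_config(100, 1000, seed = 5)  # 1e5 draws
  set.seed(5)
  X <- sample_genotypes(cfg)
  expect_true(all(X %in% c(1, 2, 3)))
  freqs <- tabulate(as.vector(X), 3) / length(X)
  expect_lt(abs(freqs[1] - 0.25), 0.01)
  expect_lt(abs(freqs[2] - 0.50), 0.01)
  expect_lt(abs(freqs[3] - 0.25), 0.01)
})

test_that("expression generation solves the structural equations", {
  # B = 0, F = I, no noise: Y equals X
  cfg <- sgrn_sim_config(4, 6, seed = 1)
  mod <- structure(list(B = matrix(0, 4, 4), F = diag(4),
                        noise_variance = 0),
                   class = "sem_model")
  set.seed(1)
  X <- sample_genotypes(cfg)
  gen <- generate_expression(mod, X, E = matrix(0, 4, 6))
  expect_equal(unname(gen$Y), unname(X) * 1)

  # 2-gene chain b21 = 1, F = I, x = (1,1): y = (1, 2)
  mod2 <- structure(list(B = matrix(c(0, 1, 0, 0), 2, 2),
                         F = diag(2), noise_variance = 0),
                    class = "sem_model")
  g2 <- generate_expression(mod2, matrix(1, 2, 2),
                            E = matrix(0, 2, 2))
  expect_equal(unname(g2$Y[, 1]), c(1, 2))

  # singular (I - B) is rejected with a clear message
  bad <- structure(list(B = diag(2), F = diag(2), noise_variance = 0),
                   class = "sem_model")
  expect_error(generate_expression(bad, matrix(1, 2, 2)), "singular")
})

test_that("simulated datasets store the exact noise realization", {
  sim <- sgrn_simulate(sgrn_sim_config(10, 100, 2, seed = 17))
  resid <- (diag(10) - sim$model$B) %*% sim$Y - sim$model$F %*% sim$X
  expect_lt(max(abs(resid - sim$E)), 1e-10)
  # structural noise variance matches the configured 0.01
  sim2 <- sgrn_simulate(sgrn_sim_config(10, 500, 1, seed = 23))
  r2 <- (diag(10) - sim2$model$B) %*% sim2$Y - sim2$model$F %*% sim2$X
  expect_lt(abs(var(as.vector(r2)) - 0.01) / 0.01, 0.2)
})

test_that("the same seed reproduces a dataset bit for bit", {
  a <- sgrn_simulate(sgrn_sim_config(8, 40, 1.5, seed = 99))
  b <- sgrn_simulate(sgrn_sim_config(8, 40, 1.5, seed = 99))
  expect_identical(a$Y, b$Y)
  expect_identical(a$X, b$X)
  expect_identical(a$model$B, b$model$B)
})
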