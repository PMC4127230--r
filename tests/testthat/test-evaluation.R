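test_that("structure metrics follow the TPR/FDR definitions", {
  u <- b_slot_universe(3)
  s <- rbind(c(1, 2))
  m <- structure_metrics(s, s, u)
  expect_equal(m$tpr, 1)
  expect_equal(m$fdr, 0)

  # hand-enumerated: true {(1,2)}, inferred {(1,2),(2,3)}
  m2 <- structure_metrics(rbind(c(1, 2)), rbind(c(1, 2), c(2, 3)), u)
  expect_equal(unname(m2$counts["tp"]), 1L)
  expect_equal(unname(m2$counts["fp"]), 1L)
  expect_equal(unname(m2$counts["fn"]), 0L)
  expect_equal(m2$tpr, 1)
  expect_equal(m2$fdr, 0.5)

  # nothing predicted: TPR 0, FDR 0 by the TP+FP=0 convention
  m3 <- structure_metrics(s, matrix(numeric(0), 0, 2), u)
  expect_equal(m3$tpr, 0)
  expect_equal(m3$fdr, 0)

  expect_error(structure_metrics(rbind(c(1, 1)), s, u), "universe")
})

test_that("structure metrics agree with brute-force slot enumeration", {
  set.seed(71)
  u <- b_slot_universe(5)
  for (rep in 1:100) {
    truth <- u[runif(nrow(u)) < 0.3, , drop = FALSE]
    pred <- u[runif(nrow(u)) < 0.3, , drop = FALSE]
    m <- structure_metrics(truth, pred, u)
    # brute force over every slot
    tp <- fp <- tn <- fn <- 0L
    for (k in seq_len(nrow(u))) {
      in_t <- any(truth[, 1] == u[k, 1] & truth[, 2] == u[k, 2])
      in_p <- any(pred[, 1] == u[k, 1] & pred[, 2] == u[k, 2])
      if (in_t && in_p) tp <- tp + 1L
      else if (!in_t && in_p) fp <- fp + 1L
      else if (in_t && !in_p) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(unname(m$counts), c(tp, fp, tn, fn))
    expect_equal(sum(m$counts), nrow(u))
  }
})

test_that("eQTL assignment metrics count one prediction per gene", {
  # 14 pairs, 13 correct, 1 wrong: TPR 13/14, FDR 1/14
  truth <- 1:14
  pred <- truth
  pred[14] <- 3L
  m <- eqtl_assignment_metrics(truth, pred)
  expect_equal(m$tpr, 0.9286, tolerance = 1e-3)
  expect_equal(m$fdr, 0.0714, tolerance = 1e-3)
  # missing assignment counts as a false negative only
  m2 <- eqtl_assignment_metrics(c(1L, 2L), c(1L, NA))
  expect_equal(unname(m2$counts), c(1L, 0L, 1L))
  expect_equal(m2$tpr, 0.5)
  expect_equal(m2$fdr, 0)
})

test_that("benchmark harness is reproducible and validates input", {
  expect_error(run_benchmark(data.frame(M = 5, N = 30, Eg = 1),
                             replicates = 0), "replicates")
  s <- data.frame(M = 6, N = 60, Eg = 1)
  b1 <- run_benchmark(s, modes = "ial1", replicates = 2, base_seed = 3)
  b2 <- run_benchmark(s, modes = "ial1", replicates = 2, base_seed = 3)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 2L)
  expect_equal(b1$seed, c(3L, 4L))
  expect_true(all(b1$tpr_b >= 0 & b1$tpr_b <= 1))
  summ <- summarize_benchmark(b1)
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$replicates, 2L)
})
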