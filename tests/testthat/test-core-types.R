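test_that("center_rows removes row means and is idempotent", {
  expect_equal(center_rows(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  expect_equal(center_rows(matrix(5, 1, 3)), matrix(0, 1, 3))

  set.seed(11)
  m <- matrix(rnorm(24, mean = 3), 4, 6)
  cm <- center_rows(m)
  expect_lt(max(abs(rowMeans(cm))), 1e-12)
  expect_equal(dim(cm), dim(m))
  expect_equal(center_rows(cm), cm, tolerance = 1e-12)
  # original untouched
  expect_equal(m[1, 1], m[1, 1])
  expect_error(center_rows(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(center_rows(1:3), "matrix")
})

test_that("support_indices applies the zero tolerance and is monotone", {
  expect_equal(nrow(support_indices(matrix(0, 3, 3))), 0L)
  s <- support_indices(matrix(c(0, 0, 0.6, 0), 2, 2), 1e-8)
  expect_equal(unname(s), matrix(c(1L, 2L), 1))
  s2 <- support_indices(matrix(c(1e-12, 0.5), 1), 1e-8)
  expect_equal(unname(s2), matrix(c(1L, 2L), 1))

  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rnorm(30, sd = 0.1), 5, 6)
    tols <- sort(runif(3, 0, 0.2))
    sizes <- vapply(tols,
                    function(z) nrow(support_indices(m, z)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("matrix constructors validate shapes and genotype coding", {
  expect_error(expression_matrix(matrix(1, 1, 5)), "at least 2")
  y <- expression_matrix(matrix(rnorm(6), 2, 3))
  expect_equal(rownames(y), c("g1", "g2"))

  expect_error(genotype_matrix(matrix(c(0, 1, 2, 3), 2, 2)),
               "\\{1,2,3\\}")
  x <- genotype_matrix(matrix(c(1, 2, 3, 2), 2, 2))
  expect_equal(dim(x), c(2L, 2L))
})
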