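test_that("materialize produces a right stochastic matrix", {
  expect_equal(materialize(matrix(0, 2, 2)), matrix(0.5, 2, 2))
  A <- materialize(matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(A[1, ], c(exp(10), 1) / (exp(10) + 1), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    phi <- matrix(rnorm(25, sd = 3), 5, 5)
    A <- materialize(phi)
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
    expect_true(all(A > 0))
  }
})

test_that("forward map reduces to concatenation for the identity matrix", {
  mix <- mixing_init(4, 2)
  mix$phi <- diag(40, 4)                      # permutation special case
  z <- matrix(rnorm(6), 3, 2)
  X <- matrix(rnorm(6), 3, 2)
  expect_equal(forward_map(mix, z, X), cbind(z, X), tolerance = 1e-12)
})

test_that("the 2x2 map with a1 = 1, a2 = 0 sends z to x1 and X to x2", {
  mix <- mixing_init(2, 1)
  mix$phi <- matrix(c(40, 0, 0, 40), 2, 2)    # A = [[1,0],[0,1]] up to 4e-18
  x <- forward_map(mix, 1.5, -0.7)
  expect_equal(as.numeric(x), c(1.5, -0.7), tolerance = 1e-12)
  iv <- inverse_map(mix, x)
  expect_equal(as.numeric(iv$z), 1.5, tolerance = 1e-12)
})

test_that("forward then inverse round-trips for random positive-det maps", {
  set.seed(3)
  for (i in 1:5) {
    mix <- mixing_init(6, 2)
    mix$phi <- diag(1.5, 6) + matrix(rnorm(36, sd = 0.4), 6, 6)
    if (cgflow:::det_sign(mix) <= 0) next
    z <- matrix(rnorm(8), 4, 2)
    X <- matrix(rnorm(16), 4, 4)
    iv <- inverse_map(mix, forward_map(mix, z, X))
    expect_equal(iv$z, z, tolerance = 1e-10)
    expect_equal(iv$X, X, tolerance = 1e-10)
  }
})

test_that("log_abs_det matches closed forms and the eigenvalue oracle", {
  expect_equal(log_abs_det(diag(3)), 0)
  expect_equal(log_abs_det(matrix(c(1, 0, 0, 2), 2, 2)), log(2))
  set.seed(4)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4, 4)
    expect_equal(log_abs_det(A), sum(log(abs(eigen(A)$values))),
                 tolerance = 1e-8)
  }
  ## block_size multiplicity
  mix <- mixing_init(6, 3, block_size = 3L, diag_boost = 2)
  A <- materialize(mix)
  expect_equal(log_abs_det(mix), 3 * log(det(A)), tolerance = 1e-12)
})

test_that("singular maps are rejected", {
  mix <- mixing_init(2, 1)
  ## phi with identical rows -> A has identical rows -> singular
  mix$phi <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  expect_error(forward_map(mix, 1, 1), "singular")
  expect_error(inverse_map(mix, c(1, 1)), "singular")
})

test_that("row-stochastic maps are translation equivariant, others are not", {
  mix <- mixing_init(12, 6, block_size = 3L, diag_boost = 1)
  mix$phi <- mix$phi + matrix(rnorm(16, sd = 0.7), 4, 4)
  t <- c(0.3, -1.2, 2.0)
  expect_true(translation_equivariance_check(mix, t))
  expect_true(translation_equivariance_check(mix, c(0, 0, 0)))
  ## counterexample: a row summing to 2 breaks equivariance
  A_bad <- materialize(matrix(rnorm(16), 4, 4))
  A_bad[1, ] <- 2 * A_bad[1, ]
  expect_false(translation_equivariance_check(A_bad, t, dim_z = 6))
})

test_that("log K is independent of (z, X) and its sample gradient is zero", {
  ## for the linear map the transformed-force log K corrections of the
  ## chain rule vanish identically: the per-sample phi-gradient comes only
  ## from the outer product with the configuration
  mix <- mixing_init(4, 2, diag_boost = 1)
  expect_equal(log_abs_det(mix), log_abs_det(mix))  # constant by construction
  V1 <- matrix(rnorm(8), 2, 4)
  c1 <- cgflow:::mix_forward(mix, V1)
  c2 <- cgflow:::mix_forward(mix, 5 * V1)
  ## the map Jacobian (and hence log K) does not change with the input
  expect_equal(c1$A, c2$A)
})

test_that("mixing matrices export to CSV", {
  mix <- mixing_init(3, 1, diag_boost = 1)
  path <- tempfile(fileext = ".csv")
  mixing_write_csv(mix, path)
  M <- as.matrix(read.csv(path))
  expect_equal(unname(M), materialize(mix), tolerance = 1e-12)
})
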