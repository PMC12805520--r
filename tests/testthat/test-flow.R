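test_that("identity-initialized flow is the identity with zero log-Jacobian", {
  for (dz in c(1L, 3L)) {
    fl <- with_seed(1, flow_init(dz, 4L, interval = 4))
    fs <- flow_sample(fl, 50, seed = 2)
    expect_equal(fs$z, fs$eps)
    expect_equal(fs$logJ, rep(0, 50))
  }
})

test_that("samples never leave the spline support", {
  fl <- with_seed(3, flow_init(2L, 4L, interval = 4))
  ## jitter all parameters to get a non-trivial transform
  v <- cgflow:::flow_get(fl)
  fl <- cgflow:::flow_set(fl, v + with_seed(4, rnorm(length(v), sd = 0.2)))
  fs <- flow_sample(fl, 2000, seed = 5)
  expect_true(all(abs(fs$z) <= 4))
})

test_that("base samples match truncated-normal moments", {
  fl <- with_seed(6, flow_init(1L, 1L, interval = 4))
  fs <- flow_sample(fl, 1e5, seed = 7)
  v_exact <- cgflow:::truncnorm_var(4)
  expect_equal(mean(fs$eps), 0, tolerance = 3 / sqrt(1e5) * sqrt(v_exact))
  expect_equal(var(as.numeric(fs$eps)), v_exact, tolerance = 0.02)
})

test_that("identity-flow log-density equals the truncated normal", {
  fl <- with_seed(8, flow_init(1L, 2L, interval = 5))
  lp <- flow_log_prob(fl, matrix(0, 1, 1))
  expect_equal(lp, dnorm(0, log = TRUE) - cgflow:::truncnorm_lognorm(5),
               tolerance = 1e-12)
  expect_equal(flow_log_prob(fl, matrix(6, 1, 1)), -Inf)
})

test_that("flow density is normalized (1-D quadrature)", {
  fl <- with_seed(9, flow_init(1L, 3L, interval = 4))
  v <- cgflow:::flow_get(fl)
  fl <- cgflow:::flow_set(fl, v + with_seed(10, rnorm(length(v), sd = 0.2)))
  ## composite Simpson on a fine grid (the spline density has knot kinks
  ## that defeat adaptive quadrature at tight tolerances)
  n <- 8000L
  g <- seq(-4, 4, length.out = n + 1L)
  fv <- exp(flow_log_prob(fl, matrix(g, ncol = 1)))
  h <- g[2] - g[1]
  val <- h / 3 * (fv[1] + fv[n + 1L] + 4 * sum(fv[seq(2, n, 2)]) +
                  2 * sum(fv[seq(3, n - 1, 2)]))
  expect_equal(val, 1, tolerance = 1e-6)
})

test_that("inverse consistency g^-1(g(eps)) = eps", {
  for (dz in c(1L, 2L, 3L)) {
    fl <- with_seed(11 + dz, flow_init(dz, 4L, interval = 4))
    v <- cgflow:::flow_get(fl)
    fl <- cgflow:::flow_set(fl, v + with_seed(20 + dz, rnorm(length(v), sd = 0.1)))
    fs <- flow_sample(fl, 200, seed = 30 + dz)
    iv <- cgflow:::flow_inverse(fl, fs$z)
    expect_equal(iv$eps, fs$eps, tolerance = 1e-8)
    expect_equal(iv$logJ_fwd, fs$logJ, tolerance = 1e-8)
  }
})

test_that("analytic log J matches the finite-difference Jacobian", {
  for (dz in c(1L, 2L, 3L)) {
    fl <- with_seed(41 + dz, flow_init(dz, 3L, interval = 4))
    v <- cgflow:::flow_get(fl)
    fl <- cgflow:::flow_set(fl, v + with_seed(50 + dz, rnorm(length(v), sd = 0.2)))
    eps <- with_seed(60 + dz, matrix(runif(dz, -3, 3), 1, dz))
    fw <- cgflow:::flow_forward(fl, eps)
    h <- 1e-6
    J <- matrix(0, dz, dz)
    for (j in seq_len(dz)) {
      ep <- eps; ep[1, j] <- ep[1, j] + h
      em <- eps; em[1, j] <- em[1, j] - h
      J[, j] <- (cgflow:::flow_forward(fl, ep)$z - cgflow:::flow_forward(fl, em)$z) / (2 * h)
    }
    expect_equal(fw$logJ, log(abs(det(J))), tolerance = 1e-5)
  }
})

test_that("boundary derivatives are one (linear tails)", {
  K <- 8L
  set.seed(71)
  w_raw <- matrix(rnorm(2 * K), 2, K)
  h_raw <- matrix(rnorm(2 * K), 2, K)
  d_raw <- matrix(rnorm(2 * (K - 1)), 2, K - 1)
  fw <- cgflow:::rqs_forward(c(-4, 4), w_raw, h_raw, d_raw, 4)
  expect_equal(fw$y, c(-4, 4), tolerance = 1e-12)
  expect_equal(fw$logdet, c(0, 0), tolerance = 1e-10)
})

test_that("layer layout follows the dimension rule and the presets", {
  ## one-dimensional z: plain spline layers without a coupling split
  fl1 <- with_seed(81, flow_init(1L, 6L))
  expect_true(all(vapply(fl1$layers, function(l) l$type, "") == "plain"))
  expect_equal(preset("dw")$model$n_layers, 6L)
  ## multivariate z: alternating-mask coupling layers
  fl2 <- with_seed(82, flow_init(2L, 4L))
  expect_true(all(vapply(fl2$layers, function(l) l$type, "") == "coupling"))
  masks <- vapply(fl2$layers, function(l) l$mask[1], NA)
  expect_true(all(masks == rep(c(TRUE, FALSE), 2)))
  expect_equal(preset("ala")$model$n_layers, 8L)
  expect_equal(preset("ala")$model$dim_z, 15L)
})

test_that("change of variables holds at random base points", {
  fl <- with_seed(91, flow_init(2L, 3L))
  v <- cgflow:::flow_get(fl)
  fl <- cgflow:::flow_set(fl, v + with_seed(92, rnorm(length(v), sd = 0.1)))
  fs <- flow_sample(fl, 100, seed = 93)
  lq_base <- rowSums(matrix(cgflow:::dtruncnorm_std(as.numeric(fs$eps), 4, log = TRUE), 100, 2))
  expect_equal(lq_base, flow_log_prob(fl, fs$z) + fs$logJ, tolerance = 1e-8)
})

test_that("C++ spline hot path matches the R reference implementation", {
  set.seed(101)
  M <- 40L; K <- 8L; B <- 4
  w_raw <- matrix(rnorm(M * K, sd = 0.7), M, K)
  h_raw <- matrix(rnorm(M * K, sd = 0.7), M, K)
  d_raw <- matrix(rnorm(M * (K - 1), sd = 0.7), M, K - 1)
  x <- runif(M, -B, B)
  fc <- cgflow:::rqs_forward_cpp(x, w_raw, h_raw, d_raw, B)
  fr <- cgflow:::rqs_forward_ref(x, w_raw, h_raw, d_raw, B)
  expect_equal(fc$y, fr$y, tolerance = 1e-12)
  expect_equal(fc$logdet, fr$logdet, tolerance = 1e-12)
  gy <- rnorm(M); gl <- rnorm(M)
  bc <- cgflow:::rqs_backward_cpp(fc$cache, gy, gl)
  br <- cgflow:::rqs_backward_ref(fr$cache, gy, gl)
  expect_equal(bc$gx, br$gx, tolerance = 1e-10)
  expect_equal(bc$gw_raw, br$gw_raw, tolerance = 1e-10)
  expect_equal(bc$gh_raw, br$gh_raw, tolerance = 1e-10)
  expect_equal(bc$gd_raw, br$gd_raw, tolerance = 1e-10)
  ic <- cgflow:::rqs_inverse_cpp(fr$y, w_raw, h_raw, d_raw, B)
  ir <- cgflow:::rqs_inverse_ref(fr$y, w_raw, h_raw, d_raw, B)
  expect_equal(ic$x, ir$x, tolerance = 1e-10)
  expect_equal(ic$logdet_fwd, ir$logdet_fwd, tolerance = 1e-10)
})

test_that("C++ MLP hot path matches the R reference implementation", {
  net <- with_seed(7, cgflow:::mlp_init(3L, 5L, 16L, 2L))
  X <- with_seed(8, matrix(rnorm(60), 20, 3))
  fc <- cgflow:::mlp_forward(net, X)
  fr <- cgflow:::mlp_forward_ref(net, X)
  expect_equal(fc$out, fr$out, tolerance = 1e-12)
  gout <- with_seed(9, matrix(rnorm(100), 20, 5))
  bc <- cgflow:::mlp_backward(net, fc, gout)
  br <- cgflow:::mlp_backward_ref(net, fr, gout)
  expect_equal(cgflow:::mlp_grad_flat(bc), cgflow:::mlp_grad_flat(br),
               tolerance = 1e-12)
  expect_equal(bc$gin, br$gin, tolerance = 1e-12)
})
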