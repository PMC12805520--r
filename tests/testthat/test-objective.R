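test_that("loss at the exact Gaussian optimum equals -log 2pi", {
  ## 2D standard Gaussian target; model = identity flow (truncated base,
  ## truncation mass ~1e-6 at B = 5), unit conditional, identity map
  m <- exact_gaussian_model()
  tg <- target_gaussian(2)
  le <- loss_estimate(m, tg, beta = 1, n = 20000, seed = 1)
  b <- le$batch
  per <- b$U_x + b$log_qX + b$log_qz            # per-sample loss summand
  se <- sd(per) / sqrt(length(per))
  expect_lt(abs(le$loss - (-log(2 * pi))), 3 * se + 1e-4)
})

test_that("at beta = 0 the loss is independent of the potential", {
  m <- tiny_model(2, 1)
  l1 <- loss_estimate(m, target_gaussian(2), 0, 500, seed = 2)$loss
  l2 <- loss_estimate(m, target_double_well(), 0, 500, seed = 2)$loss
  expect_identical(l1, l2)
})

test_that("pathwise gradient matches finite differences of the loss (n = 8)", {
  ## the build's primary correctness gate: the hand-assembled force-based
  ## estimator against an independent numerical differentiation of the
  ## same-seed loss
  cases <- list(
    list(m = tiny_model(2, 1, seed = 5), tg = target_double_well(), beta = 0.7),
    list(m = tiny_model(4, 2, n_layers = 3, seed = 6),
         tg = build_gmm_target(2, 2, seed = 6)$target, beta = 0.9)
  )
  for (cs in cases) {
    ge <- gradient_estimate(cs$m, cs$tg, cs$beta, n = 8, seed = 7)
    gf <- fd_loss_grad(cs$m, cs$tg, cs$beta, n = 8, seed = 7)
    expect_lt(max(abs(ge$grad - gf) / pmax(1, abs(gf))), 1e-5)
  }
})

test_that("gradient vanishes at the exact Gaussian optimum", {
  m <- exact_gaussian_model()
  tg <- target_gaussian(2)
  g_opt <- gradient_estimate(m, tg, 1, n = 4000, seed = 8)$grad
  sl <- cgflow:::model_param_slices(m)
  free <- c(sl$flow, sl$cond)                   # phi frozen at +/- large
  m2 <- model_set_params(m, model_get_params(m) +
                           with_seed(9, rnorm(length(model_get_params(m)), sd = 0.3)))
  g_off <- gradient_estimate(m2, tg, 1, n = 4000, seed = 8)$grad
  expect_lt(sqrt(sum(g_opt[free]^2)), 0.1 * sqrt(sum(g_off[free]^2)))
})

test_that("phi only enters through the energy term", {
  ## perturbing phi under a fixed seed changes the energy term but leaves
  ## the model entropy terms (log q parts) untouched
  m <- tiny_model(2, 1, seed = 10)
  b1 <- sample_batch(m, target_double_well(), 1, 64, seed = 11)
  m2 <- m
  m2$mixing$phi <- m2$mixing$phi + matrix(c(0.3, -0.1, 0.2, 0.1), 2, 2)
  b2 <- sample_batch(m2, target_double_well(), 1, 64, seed = 11)
  expect_identical(b1$log_qz, b2$log_qz)
  expect_identical(b1$log_qX, b2$log_qX)
  expect_false(isTRUE(all.equal(b1$U_x, b2$U_x)))
})

test_that("exactly one energy and one force call per sample", {
  tg <- target_double_well()
  m <- tiny_model(2, 1, seed = 12)
  invisible(target_counts(tg, reset = TRUE))
  invisible(gradient_estimate(m, tg, 0.5, n = 37, seed = 13))
  cnt <- target_counts(tg)
  expect_equal(cnt$energy, 37)
  expect_equal(cnt$force, 37)
  invisible(target_counts(tg, reset = TRUE))
  invisible(loss_estimate(m, tg, 0.5, n = 21, seed = 14))
  cnt <- target_counts(tg)
  expect_equal(cnt$energy, 21)
  expect_equal(cnt$force, 0)
})

test_that("non-finite energies are excluded and counted; >50% aborts", {
  half_bad <- potential_target(2,
    energy = function(x) ifelse(x[, 1] > 0, Inf, 0.5 * rowSums(x^2)),
    force = function(x) -x, label = "half_bad")
  m <- exact_gaussian_model()
  le <- loss_estimate(m, half_bad, 1, 400, seed = 15)
  expect_gt(le$batch$n_excluded, 0)
  expect_true(is.finite(le$loss))
  all_bad <- potential_target(2,
    energy = function(x) rep(Inf, nrow(x)),
    force = function(x) -x, label = "all_bad")
  expect_error(loss_estimate(m, all_bad, 1, 50, seed = 16), "non-finite")
})

test_that("median-based skip and clip rules apply as stated", {
  st <- adam_init(3, lr = 0.1, skip_clip = TRUE)
  st$norm_history <- rep(1, 50)                 # median norm = 1
  p0 <- c(0, 0, 0)
  ## 11x median: skipped, history updated
  g <- c(11, 0, 0)
  out <- sgd_step(st, p0, g)
  expect_true(out$skipped)
  expect_equal(out$params, p0)
  expect_equal(tail(out$state$norm_history, 1), 11)
  ## 6x median: clipped to 5x then applied
  g <- c(6, 0, 0)
  out <- sgd_step(st, p0, g)
  expect_false(out$skipped)
  ref <- sgd_step(st, p0, c(5, 0, 0))           # plain step with the clipped norm
  expect_equal(out$params, ref$params)
  ## below 5x: plain Adam step
  g <- c(2, 0, 0)
  out <- sgd_step(st, p0, g)
  expect_false(out$skipped)
  expect_lt(out$params[1], 0)
  ## without history the rules are inactive
  st2 <- adam_init(3, lr = 0.1, skip_clip = TRUE)
  out <- sgd_step(st2, p0, c(1000, 0, 0))
  expect_false(out$skipped)
})

test_that("gradient estimator is unbiased against a large-sample reference", {
  m <- tiny_model(2, 1, n_layers = 1L, n_knots = 4L, width = 4L, seed = 17)
  tg <- target_gaussian(2)
  reps <- vapply(1:200, function(s)
    gradient_estimate(m, tg, 0.8, n = 100, seed = 1000 + s)$grad,
    numeric(length(model_get_params(m))))
  mu <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  ref <- gradient_estimate(m, tg, 0.8, n = 2e5, seed = 999)$grad
  ## componentwise agreement within 3 standard errors (plus the reference's
  ## own MC error, absorbed by a floor on the tolerance)
  expect_true(all(abs(mu - ref) <= 3 * se + 3 * abs(ref) / sqrt(2e5) + 1e-3))
})

test_that("loss decreases over optimization on the double well", {
  m <- tiny_model(2, 1, n_layers = 3L, n_knots = 6L, jitter = 0, seed = 18)
  tg <- target_double_well()
  cfg <- train_config(n_samples = 100L, L = 250L, seed = 18L)
  res <- train(m, tg, NULL, cfg, beta_target = 0.4, total_steps = 250L)
  expect_lt(mean(tail(res$log$loss, 50)), mean(head(res$log$loss, 50)))
})
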