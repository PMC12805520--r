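## synthetic batch with analytically known ingredients: z ~ N(0, s2) in one
## dimension against the Gaussian target U = x^2/2 (so p_beta = N(0, 1/beta))
gaussian_batch <- function(n, s2 = 2, seed = 1) {
  x <- with_seed(seed, rnorm(n, sd = sqrt(s2)))
  structure(list(U_x = 0.5 * x^2, log_qz = dnorm(x, sd = sqrt(s2), log = TRUE),
                 log_qX = rep(0, n), logK = 0, ok = rep(TRUE, n)),
            class = "sample_batch")
}

## closed form: KL(N(0,s2) || N(0,1/beta)) = (s2 beta - 1 - log(s2 beta))/2
gauss_kl <- function(s2, beta) 0.5 * (s2 * beta - 1 - log(s2 * beta))

test_that("delta_kl is exactly zero at dbeta = 0", {
  b <- gaussian_batch(100)
  expect_identical(delta_kl(b, 1, 0), 0)
})

test_that("delta_kl matches the closed-form Gaussian KL ratio", {
  b <- gaussian_batch(1e5, s2 = 2, seed = 2)
  est <- delta_kl(b, 1, 0.5)
  exact <- (gauss_kl(2, 1.5) - gauss_kl(2, 1)) / gauss_kl(2, 1)
  expect_equal(est, exact, tolerance = 0.05)    # MC error at n = 1e5
  ## and at a second pair of betas
  est2 <- delta_kl(b, 0.8, 0.3)
  exact2 <- (gauss_kl(2, 1.1) - gauss_kl(2, 0.8)) / gauss_kl(2, 0.8)
  expect_equal(est2, exact2, tolerance = 0.05)
})

test_that("delta_kl is nondecreasing in dbeta on a model batch", {
  m <- tiny_model(2, 1, seed = 3)
  b <- sample_batch(m, target_double_well(), 0.3, 4000, seed = 4,
                    with_forces = FALSE)
  grid <- seq(0, 0.05, length.out = 11)
  vals <- vapply(grid, function(db) delta_kl(b, 0.3, db), 1)
  expect_true(all(diff(vals) > -1e-6))
})

test_that("next_beta takes the remaining-gap branch near beta_target", {
  sched <- tempering_schedule(beta0 = 0.01, beta_target = 1,
                              dkl_max = 0.1, dbeta_max = 0.05)
  b <- gaussian_batch(5000, seed = 5)
  nb <- next_beta(b, 0.999, sched)
  expect_equal(nb$beta_next, 1)
  expect_equal(nb$dbeta, 0.001)
})

test_that("flat delta-KL takes the dbeta_max branch", {
  ## constant-energy target: p_beta identical for all beta, delta KL = 0
  m <- tiny_model(2, 1, jitter = 0.05, seed = 6)
  flat <- potential_target(2, energy = function(x) rep(0, nrow(x)),
                           force = function(x) 0 * x, label = "flat")
  b <- sample_batch(m, flat, 0.5, 2000, seed = 7, with_forces = FALSE)
  sched <- tempering_schedule(beta0 = 0.01, beta_target = 1,
                              dkl_max = 0.1, dbeta_max = 0.05)
  nb <- next_beta(b, 0.5, sched)
  expect_equal(nb$dbeta, 0.05)
  expect_lt(abs(nb$dkl), 1e-8)
})

test_that("bisection root matches a dense-grid search", {
  m <- tiny_model(2, 1, seed = 8)
  b <- sample_batch(m, target_double_well(), 0.2, 4000, seed = 9,
                    with_forces = FALSE)
  sched <- tempering_schedule(beta0 = 0.01, beta_target = 1,
                              dkl_max = 0.05, dbeta_max = 0.2)
  nb <- next_beta(b, 0.2, sched)
  grid <- seq(1e-4, 0.2, by = 1e-4)
  vals <- vapply(grid, function(db) delta_kl(b, 0.2, db), 1)
  best <- grid[which.min(abs(vals - sched$dkl_max))]
  expect_lt(abs(nb$dbeta - best), 1e-3)
})

test_that("a failing delta-KL estimate falls back to dbeta_max/10", {
  bad <- gaussian_batch(100, seed = 10)
  bad$U_x[1] <- Inf                             # poisoned cached energy
  bad$ok[1] <- TRUE
  sched <- tempering_schedule(beta0 = 0.01, beta_target = 1,
                              dkl_max = 0.1, dbeta_max = 0.05)
  expect_warning(nb <- next_beta(bad, 0.5, sched), "falling back")
  expect_equal(nb$dbeta, 0.005)
})

test_that("training is deterministic and the schedule is well-formed", {
  tg <- target_double_well()
  m <- tiny_model(2, 1, jitter = 0, seed = 11)
  sched <- tempering_schedule(beta0 = 0.05, beta_target = 0.3,
                              dkl_max = 0.5, dbeta_max = 0.1)
  cfg <- train_config(n_samples = 60L, L = 15L, L_initial = 10L, seed = 12L)
  r1 <- train(m, tg, sched, cfg)
  r2 <- train(m, tg, sched, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$log$loss, r2$log$loss)
  betas <- r1$history$beta
  expect_true(all(diff(betas) > 0))
  expect_equal(tail(betas, 1), 0.3)
  expect_true(all(betas <= 0.3))
  ## every accepted dbeta obeys the min rule caps
  expect_true(all(r1$history$dbeta[-1] <= 0.1 + 1e-12))
  ## one checkpoint per accepted beta
  expect_equal(length(r1$checkpoints), nrow(r1$history))
})

test_that("an unbinding threshold reduces to fixed dbeta_max jumps", {
  tg <- target_gaussian(2)
  m <- tiny_model(2, 1, jitter = 0, seed = 13)
  sched <- tempering_schedule(beta0 = 0.1, beta_target = 0.5,
                              dkl_max = Inf, dbeta_max = 0.1)
  cfg <- train_config(n_samples = 50L, L = 5L, L_initial = 0L, seed = 14L)
  res <- train(m, tg, sched, cfg)
  ## ceil((0.5 - 0.1)/0.1) = 4 tempering increments after the initial stage
  expect_equal(nrow(res$history), 1L + 4L)
  expect_equal(res$history$dbeta[-1], rep(0.1, 4), tolerance = 1e-12)
})
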