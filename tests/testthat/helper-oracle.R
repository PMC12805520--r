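## Shared oracles and tiny-model builders for the test suite.

## Independent gradient oracle: central finite differences of the loss
## under the same seed (the pathwise estimator must differentiate exactly
## this function of the parameters).
fd_loss_grad <- function(model, target, beta, n, seed, h = 1e-5) {
  p0 <- model_get_params(model)
  g <- numeric(length(p0))
  for (i in seq_along(p0)) {
    pp <- p0; pp[i] <- pp[i] + h
    pm <- p0; pm[i] <- pm[i] - h
    g[i] <- (loss_estimate(model_set_params(model, pp), target, beta, n, seed)$loss -
             loss_estimate(model_set_params(model, pm), target, beta, n, seed)$loss) / (2 * h)
  }
  g
}

## small model whose parameters have been jittered away from the identity
tiny_model <- function(dim_x, dim_z, n_layers = 2L, n_knots = 4L,
                       interval = 4, width = 8L, jitter = 0.1,
                       seed = 5L, block_size = 1L) {
  m <- cg_model(dim_x, dim_z, block_size = block_size, n_layers = n_layers,
                n_knots = n_knots, interval = interval, flow_width = width,
                flow_depth = 2L, cond_width = width, cond_depth = 2L,
                seed = seed)
  if (jitter > 0) {
    p <- model_get_params(m)
    m <- model_set_params(m, p + with_seed(seed + 1L, rnorm(length(p), sd = jitter)))
  }
  m
}

## model that is exactly the 2D standard Gaussian (up to base truncation):
## identity flow, mu = 0 / sigma = 1 conditional, A = I (phi frozen at a
## large diagonal, the permutation-matrix special case)
exact_gaussian_model <- function(dim_x = 2L, dim_z = 1L, interval = 5) {
  m <- cg_model(dim_x, dim_z, n_layers = 2L, n_knots = 4L,
                interval = interval, flow_width = 8L, cond_width = 8L,
                seed = 2L)
  m$mixing$phi <- diag(40, m$mixing$n_pseudo)
  m
}

## quadrature of the double-well x1 marginal (left-basin mass, mean, ...)
dw_marginal_moment <- function(fun, beta = 1) {
  u1 <- function(t) 0.25 * t^4 - 3 * t^2 + t
  Z <- integrate(function(t) exp(-beta * u1(t)), -Inf, Inf, rel.tol = 1e-10)$value
  integrate(function(t) fun(t) * exp(-beta * u1(t)) / Z, -Inf, Inf,
            rel.tol = 1e-10)$value
}
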