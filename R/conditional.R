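## Conditional "fast"-coordinate model q_theta(X | z) = N(mu(z), diag
## sigma^2(z)). A single ReLU MLP maps z to the concatenated (mu, log sigma)
## heads; log sigma is clamped to [-10, 5] because the entropy term of the
## objective is unbounded below and the flow is a poor approximation early
## in training.

COND_LOGSIG_MIN <- -10
COND_LOGSIG_MAX <- 5

#' Construct a conditional Gaussian model
#'
#' @param dim_z input (slow coordinate) dimension.
#' @param dim_X output (fast coordinate) dimension.
#' @param width,depth MLP hyperparameters (ReLU hidden layers).
#' @return object of class `cond_model`.
#' @export
cond_init <- function(dim_z, dim_X, width = 32L, depth = 2L) {
  stopifnot(dim_z >= 1, dim_X >= 1)
  net <- mlp_init(dim_z, 2L * dim_X, width, depth, zero_last = TRUE,
                  last_bias = rep(0, 2L * dim_X))
  structure(list(dim_z = as.integer(dim_z), dim_X = as.integer(dim_X),
                 net = net), class = "cond_model")
}

cond_forward <- function(cond, z) {
  mf <- mlp_forward(cond$net, z)
  dX <- cond$dim_X
  mu <- mf$out[, seq_len(dX), drop = FALSE]
  logsig_raw <- mf$out[, dX + seq_len(dX), drop = FALSE]
  logsig <- clamp(logsig_raw, COND_LOGSIG_MIN, COND_LOGSIG_MAX)
  list(mu = mu, logsig = logsig, logsig_raw = logsig_raw, mlp = mf)
}

## gmu, glogsig: n x dim_X gradients. Returns flat param grads + grad w.r.t. z.
cond_backward <- function(cond, cache, gmu, glogsig) {
  active <- cache$logsig_raw > COND_LOGSIG_MIN & cache$logsig_raw < COND_LOGSIG_MAX
  gout <- cbind(gmu, glogsig * active)
  mb <- mlp_backward(cond$net, cache$mlp, gout)
  list(flat = mlp_grad_flat(mb), gz = mb$gin)
}

#' Sample fast coordinates given slow coordinates
#'
#' Reparameterized draw X = mu(z) + sigma(z) * eps_X with eps_X standard
#' normal (full support; only the slow-coordinate base is truncated).
#'
#' @param cond a `cond_model`.
#' @param z matrix n x dim_z.
#' @param seed optional integer seed.
#' @return list with `X`, `eps_X`, `mu`, `logsig`.
#' @export
cond_sample <- function(cond, z, seed = NULL) {
  if (is.null(dim(z))) z <- matrix(z, ncol = cond$dim_z)
  cf <- cond_forward(cond, z)
  n <- nrow(z)
  draw <- function() matrix(rnorm(n * cond$dim_X), n, cond$dim_X)
  eps_X <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(X = cf$mu + exp(cf$logsig) * eps_X, eps_X = eps_X,
       mu = cf$mu, logsig = cf$logsig)
}

#' Conditional log-density log q(X | z)
#'
#' @param cond a `cond_model`.
#' @param X matrix n x dim_X.
#' @param z matrix n x dim_z.
#' @return numeric vector of diagonal-Gaussian log-densities.
#' @export
cond_log_prob <- function(cond, X, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = cond$dim_z)
  if (is.null(dim(X))) X <- matrix(X, ncol = cond$dim_X)
  cf <- cond_forward(cond, z)
  -0.5 * cond$dim_X * log(2 * pi) - rowSums(cf$logsig) -
    0.5 * rowSums((X - cf$mu)^2 / exp(2 * cf$logsig))
}

#' Entropy term of the objective
#'
#' Returns -1/2 mean_i log det diag sigma^2(z_i) (additive Gaussian
#' constants dropped), the contribution of the conditional entropy to the
#' reverse-KL objective.
#'
#' @param cond a `cond_model`.
#' @param z matrix n x dim_z.
#' @return scalar.
#' @export
entropy_term <- function(cond, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = cond$dim_z)
  cf <- cond_forward(cond, z)
  -mean(rowSums(cf$logsig))
}

cond_get <- function(cond) mlp_get(cond$net)
cond_set <- function(cond, v) { cond$net <- mlp_set(cond$net, v); cond }
cond_n_params <- function(cond) mlp_n_params(cond$net)
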