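## Reverse-KL objective and its pathwise Monte-Carlo gradient estimator.
##
## The loss (up to the constant log Z_beta) is
##   L = beta <U_phi> + <log q(X|z)> + <log q(z)>
## with U_phi = U(x) - beta^-1 log K_phi, estimated from N reparameterized
## samples. Exactly one energy and one force evaluation are made per sample;
## the force F_x = -grad U enters the gradient as the adjoint of the U(x)
## node, and is pushed through the linear map (the log K_phi terms of the
## transformed forces vanish because K_phi is constant in (z, X)), the
## conditional reparameterization and the spline flow by the chain rule.
## The parameter-free constants (log Z_beta, Gaussian constants, base
## entropy) carry no gradient.

#' Draw a reparameterized sample batch from the model
#'
#' Runs the generative path eps -> z -> X -> x, evaluates energies and
#' forces once per sample, and returns everything downstream consumers need
#' (the tempering module reuses the cached energies without new target
#' calls). Samples with non-finite energy are flagged; more than 50%
#' non-finite aborts with a diagnostic.
#'
#' @param model a `cg_model`.
#' @param target a `potential_target`.
#' @param beta inverse temperature (>= 0).
#' @param n batch size.
#' @param seed integer seed (fans out to base and conditional substreams).
#' @param with_forces also evaluate forces (needed for gradients).
#' @param keep_caches keep layer caches for backpropagation.
#' @return object of class `sample_batch`.
#' @export
sample_batch <- function(model, target, beta, n, seed = NULL,
                         with_forces = TRUE, keep_caches = FALSE) {
  stopifnot(beta >= 0, n >= 1, model$dim_x == target$dim_x)
  B <- model$flow$B
  eps <- if (is.null(seed)) {
    matrix(rtruncnorm_std(n * model$dim_z, B), n, model$dim_z)
  } else with_seed(substream_seed(seed, "flow_base"),
                   matrix(rtruncnorm_std(n * model$dim_z, B), n, model$dim_z))
  fw <- flow_forward(model$flow, eps)
  cf <- cond_forward(model$cond, fw$z)
  eps_X <- if (is.null(seed)) {
    matrix(rnorm(n * model$dim_X), n, model$dim_X)
  } else with_seed(substream_seed(seed, "cond_base"),
                   matrix(rnorm(n * model$dim_X), n, model$dim_X))
  X <- cf$mu + exp(cf$logsig) * eps_X
  V <- zx_concat(fw$z, X)
  mx <- mix_forward(model$mixing, V)
  x <- mx$x
  U <- target$energy(x)
  ok <- is.finite(U)
  if (mean(!ok) > 0.5)
    stop(sprintf("%.0f%% of batch energies are non-finite; aborting", 100 * mean(!ok)))
  Fx <- if (with_forces) target$force(x) else NULL
  logK <- log_abs_det(model$mixing)
  log_qz <- rowSums(matrix(dtruncnorm_std(as.numeric(eps), B, log = TRUE),
                           n, model$dim_z)) - fw$logJ
  log_qX <- -0.5 * model$dim_X * log(2 * pi) - rowSums(cf$logsig) -
    0.5 * rowSums(eps_X^2)
  U_phi <- if (beta > 0) U - logK / beta else U
  Fv <- if (with_forces) block_apply(t(mx$A), Fx, model$mixing$block_size) else NULL
  out <- list(
    eps = eps, eps_X = eps_X, z = fw$z, X = X, x = x,
    U_x = U, F_x = Fx, U_phi = U_phi, logK = logK, ok = ok,
    n_excluded = sum(!ok),
    F_z = if (with_forces) Fv[, seq_len(model$dim_z), drop = FALSE] else NULL,
    F_X = if (with_forces) Fv[, model$dim_z + seq_len(model$dim_X), drop = FALSE] else NULL,
    log_qz = log_qz, log_qX = log_qX, logJ = fw$logJ,
    mu = cf$mu, logsig = cf$logsig, beta = beta
  )
  if (keep_caches) out$caches <- list(flow = fw$caches, cond = cf, mix = mx)
  class(out) <- "sample_batch"
  out
}

batch_loss <- function(batch) {
  ## beta <U_phi> written as beta <U> - log K so that beta = 0 stays exact
  ok <- batch$ok
  batch$beta * mean(batch$U_x[ok]) - batch$logK + mean(batch$log_qX[ok]) +
    mean(batch$log_qz[ok])
}

#' Monte-Carlo estimate of the reverse-KL loss
#'
#' Estimates beta <U_phi> + <log q(X|z)> + <log q(z)> (the reverse KL up to
#' the constant log Z_beta) from `n` one-shot samples; exactly one energy
#' evaluation per sample. At the exact optimum the value converges to
#' -log Z_beta.
#'
#' @inheritParams sample_batch
#' @return list with `loss` (scalar) and `batch` (reusable `sample_batch`).
#' @export
loss_estimate <- function(model, target, beta, n, seed = NULL) {
  batch <- sample_batch(model, target, beta, n, seed, with_forces = FALSE)
  list(loss = batch_loss(batch), batch = batch)
}

#' Pathwise gradient estimate of the reverse-KL loss
#'
#' Hand-assembled reverse-mode chain rule through the reparameterized
#' sampling path, using the cached forces as the adjoint of the energy node
#' (one energy + one force call per sample). For the linear map the
#' grad-log-K contributions reduce to the constant-matrix term
#' -grad_phi log|det A_phi|.
#'
#' @inheritParams sample_batch
#' @return list with `grad` (flat vector, layout of [model_get_params()]),
#'   `loss`, and `batch`.
#' @export
gradient_estimate <- function(model, target, beta, n, seed = NULL) {
  batch <- sample_batch(model, target, beta, n, seed, with_forces = TRUE,
                        keep_caches = TRUE)
  w <- ifelse(batch$ok, 1 / sum(batch$ok), 0)       # per-sample weights
  ## d(beta mean U)/dx = -beta w F_x
  gx <- -beta * w * batch$F_x
  mb <- mix_backward(model$mixing, batch$caches$mix, gx)
  gphi <- mb$gphi - grad_logdet_phi(model$mixing)   # -log K term
  dz <- model$dim_z
  gz <- mb$gV[, seq_len(dz), drop = FALSE]
  gX <- mb$gV[, dz + seq_len(model$dim_X), drop = FALSE]
  ## conditional: X = mu + exp(logsig) eps_X; entropy term -mean rowSums(logsig)
  gmu <- gX
  glogsig <- gX * exp(batch$logsig) * batch$eps_X - w
  cb <- cond_backward(model$cond, batch$caches$cond, gmu, glogsig)
  gz <- gz + cb$gz
  ## flow: -mean logJ term plus the pushed-back z gradient
  fb <- flow_backward(model$flow, batch$caches$flow, gz, -w)
  list(grad = c(fb$flat, cb$flat, as.numeric(gphi)),
       loss = batch_loss(batch), batch = batch)
}

## --- optimizer ---------------------------------------------------------------

#' Initialize an Adam optimizer state
#'
#' Adam moments follow the training setup used throughout: beta1 = 0.99,
#' beta2 = 0.999, eps = 1e-8. The optional median-based skip/clip scheme
#' tracks the gradient norms of the last 50 updates: steps with norm > 10x
#' the median are skipped, norms > 5x the median are clipped to 5x.
#'
#' @param n_params number of parameters.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moments.
#' @param skip_clip enable the median-based skip/clip scheme.
#' @return optimizer state list.
#' @export
adam_init <- function(n_params, lr = 1e-3, beta1 = 0.99, beta2 = 0.999,
                      eps = 1e-8, skip_clip = FALSE) {
  list(m = rep(0, n_params), v = rep(0, n_params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       skip_clip = skip_clip, norm_history = numeric(0), n_skipped = 0L)
}

#' One SGD (Adam) update with optional skip/clip
#'
#' @param state optimizer state from [adam_init()].
#' @param params flat parameter vector.
#' @param grad flat gradient vector.
#' @return list with updated `params`, `state`, and `skipped` flag.
#' @export
sgd_step <- function(state, params, grad) {
  gnorm <- sqrt(sum(grad^2))
  skipped <- FALSE
  if (state$skip_clip && length(state$norm_history) >= 10L) {
    med <- median(state$norm_history)
    if (gnorm > 10 * med) {
      skipped <- TRUE
      state$n_skipped <- state$n_skipped + 1L
    } else if (gnorm > 5 * med) {
      grad <- grad * (5 * med / gnorm)
    }
  }
  state$norm_history <- c(tail(state$norm_history, 49L), gnorm)
  if (!skipped) {
    state$t <- state$t + 1L
    state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
    state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
    mhat <- state$m / (1 - state$beta1^state$t)
    vhat <- state$v / (1 - state$beta2^state$t)
    params <- params - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state, skipped = skipped, gnorm = gnorm)
}
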