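## Adaptive inverse-temperature schedule and the outer training loop.
## beta starts near 0 (where the tempered Boltzmann target is almost
## uniform and easily matched) and is increased adaptively: each increment
## delta-beta is chosen so that the relative change in the reverse
## KL-divergence stays below a user threshold, capped by delta-beta_max and
## by the remaining gap to beta_target.
##
## The delta-KL estimator reuses the cached energies of a batch drawn from
## the current model (no extra energy calls): with u = U(x), lq = log q and
## logK the map log-Jacobian,
##   KL(q || p_beta) = <lq> + beta <u> - logK + log Zhat_beta,
##   log Zhat_beta   = logmeanexp(-beta u + logK - lq)
## i.e. the log-partition level is anchored by self-normalized importance
## sampling from the same batch. The SI detailing the original numerical
## scheme is unavailable; this reconstruction is validated against
## closed-form Gaussian-Gaussian KL divergences in the test suite.

#' Construct a tempering schedule
#'
#' @param beta0 initial inverse temperature (> 0, near 0).
#' @param beta_target final inverse temperature.
#' @param dkl_max maximum relative KL change per tempering step.
#' @param dbeta_max maximum inverse-temperature increment.
#' @return object of class `tempering_schedule`.
#' @export
tempering_schedule <- function(beta0 = 0.01, beta_target = 1,
                               dkl_max = 0.1, dbeta_max = 0.05) {
  stopifnot(beta0 > 0, beta_target > beta0, dkl_max > 0, dbeta_max > 0)
  structure(list(beta0 = beta0, beta_target = beta_target,
                 dkl_max = dkl_max, dbeta_max = dbeta_max),
            class = "tempering_schedule")
}

#' Training configuration
#'
#' @param n_samples N, samples per gradient estimate.
#' @param L inner SGD updates per tempering step.
#' @param L_initial extra updates at the initial beta0 (in addition to L).
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moments.
#' @param seed master seed (fans out to all substreams).
#' @param skip_clip enable the median skip/clip scheme (molecular presets).
#' @param n_kl batch size for the delta-KL estimate (default `n_samples`).
#' @param conv_loss_tol relative loss-stability threshold for early
#'   convergence inside a tempering step (windows must also agree within
#'   twice their pooled Monte-Carlo standard error).
#' @param conv_grad_frac multiple of the step-start gradient norm that the
#'   current norm must not exceed at convergence (default 1: non-increase).
#' @param early_stop enable early convergence detection inside tempering
#'   steps; disable to always run the full `L` updates (useful when the
#'   mixing map, which learns on a slower timescale than the loss
#'   plateaus, needs the whole inner budget).
#' @return list of class `train_config`.
#' @export
train_config <- function(n_samples = 500L, L = 100L, L_initial = 0L,
                         lr = 1e-3, adam_beta1 = 0.99, adam_beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L, skip_clip = FALSE,
                         n_kl = NULL, conv_loss_tol = 1e-4,
                         conv_grad_frac = 1, early_stop = TRUE) {
  stopifnot(n_samples >= 2, L >= 1, L_initial >= 0, lr > 0)
  structure(list(n_samples = as.integer(n_samples), L = as.integer(L),
                 L_initial = as.integer(L_initial), lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 skip_clip = skip_clip,
                 n_kl = as.integer(if (is.null(n_kl)) n_samples else n_kl),
                 conv_loss_tol = conv_loss_tol,
                 conv_grad_frac = conv_grad_frac,
                 early_stop = isTRUE(early_stop)),
            class = "train_config")
}

#' Relative KL change under an inverse-temperature increment
#'
#' Importance-sampling estimate of
#' \[KL(q || p_\{beta+dbeta\}) - KL(q || p_beta)\] / KL(q || p_beta)
#' from a batch drawn from the current model at `beta` (cached energies are
#' reused; no new target evaluations). Returns exactly 0 at `dbeta = 0`.
#'
#' @param batch a `sample_batch` drawn at the current beta.
#' @param beta current inverse temperature.
#' @param dbeta proposed increment (>= 0).
#' @return scalar estimate.
#' @export
delta_kl <- function(batch, beta, dbeta) {
  stopifnot(dbeta >= 0)
  if (dbeta == 0) return(0)
  kl0 <- kl_estimate(batch, beta)$kl
  if (!is.finite(kl0) || kl0 <= 0)
    stop("KL(q || p_beta) estimate non-positive (", format(kl0),
         "); model at target resolution or batch too small")
  (kl_estimate(batch, beta + dbeta)$kl - kl0) / kl0
}

## self-normalized-IS estimate of KL(q || p_beta) (up to target resolution)
## with a first-order (delta-method) Monte-Carlo standard error
kl_estimate <- function(batch, beta) {
  ok <- batch$ok
  u <- batch$U_x[ok]
  lq <- batch$log_qz[ok] + batch$log_qX[ok]
  a <- lq + beta * u - batch$logK
  lb <- -beta * u + batch$logK - lq
  m <- max(lb)
  b <- exp(lb - m)
  kl <- mean(a) + m + log(mean(b))
  infl <- a + b / mean(b)                          # influence values
  list(kl = kl, se = sd(infl) / sqrt(length(a)))
}

#' Select the next inverse temperature
#'
#' delta-beta is the minimum of: the bisection root of
#' delta_kl(dbeta) = dkl_max on (0, dbeta_max\] (tolerance 1e-4 in dbeta),
#' dbeta_max itself, and the remaining gap beta_target - beta. If the
#' delta-KL estimate fails, falls back to dbeta_max / 10 with a warning.
#'
#' @param batch a `sample_batch` drawn from the current model at `beta`.
#' @param beta current inverse temperature (< beta_target).
#' @param schedule a `tempering_schedule`.
#' @return list with `beta_next`, `dbeta`, `dkl` (estimate at the accepted
#'   increment).
#' @export
next_beta <- function(batch, beta, schedule) {
  stopifnot(beta < schedule$beta_target)
  gap <- schedule$beta_target - beta
  cap <- min(schedule$dbeta_max, gap)
  ## noise floor: when the current KL is indistinguishable from zero at
  ## the batch's Monte-Carlo resolution, the model tracks the tempered
  ## target as well as it can be measured and the relative-change
  ## threshold is unbinding (any change is "infinite" relative to an
  ## exact fit); take the capped step rather than crawling
  kl0 <- tryCatch(kl_estimate(batch, beta), error = function(e) e)
  if (!inherits(kl0, "error") && is.finite(kl0$kl) && kl0$kl > 0 &&
      kl0$kl <= 2 * kl0$se) {
    return(list(beta_next = beta + cap, dbeta = cap, dkl = 0))
  }
  dkl_cap <- tryCatch(delta_kl(batch, beta, cap), error = function(e) e)
  if (inherits(dkl_cap, "error")) {
    warning("delta-KL estimate failed (", conditionMessage(dkl_cap),
            "); falling back to dbeta_max/10")
    db <- min(schedule$dbeta_max / 10, gap)
    return(list(beta_next = beta + db, dbeta = db, dkl = NA_real_))
  }
  if (dkl_cap <= schedule$dkl_max) {
    ## threshold never binds: take the cap (dbeta_max or the remaining gap)
    return(list(beta_next = beta + cap, dbeta = cap, dkl = dkl_cap))
  }
  lo <- 0; hi <- cap
  while (hi - lo > 1e-4) {
    mid <- 0.5 * (lo + hi)
    if (delta_kl(batch, beta, mid) < schedule$dkl_max) lo <- mid else hi <- mid
  }
  db <- 0.5 * (lo + hi)
  list(beta_next = beta + db, dbeta = db, dkl = delta_kl(batch, beta, db))
}

#' Train a CG model with adaptive tempering
#'
#' The outer loop increments beta by the adaptive rule; the inner loop runs
#' up to `L` Adam updates on the Monte-Carlo gradient estimate (plus
#' `L_initial` extra updates at beta0). The model is checkpointed at every
#' accepted beta, so a generative model is available at all intermediate
#' inverse temperatures. Inner steps stop early once consecutive loss
#' windows are statistically flat (see [train_config()]) and the gradient
#' norm has not grown past its step-start value. A positive mixing-matrix determinant
#' is maintained by monitoring: any update that flips the sign is reverted.
#'
#' @param model a `cg_model`.
#' @param target a `potential_target`.
#' @param schedule a `tempering_schedule`, or `NULL` for plain untempered
#'   training at `beta_target` (used by the tempering-necessity contrast).
#' @param config a `train_config`.
#' @param beta_target target beta for untempered training (`schedule = NULL`).
#' @param total_steps total updates for untempered training.
#' @param verbose print one line per tempering step.
#' @return list with `model` (trained), `history` (one row per tempering
#'   step), `log` (one row per update), `checkpoints` (named list of flat
#'   parameter vectors per accepted beta), `diverged` flag.
#' @export
train <- function(model, target, schedule, config, beta_target = 1,
                  total_steps = NULL, verbose = FALSE) {
  params <- model_get_params(model)
  opt <- adam_init(length(params), lr = config$lr, beta1 = config$adam_beta1,
                   beta2 = config$adam_beta2, eps = config$adam_eps,
                   skip_clip = config$skip_clip)
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$opt <- opt
  env$gstep <- 0L
  env$bad_streak <- 0L
  env$diverged <- FALSE
  env$log <- vector("list", 0L)

  inner <- function(beta, steps) {
    model <<- model_set_params(model, env$params)
    losses <- numeric(0)
    g0 <- NA_real_
    used <- 0L
    for (s in seq_len(steps)) {
      ge <- gradient_estimate(model, target, beta, config$n_samples,
                              seed = substream_seed(config$seed, "train", env$gstep))
      env$gstep <- env$gstep + 1L
      used <- s
      if (!is.finite(ge$loss)) {
        env$bad_streak <- env$bad_streak + 1L
        if (env$bad_streak >= 20L) { env$diverged <- TRUE; break }
        next
      }
      env$bad_streak <- 0L
      st <- sgd_step(env$opt, env$params, ge$grad)
      ## det > 0 monitor: revert any step that flips the determinant sign
      trial <- model_set_params(model, st$params)
      if (det_sign(trial$mixing) <= 0) {
        env$opt$norm_history <- st$state$norm_history
      } else {
        env$params <- st$params
        env$opt <- st$state
        model <<- trial
      }
      losses <- c(losses, ge$loss)
      if (is.na(g0) && !st$skipped) g0 <- st$gnorm
      env$log[[length(env$log) + 1L]] <-
        c(step = env$gstep, beta = beta, loss = ge$loss,
          grad_norm = st$gnorm, skipped = as.numeric(st$skipped),
          energy_calls = target$counter$energy)
      ## noise-aware convergence: stop once two disjoint 20-step loss
      ## windows are statistically indistinguishable (within twice their
      ## pooled MC standard error, floored by the relative tolerance) and
      ## the gradient norm is no longer decreasing below its start value
      if (config$early_stop && s >= 40L && s %% 10L == 0L &&
          length(losses) >= 40L) {
        w_new <- tail(losses, 20L)
        w_old <- head(tail(losses, 40L), 20L)
        se <- sqrt(var(w_new) / 20 + var(w_old) / 20)
        thr <- max(config$conv_loss_tol * abs(mean(w_old)), 2 * se)
        if (abs(mean(w_new) - mean(w_old)) < thr &&
            st$gnorm < config$conv_grad_frac * g0)
          break
      }
    }
    list(loss = if (length(losses)) tail(losses, 1L) else NA_real_, used = used)
  }

  history <- list()
  checkpoints <- list()
  if (is.null(schedule)) {
    steps <- if (is.null(total_steps)) config$L_initial + config$L else total_steps
    res <- inner(beta_target, steps)
    history[[1L]] <- data.frame(k = 0L, beta = beta_target, dbeta = NA_real_,
                                dkl = NA_real_, inner_steps = res$used,
                                loss = res$loss)
    checkpoints[[sprintf("k%03d_beta%.6f", 0L, beta_target)]] <- env$params
  } else {
    beta <- schedule$beta0
    k <- 0L
    res <- inner(beta, config$L_initial + config$L)
    history[[1L]] <- data.frame(k = k, beta = beta, dbeta = NA_real_,
                                dkl = NA_real_, inner_steps = res$used,
                                loss = res$loss)
    checkpoints[[sprintf("k%03d_beta%.6f", k, beta)]] <- env$params
    if (verbose) message(sprintf("k=%d beta=%.4f loss=%.4f", k, beta, res$loss))
    while (beta < schedule$beta_target && !env$diverged) {
      model <- model_set_params(model, env$params)
      kl_batch <- sample_batch(model, target, beta, config$n_kl,
                               seed = substream_seed(config$seed, "delta_kl", k),
                               with_forces = FALSE)
      nb <- next_beta(kl_batch, beta, schedule)
      beta <- nb$beta_next
      k <- k + 1L
      res <- inner(beta, config$L)
      history[[k + 1L]] <- data.frame(k = k, beta = beta, dbeta = nb$dbeta,
                                      dkl = nb$dkl, inner_steps = res$used,
                                      loss = res$loss)
      checkpoints[[sprintf("k%03d_beta%.6f", k, beta)]] <- env$params
      if (verbose) message(sprintf("k=%d beta=%.4f dkl=%.3f loss=%.4f",
                                   k, beta, nb$dkl, res$loss))
    }
  }
  list(model = model_set_params(model, env$params),
       history = do.call(rbind, history),
       log = as.data.frame(do.call(rbind, env$log)),
       checkpoints = checkpoints,
       diverged = env$diverged)
}
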