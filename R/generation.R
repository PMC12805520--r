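## One-shot sampling, free energies over the slow coordinates, and
## importance-sampling reweighting of observables.

#' One-shot samples from a trained model
#'
#' eps -> z = g(eps) -> X ~ q(X|z) -> x = f_phi(X, z); samples are
#' independent across the batch. No target evaluations are made.
#'
#' @param model a `cg_model`.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return list with `x`, `z`, `X`, `eps`, `eps_X`, `log_q` (joint model
#'   log-density at the drawn samples).
#' @export
one_shot <- function(model, n, seed = NULL) {
  B <- model$flow$B
  eps <- if (is.null(seed)) {
    matrix(rtruncnorm_std(n * model$dim_z, B), n, model$dim_z)
  } else with_seed(substream_seed(seed, "flow_base"),
                   matrix(rtruncnorm_std(n * model$dim_z, B), n, model$dim_z))
  fw <- flow_forward(model$flow, eps)
  cs <- cond_sample(model$cond, fw$z,
                    seed = if (is.null(seed)) NULL else substream_seed(seed, "cond_base"))
  x <- forward_map(model$mixing, fw$z, cs$X)
  log_qz <- rowSums(matrix(dtruncnorm_std(as.numeric(eps), B, log = TRUE),
                           n, model$dim_z)) - fw$logJ
  log_qX <- -0.5 * model$dim_X * log(2 * pi) - rowSums(cs$logsig) -
    0.5 * rowSums(cs$eps_X^2)
  list(x = x, z = fw$z, X = cs$X, eps = eps, eps_X = cs$eps_X,
       log_q = log_qz + log_qX, log_qz = log_qz, log_qX = log_qX)
}

#' Free energy over the slow coordinates
#'
#' A(z) = -beta^-1 log q_theta(z); +Inf outside the spline support.
#'
#' @param model a `cg_model`.
#' @param z matrix of slow-coordinate points (n x dim_z).
#' @param beta inverse temperature (> 0).
#' @return numeric vector A(z).
#' @export
free_energy <- function(model, z, beta = 1) {
  stopifnot(beta > 0)
  lp <- flow_log_prob(model$flow, z)
  out <- -lp / beta
  out[!is.finite(lp)] <- Inf
  out
}

#' Importance-sampling reweighted expectation of an observable
#'
#' Self-normalized estimate sum_m W^(m) a(x^(m)) with unnormalized weights
#' w^(m) = exp(-beta U_phi^(m)) / q(X^(m), z^(m)), plus the effective sample
#' size ESS = 1 / sum W^2 and the self-normalized-IS standard error. ESS
#' below 1% of M triggers a degeneracy warning (the estimate is still
#' returned).
#'
#' @param model a `cg_model`.
#' @param target a `potential_target`.
#' @param beta inverse temperature.
#' @param observable function of a configuration batch (n x dim_x matrix)
#'   returning a numeric vector, one value per row.
#' @param M number of one-shot samples.
#' @param seed integer seed.
#' @return object of class `is_report`.
#' @export
reweighted_expectation <- function(model, target, beta, observable, M,
                                   seed = NULL) {
  batch <- sample_batch(model, target, beta, M, seed, with_forces = FALSE)
  ok <- batch$ok
  lq <- batch$log_qz[ok] + batch$log_qX[ok]
  lw <- -beta * batch$U_x[ok] + batch$logK - lq      # log exp(-beta U_phi)/q
  lw <- lw - max(lw)
  w <- exp(lw)
  W <- w / sum(w)
  ess <- 1 / sum(W^2)
  if (ess < 0.01 * M)
    warning(sprintf("IS weights degenerate: ESS = %.1f of M = %d", ess, M))
  a <- observable(batch$x[ok, , drop = FALSE])
  est <- sum(W * a)
  se <- sqrt(sum(W^2 * (a - est)^2))
  structure(list(M = M, n_used = sum(ok), weights = w, W = W, ess = ess,
                 estimate = est, se = se, beta = beta),
            class = "is_report")
}

#' @export
print.is_report <- function(x, ...) {
  cat(sprintf("<is_report> estimate = %.6g +/- %.2g (ESS %.1f / %d, beta = %g)\n",
              x$estimate, x$se, x$ess, x$M, x$beta))
  invisible(x)
}

#' Write one-shot samples as CSV
#'
#' One row per sample: columns x_1..x_d, then U, log_q and the normalized
#' IS weight (weights sum to 1).
#'
#' @param model a `cg_model`.
#' @param target a `potential_target` (for energies/weights).
#' @param beta inverse temperature.
#' @param n number of samples.
#' @param path output path.
#' @param seed integer seed.
#' @return the data frame, invisibly.
#' @export
write_samples_csv <- function(model, target, beta, n, path, seed = NULL) {
  df <- samples_data_frame(model, target, beta, n, seed)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

samples_data_frame <- function(model, target, beta, n, seed = NULL) {
  if (n == 0) {
    cols <- c(paste0("x", seq_len(model$dim_x)), "U", "log_q", "w")
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    return(df)
  }
  os <- one_shot(model, n, seed)
  U <- target$energy(os$x)
  lw <- -beta * U + log_abs_det(model$mixing) - os$log_q
  lw <- lw - max(lw[is.finite(lw)])
  w <- exp(lw)
  df <- as.data.frame(os$x)
  names(df) <- paste0("x", seq_len(model$dim_x))
  df$U <- U
  df$log_q <- os$log_q
  df$w <- w / sum(w)
  df
}
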