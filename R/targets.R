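## Boltzmann targets: the contract is an energy U(x) and the force -grad U(x),
## both batched (rows of a matrix are configurations). Energies are
## dimensionless (k_B T = 1 at beta = 1); beta enters only in the objective
## and tempering modules, never inside a target.

#' Construct a Boltzmann target
#'
#' A target is the unnormalized density p(x) = exp(-beta U(x)) / Z_beta,
#' specified through its potential energy and forces. Both callables must
#' accept a single configuration (numeric vector of length `dim_x`) or a
#' batch (matrix with `dim_x` columns); `energy` returns a scalar per row and
#' `force` a matrix of the same shape as its input. Evaluations are counted
#' (see [target_counts()]) so tests can assert the one-energy-call-per-sample
#' training contract.
#'
#' @param dim_x number of scalar coordinates.
#' @param energy function mapping a batch matrix to a numeric vector of U(x).
#' @param force function mapping a batch matrix to the matrix -grad U(x).
#' @param label short name used in logs.
#' @return an object of class `potential_target`.
#' @export
potential_target <- function(dim_x, energy, force, label = "target") {
  stopifnot(is.numeric(dim_x), length(dim_x) == 1L, dim_x >= 1, dim_x == round(dim_x))
  counter <- new.env(parent = emptyenv())
  counter$energy <- 0
  counter$force <- 0
  raw_energy <- energy
  raw_force <- force
  obj <- list(
    dim_x = as.integer(dim_x),
    energy = function(x) {
      x <- as_batch(x, dim_x)
      counter$energy <- counter$energy + nrow(x)
      raw_energy(x)
    },
    force = function(x) {
      x <- as_batch(x, dim_x)
      counter$force <- counter$force + nrow(x)
      raw_force(x)
    },
    label = label,
    counter = counter
  )
  class(obj) <- "potential_target"
  obj
}

as_batch <- function(x, dim_x) {
  if (is.null(dim(x))) {
    if (length(x) != dim_x)
      stop("configuration has ", length(x), " components; expected ", dim_x)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != dim_x)
    stop("configuration batch has ", ncol(x), " columns; expected ", dim_x)
  x
}

#' @export
print.potential_target <- function(x, ...) {
  cat("<potential_target> ", x$label, " (dim_x = ", x$dim_x, ")\n", sep = "")
  invisible(x)
}

#' Energy/force evaluation counts of a target
#'
#' @param target a `potential_target`.
#' @param reset if `TRUE`, zero the counters after reading.
#' @return list with elements `energy` and `force` (configurations counted).
#' @export
target_counts <- function(target, reset = FALSE) {
  out <- list(energy = target$counter$energy, force = target$counter$force)
  if (reset) {
    target$counter$energy <- 0
    target$counter$force <- 0
  }
  out
}

## --- double well ------------------------------------------------------------

#' Asymmetric two-dimensional double-well potential
#'
#' U(x) = x1^4/4 - 3 x1^2 + x1 + x2^2/2. The x1 direction separates two
#' metastable basins (near -2.5 and +2.5) with strongly unequal weights; x2
#' is a harmonic "fast" direction. At beta = 1 the left basin holds about
#' 99\% of the probability mass.
#'
#' @param x a 2-vector or a matrix with 2 columns.
#' @return energy value(s).
#' @export
double_well <- function(x) {
  x <- as_batch(x, 2L)
  x1 <- x[, 1L]; x2 <- x[, 2L]
  0.25 * x1^4 - 3 * x1^2 + x1 + 0.5 * x2^2
}

#' Force of the double-well potential
#'
#' Analytic -grad U: (-(x1^3 - 6 x1 + 1), -x2).
#'
#' @param x a 2-vector or a matrix with 2 columns.
#' @return matrix of forces, same shape as the batch.
#' @export
double_well_force <- function(x) {
  x <- as_batch(x, 2L)
  cbind(-(x[, 1L]^3 - 6 * x[, 1L] + 1), -x[, 2L])
}

#' The double-well Boltzmann target
#' @return a `potential_target` with `dim_x = 2`.
#' @export
target_double_well <- function() {
  potential_target(2L, double_well, double_well_force, label = "double_well")
}

## Isotropic standard Gaussian, U = |x|^2/2: tractable target for tests.
#' Standard Gaussian target (tractable test case)
#' @param dim dimension.
#' @return a `potential_target`.
#' @export
target_gaussian <- function(dim = 2L) {
  potential_target(dim,
    energy = function(x) 0.5 * rowSums(x^2),
    force = function(x) -x,
    label = paste0("gaussian", dim))
}

## --- Gaussian mixture target -------------------------------------------------

#' Build the Gaussian-mixture Boltzmann target
#'
#' The target joint density factorizes as p(x) = p(x_X | x_z) p(x_z) where
#' p(x_z) is a three-component Gaussian mixture with equal weights 1/3,
#' means drawn uniformly on \[-1, 1\]^dim_xz and diagonal covariance 0.01 I,
#' and p(x_X | x_z) = N(B x_z, 0.01 I) with B drawn entrywise from a
#' standard normal. The block partition (x_z first, then x_X in the
#' concatenated coordinate vector) is used only to construct the target; it
#' is never revealed to training. Draw order under the seed: means first
#' (component by component), then B (column-major).
#'
#' @param dim_xz dimension of the multimodal block (>= 1).
#' @param dim_xX dimension of the conditional block (>= 0).
#' @param seed integer seed fixing means and B.
#' @param weights mixture weights (default equal thirds).
#' @param mode_var per-coordinate mode variance (default 0.01).
#' @param cond_var per-coordinate conditional variance (default 0.01).
#' @return list with elements `spec` (a `gmm_target_spec`) and `target`
#'   (a `potential_target` of dimension `dim_xz + dim_xX`).
#' @export
build_gmm_target <- function(dim_xz, dim_xX, seed = 1L,
                             weights = rep(1 / 3, 3),
                             mode_var = 0.01, cond_var = 0.01) {
  if (dim_xz < 1) stop("dim_xz must be >= 1")
  if (dim_xX < 0) stop("dim_xX must be >= 0")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (mode_var <= 0 || cond_var <= 0) stop("covariance entries must be strictly positive")
  K <- length(weights)
  draws <- with_seed(substream_seed(seed, "gmm_target"), {
    ## draw order: means component by component, then B column-major
    means <- matrix(runif(K * dim_xz, -1, 1), nrow = K, byrow = TRUE)
    B <- if (dim_xX > 0) matrix(rnorm(dim_xX * dim_xz), nrow = dim_xX, ncol = dim_xz) else
      matrix(0, nrow = 0L, ncol = dim_xz)
    list(means = means, B = B)
  })
  spec <- structure(list(
    dim_xz = as.integer(dim_xz), dim_xX = as.integer(dim_xX),
    weights = weights, means = draws$means, mode_var = mode_var,
    B = draws$B, cond_var = cond_var, seed = as.integer(seed)
  ), class = "gmm_target_spec")
  list(spec = spec, target = gmm_spec_to_target(spec))
}

## Mixture block: log p(x_z) and its gradient, vectorized over rows.
gmm_logp_xz <- function(spec, xz) {
  K <- length(spec$weights)
  d <- spec$dim_xz
  lw <- matrix(NA_real_, nrow(xz), K)
  for (k in seq_len(K)) {
    dk <- sweep(xz, 2L, spec$means[k, ], "-")
    lw[, k] <- log(spec$weights[k]) - 0.5 * rowSums(dk^2) / spec$mode_var -
      0.5 * d * log(2 * pi * spec$mode_var)
  }
  list(logp = row_logsumexp(lw), logw = lw)
}

#' Evaluate the mixture-target joint log-density directly
#'
#' Brute-force evaluation of log p(x_z) + log p(x_X | x_z); used as the
#' independent oracle against the target's energy.
#'
#' @param spec a `gmm_target_spec`.
#' @param x batch matrix (columns: x_z block then x_X block).
#' @return numeric vector of log-densities.
#' @export
gmm_log_density <- function(spec, x) {
  x <- as_batch(x, spec$dim_xz + spec$dim_xX)
  xz <- x[, seq_len(spec$dim_xz), drop = FALSE]
  lp <- gmm_logp_xz(spec, xz)$logp
  if (spec$dim_xX > 0) {
    xX <- x[, spec$dim_xz + seq_len(spec$dim_xX), drop = FALSE]
    mu <- xz %*% t(spec$B)
    lp <- lp - 0.5 * rowSums((xX - mu)^2) / spec$cond_var -
      0.5 * spec$dim_xX * log(2 * pi * spec$cond_var)
  }
  lp
}

gmm_spec_to_target <- function(spec) {
  dz <- spec$dim_xz; dX <- spec$dim_xX
  energy <- function(x) -gmm_log_density(spec, x)
  force <- function(x) {
    xz <- x[, seq_len(dz), drop = FALSE]
    parts <- gmm_logp_xz(spec, xz)
    resp <- exp(parts$logw - parts$logp)          # responsibilities, rows sum to 1
    gz <- matrix(0, nrow(x), dz)
    for (k in seq_along(spec$weights)) {
      dk <- sweep(xz, 2L, spec$means[k, ], "-")
      gz <- gz - resp[, k] * dk / spec$mode_var   # d log p(x_z) / d x_z
    }
    if (dX > 0) {
      xX <- x[, dz + seq_len(dX), drop = FALSE]
      r <- (xX - xz %*% t(spec$B)) / spec$cond_var
      gz <- gz + r %*% spec$B                     # chain through the mean B x_z
      cbind(gz, -r)
    } else gz
  }
  potential_target(dz + dX, energy, force,
                   label = sprintf("gmm_%dz_%dX", dz, dX))
}

#' @export
print.gmm_target_spec <- function(x, ...) {
  cat("<gmm_target_spec> dim_xz =", x$dim_xz, "dim_xX =", x$dim_xX,
      "modes =", length(x$weights), "seed =", x$seed, "\n")
  invisible(x)
}

#' Serialize / deserialize a mixture-target spec as JSON
#'
#' @param spec a `gmm_target_spec`.
#' @param path file path.
#' @return `gmm_spec_write` returns `path` invisibly; `gmm_spec_read`
#'   returns the reconstructed `gmm_target_spec`.
#' @export
gmm_spec_write <- function(spec, path) {
  jsonlite::write_json(list(
    dim_xz = spec$dim_xz, dim_xX = spec$dim_xX, weights = spec$weights,
    means = spec$means, mode_var = spec$mode_var, B = spec$B,
    cond_var = spec$cond_var, seed = spec$seed
  ), path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname gmm_spec_write
#' @export
gmm_spec_read <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    dim_xz = as.integer(j$dim_xz), dim_xX = as.integer(j$dim_xX),
    weights = as.numeric(j$weights),
    means = matrix(as.numeric(j$means), nrow = length(j$weights), byrow = FALSE),
    mode_var = j$mode_var,
    B = if (j$dim_xX > 0) matrix(as.numeric(j$B), nrow = j$dim_xX) else matrix(0, 0, j$dim_xz),
    cond_var = j$cond_var, seed = as.integer(j$seed)
  ), class = "gmm_target_spec")
}

#' Check a target's forces against central finite differences
#'
#' @param target a `potential_target`.
#' @param x configuration(s) at which to probe.
#' @param h step size.
#' @return maximum relative error over probed entries.
#' @export
check_forces <- function(target, x, h = 1e-5) {
  x <- as_batch(x, target$dim_x)
  f <- target$force(x)
  g <- matrix(NA_real_, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    xp <- x; xp[, j] <- xp[, j] + h
    xm <- x; xm[, j] <- xm[, j] - h
    g[, j] <- -(target$energy(xp) - target$energy(xm)) / (2 * h)
  }
  max(abs(f - g) / pmax(1, abs(g)))
}
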