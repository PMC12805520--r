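## The learnable linear coarse-graining bijection x = A_phi (z, X). Rows of
## A_phi are a softmax of an unconstrained parameter matrix phi, so A_phi is
## right stochastic for every parameter value and the map is equivariant to
## rigid-body translations by construction (block_size = 3). Synthetic
## per-coordinate targets use block_size = 1; molecular targets expand each
## pseudo-atom row by the 3x3 identity (block_size = 3). The Jacobian
## K_phi = |det A_phi|^block_size is independent of (z, X).

#' Construct a mixing matrix (learnable linear CG map)
#'
#' Initialization follows the near-uniform-with-boosted-diagonal scheme: phi
#' is zero except for `diag_boost` added to the diagonal, which makes A_phi
#' as uniform as possible while guaranteeing det(A_phi) > 0 (the eigenvalues
#' are one near-unit value and n-1 equal positive values).
#'
#' @param dim_x total number of scalar coordinates.
#' @param dim_z number of slow scalar coordinates (multiple of `block_size`).
#' @param block_size 1 (per-coordinate mixing) or 3 (pseudo-atom mixing).
#' @param diag_boost positive constant added to diagonal phi entries.
#' @return object of class `mixing_matrix`.
#' @export
mixing_init <- function(dim_x, dim_z, block_size = 1L, diag_boost = 0.5) {
  stopifnot(dim_x %% block_size == 0, dim_z %% block_size == 0,
            dim_z >= 1, dim_z < dim_x)
  n_pseudo <- dim_x %/% block_size
  phi <- diag(diag_boost, n_pseudo)
  structure(list(phi = phi, dim_x = as.integer(dim_x),
                 dim_z = as.integer(dim_z),
                 block_size = as.integer(block_size),
                 n_pseudo = as.integer(n_pseudo)),
            class = "mixing_matrix")
}

#' Materialize A_phi from phi by row-wise softmax
#'
#' @param phi square parameter matrix (or a `mixing_matrix`).
#' @return right stochastic matrix of the same shape.
#' @export
materialize <- function(phi) {
  if (inherits(phi, "mixing_matrix")) phi <- phi$phi
  stopifnot(nrow(phi) == ncol(phi))
  m <- apply(phi, 1L, max)
  e <- exp(phi - m)
  e / rowSums(e)
}

check_nonsingular <- function(A) {
  if (safe_rcond(A) < 1e-12)
    stop("mixing matrix is numerically singular (rcond < 1e-12)")
  invisible(TRUE)
}

## stack (z, X) into the pseudo-coordinate vector v (z block first)
zx_concat <- function(z, X) cbind(z, X)

## apply A blockwise: out[, (i-1)b + r] = sum_j A[i, j] V[, (j-1)b + r]
block_apply <- function(A, V, b) {
  n <- nrow(V)
  p <- nrow(A)
  out <- matrix(0, n, p * b)
  for (r in seq_len(b)) {
    cols <- seq.int(r, by = b, length.out = p)
    out[, cols] <- V[, cols, drop = FALSE] %*% t(A)
  }
  out
}

#' Forward CG map x = A_phi (z, X)
#'
#' @param mix a `mixing_matrix`.
#' @param z slow coordinates (n x dim_z matrix or vector).
#' @param X fast coordinates (n x (dim_x - dim_z) matrix or vector).
#' @return matrix of configurations x (n x dim_x).
#' @export
forward_map <- function(mix, z, X) {
  if (is.null(dim(z))) z <- matrix(z, ncol = mix$dim_z)
  if (is.null(dim(X))) X <- matrix(X, ncol = mix$dim_x - mix$dim_z)
  A <- materialize(mix)
  check_nonsingular(A)
  block_apply(A, zx_concat(z, X), mix$block_size)
}

#' Inverse CG map x -> (z, X)
#'
#' Exact linear solve; the first `dim_z` outputs are the slow coordinates.
#'
#' @param mix a `mixing_matrix`.
#' @param x configurations (n x dim_x matrix or vector).
#' @return list with matrices `z` and `X`.
#' @export
inverse_map <- function(mix, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = mix$dim_x)
  A <- materialize(mix)
  check_nonsingular(A)
  V <- block_apply(solve(A), x, mix$block_size)
  list(z = V[, seq_len(mix$dim_z), drop = FALSE],
       X = V[, mix$dim_z + seq_len(mix$dim_x - mix$dim_z), drop = FALSE])
}

#' log |det| of the CG map Jacobian
#'
#' log K_phi = block_size * log |det A_phi| (each pseudo-atom row counts
#' block_size times through the identity expansion); independent of (z, X).
#'
#' @param mix a `mixing_matrix` (or a bare square matrix, taken as A).
#' @return scalar log |det|.
#' @export
log_abs_det <- function(mix) {
  if (inherits(mix, "mixing_matrix")) {
    A <- materialize(mix); b <- mix$block_size
  } else { A <- mix; b <- 1L }
  dt <- determinant(A, logarithm = TRUE)
  if (dt$sign == 0 || !is.finite(dt$modulus))
    stop("mixing matrix has zero determinant")
  b * as.numeric(dt$modulus)
}

det_sign <- function(mix) {
  determinant(materialize(mix), logarithm = TRUE)$sign
}

#' Check translation equivariance of the CG map
#'
#' For block_size = 3, translating every pseudo-atom (z and X blocks) by t
#' must translate every output atom by t; holds unconditionally for
#' row-stochastic A. Also accepts a bare matrix `A` for counterexamples.
#'
#' @param mix a `mixing_matrix` or a bare pseudo-atom matrix A.
#' @param t translation 3-vector.
#' @param dim_z slow scalar coordinates when a bare matrix is supplied.
#' @param tol tolerance.
#' @return logical.
#' @export
translation_equivariance_check <- function(mix, t, dim_z = NULL, tol = 1e-10) {
  stopifnot(length(t) == 3L)
  if (inherits(mix, "mixing_matrix")) {
    stopifnot(mix$block_size == 3L)
    A <- materialize(mix); dz <- mix$dim_z; dx <- mix$dim_x
  } else {
    A <- mix; dz <- dim_z; dx <- 3L * nrow(A)
  }
  set.seed(7)
  v <- matrix(rnorm(2 * dx), 2, dx)
  tv <- rep(t, dx / 3L)
  x0 <- block_apply(A, v, 3L)
  x1 <- block_apply(A, sweep(v, 2L, tv, "+"), 3L)
  max(abs(x1 - (x0 + matrix(tv, 2, dx, byrow = TRUE)))) <= tol
}

## --- gradients ---------------------------------------------------------------

## chain dL/dA -> dL/dphi through the row-wise softmax
softmax_rows_backward <- function(A, gA) {
  A * (gA - rowSums(gA * A))
}

## gradient of b * log|det A(phi)| w.r.t. phi
grad_logdet_phi <- function(mix) {
  A <- materialize(mix)
  gA <- mix$block_size * t(solve(A))
  softmax_rows_backward(A, gA)
}

## forward with cache for backprop; V = (z, X) stacked
mix_forward <- function(mix, V) {
  A <- materialize(mix)
  list(x = block_apply(A, V, mix$block_size), A = A, V = V)
}

## gx: n x dim_x gradient w.r.t. x. Returns grad w.r.t. phi (from the map
## only, not log K) and grad w.r.t. V.
mix_backward <- function(mix, cache, gx) {
  b <- mix$block_size
  p <- mix$n_pseudo
  gA <- matrix(0, p, p)
  gV <- matrix(0, nrow(gx), ncol(gx))
  for (r in seq_len(b)) {
    cols <- seq.int(r, by = b, length.out = p)
    gA <- gA + crossprod(gx[, cols, drop = FALSE], cache$V[, cols, drop = FALSE])
    gV[, cols] <- gx[, cols, drop = FALSE] %*% cache$A
  }
  list(gphi = softmax_rows_backward(cache$A, gA), gV = gV)
}

mix_get <- function(mix) as.numeric(mix$phi)
mix_set <- function(mix, v) { mix$phi[] <- v; mix }
mix_n_params <- function(mix) length(mix$phi)

#' Export A_phi (or its inverse) as a CSV matrix
#'
#' @param mix a `mixing_matrix`.
#' @param path file path.
#' @param inverse write the inverse matrix instead.
#' @return `path`, invisibly.
#' @export
mixing_write_csv <- function(mix, path, inverse = FALSE) {
  A <- materialize(mix)
  if (inverse) A <- solve(A)
  write.csv(A, path, row.names = FALSE)
  invisible(path)
}
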