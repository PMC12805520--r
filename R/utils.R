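#' @importFrom stats dnorm pnorm qnorm rnorm runif median sd var integrate
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib cgflow, .registration = TRUE
NULL

## Numerically stable log(sum(exp(x))) and log(mean(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

## Row-wise logsumexp for a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

softplus <- function(x) {
  # stable: log(1 + exp(x))
  out <- x
  low <- x <= 30
  out[low] <- log1p(exp(x[low]))
  out
}

inv_softplus <- function(y) log(expm1(y))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a substream seed from a master seed
#'
#' One global seed fans out to named substreams (base draws, conditional
#' draws, target construction, delta-KL batches) so components can be
#' re-seeded independently and reproducibly. The result is always a valid
#' 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param stream substream name.
#' @param k optional extra integer offset (e.g. a step counter).
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream, k = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + as.numeric(k) * 7919) %% 2147483647)
}

## Evaluate an expression with a local RNG state; restores the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## --- truncated standard normal on [-a, a] ----------------------------------

## log normalizing constant: log(Phi(a) - Phi(-a))
truncnorm_lognorm <- function(a) {
  log(pnorm(a) - pnorm(-a))
}

rtruncnorm_std <- function(n, a) {
  lo <- pnorm(-a)
  hi <- pnorm(a)
  qnorm(lo + runif(n) * (hi - lo))
}

dtruncnorm_std <- function(x, a, log = FALSE) {
  ld <- dnorm(x, log = TRUE) - truncnorm_lognorm(a)
  ld[abs(x) > a] <- -Inf
  if (log) ld else exp(ld)
}

## mean 0; variance of the symmetric truncated standard normal
truncnorm_var <- function(a) {
  1 - 2 * a * dnorm(a) / (pnorm(a) - pnorm(-a))
}

## Reciprocal condition number (1-norm) of a square matrix.
safe_rcond <- function(A) {
  out <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}
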