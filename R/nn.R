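## Minimal feedforward network (ReLU hidden layers, linear output) with
## hand-written reverse-mode backprop. Batches are row-major: input n x d_in.
## `depth` counts hidden layers (Table conventions: "MLP layers 2, width 32"
## means two hidden layers of width 32).

mlp_init <- function(d_in, d_out, width, depth, zero_last = FALSE,
                     last_bias = NULL) {
  dims <- c(d_in, rep(width, depth), d_out)
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    sdev <- sqrt(2 / dims[l])                       # He initialization
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sdev), dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  if (zero_last) W[[L]][] <- 0
  if (!is.null(last_bias)) b[[L]] <- last_bias
  list(W = W, b = b, d_in = d_in, d_out = d_out)
}

mlp_forward <- function(net, X) {
  mlp_forward_cpp(net$W, net$b, X)
}

## pure-R reference (cross-checked against the C++ hot path in tests)
mlp_forward_ref <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    if (l < L) Z[Z < 0] <- 0
    acts[[l + 1L]] <- Z
  }
  list(out = acts[[L + 1L]], acts = acts)
}

## gout: n x d_out gradient of the loss w.r.t. the output.
## Returns parameter gradients (same shapes) and the input gradient.
mlp_backward <- function(net, cache, gout) {
  mlp_backward_cpp(net$W, cache$acts, gout)
}

mlp_backward_ref <- function(net, cache, gout) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  g <- gout
  for (l in rev(seq_len(L))) {
    a <- cache$acts[[l]]
    gW[[l]] <- crossprod(a, g)
    gb[[l]] <- colSums(g)
    g <- g %*% t(net$W[[l]])
    if (l > 1L) g <- g * (cache$acts[[l]] > 0)      # ReLU mask
  }
  list(W = gW, b = gb, gin = g)
}

## --- flat parameter plumbing -------------------------------------------------

mlp_get <- function(net) {
  unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)), use.names = FALSE)
}

mlp_set <- function(net, v) {
  i <- 0L
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]][] <- v[i + seq_len(n)]; i <- i + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]][] <- v[i + seq_len(n)]; i <- i + n
  }
  net
}

mlp_grad_flat <- function(g) {
  unlist(c(lapply(g$W, as.numeric), lapply(g$b, as.numeric)), use.names = FALSE)
}

mlp_n_params <- function(net) {
  sum(vapply(net$W, length, 1L)) + sum(vapply(net$b, length, 1L))
}
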