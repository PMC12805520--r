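## The full generative CG model: mixing bijection + slow-coordinate flow +
## fast-coordinate conditional Gaussian. Parameters are exposed as one flat
## numeric vector (layout: flow, conditional, phi) for the optimizer and for
## finite-difference oracles.

#' Construct a generative coarse-graining model
#'
#' @param dim_x configuration dimension of the target.
#' @param dim_z number of slow scalar coordinates (1 <= dim_z < dim_x).
#' @param block_size 1 for per-coordinate targets, 3 for molecular targets.
#' @param n_layers,n_knots,interval,flow_width,flow_depth flow hyperparameters
#'   (see [flow_init()]); `interval` is the shared spline support and base
#'   truncation half-width.
#' @param cond_width,cond_depth conditional MLP hyperparameters.
#' @param diag_boost diagonal boost of the mixing initialization.
#' @param seed integer seed for the network initialization draws.
#' @return object of class `cg_model`.
#' @export
cg_model <- function(dim_x, dim_z, block_size = 1L,
                     n_layers = 6L, n_knots = 8L, interval = 4,
                     flow_width = 32L, flow_depth = 2L,
                     cond_width = 32L, cond_depth = 2L,
                     diag_boost = 0.5, seed = 1L) {
  stopifnot(dim_z >= 1, dim_z < dim_x)
  dim_X <- dim_x - dim_z
  obj <- with_seed(substream_seed(seed, "model_init"), {
    list(flow = flow_init(dim_z, n_layers, n_knots, interval,
                          flow_width, flow_depth),
         cond = cond_init(dim_z, dim_X, cond_width, cond_depth),
         mixing = mixing_init(dim_x, dim_z, block_size, diag_boost))
  })
  obj$dim_x <- as.integer(dim_x)
  obj$dim_z <- as.integer(dim_z)
  obj$dim_X <- as.integer(dim_X)
  class(obj) <- "cg_model"
  obj
}

#' @export
print.cg_model <- function(x, ...) {
  cat("<cg_model> dim_x =", x$dim_x, "= dim_z", x$dim_z, "+ dim_X", x$dim_X,
      "| params:", length(model_get_params(x)), "\n")
  invisible(x)
}

#' Get / set the flat parameter vector of a model
#'
#' Layout: flow parameters, conditional-MLP parameters, mixing phi.
#' @param model a `cg_model`.
#' @param v flat numeric vector (for `model_set_params`).
#' @return numeric vector / updated model.
#' @export
model_get_params <- function(model) {
  c(flow_get(model$flow), cond_get(model$cond), mix_get(model$mixing))
}

#' @rdname model_get_params
#' @export
model_set_params <- function(model, v) {
  nf <- flow_n_params(model$flow)
  nc <- cond_n_params(model$cond)
  np <- mix_n_params(model$mixing)
  stopifnot(length(v) == nf + nc + np)
  model$flow <- flow_set(model$flow, v[seq_len(nf)])
  model$cond <- cond_set(model$cond, v[nf + seq_len(nc)])
  model$mixing <- mix_set(model$mixing, v[nf + nc + seq_len(np)])
  model
}

## index slices into the flat vector, used by term-isolation tests
model_param_slices <- function(model) {
  nf <- flow_n_params(model$flow)
  nc <- cond_n_params(model$cond)
  np <- mix_n_params(model$mixing)
  list(flow = seq_len(nf), cond = nf + seq_len(nc), phi = nf + nc + seq_len(np))
}
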