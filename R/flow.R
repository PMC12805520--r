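## Normalizing flow q_theta(z) over the slow coordinates: a stack of
## monotone rational-quadratic spline layers mapping [-B, B]^dim_z onto
## itself, over a truncated standard-normal base on the same interval. For
## dim_z = 1 the layers are plain elementwise splines with directly
## trainable knots (coupling layers cannot split one dimension); for
## dim_z >= 2 they are Real-NVP-style coupling layers with alternating
## masks whose spline parameters are emitted by a small ReLU conditioner
## network. All layers are identity-initialized (knots on the diagonal,
## unit derivatives) so the initial density is the broad truncated base.

#' Construct a spline flow model
#'
#' @param dim_z number of slow coordinates.
#' @param n_layers number of spline (or coupling) layers.
#' @param n_knots number of spline bins K.
#' @param interval half-width B of the shared spline support and base
#'   truncation interval \[-B, B\].
#' @param width,depth conditioner MLP hyperparameters (coupling layers only).
#' @return an object of class `flow_model`.
#' @export
flow_init <- function(dim_z, n_layers, n_knots = 8L, interval = 4,
                      width = 32L, depth = 2L) {
  stopifnot(dim_z >= 1, n_layers >= 1, n_knots >= 2)
  K <- as.integer(n_knots)
  layers <- vector("list", n_layers)
  id_raw <- rqs_identity_raw(K)
  for (l in seq_len(n_layers)) {
    if (dim_z == 1L) {
      layers[[l]] <- list(type = "plain",
                          theta = matrix(id_raw, nrow = 1L))
    } else {
      mask <- (seq_len(dim_z) + l) %% 2L == 0L       # alternating elements
      n_trans <- sum(!mask)
      net <- mlp_init(sum(mask), n_trans * (3L * K - 1L), width, depth,
                      zero_last = TRUE, last_bias = rep(id_raw, n_trans))
      layers[[l]] <- list(type = "coupling", mask = mask, net = net)
    }
  }
  structure(list(dim_z = as.integer(dim_z), n_layers = as.integer(n_layers),
                 K = K, B = interval, width = as.integer(width),
                 depth = as.integer(depth), layers = layers),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat("<flow_model> dim_z =", x$dim_z, "layers =", x$n_layers,
      if (x$dim_z == 1L) "(plain spline)" else "(coupling)",
      "K =", x$K, "interval = [", -x$B, ",", x$B, "]\n")
  invisible(x)
}

## expand an n x p conditioner output into stacked (n*n_trans) x (3K-1) rows
theta_stack <- function(out, n_trans, K) {
  n <- nrow(out)
  p <- 3L * K - 1L
  th <- matrix(0, n * n_trans, p)
  for (t in seq_len(n_trans)) th[(t - 1L) * n + seq_len(n), ] <- out[, (t - 1L) * p + seq_len(p)]
  th
}

## Forward pass eps -> z with per-sample log|det dz/deps| and caches.
flow_forward <- function(flow, eps) {
  n <- nrow(eps)
  K <- flow$K; B <- flow$B
  z <- eps
  logJ <- rep(0, n)
  caches <- vector("list", flow$n_layers)
  for (l in seq_len(flow$n_layers)) {
    ly <- flow$layers[[l]]
    if (ly$type == "plain") {
      d <- flow$dim_z
      th <- ly$theta[rep(seq_len(d), each = n), , drop = FALSE]
      sp <- rqs_split_raw(th, K)
      fw <- rqs_forward(as.numeric(z), sp$w, sp$h, sp$d, B)
      z <- matrix(fw$y, n, d)
      logJ <- logJ + rowSums(matrix(fw$logdet, n, d))
      caches[[l]] <- list(rqs = fw$cache)
    } else {
      mask <- ly$mask
      n_trans <- sum(!mask)
      xm <- z[, mask, drop = FALSE]
      mf <- mlp_forward(ly$net, xm)
      th <- theta_stack(mf$out, n_trans, K)
      sp <- rqs_split_raw(th, K)
      xt <- as.numeric(z[, !mask, drop = FALSE])
      fw <- rqs_forward(xt, sp$w, sp$h, sp$d, B)
      z2 <- z
      z2[, !mask] <- matrix(fw$y, n, n_trans)
      logJ <- logJ + rowSums(matrix(fw$logdet, n, n_trans))
      caches[[l]] <- list(mlp = mf, rqs = fw$cache)
      z <- z2
    }
  }
  list(z = z, logJ = logJ, caches = caches)
}

## Backward pass: gz is n x dim_z gradient w.r.t. the output z, glogJ a
## length-n gradient w.r.t. the per-sample logJ. Returns the flat parameter
## gradient (same layout as flow_get) and the gradient w.r.t. eps.
flow_backward <- function(flow, caches, gz, glogJ) {
  n <- nrow(gz)
  K <- flow$K
  p <- 3L * K - 1L
  grads <- vector("list", flow$n_layers)
  for (l in rev(seq_len(flow$n_layers))) {
    ly <- flow$layers[[l]]
    if (ly$type == "plain") {
      d <- flow$dim_z
      bk <- rqs_backward(caches[[l]]$rqs, as.numeric(gz), rep(glogJ, d))
      gth_rows <- cbind(bk$gw_raw, bk$gh_raw, bk$gd_raw)    # (n*d) x p
      gth <- matrix(0, d, p)
      for (t in seq_len(d)) gth[t, ] <- colSums(gth_rows[(t - 1L) * n + seq_len(n), , drop = FALSE])
      grads[[l]] <- list(theta = gth)
      gz <- matrix(bk$gx, n, d)
    } else {
      mask <- ly$mask
      n_trans <- sum(!mask)
      gy <- as.numeric(gz[, !mask, drop = FALSE])
      bk <- rqs_backward(caches[[l]]$rqs, gy, rep(glogJ, n_trans))
      gth_rows <- cbind(bk$gw_raw, bk$gh_raw, bk$gd_raw)
      gout <- matrix(0, n, n_trans * p)
      for (t in seq_len(n_trans)) gout[, (t - 1L) * p + seq_len(p)] <- gth_rows[(t - 1L) * n + seq_len(n), ]
      mb <- mlp_backward(ly$net, caches[[l]]$mlp, gout)
      grads[[l]] <- list(net = mb)
      gz_new <- gz
      gz_new[, mask] <- gz[, mask, drop = FALSE] + mb$gin
      gz_new[, !mask] <- matrix(bk$gx, n, n_trans)
      gz <- gz_new
    }
  }
  list(flat = flow_grads_flat(flow, grads), geps = gz)
}

## Inverse pass z -> eps, accumulating the forward log-determinant at the
## preimage (so log q(z) = log base(eps) - logJ_fwd).
flow_inverse <- function(flow, z) {
  n <- nrow(z)
  K <- flow$K; B <- flow$B
  logJ <- rep(0, n)
  for (l in rev(seq_len(flow$n_layers))) {
    ly <- flow$layers[[l]]
    if (ly$type == "plain") {
      d <- flow$dim_z
      th <- ly$theta[rep(seq_len(d), each = n), , drop = FALSE]
      sp <- rqs_split_raw(th, K)
      iv <- rqs_inverse(as.numeric(z), sp$w, sp$h, sp$d, B)
      z <- matrix(iv$x, n, d)
      logJ <- logJ + rowSums(matrix(iv$logdet_fwd, n, d))
    } else {
      mask <- ly$mask
      n_trans <- sum(!mask)
      xm <- z[, mask, drop = FALSE]                  # unchanged by this layer
      mf <- mlp_forward(ly$net, xm)
      th <- theta_stack(mf$out, n_trans, K)
      sp <- rqs_split_raw(th, K)
      iv <- rqs_inverse(as.numeric(z[, !mask, drop = FALSE]), sp$w, sp$h, sp$d, B)
      z[, !mask] <- matrix(iv$x, n, n_trans)
      logJ <- logJ + rowSums(matrix(iv$logdet_fwd, n, n_trans))
    }
  }
  list(eps = z, logJ_fwd = logJ)
}

#' Sample from the flow
#'
#' Draws base samples from the truncated standard normal on the spline
#' interval and pushes them through the spline stack; all samples stay
#' inside the support by construction.
#'
#' @param flow a `flow_model`.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return list with `z` (n x dim_z), `logJ` (length n) and `eps`.
#' @export
flow_sample <- function(flow, n, seed = NULL) {
  draw <- function() matrix(rtruncnorm_std(n * flow$dim_z, flow$B), n, flow$dim_z)
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  fw <- flow_forward(flow, eps)
  list(z = fw$z, logJ = fw$logJ, eps = eps)
}

#' Log-density of the flow
#'
#' Change of variables through the inverse spline stack. Points outside the
#' spline support have zero density (-Inf returned).
#'
#' @param flow a `flow_model`.
#' @param z matrix of points (n x dim_z).
#' @return numeric vector of log q(z).
#' @export
flow_log_prob <- function(flow, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = flow$dim_z)
  outside <- apply(abs(z) > flow$B, 1L, any)
  zc <- clamp(z, -flow$B, flow$B)
  iv <- flow_inverse(flow, zc)
  ## round-off can push recovered base points a few ulp outside the support
  eps <- clamp(iv$eps, -flow$B, flow$B)
  lp <- rowSums(matrix(dtruncnorm_std(as.numeric(eps), flow$B, log = TRUE),
                       nrow(z), flow$dim_z)) - iv$logJ_fwd
  lp[outside] <- -Inf
  lp
}

## --- flat parameters ---------------------------------------------------------

flow_get <- function(flow) {
  unlist(lapply(flow$layers, function(ly) {
    if (ly$type == "plain") as.numeric(ly$theta) else mlp_get(ly$net)
  }), use.names = FALSE)
}

flow_set <- function(flow, v) {
  i <- 0L
  for (l in seq_along(flow$layers)) {
    ly <- flow$layers[[l]]
    if (ly$type == "plain") {
      k <- length(ly$theta)
      flow$layers[[l]]$theta[] <- v[i + seq_len(k)]; i <- i + k
    } else {
      k <- mlp_n_params(ly$net)
      flow$layers[[l]]$net <- mlp_set(ly$net, v[i + seq_len(k)]); i <- i + k
    }
  }
  flow
}

flow_grads_flat <- function(flow, grads) {
  unlist(lapply(seq_along(grads), function(l) {
    if (flow$layers[[l]]$type == "plain") as.numeric(grads[[l]]$theta)
    else mlp_grad_flat(grads[[l]]$net)
  }), use.names = FALSE)
}

flow_n_params <- function(flow) length(flow_get(flow))
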