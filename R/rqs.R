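## Monotone rational-quadratic spline bijections on [-B, B] with linear tails
## (boundary derivatives fixed to 1), in the Durkan et al. parameterization:
## K bin widths and heights from a softmax (with a small minimum bin
## fraction), K-1 strictly positive internal knot derivatives from a
## softplus. All functions are elementwise over M inputs, each with its own
## parameter rows (M x K matrices) so the same code serves both plain layers
## (rows replicated) and coupling layers (rows emitted by a conditioner).

RQS_MIN_BIN <- 1e-3

## raw (M x K) -> bin sizes summing to 2B, each >= 2B*RQS_MIN_BIN
rqs_bins <- function(raw, B) {
  K <- ncol(raw)
  m <- raw[cbind(seq_len(nrow(raw)), max.col(raw, ties.method = "first"))]
  e <- exp(raw - m)
  p <- e / rowSums(e)
  c1 <- 2 * B * (1 - K * RQS_MIN_BIN)
  list(sizes = c1 * p + 2 * B * RQS_MIN_BIN, p = p, c1 = c1)
}

## identity-initialized raw parameter vector of length 3K-1
rqs_identity_raw <- function(K) {
  c(rep(0, 2 * K), rep(inv_softplus(1), K - 1L))
}

rqs_split_raw <- function(theta, K) {
  ## theta: M x (3K-1)
  list(w = theta[, seq_len(K), drop = FALSE],
       h = theta[, K + seq_len(K), drop = FALSE],
       d = theta[, 2L * K + seq_len(K - 1L), drop = FALSE])
}

## Forward transform. x: length-M vector; w_raw/h_raw: M x K; d_raw: M x (K-1).
## Returns y, logdet (elementwise log dy/dx) and a cache for the backward pass.
rqs_forward_ref <- function(x, w_raw, h_raw, d_raw, B) {
  M <- length(x)
  K <- ncol(w_raw)
  wb <- rqs_bins(w_raw, B)
  hb <- rqs_bins(h_raw, B)
  widths <- wb$sizes
  heights <- hb$sizes
  tri <- upper.tri(diag(K), diag = TRUE)
  cw <- widths %*% tri                              # right knot positions - (-B)
  ch <- heights %*% tri
  d_int <- softplus(d_raw)                          # internal derivatives
  inside <- abs(x) <= B
  xc <- clamp(x, -B, B)
  ## bin index: count of interior right-knots strictly below x
  if (K > 1L) {
    kx <- rowSums(xc - (-B) > cw[, seq_len(K - 1L), drop = FALSE] + 1e-14) + 1L
  } else kx <- rep(1L, M)
  kx <- pmin(kx, K)
  idx <- cbind(seq_len(M), kx)
  w <- widths[idx]
  h <- heights[idx]
  cw0 <- cbind(0, cw)                               # padded cumulatives
  ch0 <- cbind(0, ch)
  xk0 <- -B + cw0[idx]
  y0 <- -B + ch0[idx]
  dpadL <- cbind(1, d_int)                          # boundary derivatives = 1
  dpadR <- cbind(d_int, 1)
  dk <- dpadL[idx]
  dk1 <- dpadR[idx]
  xi <- clamp((xc - xk0) / w, 0, 1)
  s <- h / w
  q <- xi * (1 - xi)
  dsum <- dk + dk1
  D <- s + (dsum - 2 * s) * q
  N <- h * (s * xi^2 + dk * q)
  y <- y0 + N / D
  P <- dk1 * xi^2 + 2 * s * q + dk * (1 - xi)^2
  logdet <- 2 * log(s) + log(P) - 2 * log(D)
  ## linear tails
  y[!inside] <- x[!inside]
  logdet[!inside] <- 0
  list(y = y, logdet = logdet,
       cache = list(x = x, xc = xc, inside = inside, K = K, B = B,
                    kx = kx, idx = idx, w = w, h = h, xk0 = xk0, y0 = y0,
                    dk = dk, dk1 = dk1, xi = xi, s = s, q = q, D = D, N = N,
                    P = P, wb = wb, hb = hb, d_raw = d_raw, d_int = d_int))
}

## Backward pass: gy, glog are length-M gradients w.r.t. y and logdet.
## Returns gx (length M) and gradients w.r.t. the raw parameter matrices.
rqs_backward_ref <- function(cache, gy, glog) {
  with(cache, {
    M <- length(x)
    gy_orig <- gy
    gy <- gy * inside
    glog <- glog * inside
    one_m_xi <- 1 - xi
    dq <- 1 - 2 * xi
    dsum <- dk + dk1
    ## partials w.r.t. xi
    dN_dxi <- h * (2 * s * xi + dk * dq)
    dD_dxi <- (dsum - 2 * s) * dq
    dy_dxi <- (dN_dxi * D - N * dD_dxi) / D^2
    dP_dxi <- 2 * dk1 * xi + 2 * s * dq - 2 * dk * one_m_xi
    dlog_dxi <- dP_dxi / P - 2 * dD_dxi / D
    ## partials w.r.t. s
    dN_ds <- h * xi^2
    dD_ds <- 1 - 2 * q
    dy_ds <- (dN_ds * D - N * dD_ds) / D^2
    dlog_ds <- 2 / s + 2 * q / P - 2 * dD_ds / D
    ## partials w.r.t. dk / dk1
    dy_ddk <- (h * q * D - N * q) / D^2
    dlog_ddk <- one_m_xi^2 / P - 2 * q / D
    dy_ddk1 <- -N * q / D^2
    dlog_ddk1 <- xi^2 / P - 2 * q / D

    c_xi <- gy * dy_dxi + glog * dlog_dxi           # combined xi-channel
    c_s <- gy * dy_ds + glog * dlog_ds
    gx <- c_xi / w
    g_xk0 <- -c_xi / w
    g_w <- c_xi * (-xi / w) + c_s * (-s / w)
    g_h <- gy * (N / h) / D + c_s / w
    g_y0 <- gy
    g_dk <- gy * dy_ddk + glog * dlog_ddk
    g_dk1 <- gy * dy_ddk1 + glog * dlog_ddk1

    ## scatter to per-bin width/height gradients:
    ## width_j receives g_xk0 for j < k and g_w for j = k (heights likewise)
    below <- outer(kx, seq_len(K), ">")             # M x K logical
    gW <- below * g_xk0
    gW[idx] <- gW[idx] + g_w
    gH <- below * g_y0
    gH[idx] <- gH[idx] + g_h
    ## chain through softmax bin parameterization
    gw_raw <- softmax_backward(wb, gW)
    gh_raw <- softmax_backward(hb, gH)
    ## derivatives: internal knot j is right end of bin j and left end of bin j+1
    gd_raw <- matrix(0, M, K - 1L)
    if (K > 1L) {
      sel <- kx > 1L                                 # left derivative is internal
      if (any(sel)) {
        ii <- cbind(which(sel), kx[sel] - 1L)
        gd_raw[ii] <- gd_raw[ii] + g_dk[sel]
      }
      sel <- kx < K                                  # right derivative is internal
      if (any(sel)) {
        ii <- cbind(which(sel), kx[sel])
        gd_raw[ii] <- gd_raw[ii] + g_dk1[sel]
      }
      gd_raw <- gd_raw * sigmoid(d_raw)              # softplus'
    }
    ## linear tails: identity gradient for x, none for parameters
    gx[!inside] <- gy_orig[!inside]
    list(gx = gx, gw_raw = gw_raw, gh_raw = gh_raw, gd_raw = gd_raw)
  })
}

## gradient of (c1 * softmax(raw) + c0) w.r.t. raw, given gradient on sizes
softmax_backward <- function(bins, gsizes) {
  gp <- bins$c1 * gsizes
  bins$p * (gp - rowSums(gp * bins$p))
}

## Inverse transform (no parameter gradients needed). y: length-M vector.
rqs_inverse_ref <- function(y, w_raw, h_raw, d_raw, B) {
  M <- length(y)
  K <- ncol(w_raw)
  wb <- rqs_bins(w_raw, B)
  hb <- rqs_bins(h_raw, B)
  tri <- upper.tri(diag(K), diag = TRUE)
  cw <- wb$sizes %*% tri
  ch <- hb$sizes %*% tri
  d_int <- softplus(d_raw)
  inside <- abs(y) <= B
  yc <- clamp(y, -B, B)
  if (K > 1L) {
    kx <- rowSums(yc - (-B) > ch[, seq_len(K - 1L), drop = FALSE] + 1e-14) + 1L
  } else kx <- rep(1L, M)
  kx <- pmin(kx, K)
  idx <- cbind(seq_len(M), kx)
  w <- wb$sizes[idx]
  h <- hb$sizes[idx]
  cw0 <- cbind(0, cw)
  ch0 <- cbind(0, ch)
  xk0 <- -B + cw0[idx]
  y0 <- -B + ch0[idx]
  dpadL <- cbind(1, d_int)
  dpadR <- cbind(d_int, 1)
  dk <- dpadL[idx]
  dk1 <- dpadR[idx]
  s <- h / w
  dy <- yc - y0
  Dl <- dk + dk1 - 2 * s
  a <- h * (s - dk) + dy * Dl
  b <- h * dk - dy * Dl
  cc <- -s * dy
  disc <- pmax(b^2 - 4 * a * cc, 0)
  xi <- 2 * cc / (-b - sqrt(disc))
  xi <- clamp(xi, 0, 1)
  ## Newton polish: the closed form can lose precision in strongly
  ## contracting bins (tiny dy/dx), where small errors in xi are amplified
  for (it in 1:3) {
    q <- xi * (1 - xi)
    D <- s + (dk + dk1 - 2 * s) * q
    fx <- h * (s * xi^2 + dk * q) / D - dy
    dfx <- s^2 * (dk1 * xi^2 + 2 * s * q + dk * (1 - xi)^2) / D^2 * w
    xi <- clamp(xi - fx / pmax(dfx, 1e-300), 0, 1)
  }
  x <- xk0 + xi * w
  q <- xi * (1 - xi)
  D <- s + (dk + dk1 - 2 * s) * q
  P <- dk1 * xi^2 + 2 * s * q + dk * (1 - xi)^2
  logdet_fwd <- 2 * log(s) + log(P) - 2 * log(D)
  x[!inside] <- y[!inside]
  logdet_fwd[!inside] <- 0
  list(x = x, logdet_fwd = logdet_fwd)
}

## Hot-path dispatch: the C++ implementations (src/rqs.cpp) mirror the
## reference R versions above; tests cross-check the two routes.
rqs_forward <- function(x, w_raw, h_raw, d_raw, B) {
  rqs_forward_cpp(as.numeric(x), w_raw, h_raw, d_raw, B)
}

rqs_backward <- function(cache, gy, glog) {
  if (is.environment(cache) || !is.null(cache$wb))   # reference cache
    return(rqs_backward_ref(cache, gy, glog))
  rqs_backward_cpp(cache, gy, glog)
}

rqs_inverse <- function(y, w_raw, h_raw, d_raw, B) {
  rqs_inverse_cpp(as.numeric(y), w_raw, h_raw, d_raw, B)
}
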