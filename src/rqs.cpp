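// Rational-quadratic spline forward/backward/inverse, C++ hot path.
// Mirrors the reference R implementation (R/rqs.R, rqs_*_ref) exactly;
// the test suite cross-checks the two on random inputs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MIN_BIN = 1e-3;   // keep in sync with RQS_MIN_BIN

static inline double softplus1(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

// [[Rcpp::export]]
List rqs_forward_cpp(NumericVector x, NumericMatrix w_raw, NumericMatrix h_raw,
                     NumericMatrix d_raw, double B) {
  const int M = x.size(), K = w_raw.ncol();
  const double c1 = 2.0 * B * (1.0 - K * MIN_BIN), c0 = 2.0 * B * MIN_BIN;
  NumericMatrix pw(M, K), ph(M, K);
  NumericVector y(M), logdet(M), w(M), h(M), xk0(M), y0(M), dk(M), dk1(M),
      xi(M), s(M), q(M), D(M), N(M), P(M);
  IntegerVector kx(M);
  LogicalVector inside(M);
  std::vector<double> cw(K), ch(K);
  for (int i = 0; i < M; ++i) {
    // row softmaxes
    double mw = w_raw(i, 0), mh = h_raw(i, 0);
    for (int k = 1; k < K; ++k) {
      if (w_raw(i, k) > mw) mw = w_raw(i, k);
      if (h_raw(i, k) > mh) mh = h_raw(i, k);
    }
    double sw = 0, sh = 0;
    for (int k = 0; k < K; ++k) {
      pw(i, k) = std::exp(w_raw(i, k) - mw); sw += pw(i, k);
      ph(i, k) = std::exp(h_raw(i, k) - mh); sh += ph(i, k);
    }
    double acw = 0, ach = 0;
    for (int k = 0; k < K; ++k) {
      pw(i, k) /= sw; ph(i, k) /= sh;
      acw += c1 * pw(i, k) + c0; cw[k] = acw;
      ach += c1 * ph(i, k) + c0; ch[k] = ach;
    }
    bool ins = std::fabs(x[i]) <= B;
    inside[i] = ins;
    double xc = x[i] < -B ? -B : (x[i] > B ? B : x[i]);
    int k = 0;
    while (k < K - 1 && xc + B > cw[k] + 1e-14) ++k;
    kx[i] = k + 1;                           // 1-based for R parity
    double wi = c1 * pw(i, k) + c0, hi = c1 * ph(i, k) + c0;
    double x0 = -B + (k > 0 ? cw[k - 1] : 0.0);
    double yy0 = -B + (k > 0 ? ch[k - 1] : 0.0);
    double dl = (k == 0) ? 1.0 : softplus1(d_raw(i, k - 1));
    double dr = (k == K - 1) ? 1.0 : softplus1(d_raw(i, k));
    double xii = (xc - x0) / wi;
    if (xii < 0) xii = 0; if (xii > 1) xii = 1;
    double si = hi / wi, qi = xii * (1.0 - xii);
    double Di = si + (dl + dr - 2.0 * si) * qi;
    double Ni = hi * (si * xii * xii + dl * qi);
    double Pi = dr * xii * xii + 2.0 * si * qi + dl * (1.0 - xii) * (1.0 - xii);
    w[i] = wi; h[i] = hi; xk0[i] = x0; y0[i] = yy0; dk[i] = dl; dk1[i] = dr;
    xi[i] = xii; s[i] = si; q[i] = qi; D[i] = Di; N[i] = Ni; P[i] = Pi;
    if (ins) {
      y[i] = yy0 + Ni / Di;
      logdet[i] = 2.0 * std::log(si) + std::log(Pi) - 2.0 * std::log(Di);
    } else {
      y[i] = x[i];
      logdet[i] = 0.0;
    }
  }
  List cache = List::create(
      _["x"] = x, _["inside"] = inside, _["K"] = K, _["B"] = B,
      _["kx"] = kx, _["w"] = w, _["h"] = h, _["xk0"] = xk0, _["y0"] = y0,
      _["dk"] = dk, _["dk1"] = dk1, _["xi"] = xi, _["s"] = s, _["q"] = q,
      _["D"] = D, _["N"] = N, _["P"] = P, _["pw"] = pw, _["ph"] = ph,
      _["c1"] = c1, _["d_raw"] = d_raw);
  return List::create(_["y"] = y, _["logdet"] = logdet, _["cache"] = cache);
}

// [[Rcpp::export]]
List rqs_backward_cpp(List cache, NumericVector gy, NumericVector glog) {
  NumericVector x = cache["x"], w = cache["w"], h = cache["h"],
      xk0 = cache["xk0"], y0 = cache["y0"], dk = cache["dk"],
      dk1 = cache["dk1"], xi = cache["xi"], s = cache["s"], q = cache["q"],
      D = cache["D"], N = cache["N"], P = cache["P"];
  IntegerVector kx = cache["kx"];
  LogicalVector inside = cache["inside"];
  NumericMatrix pw = cache["pw"], ph = cache["ph"];
  NumericMatrix d_raw = cache["d_raw"];
  const double c1 = cache["c1"];
  const int M = x.size(), K = cache["K"];
  NumericVector gx(M);
  NumericMatrix gw_raw(M, K), gh_raw(M, K), gd_raw(M, std::max(K - 1, 0));
  std::vector<double> gW(K), gH(K);
  for (int i = 0; i < M; ++i) {
    if (!inside[i]) { gx[i] = gy[i]; continue; }
    const double gyi = gy[i], gli = glog[i];
    const double xii = xi[i], si = s[i], qi = q[i], Di = D[i], Ni = N[i],
        Pi = P[i], dl = dk[i], dr = dk1[i], wi = w[i], hi = h[i];
    const double omx = 1.0 - xii, dq = 1.0 - 2.0 * xii, dsum = dl + dr;
    const double D2 = Di * Di;
    // xi channel
    const double dN_dxi = hi * (2.0 * si * xii + dl * dq);
    const double dD_dxi = (dsum - 2.0 * si) * dq;
    const double dy_dxi = (dN_dxi * Di - Ni * dD_dxi) / D2;
    const double dP_dxi = 2.0 * dr * xii + 2.0 * si * dq - 2.0 * dl * omx;
    const double dlog_dxi = dP_dxi / Pi - 2.0 * dD_dxi / Di;
    // s channel
    const double dN_ds = hi * xii * xii;
    const double dD_ds = 1.0 - 2.0 * qi;
    const double dy_ds = (dN_ds * Di - Ni * dD_ds) / D2;
    const double dlog_ds = 2.0 / si + 2.0 * qi / Pi - 2.0 * dD_ds / Di;
    // derivative channels
    const double dy_ddk = (hi * qi * Di - Ni * qi) / D2;
    const double dlog_ddk = omx * omx / Pi - 2.0 * qi / Di;
    const double dy_ddk1 = -Ni * qi / D2;
    const double dlog_ddk1 = xii * xii / Pi - 2.0 * qi / Di;

    const double c_xi = gyi * dy_dxi + gli * dlog_dxi;
    const double c_s = gyi * dy_ds + gli * dlog_ds;
    gx[i] = c_xi / wi;
    const double g_xk0 = -c_xi / wi;
    const double g_w = c_xi * (-xii / wi) + c_s * (-si / wi);
    const double g_h = gyi * (Ni / hi) / Di + c_s / wi;
    const double g_y0 = gyi;
    const double g_dk = gyi * dy_ddk + gli * dlog_ddk;
    const double g_dk1 = gyi * dy_ddk1 + gli * dlog_ddk1;

    const int k = kx[i] - 1;                // 0-based bin
    double dotW = 0, dotH = 0;
    for (int j = 0; j < K; ++j) {
      gW[j] = (j < k) ? g_xk0 : 0.0;
      gH[j] = (j < k) ? g_y0 : 0.0;
    }
    gW[k] += g_w; gH[k] += g_h;
    for (int j = 0; j < K; ++j) {
      dotW += c1 * gW[j] * pw(i, j);
      dotH += c1 * gH[j] * ph(i, j);
    }
    for (int j = 0; j < K; ++j) {
      gw_raw(i, j) = pw(i, j) * (c1 * gW[j] - dotW);
      gh_raw(i, j) = ph(i, j) * (c1 * gH[j] - dotH);
    }
    if (K > 1) {
      if (k > 0) {                          // left derivative is internal knot k-1
        double sig = 1.0 / (1.0 + std::exp(-d_raw(i, k - 1)));
        gd_raw(i, k - 1) += g_dk * sig;
      }
      if (k < K - 1) {                      // right derivative is internal knot k
        double sig = 1.0 / (1.0 + std::exp(-d_raw(i, k)));
        gd_raw(i, k) += g_dk1 * sig;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw_raw"] = gw_raw,
                      _["gh_raw"] = gh_raw, _["gd_raw"] = gd_raw);
}

// [[Rcpp::export]]
List rqs_inverse_cpp(NumericVector y, NumericMatrix w_raw, NumericMatrix h_raw,
                     NumericMatrix d_raw, double B) {
  const int M = y.size(), K = w_raw.ncol();
  const double c1 = 2.0 * B * (1.0 - K * MIN_BIN), c0 = 2.0 * B * MIN_BIN;
  NumericVector x(M), logdet(M);
  std::vector<double> pw(K), ph(K), cw(K), ch(K);
  for (int i = 0; i < M; ++i) {
    double mw = w_raw(i, 0), mh = h_raw(i, 0);
    for (int k = 1; k < K; ++k) {
      if (w_raw(i, k) > mw) mw = w_raw(i, k);
      if (h_raw(i, k) > mh) mh = h_raw(i, k);
    }
    double sw = 0, sh = 0;
    for (int k = 0; k < K; ++k) {
      pw[k] = std::exp(w_raw(i, k) - mw); sw += pw[k];
      ph[k] = std::exp(h_raw(i, k) - mh); sh += ph[k];
    }
    double acw = 0, ach = 0;
    for (int k = 0; k < K; ++k) {
      acw += c1 * pw[k] / sw + c0; cw[k] = acw;
      ach += c1 * ph[k] / sh + c0; ch[k] = ach;
    }
    bool ins = std::fabs(y[i]) <= B;
    double yc = y[i] < -B ? -B : (y[i] > B ? B : y[i]);
    int k = 0;
    while (k < K - 1 && yc + B > ch[k] + 1e-14) ++k;
    double wi = c1 * pw[k] / sw + c0, hi = c1 * ph[k] / sh + c0;
    double x0 = -B + (k > 0 ? cw[k - 1] : 0.0);
    double yy0 = -B + (k > 0 ? ch[k - 1] : 0.0);
    double dl = (k == 0) ? 1.0 : softplus1(d_raw(i, k - 1));
    double dr = (k == K - 1) ? 1.0 : softplus1(d_raw(i, k));
    double si = hi / wi, dy = yc - yy0;
    double Dl = dl + dr - 2.0 * si;
    double a = hi * (si - dl) + dy * Dl;
    double b = hi * dl - dy * Dl;
    double cc = -si * dy;
    double disc = b * b - 4.0 * a * cc;
    if (disc < 0) disc = 0;
    double xii = 2.0 * cc / (-b - std::sqrt(disc));
    if (xii < 0) xii = 0; if (xii > 1) xii = 1;
    for (int it = 0; it < 3; ++it) {        // Newton polish
      double qi = xii * (1.0 - xii);
      double Di = si + Dl * qi;
      double fx = hi * (si * xii * xii + dl * qi) / Di - dy;
      double Pi = dr * xii * xii + 2.0 * si * qi +
          dl * (1.0 - xii) * (1.0 - xii);
      double dfx = si * si * Pi / (Di * Di) * wi;
      if (dfx < 1e-300) dfx = 1e-300;
      xii -= fx / dfx;
      if (xii < 0) xii = 0; if (xii > 1) xii = 1;
    }
    double qi = xii * (1.0 - xii);
    double Di = si + Dl * qi;
    double Pi = dr * xii * xii + 2.0 * si * qi + dl * (1.0 - xii) * (1.0 - xii);
    if (ins) {
      x[i] = x0 + xii * wi;
      logdet[i] = 2.0 * std::log(si) + std::log(Pi) - 2.0 * std::log(Di);
    } else {
      x[i] = y[i];
      logdet[i] = 0.0;
    }
  }
  return List::create(_["x"] = x, _["logdet_fwd"] = logdet);
}
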