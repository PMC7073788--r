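#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam update, in place: the caller owns p, m and v exclusively.
// lr_t carries the bias-correction factors; wd is the decoupled-from-nothing
// classic L2 term added to the gradient.
// [[Rcpp::export]]
void adam_step_inplace(NumericVector p, NumericVector m, NumericVector v,
                       NumericVector g, double lr_t, double b1, double b2,
                       double eps, double wd) {
  R_xlen_t n = p.size();
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i] + wd * pp[i];
    double mi = b1 * pm[i] + (1.0 - b1) * gi;
    double vi = b2 * pv[i] + (1.0 - b2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr_t * mi / (std::sqrt(vi) + eps);
  }
}

// column means and biased column variances in one pass
// [[Rcpp::export]]
List col_mean_var(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector mu(nc), var(nc);
  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < nr; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    double m = s / nr;
    mu[j] = m;
    var[j] = s2 / nr - m * m;
    if (var[j] < 0) var[j] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// out[i,j] = x[i,j] * scale[j] + shift[j]
// [[Rcpp::export]]
NumericMatrix col_affine(NumericMatrix x, NumericVector scale,
                         NumericVector shift) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    double *oc = &out(0, j);
    double a = scale[j], b = shift[j];
    for (int i = 0; i < nr; ++i) oc[i] = col[i] * a + b;
  }
  return out;
}

// batch-norm backward for column-normalized data:
//   dxhat = dout * gamma_j
//   dx = (dxhat - mean_i(dxhat) - xhat * mean_i(dxhat * xhat)) * inv_sd_j
// [[Rcpp::export]]
List bn_backward_cpp(NumericMatrix dout, NumericMatrix xhat,
                     NumericVector inv_sd, NumericVector gamma) {
  int nr = dout.nrow(), nc = dout.ncol();
  NumericMatrix dx(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int j = 0; j < nc; ++j) {
    const double *dc = &dout(0, j);
    const double *xc = &xhat(0, j);
    double *ox = &dx(0, j);
    double g = gamma[j], s = inv_sd[j];
    double sum_d = 0.0, sum_dx = 0.0;
    for (int i = 0; i < nr; ++i) {
      sum_d += dc[i];
      sum_dx += dc[i] * xc[i];
    }
    dbeta[j] = sum_d;
    dgamma[j] = sum_dx;
    double m1 = g * sum_d / nr, m2 = g * sum_dx / nr;
    for (int i = 0; i < nr; ++i)
      ox[i] = (g * dc[i] - m1 - xc[i] * m2) * s;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// mean of `shots` iid zero-mean Gaussian noise vectors, drawn shot-major
// from R's uniform RNG stream (polar method); sd may be a scalar or one
// value per channel
// [[Rcpp::export]]
NumericVector noise_mean_cpp(int n, int shots, NumericVector sd) {
  NumericVector acc(n);
  bool scalar_sd = sd.size() == 1;
  GetRNGstate();
  double spare = 0.0;
  bool has_spare = false;
  for (int s = 0; s < shots; ++s)
    for (int i = 0; i < n; ++i) {
      double z;
      if (has_spare) {
        z = spare;
        has_spare = false;
      } else {
        double u, v, r2;
        do {
          u = 2.0 * unif_rand() - 1.0;
          v = 2.0 * unif_rand() - 1.0;
          r2 = u * u + v * v;
        } while (r2 >= 1.0 || r2 == 0.0);
        double f = std::sqrt(-2.0 * std::log(r2) / r2);
        z = u * f;
        spare = v * f;
        has_spare = true;
      }
      acc[i] += z * (scalar_sd ? sd[0] : sd[i]);
    }
  PutRNGstate();
  for (int i = 0; i < n; ++i) acc[i] /= shots;
  return acc;
}

// full linear convolution: out[m] = sum_j x[j] * f[m - j + 1]
// [[Rcpp::export]]
NumericVector conv_full_cpp(NumericVector x, NumericVector f) {
  int n = x.size(), p = f.size();
  NumericVector out(n + p - 1);
  for (int j = 0; j < p; ++j) {
    double fj = f[j];
    if (fj == 0.0) continue;
    for (int i = 0; i < n; ++i) out[i + j] += x[i] * fj;
  }
  return out;
}
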