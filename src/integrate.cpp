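// Fixed-step RK4 core for the coupled Wendling network.
//
// The vector field mirrors network_derivatives() in R/model.R; it lives in
// C++ because the coupling sweep integrates the network thousands of times.
// The external input is sampled once per step (one value per region) and
// held constant across the four RK4 stages; noise is drawn in R so that all
// randomness stays under R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Pars {
  double A, B, G, a, b, g;
  double C1, C2, C3, C4, C5, C6, C7;
  double v0, e0, r;
};

inline vec sigm(const vec& v, const Pars& p) {
  return 2.0 * p.e0 / (1.0 + exp(p.r * (p.v0 - v)));
}

// y is N x 10 (columns y0..y9); CS is the effective coupling c_global * W
mat deriv(const mat& y, const mat& CS, const Pars& p, const vec& input,
          bool coupled) {
  const vec y0 = y.col(0), y1 = y.col(1), y2 = y.col(2), y3 = y.col(3),
            y4 = y.col(4), y5 = y.col(5), y6 = y.col(6), y7 = y.col(7),
            y8 = y.col(8), y9 = y.col(9);
  const vec s_out = sigm(y1 - y2 - y3, p);
  vec coup(y.n_rows, fill::zeros);
  if (coupled) coup = CS * s_out;

  mat d(y.n_rows, 10);
  d.col(0) = y5;
  d.col(1) = y6;
  d.col(2) = y7;
  d.col(3) = y8;
  d.col(4) = y9;
  d.col(5) = p.A * p.a * s_out - 2.0 * p.a * y5 - p.a * p.a * y0;
  d.col(6) = p.A * p.a * (input + coup + p.C2 * sigm(p.C1 * y0, p)) -
             2.0 * p.a * y6 - p.a * p.a * y1;
  d.col(7) = p.B * p.b * p.C4 * sigm(p.C3 * y0, p) -
             2.0 * p.b * y7 - p.b * p.b * y2;
  d.col(8) = p.G * p.g * p.C7 * sigm(p.C5 * y0 - y4, p) -
             2.0 * p.g * y8 - p.g * p.g * y3;
  d.col(9) = p.B * p.b * p.C6 * sigm(p.C3 * y0, p) -
             2.0 * p.b * y9 - p.b * p.b * y4;
  return d;
}

} // namespace

// [[Rcpp::export(name = ".rk4_core")]]
Rcpp::List rk4_core(const arma::mat& y_init, const arma::mat& cs,
                    const Rcpp::NumericVector& par, const arma::mat& noise,
                    double h) {
  Pars p;
  p.A = par["A"];  p.B = par["B"];  p.G = par["G"];
  p.a = par["a"];  p.b = par["b"];  p.g = par["g"];
  p.C1 = par["C1"]; p.C2 = par["C2"]; p.C3 = par["C3"]; p.C4 = par["C4"];
  p.C5 = par["C5"]; p.C6 = par["C6"]; p.C7 = par["C7"];
  p.v0 = par["v0"]; p.e0 = par["e0"]; p.r = par["r"];

  const uword n = y_init.n_rows;
  const uword n_steps = noise.n_cols;
  const bool coupled = any(vectorise(cs) != 0.0);

  mat y = y_init;
  mat out(n, n_steps);

  for (uword s = 0; s < n_steps; ++s) {
    const vec input = noise.col(s); // held constant over the 4 stages
    const mat k1 = deriv(y, cs, p, input, coupled);
    const mat k2 = deriv(y + 0.5 * h * k1, cs, p, input, coupled);
    const mat k3 = deriv(y + 0.5 * h * k2, cs, p, input, coupled);
    const mat k4 = deriv(y + h * k3, cs, p, input, coupled);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

    if (!y.is_finite()) {
      uword bad_region = 0;
      for (uword i = 0; i < n; ++i) {
        if (!y.row(i).is_finite()) { bad_region = i + 1; break; }
      }
      Rcpp::stop("integration diverged at step %d (region %d)",
                 (int)(s + 1), (int)bad_region);
    }
    out.col(s) = y.col(1) - y.col(2) - y.col(3);
  }

  return Rcpp::List::create(Rcpp::Named("output") = out,
                            Rcpp::Named("state") = y);
}
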