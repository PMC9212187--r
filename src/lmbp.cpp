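// Levenberg-Marquardt backpropagation for a fixed-architecture MLP:
// inputs -> tanh(h1) -> tanh(h2) -> logistic(1).  Parameters live in one
// flat vector x = [vec(W1), b1, vec(W2), b2, vec(W3), b3] (column-major).
// The Jacobian J = d e / d x with e = y - a is built row-by-row from the
// layer sensitivities; the update is x <- x - (J'J + mu I)^{-1} J'e.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct MlpShape {
  int nin, h1, h2;
  int np() const { return h1 * nin + h1 + h2 * h1 + h2 + h2 + 1; }
};

struct MlpW {
  mat W1, W2;
  rowvec W3;
  vec b1, b2;
  double b3;
};

static MlpW unpack(const vec& x, const MlpShape& s) {
  MlpW w;
  int o = 0;
  w.W1 = reshape(x.subvec(o, o + s.h1 * s.nin - 1), s.h1, s.nin); o += s.h1 * s.nin;
  w.b1 = x.subvec(o, o + s.h1 - 1); o += s.h1;
  w.W2 = reshape(x.subvec(o, o + s.h2 * s.h1 - 1), s.h2, s.h1); o += s.h2 * s.h1;
  w.b2 = x.subvec(o, o + s.h2 - 1); o += s.h2;
  w.W3 = x.subvec(o, o + s.h2 - 1).t(); o += s.h2;
  w.b3 = x(o);
  return w;
}

static inline double logistic(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// forward pass over all rows of X; optionally fill layer activations
static vec forward_all(const vec& x, const MlpShape& s, const mat& X,
                       mat* A1 = nullptr, mat* A2 = nullptr) {
  MlpW w = unpack(x, s);
  mat a1 = tanh(X * w.W1.t() + repmat(w.b1.t(), X.n_rows, 1));
  mat a2 = tanh(a1 * w.W2.t() + repmat(w.b2.t(), X.n_rows, 1));
  vec n3 = a2 * w.W3.t() + w.b3;
  vec out(n3.n_elem);
  for (uword i = 0; i < n3.n_elem; ++i) out(i) = logistic(n3(i));
  if (A1) *A1 = a1;
  if (A2) *A2 = a2;
  return out;
}

// Jacobian of the error vector e = y - a3 (n x np) and e itself
static void jacobian(const vec& x, const MlpShape& s, const mat& X,
                     const vec& y, mat& J, vec& e) {
  MlpW w = unpack(x, s);
  mat A1, A2;
  vec a3 = forward_all(x, s, X, &A1, &A2);
  e = y - a3;
  const int n = X.n_rows;
  J.set_size(n, s.np());
  for (int i = 0; i < n; ++i) {
    rowvec a1 = A1.row(i), a2 = A2.row(i);
    double s3 = a3(i) * (1.0 - a3(i));          // logistic derivative
    rowvec d2 = s3 * w.W3 % (1.0 - square(a2)); // 1 x h2
    rowvec d1 = (d2 * w.W2) % (1.0 - square(a1)); // 1 x h1
    int o = 0;
    // de/dW1 = -(d1' x_row), column-major over (h1 x nin)
    for (int c = 0; c < s.nin; ++c)
      for (int r = 0; r < s.h1; ++r) J(i, o++) = -d1(r) * X(i, c);
    for (int r = 0; r < s.h1; ++r) J(i, o++) = -d1(r);
    for (int c = 0; c < s.h1; ++c)
      for (int r = 0; r < s.h2; ++r) J(i, o++) = -d2(r) * a1(c);
    for (int r = 0; r < s.h2; ++r) J(i, o++) = -d2(r);
    for (int c = 0; c < s.h2; ++c) J(i, o++) = -s3 * a2(c);
    J(i, o++) = -s3;
  }
}

// [[Rcpp::export(name = ".mlp_forward_cpp")]]
arma::vec mlp_forward_cpp(const arma::vec& x, int nin, int h1, int h2,
                          const arma::mat& X) {
  MlpShape s{nin, h1, h2};
  return forward_all(x, s, X);
}

// [[Rcpp::export(name = ".mlp_jacobian_cpp")]]
Rcpp::List mlp_jacobian_cpp(const arma::vec& x, int nin, int h1, int h2,
                            const arma::mat& X, const arma::vec& y) {
  MlpShape s{nin, h1, h2};
  mat J; vec e;
  jacobian(x, s, X, y, J, e);
  return Rcpp::List::create(Rcpp::Named("J") = J, Rcpp::Named("e") = e);
}

// One LM iteration: propose x - (H + mu I)^{-1} G, escalate mu on
// rejection.  Returns the (possibly unchanged) x, the mu to use next,
// the objective after the step and whether a step was accepted.
static bool lm_iterate(vec& x, double& mu, double& F, const MlpShape& s,
                       const mat& X, const vec& y,
                       double mu_inc, double mu_dec, double mu_max,
                       double grad_tol, bool& converged) {
  mat J; vec e;
  jacobian(x, s, X, y, J, e);
  F = dot(e, e);
  mat H = J.t() * J;
  vec G = J.t() * e;
  if (norm(G, "inf") < grad_tol) { converged = true; return false; }
  while (mu <= mu_max) {
    vec dx;
    bool ok = solve(dx, H + mu * eye(H.n_rows, H.n_cols), G,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (ok) {
      vec xc = x - dx;
      vec ec = y - forward_all(xc, s, X);
      double Fc = dot(ec, ec);
      if (std::isfinite(Fc) && Fc < F) {
        x = xc; F = Fc;
        mu = std::max(mu / mu_dec, 1e-20);
        return true;
      }
    }
    mu *= mu_inc;
  }
  converged = true; // mu escalated past mu_max: no acceptable step exists
  return false;
}

// [[Rcpp::export(name = ".lmbp_train_cpp")]]
Rcpp::List lmbp_train_cpp(const arma::vec& x0, int nin, int h1, int h2,
                          const arma::mat& X, const arma::vec& y,
                          double mu0, double mu_inc, double mu_dec,
                          double mu_max, int max_epochs, double grad_tol) {
  MlpShape s{nin, h1, h2};
  vec x = x0;
  double mu = mu0;
  std::vector<double> hist;
  vec e0 = y - forward_all(x, s, X);
  double F = dot(e0, e0);
  hist.push_back(F);
  bool converged = false;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    bool accepted = lm_iterate(x, mu, F, s, X, y, mu_inc, mu_dec, mu_max,
                               grad_tol, converged);
    hist.push_back(F);
    if (!accepted) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("history") = hist,
    Rcpp::Named("mu") = mu,
    Rcpp::Named("epochs") = epoch,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".lmbp_step_cpp")]]
Rcpp::List lmbp_step_cpp(const arma::vec& x0, int nin, int h1, int h2,
                         const arma::mat& X, const arma::vec& y,
                         double mu, double mu_inc, double mu_dec,
                         double mu_max, double grad_tol) {
  MlpShape s{nin, h1, h2};
  vec x = x0;
  double F = 0.0;
  bool converged = false;
  bool accepted = lm_iterate(x, mu, F, s, X, y, mu_inc, mu_dec, mu_max,
                             grad_tol, converged);
  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("F") = F,
    Rcpp::Named("mu") = mu,
    Rcpp::Named("accepted") = accepted,
    Rcpp::Named("converged") = converged);
}
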