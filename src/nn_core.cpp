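// Numeric core of the three-layer sigmoid network: forward pass, mse
// fitness of a flat weight vector, analytic gradient, and the full-batch
// gradient-descent loop.  All stochastic draws stay on the R side, so
// these routines are pure deterministic kernels.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Pre-activations are clamped to +/-35: the widest symmetric range for
// which 1/(1+exp(-z)) stays strictly inside (0,1) in double precision.
static inline void sigm_inplace(mat &z) {
  z.clamp(-35.0, 35.0);
  z = 1.0 / (1.0 + exp(-z));
}

struct Net {
  mat W1, W2;
  rowvec b1, b2;
};

// Flat layout: W1 row-major, b1, W2 row-major, b2.
static Net unflatten(const vec &v, int ni, int nh, int no) {
  Net n;
  int i = 0;
  n.W1 = trans(reshape(v.subvec(i, i + ni * nh - 1), nh, ni)); i += ni * nh;
  n.b1 = trans(v.subvec(i, i + nh - 1)); i += nh;
  n.W2 = trans(reshape(v.subvec(i, i + nh * no - 1), no, nh)); i += nh * no;
  n.b2 = trans(v.subvec(i, i + no - 1));
  return n;
}

static vec flatten(const Net &n) {
  vec out(n.W1.n_elem + n.b1.n_elem + n.W2.n_elem + n.b2.n_elem);
  int i = 0;
  mat t1 = trans(n.W1);
  out.subvec(i, i + t1.n_elem - 1) = vectorise(t1); i += t1.n_elem;
  out.subvec(i, i + n.b1.n_elem - 1) = trans(n.b1); i += n.b1.n_elem;
  mat t2 = trans(n.W2);
  out.subvec(i, i + t2.n_elem - 1) = vectorise(t2); i += t2.n_elem;
  out.subvec(i, i + n.b2.n_elem - 1) = trans(n.b2);
  return out;
}

// Forward pass into caller-provided buffers (H: n x nh, out: n x no).
static void fwd_into(const Net &n, const mat &X, mat &H, mat &out) {
  H = X * n.W1;
  H.each_row() += n.b1;
  sigm_inplace(H);
  out = H * n.W2;
  out.each_row() += n.b2;
  sigm_inplace(out);
}

// [[Rcpp::export]]
arma::mat cpp_forward(const arma::mat &W1, const arma::rowvec &b1,
                      const arma::mat &W2, const arma::rowvec &b2,
                      const arma::mat &X) {
  Net n; n.W1 = W1; n.b1 = b1; n.W2 = W2; n.b2 = b2;
  mat H, out;
  fwd_into(n, X, H, out);
  return out;
}

// Mean squared training error of the network encoded in v.
// [[Rcpp::export]]
double cpp_mse_fitness(const arma::vec &v, const arma::mat &X,
                       const arma::vec &y, int ni, int nh, int no) {
  Net n = unflatten(v, ni, nh, no);
  mat H, out;
  fwd_into(n, X, H, out);
  return accu(square(out.col(0) - y)) / out.n_elem;
}

// Mean squared fitness of each row of V (a pack of flat weight vectors).
// [[Rcpp::export]]
arma::vec cpp_mse_fitness_batch(const arma::mat &V, const arma::mat &X,
                                const arma::vec &y, int ni, int nh, int no) {
  vec res(V.n_rows);
  mat H, out;
  for (uword i = 0; i < V.n_rows; ++i) {
    Net n = unflatten(trans(V.row(i)), ni, nh, no);
    fwd_into(n, X, H, out);
    res(i) = accu(square(out.col(0) - y)) / out.n_elem;
  }
  return res;
}

// Gradient of the mse loss at `n`, written into g; returns the mse at `n`
// itself (the forward quantities are shared between loss and gradient).
static double gradient_mse(const Net &n, const mat &X, const mat &Y,
                           Net &g, mat &H, mat &out) {
  double scale = 2.0 / (X.n_rows * Y.n_cols);
  fwd_into(n, X, H, out);
  double m = accu(square(out - Y)) / out.n_elem;
  mat d2 = scale * (out - Y) % out % (1.0 - out);
  mat d1 = (d2 * trans(n.W2)) % H % (1.0 - H);
  g.W1 = trans(X) * d1;
  g.b1 = sum(d1, 0);
  g.W2 = trans(H) * d2;
  g.b2 = sum(d2, 0);
  return m;
}

// [[Rcpp::export]]
Rcpp::List cpp_gradient(const arma::mat &W1, const arma::rowvec &b1,
                        const arma::mat &W2, const arma::rowvec &b2,
                        const arma::mat &X, const arma::mat &Y) {
  Net n; n.W1 = W1; n.b1 = b1; n.W2 = W2; n.b2 = b2;
  Net g;
  mat H, out;
  gradient_mse(n, X, Y, g, H, out);
  return Rcpp::List::create(Rcpp::Named("W1") = g.W1,
                            Rcpp::Named("b1") = trans(g.b1),
                            Rcpp::Named("W2") = g.W2,
                            Rcpp::Named("b2") = trans(g.b2));
}

// Full-batch gradient descent (optional classical momentum) from the
// network encoded in v; returns the best weight vector seen, its mse, and
// the epochs run.  Stops at the goal, at the epoch cap, or when the best
// mse has improved by less than a relative conv_tol over the last
// conv_window epochs.  Throws (with the epoch number) if weights become
// non-finite.
// [[Rcpp::export]]
Rcpp::List cpp_backprop(const arma::vec &v, const arma::mat &X,
                        const arma::vec &y, int ni, int nh, int no,
                        double lr, double momentum, double goal,
                        int max_epochs, double conv_tol, int conv_window) {
  Net cur = unflatten(v, ni, nh, no);
  mat Y(y);
  Net g, vel, best = cur;
  vel.W1 = zeros(size(cur.W1)); vel.b1 = zeros<rowvec>(cur.b1.n_elem);
  vel.W2 = zeros(size(cur.W2)); vel.b2 = zeros<rowvec>(cur.b2.n_elem);
  mat H, out;
  double best_mse = datum::inf;
  double window_ref = datum::inf;
  int epochs = 0;
  for (int e = 0; e <= max_epochs; ++e) {
    // gradient and loss share one forward pass, evaluated at `cur`
    double m = gradient_mse(cur, X, Y, g, H, out);
    if (m < best_mse) { best_mse = m; best = cur; }
    if (best_mse <= goal || e == max_epochs) break;
    if (conv_window > 0 && e > 0 && e % conv_window == 0) {
      if ((window_ref - best_mse) < conv_tol * std::max(best_mse, 1e-12))
        break;
      window_ref = best_mse;
    }
    vel.W1 = momentum * vel.W1 - lr * g.W1;
    vel.b1 = momentum * vel.b1 - lr * g.b1;
    vel.W2 = momentum * vel.W2 - lr * g.W2;
    vel.b2 = momentum * vel.b2 - lr * g.b2;
    cur.W1 += vel.W1; cur.b1 += vel.b1;
    cur.W2 += vel.W2; cur.b2 += vel.b2;
    if (!cur.W1.is_finite() || !cur.b1.is_finite() ||
        !cur.W2.is_finite() || !cur.b2.is_finite())
      Rcpp::stop("training diverged at epoch %d (non-finite weights)", e + 1);
    epochs = e + 1;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = flatten(best),
                            Rcpp::Named("train_mse") = best_mse,
                            Rcpp::Named("epochs") = epochs);
}
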