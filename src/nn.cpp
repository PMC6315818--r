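// Feed-forward network with two hidden layers, bipolar tanh activation
// g(z) = tanh(a z) at every layer including the output node, trained by
// per-sample steepest-descent backpropagation with momentum.  The training
// loop lives here because it runs up to n_max epochs over every sample;
// shuffling uses R's RNG so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// forward pass; optionally keep layer activations for backprop
static double forward_core(const arma::vec& x, const arma::mat& W1,
                           const arma::mat& W2, const arma::mat& W3,
                           double a, arma::vec* h1 = nullptr,
                           arma::vec* h2 = nullptr) {
  arma::vec xb(x.n_elem + 1);
  xb.head(x.n_elem) = x;
  xb(x.n_elem) = 1.0;
  arma::vec v1 = arma::tanh(a * (W1.t() * xb));
  arma::vec v1b(v1.n_elem + 1);
  v1b.head(v1.n_elem) = v1;
  v1b(v1.n_elem) = 1.0;
  arma::vec v2 = arma::tanh(a * (W2.t() * v1b));
  arma::vec v2b(v2.n_elem + 1);
  v2b.head(v2.n_elem) = v2;
  v2b(v2.n_elem) = 1.0;
  double y = std::tanh(a * arma::as_scalar(W3.t() * v2b));
  if (h1) *h1 = v1;
  if (h2) *h2 = v2;
  return y;
}

// gradient of the squared error e = (y - t)^2 w.r.t. all weight blocks
static double grad_core(const arma::vec& x, double target,
                        const arma::mat& W1, const arma::mat& W2,
                        const arma::mat& W3, double a,
                        arma::mat& dW1, arma::mat& dW2, arma::mat& dW3) {
  arma::vec h1, h2;
  double y = forward_core(x, W1, W2, W3, a, &h1, &h2);
  double err = y - target;
  double d3 = 2.0 * err * a * (1.0 - y * y);        // de/dz3
  arma::vec h2b(h2.n_elem + 1);
  h2b.head(h2.n_elem) = h2;
  h2b(h2.n_elem) = 1.0;
  dW3 = h2b * d3;
  arma::vec dh2 = W3.rows(0, h2.n_elem - 1) * d3;
  arma::vec d2 = dh2 % (a * (1.0 - h2 % h2));
  arma::vec h1b(h1.n_elem + 1);
  h1b.head(h1.n_elem) = h1;
  h1b(h1.n_elem) = 1.0;
  dW2 = h1b * d2.t();
  arma::vec dh1 = W2.rows(0, h1.n_elem - 1) * d2;
  arma::vec d1 = dh1 % (a * (1.0 - h1 % h1));
  arma::vec xb(x.n_elem + 1);
  xb.head(x.n_elem) = x;
  xb(x.n_elem) = 1.0;
  dW1 = xb * d1.t();
  return err * err;
}

// [[Rcpp::export]]
arma::vec nn_forward_cpp(const arma::mat& X, const arma::mat& W1,
                         const arma::mat& W2, const arma::mat& W3, double a) {
  arma::vec out(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    out(i) = forward_core(X.row(i).t(), W1, W2, W3, a);
  return out;
}

// [[Rcpp::export]]
List nn_gradient_cpp(const arma::vec& x, double target, const arma::mat& W1,
                     const arma::mat& W2, const arma::mat& W3, double a) {
  arma::mat dW1, dW2, dW3;
  double e2 = grad_core(x, target, W1, W2, W3, a, dW1, dW2, dW3);
  return List::create(_["dW1"] = dW1, _["dW2"] = dW2, _["dW3"] = dW3,
                      _["sq_error"] = e2);
}

// single per-sample update with momentum: dw = -mu * grad + P * dw_prev
// [[Rcpp::export]]
List nn_step_cpp(const arma::vec& x, double target, const arma::mat& W1,
                 const arma::mat& W2, const arma::mat& W3,
                 const arma::mat& V1, const arma::mat& V2,
                 const arma::mat& V3, double a, double mu, double momentum) {
  arma::mat dW1, dW2, dW3;
  double e2 = grad_core(x, target, W1, W2, W3, a, dW1, dW2, dW3);
  if (!dW1.is_finite() || !dW2.is_finite() || !dW3.is_finite())
    stop("non-finite gradient encountered");
  arma::mat nV1 = -mu * dW1 + momentum * V1;
  arma::mat nV2 = -mu * dW2 + momentum * V2;
  arma::mat nV3 = -mu * dW3 + momentum * V3;
  return List::create(_["W1"] = W1 + nV1, _["W2"] = W2 + nV2,
                      _["W3"] = W3 + nV3, _["V1"] = nV1, _["V2"] = nV2,
                      _["V3"] = nV3, _["sq_error"] = e2);
}

static double sse_set(const arma::mat& X, const arma::vec& y,
                      const arma::uvec& idx, const arma::mat& W1,
                      const arma::mat& W2, const arma::mat& W3, double a) {
  double s = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    double p = forward_core(X.row(idx(k)).t(), W1, W2, W3, a);
    double e = p - y(idx(k));
    s += e * e;
  }
  return s;
}

// full training loop: per-sample (or per-epoch batch) steepest descent with
// momentum, per-epoch reshuffling via R's RNG, best-so-far weight selection
// on the overfit-protection set, patience-based stopping
// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::uvec& train_idx, const arma::uvec& over_idx,
                  arma::mat W1, arma::mat W2, arma::mat W3,
                  double a, double mu, double momentum,
                  int n_max, int n_stop, bool batch) {
  arma::mat V1(arma::size(W1), arma::fill::zeros);
  arma::mat V2(arma::size(W2), arma::fill::zeros);
  arma::mat V3(arma::size(W3), arma::fill::zeros);
  // candidates for best-so-far selection start at the epoch-1 snapshot;
  // the untrained initial weights are never returned
  arma::mat bW1, bW2, bW3;
  double best = arma::datum::inf;
  int best_epoch = 0, stale = 0;
  std::vector<double> hist_train, hist_over;
  const int nt = train_idx.n_elem;
  arma::mat dW1, dW2, dW3, aW1, aW2, aW3;

  for (int epoch = 1; epoch <= n_max; ++epoch) {
    // fresh seeded shuffle of the sample order each epoch (R RNG)
    IntegerVector ord = Rcpp::sample(nt, nt, false) - 1;
    double train_sse = 0.0;
    if (batch) {
      aW1.zeros(arma::size(W1));
      aW2.zeros(arma::size(W2));
      aW3.zeros(arma::size(W3));
      for (int k = 0; k < nt; ++k) {
        arma::uword i = train_idx(ord[k]);
        train_sse += grad_core(X.row(i).t(), y(i), W1, W2, W3, a,
                               dW1, dW2, dW3);
        aW1 += dW1; aW2 += dW2; aW3 += dW3;
      }
      V1 = -mu * aW1 + momentum * V1;
      V2 = -mu * aW2 + momentum * V2;
      V3 = -mu * aW3 + momentum * V3;
      W1 += V1; W2 += V2; W3 += V3;
    } else {
      for (int k = 0; k < nt; ++k) {
        arma::uword i = train_idx(ord[k]);
        train_sse += grad_core(X.row(i).t(), y(i), W1, W2, W3, a,
                               dW1, dW2, dW3);
        V1 = -mu * dW1 + momentum * V1;
        V2 = -mu * dW2 + momentum * V2;
        V3 = -mu * dW3 + momentum * V3;
        W1 += V1; W2 += V2; W3 += V3;
      }
    }
    if (!W1.is_finite() || !W2.is_finite() || !W3.is_finite())
      stop("non-finite weights at epoch %d (diverged)", epoch);
    double over_sse = sse_set(X, y, over_idx, W1, W2, W3, a);
    hist_train.push_back(train_sse);
    hist_over.push_back(over_sse);
    if (over_sse < best) {
      best = over_sse;
      bW1 = W1; bW2 = W2; bW3 = W3;
      best_epoch = epoch;
      stale = 0;
    } else if (++stale >= n_stop) break;
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["W1"] = bW1, _["W2"] = bW2, _["W3"] = bW3,
                      _["best_overfit_sse"] = best,
                      _["best_epoch"] = best_epoch,
                      _["train_sse"] = hist_train,
                      _["overfit_sse"] = hist_over);
}
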