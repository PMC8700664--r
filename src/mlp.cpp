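// Multilayer perceptron core: forward pass, backprop, and the three
// training methods (batch gradient descent, conjugate gradient with
// Powell-Beale restarts, random-order incremental updates).  Kept in
// C++ because the wavelength-selection and structure-tuning
// metaheuristics train thousands of small networks per run.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// transfer ids: 0 logsig, 1 radbas, 2 satlins, 3 hardlim,
//               4 tribas, 5 netinv, 6 tansig, 7 purelin
static const double NETINV_EPS = 1e-12;

static arma::mat tf_apply(const int id, const arma::mat& x) {
  switch (id) {
  case 0: return 1.0 / (1.0 + arma::exp(-x));
  case 1: return arma::exp(-arma::square(x));
  case 2: return arma::clamp(x, -1.0, 1.0);
  case 3: return arma::conv_to<arma::mat>::from(x >= 0.0);
  case 4: { arma::mat r = 1.0 - arma::abs(x); r.elem(arma::find(r < 0.0)).zeros(); return r; }
  case 5: { // netinv, guarded at 0: sign-preserving 1/eps
    arma::mat r = x;
    r.transform([](double v) {
      if (std::abs(v) < NETINV_EPS) return (v < 0.0 ? -1.0 : 1.0) / NETINV_EPS;
      return 1.0 / v;
    });
    return r;
  }
  case 6: return arma::tanh(x);
  case 7: return x;
  default: stop("unknown transfer id");
  }
}

// derivative w.r.t. the pre-activation z
static arma::mat tf_deriv(const int id, const arma::mat& x) {
  switch (id) {
  case 0: { arma::mat s = 1.0 / (1.0 + arma::exp(-x)); return s % (1.0 - s); }
  case 1: return -2.0 * x % arma::exp(-arma::square(x));
  case 2: { arma::mat r = x; r.transform([](double v) { return (v > -1.0 && v < 1.0) ? 1.0 : 0.0; }); return r; }
  case 3: return arma::zeros<arma::mat>(x.n_rows, x.n_cols);
  case 4: { arma::mat r = x; r.transform([](double v) {
      if (v > -1.0 && v < 0.0) return 1.0;
      if (v >= 0.0 && v < 1.0) return -1.0;
      return 0.0; }); return r; }
  case 5: { arma::mat r = x; r.transform([](double v) {
      double d = std::max(v * v, NETINV_EPS * NETINV_EPS);
      return -1.0 / d; }); return r; }
  case 6: { arma::mat t = arma::tanh(x); return 1.0 - arma::square(t); }
  case 7: return arma::ones<arma::mat>(x.n_rows, x.n_cols);
  default: stop("unknown transfer id");
  }
}

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  std::vector<int> tf;
};

static Net net_from_r(const List& W_, const List& b_, const IntegerVector& tf_) {
  Net net;
  const int L = W_.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(W_[l]));
    net.b.push_back(as<arma::rowvec>(b_[l]));
    net.tf.push_back(tf_[l]);
  }
  return net;
}

static arma::mat forward(const Net& net, const arma::mat& X,
                         std::vector<arma::mat>* Z = nullptr,
                         std::vector<arma::mat>* A = nullptr) {
  arma::mat a = X;
  if (A) A->push_back(a);
  for (size_t l = 0; l < net.W.size(); ++l) {
    arma::mat z = a * net.W[l];
    z.each_row() += net.b[l];
    a = tf_apply(net.tf[l], z);
    if (Z) Z->push_back(z);
    if (A) A->push_back(a);
  }
  return a;
}

static double mse_of(const Net& net, const arma::mat& X, const arma::mat& Y) {
  arma::mat P = forward(net, X);
  return arma::accu(arma::square(P - Y)) / (double)(Y.n_rows * Y.n_cols);
}

// batch gradient of the mean-squared error; returns loss
static double gradient(const Net& net, const arma::mat& X, const arma::mat& Y,
                       std::vector<arma::mat>& gW, std::vector<arma::rowvec>& gb) {
  std::vector<arma::mat> Z, A;
  forward(net, X, &Z, &A);
  const size_t L = net.W.size();
  const double nm = (double)(Y.n_rows * Y.n_cols);
  arma::mat delta = (2.0 / nm) * (A[L] - Y) % tf_deriv(net.tf[L - 1], Z[L - 1]);
  gW.assign(L, arma::mat());
  gb.assign(L, arma::rowvec());
  for (int l = (int)L - 1; l >= 0; --l) {
    gW[l] = A[l].t() * delta;
    gb[l] = arma::sum(delta, 0);
    if (l > 0)
      delta = (delta * net.W[l].t()) % tf_deriv(net.tf[l - 1], Z[l - 1]);
  }
  return arma::accu(arma::square(A[L] - Y)) / nm;
}

static arma::vec pack(const std::vector<arma::mat>& W, const std::vector<arma::rowvec>& b) {
  size_t n = 0;
  for (size_t l = 0; l < W.size(); ++l) n += W[l].n_elem + b[l].n_elem;
  arma::vec v(n);
  size_t k = 0;
  for (size_t l = 0; l < W.size(); ++l) {
    for (size_t i = 0; i < W[l].n_elem; ++i) v[k++] = W[l](i);
    for (size_t i = 0; i < b[l].n_elem; ++i) v[k++] = b[l](i);
  }
  return v;
}

static void unpack(const arma::vec& v, Net& net) {
  size_t k = 0;
  for (size_t l = 0; l < net.W.size(); ++l) {
    for (size_t i = 0; i < net.W[l].n_elem; ++i) net.W[l](i) = v[k++];
    for (size_t i = 0; i < net.b[l].n_elem; ++i) net.b[l](i) = v[k++];
  }
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_mlp_forward(List W_, List b_, IntegerVector tf_, NumericMatrix X_) {
  Net net = net_from_r(W_, b_, tf_);
  arma::mat X = as<arma::mat>(X_);
  return wrap(forward(net, X));
}

// Training driver.  method: 0 traingd, 1 traincgb, 2 trains.
// learn: 0 plain delta rule, 1 learnh (Hebbian-with-decay extra term),
//        2 learnsom (activation-weighted update) -- both only under trains.
// [[Rcpp::export(rng = false)]]
List cpp_mlp_train(List W_, List b_, IntegerVector tf_,
                   NumericMatrix X_, NumericMatrix Y_,
                   NumericMatrix Xval_, NumericMatrix Yval_,
                   int method, int learn, int max_epochs,
                   double lr, int patience, int seed) {
  Net net = net_from_r(W_, b_, tf_);
  arma::mat X = as<arma::mat>(X_), Y = as<arma::mat>(Y_);
  arma::mat Xv = as<arma::mat>(Xval_), Yv = as<arma::mat>(Yval_);
  const bool has_val = Xv.n_rows > 0;
  const size_t L = net.W.size();
  const arma::uword n = X.n_rows;

  std::vector<double> tr_hist, val_hist;
  std::string stop_reason = "max_epochs";
  int best_epoch = 0;

  // monitor = validation MSE when a validation set is given, else train MSE
  Net best = net;
  double best_mon = has_val ? mse_of(net, Xv, Yv) : mse_of(net, X, Y);
  int since_best = 0;

  std::mt19937 gen((unsigned)seed);
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  // conjugate-gradient state
  arma::vec g_old, d;
  double alpha_prev = 1.0;

  const double hebb = 1e-3 * lr, decay = 1e-4 * lr;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    double tr_mse = NA_REAL;
    if (method == 0) { // traingd: batch gradient descent
      std::vector<arma::mat> gW; std::vector<arma::rowvec> gb;
      tr_mse = gradient(net, X, Y, gW, gb);
      for (size_t l = 0; l < L; ++l) { net.W[l] -= lr * gW[l]; net.b[l] -= lr * gb[l]; }
    } else if (method == 1) { // traincgb: CG with Powell-Beale restarts
      std::vector<arma::mat> gW; std::vector<arma::rowvec> gb;
      tr_mse = gradient(net, X, Y, gW, gb);
      arma::vec g = pack(gW, gb);
      if (epoch == 1 || arma::dot(g, g_old) >= 0.2 * arma::dot(g, g)) {
        d = -g; // restart (Powell condition or first iteration)
      } else {
        double denom = arma::dot(g_old, g_old);
        double beta = denom > 0 ? std::max(0.0, arma::dot(g, g - g_old) / denom) : 0.0;
        d = -g + beta * d;
      }
      double slope = arma::dot(g, d);
      if (slope >= 0) { d = -g; slope = arma::dot(g, d); }
      arma::vec w0 = pack(net.W, net.b);
      double alpha = std::min(1.0, 2.0 * alpha_prev);
      double f0 = tr_mse, fnew = f0;
      bool ok = false;
      for (int t = 0; t < 25; ++t) {
        unpack(w0 + alpha * d, net);
        fnew = mse_of(net, X, Y);
        if (std::isfinite(fnew) && fnew <= f0 + 1e-4 * alpha * slope) { ok = true; break; }
        alpha *= 0.5;
      }
      if (!ok) { unpack(w0, net); stop_reason = "line_search_failed"; break; }
      alpha_prev = alpha;
      g_old = g;
    } else { // trains: random-order incremental updates (hot path for the
             // metaheuristics: buffers reused across samples)
      static thread_local std::vector<arma::rowvec> zb, ab, db_;
      if (zb.size() != L) { zb.assign(L, arma::rowvec()); db_.assign(L, arma::rowvec()); }
      if (ab.size() != L + 1) ab.assign(L + 1, arma::rowvec());
      for (arma::uword i = n; i > 1; --i) { // Fisher-Yates, own bounded draw
        arma::uword j = (arma::uword)(gen() % i);
        std::swap(order[i - 1], order[j]);
      }
      for (arma::uword ii = 0; ii < n; ++ii) {
        const arma::uword r = order[ii];
        ab[0] = X.row(r);
        for (size_t l = 0; l < L; ++l) {
          zb[l] = ab[l] * net.W[l] + net.b[l];
          ab[l + 1] = tf_apply(net.tf[l], zb[l]);
        }
        db_[L - 1] = 2.0 * (ab[L] - Y.row(r)) % tf_deriv(net.tf[L - 1], zb[L - 1]);
        for (int l = (int)L - 2; l >= 0; --l) {
          db_[l] = (db_[l + 1] * net.W[l + 1].t()) % tf_deriv(net.tf[l], zb[l]);
        }
        for (int l = (int)L - 1; l >= 0; --l) {
          arma::rowvec upd = db_[l];
          if (learn == 2) { // learnsom approx: winner-emphasized scaling
            arma::rowvec a2 = arma::square(ab[l + 1]);
            double m = a2.max();
            if (m > 0) upd %= a2 / m;
          }
          net.W[l] -= lr * (ab[l].t() * upd);
          net.b[l] -= lr * upd;
          if (learn == 1) { // learnh: Hebbian-with-decay extra term
            net.W[l] += hebb * (ab[l].t() * ab[l + 1]) - decay * net.W[l];
          }
        }
      }
      tr_mse = mse_of(net, X, Y);
    }

    if (method != 1) tr_mse = mse_of(net, X, Y);
    tr_hist.push_back(tr_mse);
    double mon = tr_mse;
    if (has_val) { double v = mse_of(net, Xv, Yv); val_hist.push_back(v); mon = v; }
    if (!std::isfinite(tr_mse) || (has_val && !std::isfinite(mon))) {
      stop_reason = "nonfinite_loss@" + std::to_string(epoch);
      break;
    }
    if (mon < best_mon - 1e-15) {
      best_mon = mon; best = net; best_epoch = epoch; since_best = 0;
    } else if (++since_best >= patience) {
      stop_reason = "early_stop";
      break;
    }
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = best.W[l]; bout[l] = best.b[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_mse"] = tr_hist, _["val_mse"] = val_hist,
                      _["best_epoch"] = best_epoch,
                      _["best_monitor"] = best_mon,
                      _["stop_reason"] = stop_reason);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_transfer(int id, NumericVector x) {
  arma::mat m(x.begin(), x.size(), 1, false);
  arma::mat r = tf_apply(id, m);
  return NumericVector(r.begin(), r.end());
}
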