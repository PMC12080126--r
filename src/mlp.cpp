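// Feed-forward multilabel classifier: ReLU hidden layers, logistic
// outputs, binary cross-entropy loss, Adam updates, inverted dropout on
// the first and last hidden layers, and per-epoch checkpointing on the
// mean per-site Matthews correlation of a validation split.
//
// All randomness (init, shuffling, dropout) flows from one mt19937_64
// generator seeded from R, so a fixed seed reproduces training exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

static mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Mean per-column MCC of binarised probabilities against 0/1 truth;
// columns whose truth is single-class are skipped (undefined MCC).
static double mean_mcc(const mat& prob, const mat& y) {
  double acc = 0.0;
  int defined = 0;
  for (uword s = 0; s < y.n_cols; ++s) {
    double tp = 0, tn = 0, fp = 0, fn = 0;
    for (uword i = 0; i < y.n_rows; ++i) {
      bool h = prob(i, s) >= 0.5, t = y(i, s) >= 0.5;
      if (t && h) ++tp; else if (!t && !h) ++tn;
      else if (!t && h) ++fp; else ++fn;
    }
    if (tp + fn == 0 || tn + fp == 0) continue;  // single-class truth
    double den = std::sqrt((tp + fp) * (tp + fn)) *
                 std::sqrt((tn + fp) * (tn + fn));
    acc += (den == 0) ? 0.0 : (tp * tn - fp * fn) / den;
    ++defined;
  }
  return defined > 0 ? acc / defined : NA_REAL;
}

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
};

static mat forward(const Net& net, const mat& x) {
  mat a = x;
  size_t L = net.W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    a = a * net.W[l];
    a.each_row() += net.b[l].t();
    a.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  mat z = a * net.W[L - 1];
  z.each_row() += net.b[L - 1].t();
  return sigmoid(z);
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& x, const arma::mat& y,
                         const arma::mat& xval, const arma::mat& yval,
                         Rcpp::IntegerVector hidden, double dropout,
                         double lr, int epochs, int batch_size,
                         int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const uword n = x.n_rows, d = x.n_cols, k = y.n_cols;
  std::vector<uword> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(static_cast<uword>(h));
  sizes.push_back(k);
  const size_t L = sizes.size() - 1;   // number of weight layers

  Net net;
  for (size_t l = 0; l < L; ++l) {
    mat w(sizes[l], sizes[l + 1]);
    double sd = std::sqrt(2.0 / sizes[l]);  // He init for ReLU stacks
    for (uword i = 0; i < w.n_elem; ++i) w(i) = gauss(rng) * sd;
    net.W.push_back(w);
    net.b.push_back(vec(sizes[l + 1], fill::zeros));
  }

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mB(L), vB(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = zeros<mat>(size(net.W[l])); vW[l] = mW[l];
    mB[l] = zeros<vec>(net.b[l].n_elem); vB[l] = mB[l];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  Net best = net;
  double best_mcc = -2.0;
  int best_epoch = 0;
  Rcpp::NumericVector val_trace(epochs), loss_trace(epochs);

  const size_t n_hidden = L - 1;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    uword done = 0;
    while (done < n) {
      uword bs = std::min<uword>(batch_size, n - done);
      uvec idx(bs);
      for (uword i = 0; i < bs; ++i) idx(i) = order[done + i];
      done += bs;
      mat xb = x.rows(idx), yb = y.rows(idx);

      // forward with dropout on first and last hidden layers
      std::vector<mat> act(L + 1);
      std::vector<mat> mask(L, mat());
      act[0] = xb;
      for (size_t l = 0; l < L; ++l) {
        mat z = act[l] * net.W[l];
        z.each_row() += net.b[l].t();
        if (l + 1 < L) {
          z.transform([](double v) { return v > 0 ? v : 0.0; });
          bool drop_here = dropout > 0 &&
            (l == 0 || l == n_hidden - 1) && n_hidden > 0;
          if (drop_here) {
            mat m(size(z));
            for (uword i = 0; i < m.n_elem; ++i)
              m(i) = unif(rng) >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
            z %= m;
            mask[l] = m;
          }
          act[l + 1] = z;
        } else {
          act[l + 1] = sigmoid(z);
        }
      }
      mat p = clamp(act[L], 1e-7, 1.0 - 1e-7);
      ep_loss -= accu(yb % log(p) + (1.0 - yb) % log(1.0 - p));

      // backward: d(BCE)/dz_out = p - y
      mat delta = (act[L] - yb) / static_cast<double>(bs);
      for (size_t l = L; l-- > 0;) {
        mat gW = act[l].t() * delta;
        vec gB = sum(delta, 0).t();
        if (l > 0) {
          delta = delta * net.W[l].t();
          delta %= conv_to<mat>::from(act[l] > 0);
          if (mask[l - 1].n_elem > 0) delta %= mask[l - 1];
        }
        ++step;
        double corr = lr * std::sqrt(1 - std::pow(b2, step)) /
                      (1 - std::pow(b1, step));
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * square(gW);
        net.W[l] -= corr * mW[l] / (sqrt(vW[l]) + eps);
        mB[l] = b1 * mB[l] + (1 - b1) * gB;
        vB[l] = b2 * vB[l] + (1 - b2) * square(gB);
        net.b[l] -= corr * mB[l] / (sqrt(vB[l]) + eps);
      }
    }
    loss_trace[ep] = ep_loss / (n * k);

    double vm = mean_mcc(forward(net, xval), yval);
    val_trace[ep] = vm;
    if (!ISNAN(vm) && vm > best_mcc) {
      best_mcc = vm;
      best = net;
      best_epoch = ep + 1;
    }
  }
  if (best_mcc <= -2.0) { best = net; best_epoch = epochs; }

  Rcpp::List Ws(L), bs_(L);
  for (size_t l = 0; l < L; ++l) {
    Ws[l] = best.W[l];
    bs_[l] = best.b[l];
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Ws, Rcpp::Named("biases") = bs_,
    Rcpp::Named("val_mcc") = val_trace,
    Rcpp::Named("train_loss") = loss_trace,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_mcc") = best_mcc);
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(Rcpp::List weights, Rcpp::List biases,
                          const arma::mat& x) {
  Net net;
  for (int l = 0; l < weights.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(weights[l]));
    net.b.push_back(Rcpp::as<vec>(biases[l]));
  }
  return forward(net, x);
}
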