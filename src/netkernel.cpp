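// Compiled training kernel for the three-layer prognostic network.
//
// Implements the same mathematics as the R reference functions
// (net_forward / net_loss_grads): hidden blocks of affine -> batch
// normalization (population batch statistics) -> activation -> inverted
// dropout, a final affine + sigmoid output, class-weighted binary
// cross-entropy, and per-tensor Adam. All randomness (shuffling, dropout
// masks) is drawn from R's RNG so training is reproducible under
// set.seed(). The R and C++ paths are cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Layer {
  arma::mat W;
  arma::rowvec b;        // empty for hidden layers under batch norm
  arma::rowvec gamma, beta, run_mean, run_var;
  bool has_b = false, has_bn = false;
};

struct LayerCache {
  arma::mat A_in, Y, H, Zh, M;
  arma::rowvec inv_sd;
  bool has_mask = false;
};

static std::vector<Layer> read_layers(const List& layers) {
  std::vector<Layer> out(layers.size());
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    out[l].W = as<arma::mat>(ly["W"]);
    if (ly.containsElementNamed("b")) {
      out[l].b = as<arma::rowvec>(ly["b"]);
      out[l].has_b = true;
    }
    if (ly.containsElementNamed("gamma")) {
      out[l].gamma = as<arma::rowvec>(ly["gamma"]);
      out[l].beta = as<arma::rowvec>(ly["beta"]);
      out[l].run_mean = as<arma::rowvec>(ly["run_mean"]);
      out[l].run_var = as<arma::rowvec>(ly["run_var"]);
      out[l].has_bn = true;
    }
  }
  return out;
}

static List write_layers(const std::vector<Layer>& layers) {
  List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    List ly = List::create(Named("W") = layers[l].W);
    if (layers[l].has_b) ly["b"] = NumericVector(layers[l].b.begin(), layers[l].b.end());
    if (layers[l].has_bn) {
      ly["gamma"] = NumericVector(layers[l].gamma.begin(), layers[l].gamma.end());
      ly["beta"] = NumericVector(layers[l].beta.begin(), layers[l].beta.end());
      ly["run_mean"] = NumericVector(layers[l].run_mean.begin(), layers[l].run_mean.end());
      ly["run_var"] = NumericVector(layers[l].run_var.begin(), layers[l].run_var.end());
    }
    out[l] = ly;
  }
  return out;
}

static inline arma::mat act_f(const arma::mat& Y, bool sigmoid_act) {
  if (sigmoid_act) return 1.0 / (1.0 + arma::exp(-Y));
  return arma::clamp(Y, 0.0, arma::datum::inf);
}

static inline arma::mat act_df(const arma::mat& Y, const arma::mat& H,
                               bool sigmoid_act) {
  if (sigmoid_act) return H % (1.0 - H);
  return arma::conv_to<arma::mat>::from(Y > 0.0);
}

// Training-mode forward pass caching what backprop needs. When
// fixed_masks is non-null its matrices are used as dropout masks
// (gradient-check support); otherwise masks are drawn from R's RNG.
static arma::vec forward_train(std::vector<Layer>& layers, const arma::mat& X,
                               bool sigmoid_act, double dropout,
                               bool update_running,
                               const List* fixed_masks,
                               std::vector<LayerCache>& cache) {
  size_t nh = layers.size() - 1;
  arma::mat A = X;
  double m = (double)X.n_rows;
  for (size_t l = 0; l < nh; ++l) {
    Layer& ly = layers[l];
    arma::mat Z = A * ly.W;
    if (ly.has_b) Z.each_row() += ly.b;
    arma::mat Y;
    if (ly.has_bn) {
      arma::rowvec mu = arma::mean(Z, 0);
      arma::mat Zc = Z.each_row() - mu;
      arma::rowvec v = arma::mean(Zc % Zc, 0);   // population variance
      if (update_running) {
        ly.run_mean = (1.0 - BN_MOMENTUM) * ly.run_mean + BN_MOMENTUM * mu;
        ly.run_var = (1.0 - BN_MOMENTUM) * ly.run_var + BN_MOMENTUM * v;
      }
      cache[l].inv_sd = 1.0 / arma::sqrt(v + BN_EPS);
      cache[l].Zh = Zc.each_row() % cache[l].inv_sd;
      Y = cache[l].Zh.each_row() % ly.gamma;
      Y.each_row() += ly.beta;
    } else {
      Y = Z;
    }
    arma::mat H = act_f(Y, sigmoid_act);
    cache[l].A_in = A;
    cache[l].Y = Y;
    cache[l].H = H;
    if (fixed_masks != nullptr && !Rf_isNull((*fixed_masks)[l])) {
      cache[l].M = as<arma::mat>((*fixed_masks)[l]);
      cache[l].has_mask = true;
      A = H % cache[l].M;
    } else if (dropout > 0.0) {
      double keep = 1.0 - dropout;
      arma::mat M(H.n_rows, H.n_cols);
      // column-major fill matches the R reference's matrix(runif(m*d), m)
      for (arma::uword j = 0; j < M.n_cols; ++j)
        for (arma::uword i = 0; i < M.n_rows; ++i)
          M(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      cache[l].M = M;
      cache[l].has_mask = true;
      A = H % M;
    } else {
      cache[l].has_mask = false;
      A = H;
    }
  }
  Layer& out = layers[nh];
  arma::mat Zo = A * out.W;
  Zo.each_row() += out.b;
  cache[nh].A_in = A;  // store last activation in the output slot
  (void)m;
  return 1.0 / (1.0 + arma::exp(-Zo.col(0)));
}

struct Grads {
  arma::mat W;
  arma::rowvec b, gamma, beta;
};

// Backpropagation of the class-weighted binary cross-entropy. Returns the
// mean weighted loss; fills grads (same shapes as the trainable tensors).
static double backward(std::vector<Layer>& layers,
                       const std::vector<LayerCache>& cache,
                       const arma::vec& p, const arma::vec& y,
                       double w_pos, double w_neg, bool sigmoid_act,
                       std::vector<Grads>& grads) {
  size_t nh = layers.size() - 1;
  double m = (double)y.n_elem;
  arma::vec s = w_pos * y + w_neg * (1.0 - y);
  arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = arma::mean(-(w_pos * (y % arma::log(pc)) +
                             w_neg * ((1.0 - y) % arma::log(1.0 - pc))));
  arma::mat dZo = (s % (p - y)) / m;          // column vector as matrix
  grads[nh].W = cache[nh].A_in.t() * dZo;
  grads[nh].b = arma::sum(dZo, 0);
  arma::mat dA = dZo * layers[nh].W.t();

  for (int l = (int)nh - 1; l >= 0; --l) {
    const LayerCache& cc = cache[l];
    Layer& ly = layers[l];
    arma::mat dH = cc.has_mask ? arma::mat(dA % cc.M) : dA;
    arma::mat dY = dH % act_df(cc.Y, cc.H, sigmoid_act);
    arma::mat dZ;
    if (ly.has_bn) {
      grads[l].gamma = arma::sum(dY % cc.Zh, 0);
      grads[l].beta = arma::sum(dY, 0);
      arma::mat dZh = dY.each_row() % ly.gamma;
      arma::rowvec sum_dZh = arma::sum(dZh, 0);
      arma::rowvec sum_dZh_Zh = arma::sum(dZh % cc.Zh, 0);
      double mb = (double)dY.n_rows;
      dZ = mb * dZh;
      dZ.each_row() -= sum_dZh;
      dZ -= cc.Zh.each_row() % sum_dZh_Zh;
      dZ.each_row() %= (cc.inv_sd / mb);
    } else {
      dZ = dY;
      grads[l].b = arma::sum(dZ, 0);
    }
    grads[l].W = cc.A_in.t() * dZ;
    if (l > 0) dA = dZ * ly.W.t();
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_loss_grads(List layers_in, const arma::mat& X, const arma::vec& y,
                    double w_pos, double w_neg, bool sigmoid_act,
                    double dropout, Nullable<List> fixed_masks) {
  std::vector<Layer> layers = read_layers(layers_in);
  std::vector<LayerCache> cache(layers.size());
  List fm;
  const List* fmp = nullptr;
  if (fixed_masks.isNotNull()) { fm = fixed_masks.get(); fmp = &fm; }
  arma::vec p = forward_train(layers, X, sigmoid_act, dropout, false, fmp, cache);
  std::vector<Grads> grads(layers.size());
  double loss = backward(layers, cache, p, y, w_pos, w_neg, sigmoid_act, grads);
  size_t nh = layers.size() - 1;
  List gout(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    List g = List::create(Named("W") = grads[l].W);
    if (l == nh || !layers[l].has_bn)
      g["b"] = NumericVector(grads[l].b.begin(), grads[l].b.end());
    if (layers[l].has_bn) {
      g["gamma"] = NumericVector(grads[l].gamma.begin(), grads[l].gamma.end());
      g["beta"] = NumericVector(grads[l].beta.begin(), grads[l].beta.end());
    }
    gout[l] = g;
  }
  return List::create(Named("loss") = loss, Named("grads") = gout,
                      Named("p") = NumericVector(p.begin(), p.end()));
}

// [[Rcpp::export]]
arma::vec cpp_predict(List layers_in, const arma::mat& X, bool sigmoid_act) {
  std::vector<Layer> layers = read_layers(layers_in);
  size_t nh = layers.size() - 1;
  arma::mat A = X;
  for (size_t l = 0; l < nh; ++l) {
    Layer& ly = layers[l];
    arma::mat Z = A * ly.W;
    if (ly.has_b) Z.each_row() += ly.b;
    arma::mat Y;
    if (ly.has_bn) {
      arma::mat Zc = Z.each_row() - ly.run_mean;
      arma::rowvec inv_sd = 1.0 / arma::sqrt(ly.run_var + BN_EPS);
      Y = Zc.each_row() % (inv_sd % ly.gamma);
      Y.each_row() += ly.beta;
    } else {
      Y = Z;
    }
    A = act_f(Y, sigmoid_act);
  }
  arma::mat Zo = A * layers[nh].W;
  Zo.each_row() += layers[nh].b;
  return 1.0 / (1.0 + arma::exp(-Zo.col(0)));
}

struct AdamState {
  arma::mat mW, vW;
  arma::rowvec mb, vb, mg, vg, mbe, vbe;
};

static inline void adam_update(arma::mat& theta, const arma::mat& g,
                               arma::mat& m, arma::mat& v,
                               double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  theta -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

static inline void adam_update_row(arma::rowvec& theta, const arma::rowvec& g,
                                   arma::rowvec& m, arma::rowvec& v,
                                   double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  theta -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

// [[Rcpp::export]]
List cpp_train(List layers_in, const arma::mat& X, const arma::vec& y,
               int epochs, int batch_size, double lr, double dropout,
               bool sigmoid_act, double w_pos, double w_neg) {
  RNGScope rngscope;
  std::vector<Layer> layers = read_layers(layers_in);
  size_t nl = layers.size(), nh = nl - 1;
  int n = (int)X.n_rows;
  int bs = std::min(batch_size, n);

  std::vector<AdamState> state(nl);
  for (size_t l = 0; l < nl; ++l) {
    state[l].mW.zeros(layers[l].W.n_rows, layers[l].W.n_cols);
    state[l].vW.zeros(layers[l].W.n_rows, layers[l].W.n_cols);
    if (layers[l].has_b) {
      state[l].mb.zeros(layers[l].b.n_elem);
      state[l].vb.zeros(layers[l].b.n_elem);
    }
    if (layers[l].has_bn) {
      state[l].mg.zeros(layers[l].gamma.n_elem);
      state[l].vg.zeros(layers[l].gamma.n_elem);
      state[l].mbe.zeros(layers[l].beta.n_elem);
      state[l].vbe.zeros(layers[l].beta.n_elem);
    }
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  NumericVector epoch_loss(epochs);
  long tstep = 0;
  std::vector<LayerCache> cache(nl);
  std::vector<Grads> grads(nl);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    std::vector<int> starts;
    for (int s0 = 0; s0 < n; s0 += bs) starts.push_back(s0);
    // merge a trailing fragment of < 2 rows into the previous batch
    if (starts.size() > 1 && n - starts.back() < 2) starts.pop_back();

    double loss_sum = 0.0;
    for (size_t bi = 0; bi < starts.size(); ++bi) {
      int s0 = starts[bi];
      int s1 = (bi + 1 == starts.size()) ? n : starts[bi] + bs;
      arma::uvec idx(s1 - s0);
      for (int i = s0; i < s1; ++i) idx[i - s0] = (arma::uword)ord[i];
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);
      arma::vec p = forward_train(layers, Xb, sigmoid_act, dropout, true,
                                  nullptr, cache);
      double loss = backward(layers, cache, p, yb, w_pos, w_neg,
                             sigmoid_act, grads);
      ++tstep;
      double bc1 = 1.0 - std::pow(0.9, (double)tstep);
      double bc2 = 1.0 - std::pow(0.999, (double)tstep);
      for (size_t l = 0; l < nl; ++l) {
        adam_update(layers[l].W, grads[l].W, state[l].mW, state[l].vW,
                    lr, bc1, bc2);
        if (layers[l].has_b)
          adam_update_row(layers[l].b, grads[l].b, state[l].mb, state[l].vb,
                          lr, bc1, bc2);
        if (layers[l].has_bn) {
          adam_update_row(layers[l].gamma, grads[l].gamma, state[l].mg,
                          state[l].vg, lr, bc1, bc2);
          adam_update_row(layers[l].beta, grads[l].beta, state[l].mbe,
                          state[l].vbe, lr, bc1, bc2);
        }
      }
      loss_sum += loss;
    }
    epoch_loss[ep] = loss_sum / (double)starts.size();
  }
  (void)nh;
  return List::create(Named("layers") = write_layers(layers),
                      Named("epoch_loss") = epoch_loss);
}
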