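// Training / inference core for the hybrid GCN solubility regressor.
//
// The network: (optional) AFR channel gating of the L x C node-feature
// matrix, N graph-convolution layers over a degree-normalized contact
// adjacency, a tanh/softmax self-attention readout pooling residues into a
// fixed-size vector, and a sigmoid output head. The loss is the squared
// error per protein (full-batch gradient direction identical to RMSE);
// optimisation is Adam with per-protein steps.
//
// Everything here is mirrored by pure-R reference implementations in R/
// which the test suite uses as independent oracles.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

struct Pars {
  bool use_afr = false;
  mat V;                 // C x C AFR interaction kernels (row c' = filter c')
  vec bv;                // C AFR bias
  std::vector<mat> Wg;   // GCN layer weights d_in x d_out
  std::vector<vec> bg;   // GCN layer biases
  mat Wa;                // d x h_att (first readout FC)
  vec ba;                // h_att
  mat Ua;                // h_att x k (second readout FC, k heads)
  vec ca;                // k
  vec wo;                // k*d output weights
  double bo = 0.0;       // output bias
};

static Pars pars_from_list(const List& L, bool use_afr) {
  Pars p;
  p.use_afr = use_afr;
  if (use_afr) {
    p.V = as<mat>(L["V"]);
    p.bv = as<vec>(L["bv"]);
  }
  List Wg = L["Wg"], bg = L["bg"];
  for (int i = 0; i < Wg.size(); ++i) {
    p.Wg.push_back(as<mat>(Wg[i]));
    p.bg.push_back(as<vec>(bg[i]));
  }
  p.Wa = as<mat>(L["Wa"]);
  p.ba = as<vec>(L["ba"]);
  p.Ua = as<mat>(L["Ua"]);
  p.ca = as<vec>(L["ca"]);
  p.wo = as<vec>(L["wo"]);
  p.bo = as<double>(L["bo"]);
  return p;
}

static List pars_to_list(const Pars& p) {
  List Wg(p.Wg.size()), bg(p.bg.size());
  for (size_t i = 0; i < p.Wg.size(); ++i) {
    Wg[i] = p.Wg[i];
    bg[i] = p.bg[i];
  }
  List out = List::create(
      _["Wg"] = Wg, _["bg"] = bg, _["Wa"] = p.Wa, _["ba"] = p.ba,
      _["Ua"] = p.Ua, _["ca"] = p.ca, _["wo"] = p.wo, _["bo"] = p.bo);
  if (p.use_afr) {
    out["V"] = p.V;
    out["bv"] = p.bv;
  }
  return out;
}

struct Cache {
  rowvec G, O, Pnl, W;   // AFR intermediates (1 x C)
  mat X0;                // node features entering the GCN (post-AFR)
  std::vector<mat> Z, X, AX, Mask;
  mat U;                 // L x h_att
  mat Aatt;              // L x k softmax attention per head
  vec pooled;            // k*d
  double z = 0.0, s = 0.5;
};

static double relu_clamp_inf() { return arma::datum::inf; }

// Forward pass. When `rng` is non-null and dropout > 0, inverted dropout is
// applied to each GCN layer's post-ReLU activations (training mode).
static double hg_forward(const mat& H, const mat& A, const Pars& p, Cache& c,
                         double dropout, std::mt19937* rng) {
  const arma::uword L = H.n_rows;
  if (p.use_afr) {
    c.G = arma::mean(H, 0);
    c.O = (p.V * c.G.t()).t() + p.bv.t();
    c.Pnl = arma::clamp(c.O, 0.0, relu_clamp_inf());
    c.W = arma::clamp(1.0 / (1.0 + arma::exp(-c.Pnl)), 0.0,
                      1.0 - 2.220446049250313e-16);
    c.X0 = H.each_row() % c.W;
  } else {
    c.X0 = H;
  }
  c.Z.clear(); c.X.clear(); c.AX.clear(); c.Mask.clear();
  mat X = c.X0;
  const bool train_dropout = dropout > 0.0 && rng != nullptr;
  for (size_t l = 0; l < p.Wg.size(); ++l) {
    mat AX = A * X;
    mat Z = AX * p.Wg[l];
    Z.each_row() += p.bg[l].t();
    mat Xl = arma::clamp(Z, 0.0, relu_clamp_inf());
    if (train_dropout) {
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      mat M(Xl.n_rows, Xl.n_cols);
      for (arma::uword j = 0; j < M.n_elem; ++j)
        M(j) = (unif(*rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      Xl %= M;
      c.Mask.push_back(M);
    }
    c.AX.push_back(AX);
    c.Z.push_back(Z);
    c.X.push_back(Xl);
    X = Xl;
  }
  c.U = arma::tanh(X * p.Wa + arma::repmat(p.ba.t(), L, 1));
  mat E = c.U * p.Ua;
  E.each_row() += p.ca.t();
  const arma::uword k = E.n_cols, d = X.n_cols;
  c.Aatt.set_size(L, k);
  for (arma::uword h = 0; h < k; ++h) {
    vec e = E.col(h);
    vec ex = arma::exp(e - e.max());
    c.Aatt.col(h) = ex / arma::accu(ex);
  }
  c.pooled.set_size(k * d);
  for (arma::uword h = 0; h < k; ++h)
    c.pooled.subvec(h * d, (h + 1) * d - 1) = X.t() * c.Aatt.col(h);
  c.z = arma::dot(p.wo, c.pooled) + p.bo;
  c.s = 1.0 / (1.0 + std::exp(-c.z));
  return c.s;
}

struct Grads {
  mat V; vec bv;
  std::vector<mat> Wg; std::vector<vec> bg;
  mat Wa; vec ba; mat Ua; vec ca; vec wo; double bo = 0.0;
};

// Backpropagation of dL/ds through the cached forward pass.
static void hg_backward(const mat& H, const mat& A, const Pars& p,
                        const Cache& c, double dL_ds, Grads& g) {
  const double dz = dL_ds * c.s * (1.0 - c.s);
  const mat& XN = c.X.empty() ? c.X0 : c.X.back();
  const arma::uword d = XN.n_cols, L = XN.n_rows, k = c.Aatt.n_cols;

  g.wo = dz * c.pooled;
  g.bo = dz;
  vec dpooled = dz * p.wo;

  mat dXN(L, d, arma::fill::zeros);
  mat dE(L, k, arma::fill::zeros);
  for (arma::uword h = 0; h < k; ++h) {
    vec dph = dpooled.subvec(h * d, (h + 1) * d - 1);
    vec a = c.Aatt.col(h);
    vec da = XN * dph;
    dXN += a * dph.t();
    dE.col(h) = a % (da - arma::dot(a, da));
  }
  g.Ua = c.U.t() * dE;
  g.ca = arma::sum(dE, 0).t();
  mat dU = dE * p.Ua.t();
  mat dZa = dU % (1.0 - c.U % c.U);
  g.Wa = XN.t() * dZa;
  g.ba = arma::sum(dZa, 0).t();
  dXN += dZa * p.Wa.t();

  mat dX = dXN;
  g.Wg.resize(p.Wg.size());
  g.bg.resize(p.bg.size());
  for (int l = static_cast<int>(p.Wg.size()) - 1; l >= 0; --l) {
    if (!c.Mask.empty()) dX %= c.Mask[l];
    mat dZ = dX % arma::conv_to<mat>::from(c.Z[l] > 0.0);
    g.Wg[l] = c.AX[l].t() * dZ;
    g.bg[l] = arma::sum(dZ, 0).t();
    dX = A.t() * (dZ * p.Wg[l].t());
  }

  if (p.use_afr) {
    rowvec dW = arma::sum(dX % H, 0);
    rowvec dP = dW % c.W % (1.0 - c.W);
    rowvec dO = dP % arma::conv_to<rowvec>::from(c.O > 0.0);
    g.V = dO.t() * c.G;
    g.bv = dO.t();
  }
}

static void adam_mat(mat& th, const mat& g, mat& m, mat& v, double lr,
                     double b1, double b2, double eps, double t) {
  if (m.n_elem != g.n_elem) { m.zeros(arma::size(g)); v.zeros(arma::size(g)); }
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  th -= lr * (m / (1.0 - std::pow(b1, t))) /
        (arma::sqrt(v / (1.0 - std::pow(b2, t))) + eps);
}

static void adam_vec(vec& th, const vec& g, vec& m, vec& v, double lr,
                     double b1, double b2, double eps, double t) {
  if (m.n_elem != g.n_elem) { m.zeros(g.n_elem); v.zeros(g.n_elem); }
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  th -= lr * (m / (1.0 - std::pow(b1, t))) /
        (arma::sqrt(v / (1.0 - std::pow(b2, t))) + eps);
}

// [[Rcpp::export]]
List hg_forward_cpp(const arma::mat& H, const arma::mat& A, List par,
                    bool use_afr) {
  Pars p = pars_from_list(par, use_afr);
  Cache c;
  double s = hg_forward(H, A, p, c, 0.0, nullptr);
  vec att = arma::mean(c.Aatt, 1);
  List out = List::create(_["s_hat"] = s, _["attention"] = att,
                          _["pooled"] = c.pooled);
  if (use_afr) {
    out["W"] = c.W;
    out["G"] = c.G;
    out["O"] = c.O;
    out["P_nl"] = c.Pnl;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector hg_predict_cpp(List Hs, List As, List par, bool use_afr) {
  Pars p = pars_from_list(par, use_afr);
  const int n = Hs.size();
  NumericVector out(n);
  Cache c;
  for (int i = 0; i < n; ++i) {
    mat H = as<mat>(Hs[i]);
    mat A = as<mat>(As[i]);
    out[i] = hg_forward(H, A, p, c, 0.0, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat hg_afr_weights_cpp(List Hs, List par) {
  Pars p = pars_from_list(par, true);
  const int n = Hs.size();
  mat H0 = as<mat>(Hs[0]);
  mat out(n, H0.n_cols);
  for (int i = 0; i < n; ++i) {
    mat H = as<mat>(Hs[i]);
    rowvec G = arma::mean(H, 0);
    rowvec O = (p.V * G.t()).t() + p.bv.t();
    rowvec P = arma::clamp(O, 0.0, relu_clamp_inf());
    out.row(i) = arma::clamp(1.0 / (1.0 + arma::exp(-P)), 0.0,
                             1.0 - 2.220446049250313e-16);
  }
  return out;
}

// Analytic gradient of the squared-error loss (s_hat - y)^2 for one protein;
// used by the finite-difference gradient-flow tests.
// [[Rcpp::export]]
List hg_grad_cpp(const arma::mat& H, const arma::mat& A, List par,
                 bool use_afr, double y) {
  Pars p = pars_from_list(par, use_afr);
  Cache c;
  double s = hg_forward(H, A, p, c, 0.0, nullptr);
  Grads g;
  hg_backward(H, A, p, c, 2.0 * (s - y), g);
  List Wg(g.Wg.size()), bg(g.bg.size());
  for (size_t i = 0; i < g.Wg.size(); ++i) {
    Wg[i] = g.Wg[i];
    bg[i] = g.bg[i];
  }
  List out = List::create(
      _["Wg"] = Wg, _["bg"] = bg, _["Wa"] = g.Wa, _["ba"] = g.ba,
      _["Ua"] = g.Ua, _["ca"] = g.ca, _["wo"] = g.wo, _["bo"] = g.bo,
      _["s_hat"] = s);
  if (use_afr) {
    out["V"] = g.V;
    out["bv"] = g.bv;
  }
  return out;
}

// Full training driver: Adam over per-protein squared-error steps with an
// optional validation split for early stopping on validation RMSE.
// train_idx / val_idx are 1-based indices into Hs/As/y.
// [[Rcpp::export]]
List hg_train_cpp(List Hs, List As, NumericVector y, List par0, bool use_afr,
                  bool afr_bias, IntegerVector train_idx, IntegerVector val_idx,
                  int epochs, double lr, double dropout, int seed,
                  int patience, double min_delta, double clip_norm) {
  Pars p = pars_from_list(par0, use_afr);
  const int ntr = train_idx.size(), nval = val_idx.size();

  std::vector<mat> H(Hs.size()), A(As.size());
  for (int i = 0; i < Hs.size(); ++i) {
    H[i] = as<mat>(Hs[i]);
    A[i] = as<mat>(As[i]);
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  Pars m, v;  // Adam moments, same shapes as p (lazily sized)
  m.use_afr = v.use_afr = use_afr;
  m.Wg.resize(p.Wg.size()); m.bg.resize(p.bg.size());
  v.Wg.resize(p.Wg.size()); v.bg.resize(p.bg.size());
  double m_bo = 0.0, v_bo = 0.0;

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = train_idx[i] - 1;

  Pars best = p;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0;
  NumericVector tr_hist(epochs, NA_REAL), val_hist(epochs, NA_REAL);
  long t = 0;
  Cache c;
  int epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (int ii = 0; ii < ntr; ++ii) {
      const int i = order[ii];
      double s = hg_forward(H[i], A[i], p, c, dropout, &rng);
      double err = s - y[i];
      sse += err * err;
      Grads g;
      hg_backward(H[i], A[i], p, c, 2.0 * err, g);
      if (clip_norm > 0.0) {
        double sq = arma::accu(arma::square(g.Wa)) +
                    arma::accu(arma::square(g.ba)) +
                    arma::accu(arma::square(g.Ua)) +
                    arma::accu(arma::square(g.ca)) +
                    arma::accu(arma::square(g.wo)) + g.bo * g.bo;
        for (size_t l = 0; l < g.Wg.size(); ++l) {
          sq += arma::accu(arma::square(g.Wg[l])) +
                arma::accu(arma::square(g.bg[l]));
        }
        if (use_afr) {
          sq += arma::accu(arma::square(g.V)) + arma::accu(arma::square(g.bv));
        }
        const double gnorm = std::sqrt(sq);
        if (gnorm > clip_norm) {
          const double sc = clip_norm / gnorm;
          g.Wa *= sc; g.ba *= sc; g.Ua *= sc; g.ca *= sc; g.wo *= sc;
          g.bo *= sc;
          for (size_t l = 0; l < g.Wg.size(); ++l) {
            g.Wg[l] *= sc;
            g.bg[l] *= sc;
          }
          if (use_afr) { g.V *= sc; g.bv *= sc; }
        }
      }
      ++t;
      const double td = static_cast<double>(t);
      if (use_afr) {
        adam_mat(p.V, g.V, m.V, v.V, lr, b1, b2, eps, td);
        if (afr_bias) adam_vec(p.bv, g.bv, m.bv, v.bv, lr, b1, b2, eps, td);
      }
      for (size_t l = 0; l < p.Wg.size(); ++l) {
        adam_mat(p.Wg[l], g.Wg[l], m.Wg[l], v.Wg[l], lr, b1, b2, eps, td);
        adam_vec(p.bg[l], g.bg[l], m.bg[l], v.bg[l], lr, b1, b2, eps, td);
      }
      adam_mat(p.Wa, g.Wa, m.Wa, v.Wa, lr, b1, b2, eps, td);
      adam_vec(p.ba, g.ba, m.ba, v.ba, lr, b1, b2, eps, td);
      adam_mat(p.Ua, g.Ua, m.Ua, v.Ua, lr, b1, b2, eps, td);
      adam_vec(p.ca, g.ca, m.ca, v.ca, lr, b1, b2, eps, td);
      adam_vec(p.wo, g.wo, m.wo, v.wo, lr, b1, b2, eps, td);
      m_bo = b1 * m_bo + (1.0 - b1) * g.bo;
      v_bo = b2 * v_bo + (1.0 - b2) * g.bo * g.bo;
      p.bo -= lr * (m_bo / (1.0 - std::pow(b1, td))) /
              (std::sqrt(v_bo / (1.0 - std::pow(b2, td))) + eps);
    }
    tr_hist[ep] = std::sqrt(sse / ntr);
    epochs_run = ep + 1;

    if (nval > 0) {
      double vsse = 0.0;
      for (int j = 0; j < nval; ++j) {
        const int i = val_idx[j] - 1;
        double s = hg_forward(H[i], A[i], p, c, 0.0, nullptr);
        vsse += (s - y[i]) * (s - y[i]);
      }
      const double vrmse = std::sqrt(vsse / nval);
      val_hist[ep] = vrmse;
      if (vrmse < best_val - min_delta) {
        best_val = vrmse;
        best = p;
        best_epoch = ep + 1;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else {
      best = p;
      best_epoch = ep + 1;
    }
  }

  return List::create(
      _["par"] = pars_to_list(nval > 0 ? best : p),
      _["train_rmse"] = tr_hist, _["val_rmse"] = val_hist,
      _["best_epoch"] = best_epoch, _["epochs_run"] = epochs_run,
      _["best_val_rmse"] = nval > 0 ? best_val : NA_REAL);
}
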