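// Small fully connected regression network: n_in -> h1 (relu) -> h2 (relu) -> 1
// (linear), mean-squared-error loss, Adam, mini-batches, early stopping on a
// validation split.  Self-contained (seeded std::mt19937) so fits are
// bit-reproducible and depend only on the training rows and the seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Dense {
  int nin, nout;
  std::vector<double> W, b;        // W is nin x nout, column-major by output
  std::vector<double> mW, vW, mb, vb; // Adam state
  Dense(int ni, int no, std::mt19937& rng) : nin(ni), nout(no),
      W(ni * no), b(no, 0.0), mW(ni * no, 0.0), vW(ni * no, 0.0),
      mb(no, 0.0), vb(no, 0.0) {
    double lim = 1.0 / std::sqrt((double)ni); // fan-in scaled uniform init
    std::uniform_real_distribution<double> u(-lim, lim);
    for (auto& w : W) w = u(rng);
  }
};

inline void forward(const Dense& d, const std::vector<double>& x, int nrow,
                    std::vector<double>& out, bool relu) {
  out.assign((size_t)nrow * d.nout, 0.0);
  for (int r = 0; r < nrow; ++r) {
    const double* xr = &x[(size_t)r * d.nin];
    double* orow = &out[(size_t)r * d.nout];
    for (int j = 0; j < d.nout; ++j) {
      const double* wj = &d.W[(size_t)j * d.nin];
      double s = d.b[j];
      for (int i = 0; i < d.nin; ++i) s += xr[i] * wj[i];
      orow[j] = (relu && s < 0.0) ? 0.0 : s;
    }
  }
}

// grad wrt layer input given grad wrt (post-activation) output
inline void backward(Dense& d, const std::vector<double>& x, int nrow,
                     const std::vector<double>& act, std::vector<double>& gout,
                     std::vector<double>& gin, bool relu,
                     std::vector<double>& gW, std::vector<double>& gb) {
  gW.assign(d.W.size(), 0.0);
  gb.assign(d.b.size(), 0.0);
  gin.assign((size_t)nrow * d.nin, 0.0);
  for (int r = 0; r < nrow; ++r) {
    const double* xr = &x[(size_t)r * d.nin];
    double* gr = &gout[(size_t)r * d.nout];
    const double* ar = &act[(size_t)r * d.nout];
    double* gi = &gin[(size_t)r * d.nin];
    for (int j = 0; j < d.nout; ++j) {
      double g = gr[j];
      if (relu && ar[j] <= 0.0) g = 0.0;
      if (g == 0.0) continue;
      double* wj = &gW[(size_t)j * d.nin];
      const double* Wj = &d.W[(size_t)j * d.nin];
      for (int i = 0; i < d.nin; ++i) {
        wj[i] += g * xr[i];
        gi[i] += g * Wj[i];
      }
      gb[j] += g;
    }
  }
}

inline void adam_update(std::vector<double>& p, std::vector<double>& m,
                        std::vector<double>& v, const std::vector<double>& g,
                        double lr, double b1, double b2, double eps,
                        double b1t, double b2t, double inv_batch) {
  for (size_t k = 0; k < p.size(); ++k) {
    double gk = g[k] * inv_batch;
    m[k] = b1 * m[k] + (1.0 - b1) * gk;
    v[k] = b2 * v[k] + (1.0 - b2) * gk * gk;
    double mh = m[k] / (1.0 - b1t), vh = v[k] / (1.0 - b2t);
    p[k] -= lr * mh / (std::sqrt(vh) + eps);
  }
}

double mse_of(const std::vector<Dense>& net, const std::vector<double>& X,
              const std::vector<double>& y, int n, int p) {
  if (n == 0) return 0.0;
  std::vector<double> h1, h2, o;
  forward(net[0], X, n, h1, true);
  forward(net[1], h1, n, h2, true);
  forward(net[2], h2, n, o, false);
  double s = 0.0;
  for (int r = 0; r < n; ++r) { double e = o[r] - y[r]; s += e * e; }
  return s / n;
}

} // namespace

// [[Rcpp::export(name = ".mlp_fit_cpp")]]
List mlp_fit_cpp(NumericMatrix Xtr, NumericVector ytr,
                 NumericMatrix Xval, NumericVector yval,
                 int h1, int h2, double lr, int batch_size,
                 int max_epochs, int patience, int seed) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nv = Xval.nrow();
  std::mt19937 rng((unsigned)seed);
  std::vector<Dense> net;
  net.emplace_back(p, h1, rng);
  net.emplace_back(h1, h2, rng);
  net.emplace_back(h2, 1, rng);

  // row-major copies
  std::vector<double> X((size_t)n * p), Xv((size_t)nv * p), y(ytr.begin(), ytr.end()),
      yv(yval.begin(), yval.end());
  for (int r = 0; r < n; ++r)
    for (int j = 0; j < p; ++j) X[(size_t)r * p + j] = Xtr(r, j);
  for (int r = 0; r < nv; ++r)
    for (int j = 0; j < p; ++j) Xv[(size_t)r * p + j] = Xval(r, j);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double b1t = 1.0, b2t = 1.0;
  double best = R_PosInf;
  int best_epoch = 0, bad = 0, epochs_run = 0;
  std::vector<std::vector<double>> bestW(3), bestB(3);
  for (int l = 0; l < 3; ++l) { bestW[l] = net[l].W; bestB[l] = net[l].b; }

  std::vector<double> xb, yb, a1, a2, a3, g3, g2, g1, g0, gW, gb;
  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      xb.assign((size_t)bs * p, 0.0);
      yb.assign(bs, 0.0);
      for (int r = 0; r < bs; ++r) {
        int src = order[start + r];
        for (int j = 0; j < p; ++j) xb[(size_t)r * p + j] = X[(size_t)src * p + j];
        yb[r] = y[src];
      }
      forward(net[0], xb, bs, a1, true);
      forward(net[1], a1, bs, a2, true);
      forward(net[2], a2, bs, a3, false);
      g3.assign(bs, 0.0);
      for (int r = 0; r < bs; ++r) g3[r] = 2.0 * (a3[r] - yb[r]);
      b1t *= b1; b2t *= b2;
      double inv = 1.0 / bs;
      backward(net[2], a2, bs, a3, g3, g2, false, gW, gb);
      adam_update(net[2].W, net[2].mW, net[2].vW, gW, lr, b1, b2, eps, b1t, b2t, inv);
      adam_update(net[2].b, net[2].mb, net[2].vb, gb, lr, b1, b2, eps, b1t, b2t, inv);
      backward(net[1], a1, bs, a2, g2, g1, true, gW, gb);
      adam_update(net[1].W, net[1].mW, net[1].vW, gW, lr, b1, b2, eps, b1t, b2t, inv);
      adam_update(net[1].b, net[1].mb, net[1].vb, gb, lr, b1, b2, eps, b1t, b2t, inv);
      backward(net[0], xb, bs, a1, g1, g0, true, gW, gb);
      adam_update(net[0].W, net[0].mW, net[0].vW, gW, lr, b1, b2, eps, b1t, b2t, inv);
      adam_update(net[0].b, net[0].mb, net[0].vb, gb, lr, b1, b2, eps, b1t, b2t, inv);
    }
    epochs_run = ep + 1;
    double val = nv > 0 ? mse_of(net, Xv, yv, nv, p) : mse_of(net, X, y, n, p);
    if (val < best - 1e-12) {
      best = val;
      best_epoch = epochs_run;
      bad = 0;
      for (int l = 0; l < 3; ++l) { bestW[l] = net[l].W; bestB[l] = net[l].b; }
    } else if (++bad >= patience) break;
  }

  List weights(3), biases(3);
  int dims_in[3] = {p, h1, h2}, dims_out[3] = {h1, h2, 1};
  for (int l = 0; l < 3; ++l) {
    NumericMatrix W(dims_in[l], dims_out[l]);
    for (int j = 0; j < dims_out[l]; ++j)
      for (int i = 0; i < dims_in[l]; ++i) W(i, j) = bestW[l][(size_t)j * dims_in[l] + i];
    weights[l] = W;
    biases[l] = NumericVector(bestB[l].begin(), bestB[l].end());
  }
  return List::create(_["weights"] = weights, _["biases"] = biases,
                      _["epochs"] = epochs_run, _["best_epoch"] = best_epoch,
                      _["val_mse"] = best);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
NumericVector mlp_predict_cpp(List weights, List biases, NumericMatrix Xm) {
  const int n = Xm.nrow(), p = Xm.ncol();
  std::vector<Dense> net;
  std::mt19937 dummy(1);
  NumericMatrix W1 = weights[0], W2 = weights[1], W3 = weights[2];
  NumericVector B1 = biases[0], B2 = biases[1], B3 = biases[2];
  if (W1.nrow() != p) stop("feature width %d does not match network input %d", p, W1.nrow());
  net.emplace_back(W1.nrow(), W1.ncol(), dummy);
  net.emplace_back(W2.nrow(), W2.ncol(), dummy);
  net.emplace_back(W3.nrow(), W3.ncol(), dummy);
  NumericMatrix Ws[3] = {W1, W2, W3};
  NumericVector Bs[3] = {B1, B2, B3};
  for (int l = 0; l < 3; ++l) {
    for (int j = 0; j < net[l].nout; ++j) {
      for (int i = 0; i < net[l].nin; ++i)
        net[l].W[(size_t)j * net[l].nin + i] = Ws[l](i, j);
      net[l].b[j] = Bs[l][j];
    }
  }
  std::vector<double> X((size_t)n * p);
  for (int r = 0; r < n; ++r)
    for (int j = 0; j < p; ++j) X[(size_t)r * p + j] = Xm(r, j);
  std::vector<double> h1, h2, o;
  forward(net[0], X, n, h1, true);
  forward(net[1], h1, n, h2, true);
  forward(net[2], h2, n, o, false);
  return NumericVector(o.begin(), o.end());
}
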