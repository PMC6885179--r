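// Batch LSTM forward pass, backpropagation through time, and Adam training
// loop for a single base classifier. Parameters travel packed: W is
// (H+m) x 4H with column blocks [forget | input | output | candidate], so one
// GEMM per time step computes all gate pre-activations for the whole batch.
// The gate concatenation order is [h_{t-1}, x_t]: rows 1..H of W act on the
// previous hidden state, rows H+1..H+m on the (possibly dropped-out) input.
//
// All randomness (dropout masks, mini-batch shuffling) comes from a local
// mt19937 stream seeded explicitly, so training is reproducible bit-for-bit
// from the seed and independent of R's RNG state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Params {
  arma::mat W;    // (H+m) x 4H
  arma::rowvec b; // 4H
  arma::vec w_ho; // H
  double b_ho;
  int H, m;
};

Params unpack(const List& p) {
  Params out;
  out.W = as<arma::mat>(p["W"]);
  out.b = as<arma::rowvec>(p["b"]);
  out.w_ho = as<arma::vec>(p["w_ho"]);
  out.b_ho = as<double>(p["b_ho"]);
  out.H = as<int>(p["H"]);
  out.m = as<int>(p["m"]);
  return out;
}

List pack(const Params& p) {
  return List::create(_["W"] = p.W, _["b"] = p.b, _["w_ho"] = p.w_ho,
                      _["b_ho"] = p.b_ho, _["H"] = p.H, _["m"] = p.m);
}

inline arma::mat sigm(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// uniform in [0,1) from a raw mt19937 draw; avoids the implementation-defined
// std distributions so masks are identical across compilers
inline double runif01(std::mt19937& gen) {
  return gen() * (1.0 / 4294967296.0);
}

struct Cache {
  std::vector<arma::mat> Zin;            // per t: n x (H+m), h_prev || dropped x_t
  std::vector<arma::mat> F, I, O, G, C, tC;
  std::vector<arma::mat> Cprev;
  arma::mat hT;                          // n x H
};

// forward over all T steps for the rows `idx` of cube X (n_all x m x T);
// dropout applied per time step when rate > 0 and gen != nullptr
arma::vec forward_pass(const arma::cube& X, const arma::uvec& idx,
                       const Params& P, double dropout, std::mt19937* gen,
                       Cache* cache) {
  const arma::uword n = idx.n_elem, T = X.n_slices;
  const int H = P.H, m = P.m;
  arma::mat h(n, H, arma::fill::zeros), C(n, H, arma::fill::zeros);
  const double keep = 1.0 - dropout;
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat Xt = X.slice(t).rows(idx); // n x m
    if (dropout > 0 && gen != nullptr) { // inverted dropout on the input layer
      for (arma::uword j = 0; j < Xt.n_cols; ++j)
        for (arma::uword i = 0; i < Xt.n_rows; ++i)
          Xt(i, j) = (runif01(*gen) < keep) ? Xt(i, j) / keep : 0.0;
    }
    arma::mat Zin = arma::join_rows(h, Xt);       // n x (H+m)
    arma::mat Z = Zin * P.W;                      // n x 4H
    Z.each_row() += P.b;
    arma::mat F = sigm(Z.cols(0, H - 1));
    arma::mat I = sigm(Z.cols(H, 2 * H - 1));
    arma::mat O = sigm(Z.cols(2 * H, 3 * H - 1));
    arma::mat G = arma::tanh(Z.cols(3 * H, 4 * H - 1));
    arma::mat Cprev = C;
    C = F % Cprev + I % G;
    arma::mat tC = arma::tanh(C);
    h = O % tC;
    if (cache) {
      cache->Zin.push_back(Zin);
      cache->F.push_back(F); cache->I.push_back(I); cache->O.push_back(O);
      cache->G.push_back(G); cache->C.push_back(C); cache->tC.push_back(tC);
      cache->Cprev.push_back(Cprev);
    }
  }
  if (cache) cache->hT = h;
  return sigm(h * P.w_ho + P.b_ho); // n scores
}

// mean gamma-weighted binary cross entropy; scores clipped to avoid log(0)
double wbce_mean(const arma::vec& score, const arma::vec& y, double gamma) {
  const double eps = 1e-7;
  arma::vec s = arma::clamp(score, eps, 1.0 - eps);
  arma::vec per = -(gamma * y % arma::log(s) + (1.0 - y) % arma::log(1.0 - s));
  return arma::mean(per);
}

struct Grads {
  arma::mat dW;
  arma::rowvec db;
  arma::vec dw_ho;
  double db_ho;
};

// BPTT for the mean weighted BCE over the cached batch
Grads backward_pass(const Params& P, const Cache& cache, const arma::vec& score,
                    const arma::vec& y, double gamma) {
  const int H = P.H;
  const arma::uword T = cache.F.size(), n = score.n_elem;
  arma::vec w = arma::ones(n) + (gamma - 1.0) * y;   // gamma on positives
  arma::vec dlogit = (w % (score - y)) / double(n);  // d(mean loss)/d(readout logit)

  Grads g;
  g.dW.zeros(P.W.n_rows, P.W.n_cols);
  g.db.zeros(P.b.n_elem);
  g.dw_ho = cache.hT.t() * dlogit;
  g.db_ho = arma::accu(dlogit);

  arma::mat dh = dlogit * P.w_ho.t();                // n x H
  arma::mat dC(n, H, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    const arma::mat& F = cache.F[tt]; const arma::mat& I = cache.I[tt];
    const arma::mat& O = cache.O[tt]; const arma::mat& G = cache.G[tt];
    const arma::mat& tC = cache.tC[tt];
    arma::mat dO = dh % tC;
    dC += dh % O % (1.0 - tC % tC);
    arma::mat dF = dC % cache.Cprev[tt];
    arma::mat dI = dC % G;
    arma::mat dG = dC % I;
    arma::mat dZ = arma::join_rows(arma::join_rows(dF % F % (1.0 - F),
                                                   dI % I % (1.0 - I)),
                                   arma::join_rows(dO % O % (1.0 - O),
                                                   dG % (1.0 - G % G)));
    g.dW += cache.Zin[tt].t() * dZ;
    g.db += arma::sum(dZ, 0);
    arma::mat dZin = dZ * P.W.t();
    dh = dZin.cols(0, H - 1);
    dC = dC % F;
  }
  return g;
}

struct AdamState {
  arma::mat mW, vW; arma::rowvec mb, vb; arma::vec mwho, vwho;
  double mbho = 0, vbho = 0; long step = 0;
  void init(const Params& p) {
    mW.zeros(arma::size(p.W)); vW.zeros(arma::size(p.W));
    mb.zeros(p.b.n_elem); vb.zeros(p.b.n_elem);
    mwho.zeros(p.w_ho.n_elem); vwho.zeros(p.w_ho.n_elem);
  }
};

template <typename M>
inline void adam_update(M& theta, M& m1, M& m2, const M& g, double lr,
                        double b1, double b2, double eps, double c1, double c2) {
  m1 = b1 * m1 + (1.0 - b1) * g;
  m2 = b2 * m2 + (1.0 - b2) * (g % g);
  theta -= lr * (m1 / c1) / (arma::sqrt(m2 / c2) + eps);
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_forward_scores(const arma::cube& X, const List& params) {
  Params P = unpack(params);
  arma::uvec idx = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  return forward_pass(X, idx, P, 0.0, nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_loss_grad(const arma::cube& X, const arma::vec& y, double gamma,
                   const List& params) {
  Params P = unpack(params);
  arma::uvec idx = arma::regspace<arma::uvec>(0, X.n_rows - 1);
  Cache cache;
  arma::vec score = forward_pass(X, idx, P, 0.0, nullptr, &cache);
  Grads g = backward_pass(P, cache, score, y, gamma);
  return List::create(_["loss"] = wbce_mean(score, y, gamma),
                      _["dW"] = g.dW, _["db"] = g.db,
                      _["dw_ho"] = g.dw_ho, _["db_ho"] = g.db_ho);
}

// [[Rcpp::export]]
List cpp_train_lstm(const arma::cube& X, const arma::vec& y, double gamma,
                    const List& params0, const arma::uvec& train_idx,
                    const arma::uvec& val_idx, double lr, int max_epochs,
                    double dropout, int batch_size, bool early_stop,
                    unsigned int seed, double beta1, double beta2, double eps) {
  Params P = unpack(params0);
  AdamState opt; opt.init(P);
  std::mt19937 gen(seed);

  const arma::uword n_train = train_idx.n_elem;
  arma::vec y_train = y(train_idx);
  arma::vec train_loss(max_epochs), val_loss(max_epochs);
  val_loss.fill(arma::datum::nan);

  Params best = P;
  double best_val = arma::datum::inf;
  int best_epoch = 0;

  std::vector<arma::uword> order(n_train);
  for (arma::uword i = 0; i < n_train; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    if (batch_size > 0 && n_train > 1) { // Fisher-Yates with the local stream
      for (arma::uword i = n_train - 1; i > 0; --i) {
        arma::uword j = gen() % (i + 1);
        std::swap(order[i], order[j]);
      }
    }
    const arma::uword bs = (batch_size > 0)
        ? std::min<arma::uword>(batch_size, n_train) : n_train;
    double epoch_loss = 0; arma::uword n_seen = 0;
    for (arma::uword start = 0; start < n_train; start += bs) {
      arma::uword stop = std::min(start + bs, n_train) - 1;
      arma::uvec batch(stop - start + 1);
      for (arma::uword i = start; i <= stop; ++i)
        batch[i - start] = train_idx[order[i]];
      Cache cache;
      arma::vec score = forward_pass(X, batch, P, dropout, &gen, &cache);
      arma::vec yb = y(batch);
      Grads g = backward_pass(P, cache, score, yb, gamma);
      epoch_loss += wbce_mean(score, yb, gamma) * batch.n_elem;
      n_seen += batch.n_elem;
      opt.step += 1;
      double c1 = 1.0 - std::pow(beta1, (double)opt.step);
      double c2 = 1.0 - std::pow(beta2, (double)opt.step);
      adam_update(P.W, opt.mW, opt.vW, g.dW, lr, beta1, beta2, eps, c1, c2);
      adam_update(P.b, opt.mb, opt.vb, g.db, lr, beta1, beta2, eps, c1, c2);
      adam_update(P.w_ho, opt.mwho, opt.vwho, g.dw_ho, lr, beta1, beta2, eps, c1, c2);
      opt.mbho = beta1 * opt.mbho + (1.0 - beta1) * g.db_ho;
      opt.vbho = beta2 * opt.vbho + (1.0 - beta2) * g.db_ho * g.db_ho;
      P.b_ho -= lr * (opt.mbho / c1) / (std::sqrt(opt.vbho / c2) + eps);
    }
    train_loss[epoch] = epoch_loss / n_seen;
    if (early_stop && val_idx.n_elem > 0) {
      arma::vec vs = forward_pass(X, val_idx, P, 0.0, nullptr, nullptr);
      double vl = wbce_mean(vs, y(val_idx), gamma);
      val_loss[epoch] = vl;
      if (vl < best_val) { best_val = vl; best = P; best_epoch = epoch + 1; }
    }
  }
  if (!early_stop || val_idx.n_elem == 0) { best = P; best_epoch = max_epochs; }
  return List::create(_["params"] = pack(best),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss,
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = max_epochs);
}
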