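// Small batched LSTM classifier (sequence-to-one) with BPTT and Adam.
// Topology: LSTM(U) -> dropout -> dense(H, ReLU) -> dropout -> softmax(C).
// Inputs are cubes of shape (batch, channels, time). All randomness
// (init, dropout, shuffling) comes from one std::mt19937_64 stream so
// training is bit-reproducible for a fixed seed on a single thread.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat W;   // (D+U) x 4U, gate column blocks ordered i, f, g, o
  rowvec b;   // 4U
  mat W1;  // U x H
  rowvec b1;  // H
  mat W2;  // H x C
  rowvec b2;  // C
};

Params params_from_list(const Rcpp::List& p) {
  Params out;
  out.W  = Rcpp::as<mat>(p["W"]);
  out.b  = Rcpp::as<rowvec>(p["b"]);
  out.W1 = Rcpp::as<mat>(p["W1"]);
  out.b1 = Rcpp::as<rowvec>(p["b1"]);
  out.W2 = Rcpp::as<mat>(p["W2"]);
  out.b2 = Rcpp::as<rowvec>(p["b2"]);
  return out;
}

Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("W") = p.W, Rcpp::Named("b") = p.b,
      Rcpp::Named("W1") = p.W1, Rcpp::Named("b1") = p.b1,
      Rcpp::Named("W2") = p.W2, Rcpp::Named("b2") = p.b2);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

mat glorot(uword n_in, uword n_out, std::mt19937_64& rng) {
  const double lim = std::sqrt(6.0 / double(n_in + n_out));
  std::uniform_real_distribution<double> unif(-lim, lim);
  mat m(n_in, n_out);
  for (uword j = 0; j < n_out; ++j)
    for (uword i = 0; i < n_in; ++i) m(i, j) = unif(rng);
  return m;
}

// Forward pass over a batch; caches are filled only when training.
struct Cache {
  cube i, f, g, o, c, h;  // each (B, U, T)
};

mat forward(const Params& p, const cube& X, uword U, Cache* cache,
            mat* hT_out) {
  const uword B = X.n_rows, T = X.n_slices;
  mat h(B, U, fill::zeros), c(B, U, fill::zeros);
  if (cache) {
    cache->i.set_size(B, U, T); cache->f.set_size(B, U, T);
    cache->g.set_size(B, U, T); cache->o.set_size(B, U, T);
    cache->c.set_size(B, U, T); cache->h.set_size(B, U, T);
  }
  for (uword t = 0; t < T; ++t) {
    mat Z = join_rows(X.slice(t), h) * p.W;
    Z.each_row() += p.b;
    mat gi = sigmoid(Z.cols(0, U - 1));
    mat gf = sigmoid(Z.cols(U, 2 * U - 1));
    mat gg = tanh(Z.cols(2 * U, 3 * U - 1));
    mat go = sigmoid(Z.cols(3 * U, 4 * U - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    if (cache) {
      cache->i.slice(t) = gi; cache->f.slice(t) = gf;
      cache->g.slice(t) = gg; cache->o.slice(t) = go;
      cache->c.slice(t) = c;  cache->h.slice(t) = h;
    }
  }
  if (hT_out) *hT_out = h;
  return h;
}

mat softmax_rows(mat z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  void init(const Params& p) {
    m.W = zeros(size(p.W)); m.b = zeros<rowvec>(p.b.n_elem);
    m.W1 = zeros(size(p.W1)); m.b1 = zeros<rowvec>(p.b1.n_elem);
    m.W2 = zeros(size(p.W2)); m.b2 = zeros<rowvec>(p.b2.n_elem);
    v = m;
  }
  template <class M>
  void upd1(M& theta, M& mm, M& vv, const M& grad, double lr) {
    mm = b1 * mm + (1 - b1) * grad;
    vv = b2 * vv + (1 - b2) * (grad % grad);
    const double bc1 = 1 - std::pow(b1, double(step));
    const double bc2 = 1 - std::pow(b2, double(step));
    theta -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
  }
  void update(Params& p, const Params& g, double lr) {
    ++step;
    upd1(p.W, m.W, v.W, g.W, lr);   upd1(p.b, m.b, v.b, g.b, lr);
    upd1(p.W1, m.W1, v.W1, g.W1, lr); upd1(p.b1, m.b1, v.b1, g.b1, lr);
    upd1(p.W2, m.W2, v.W2, g.W2, lr); upd1(p.b2, m.b2, v.b2, g.b2, lr);
  }
};

mat bernoulli_mask(uword n_rows, uword n_cols, double keep,
                   std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat m(n_rows, n_cols);
  for (uword j = 0; j < n_cols; ++j)
    for (uword i = 0; i < n_rows; ++i)
      m(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".lstm_init")]]
Rcpp::List lstm_init_cpp(int d_in, int units, int dense_units, int n_classes,
                         int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  Params p;
  const uword D = d_in, U = units, H = dense_units, C = n_classes;
  p.W = glorot(D + U, 4 * U, rng);
  p.b = zeros<rowvec>(4 * U);
  p.b.subvec(U, 2 * U - 1).fill(1.0);  // forget-gate bias
  p.W1 = glorot(U, H, rng);
  p.b1 = zeros<rowvec>(H);
  p.W2 = glorot(H, C, rng);
  p.b2 = zeros<rowvec>(C);
  return params_to_list(p);
}

// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train_cpp(Rcpp::List params, const arma::cube& X,
                          const arma::ivec& y, int epochs, int batch_size,
                          double lr, double dropout, int seed) {
  Params p = params_from_list(params);
  const uword N = X.n_rows, D = X.n_cols, T = X.n_slices;
  const uword U = p.W1.n_rows, C = p.W2.n_cols;
  if (y.n_elem != N) Rcpp::stop("label/input length mismatch");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) ^ 0x9e3779b97f4a7c15ULL);
  Adam adam; adam.init(p);
  const double keep = 1.0 - dropout;

  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  std::vector<double> hist_loss(epochs), hist_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0; uword correct = 0;
    for (uword off = 0; off < N; off += batch_size) {
      const uword B = std::min<uword>(batch_size, N - off);
      cube Xb(B, D, T);
      ivec yb(B);
      for (uword i = 0; i < B; ++i) {
        const uword s = idx[off + i];
        for (uword t = 0; t < T; ++t) Xb.slice(t).row(i) = X.slice(t).row(s);
        yb(i) = y(s);
      }
      Cache cache; mat hT;
      forward(p, Xb, U, &cache, &hT);

      mat m0 = (keep < 1.0) ? bernoulli_mask(B, U, keep, rng)
                            : mat(B, U, fill::ones);
      mat hTd = hT % m0;
      mat a1 = hTd * p.W1; a1.each_row() += p.b1;
      a1 = clamp(a1, 0.0, datum::inf);
      mat m1 = (keep < 1.0) ? bernoulli_mask(B, a1.n_cols, keep, rng)
                            : mat(B, a1.n_cols, fill::ones);
      mat a1d = a1 % m1;
      mat logits = a1d * p.W2; logits.each_row() += p.b2;
      mat P = softmax_rows(logits);

      mat Y(B, C, fill::zeros);
      for (uword i = 0; i < B; ++i) Y(i, yb(i)) = 1.0;
      for (uword i = 0; i < B; ++i) {
        loss_sum -= std::log(std::max(P(i, yb(i)), 1e-12));
        if (index_max(P.row(i)) == uword(yb(i))) ++correct;
      }

      // top gradients
      mat dlogits = (P - Y) / double(B);
      Params g;
      g.W2 = a1d.t() * dlogits;
      g.b2 = sum(dlogits, 0);
      mat da1 = (dlogits * p.W2.t()) % m1;
      da1 %= conv_to<mat>::from(a1 > 0);
      g.W1 = hTd.t() * da1;
      g.b1 = sum(da1, 0);
      mat dh = (da1 * p.W1.t()) % m0;

      // BPTT (loss depends on h_T only)
      g.W = zeros(size(p.W));
      g.b = zeros<rowvec>(p.b.n_elem);
      mat dc(B, U, fill::zeros);
      for (uword t = T; t-- > 0;) {
        const mat& gi = cache.i.slice(t); const mat& gf = cache.f.slice(t);
        const mat& gg = cache.g.slice(t); const mat& go = cache.o.slice(t);
        const mat& ct = cache.c.slice(t);
        mat tc = tanh(ct);
        mat do_ = dh % tc;
        dc += dh % go % (1.0 - tc % tc);
        mat cprev = (t == 0) ? mat(B, U, fill::zeros) : cache.c.slice(t - 1);
        mat hprev = (t == 0) ? mat(B, U, fill::zeros) : cache.h.slice(t - 1);
        mat dZ = join_rows(
            join_rows(dc % gg % gi % (1.0 - gi),
                      dc % cprev % gf % (1.0 - gf)),
            join_rows(dc % gi % (1.0 - gg % gg),
                      do_ % go % (1.0 - go)));
        g.W += join_rows(Xb.slice(t), hprev).t() * dZ;
        g.b += sum(dZ, 0);
        mat dIn = dZ * p.W.t();
        dh = dIn.cols(D, D + U - 1);
        dc %= gf;
      }
      adam.update(p, g, lr);
    }
    hist_loss[ep] = loss_sum / double(N);
    hist_acc[ep] = double(correct) / double(N);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(p),
      Rcpp::Named("loss") = hist_loss,
      Rcpp::Named("accuracy") = hist_acc);
}

// [[Rcpp::export(name = ".lstm_predict")]]
arma::mat lstm_predict_cpp(Rcpp::List params, const arma::cube& X,
                           int batch_size) {
  Params p = params_from_list(params);
  const uword N = X.n_rows, D = X.n_cols, T = X.n_slices;
  const uword U = p.W1.n_rows, C = p.W2.n_cols;
  mat out(N, C);
  for (uword off = 0; off < N; off += batch_size) {
    const uword B = std::min<uword>(batch_size, N - off);
    cube Xb(B, D, T);
    for (uword i = 0; i < B; ++i)
      for (uword t = 0; t < T; ++t)
        Xb.slice(t).row(i) = X.slice(t).row(off + i);
    mat hT;
    forward(p, Xb, U, nullptr, &hT);
    mat a1 = hT * p.W1; a1.each_row() += p.b1;
    a1 = clamp(a1, 0.0, datum::inf);
    mat logits = a1 * p.W2; logits.each_row() += p.b2;
    out.rows(off, off + B - 1) = softmax_rows(logits);
  }
  return out;
}
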