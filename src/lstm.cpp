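// Single-layer LSTM with a rectify-then-linear scalar readout, trained by
// backpropagation through time with Adam. Gate layout follows the common
// (input, forget, cell, output) row-block convention; two bias vectors are
// kept so the uniform fan-in initialization can be applied to each
// parameter tensor independently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void adam_step(mat& theta, mat& m, mat& v, const mat& g,
                             double lr, double b1, double b2, double eps,
                             double b1t, double b2t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  theta -= lr * (m / (1.0 - b1t)) / (sqrt(v / (1.0 - b2t)) + eps);
}

// Forward pass over a batch; caches per-timestep states for the backward
// pass. X: I x B x T, returns hidden states H x B x T and outputs T x B.
struct Cache {
  cube H, C, I_, F, G_, O;
  mat Y;
};

static void forward_batch(const cube& X, const mat& Wih, const mat& Whh,
                          const vec& bih, const vec& bhh, const vec& wout,
                          double bout, Cache& cc) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = Whh.n_cols;
  (void)I;
  cc.H.set_size(H, B, T); cc.C.set_size(H, B, T);
  cc.I_.set_size(H, B, T); cc.F.set_size(H, B, T);
  cc.G_.set_size(H, B, T); cc.O.set_size(H, B, T);
  cc.Y.set_size(T, B);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  const vec b = bih + bhh;
  for (uword t = 0; t < T; ++t) {
    mat a = Wih * X.slice(t) + Whh * h;
    a.each_col() += b;
    mat ig = 1.0 / (1.0 + exp(-a.rows(0, H - 1)));
    mat fg = 1.0 / (1.0 + exp(-a.rows(H, 2 * H - 1)));
    mat gg = tanh(a.rows(2 * H, 3 * H - 1));
    mat og = 1.0 / (1.0 + exp(-a.rows(3 * H, 4 * H - 1)));
    c = fg % c + ig % gg;
    h = og % tanh(c);
    cc.I_.slice(t) = ig; cc.F.slice(t) = fg;
    cc.G_.slice(t) = gg; cc.O.slice(t) = og;
    cc.C.slice(t) = c; cc.H.slice(t) = h;
    mat r = clamp(h, 0.0, datum::inf);
    cc.Y.row(t) = wout.t() * r + bout;
  }
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube& inputs, const arma::mat& targets,
                          const arma::imat& batch_idx,
                          arma::mat Wih, arma::mat Whh,
                          arma::vec bih, arma::vec bhh,
                          arma::vec wout, double bout,
                          double lr = 1e-3, double beta1 = 0.9,
                          double beta2 = 0.999, double eps = 1e-8) {
  const uword I = inputs.n_rows, T = inputs.n_cols;
  const uword H = Whh.n_cols;
  const uword B = batch_idx.n_rows, n_iter = batch_idx.n_cols;

  mat mWih(size(Wih), fill::zeros), vWih(size(Wih), fill::zeros);
  mat mWhh(size(Whh), fill::zeros), vWhh(size(Whh), fill::zeros);
  mat bih_m(bih), bhh_m(bhh), wout_m(wout);
  mat mbih(size(bih_m), fill::zeros), vbih(size(bih_m), fill::zeros);
  mat mbhh(size(bhh_m), fill::zeros), vbhh(size(bhh_m), fill::zeros);
  mat mwout(size(wout_m), fill::zeros), vwout(size(wout_m), fill::zeros);
  mat bout_m(1, 1); bout_m(0, 0) = bout;
  mat mbout(1, 1, fill::zeros), vbout(1, 1, fill::zeros);

  vec loss_trace(n_iter);
  cube X(I, B, T);
  mat Tg(T, B);
  Cache cc;

  for (uword it = 0; it < n_iter; ++it) {
    for (uword b = 0; b < B; ++b) {
      uword s = (uword)(batch_idx(b, it) - 1);
      for (uword t = 0; t < T; ++t) X.slice(t).col(b) = inputs.slice(s).col(t);
      Tg.col(b) = targets.col(s);
    }
    forward_batch(X, Wih, Whh, vec(bih_m), vec(bhh_m), vec(wout_m),
                  bout_m(0, 0), cc);
    mat err = cc.Y - Tg;
    double loss = accu(err % err) / (double)(T * B);
    loss_trace(it) = loss;
    if (!std::isfinite(loss))
      Rcpp::stop("training loss diverged (non-finite) at iteration %d",
                 (int)(it + 1));

    // backward
    mat gWih(size(Wih), fill::zeros), gWhh(size(Whh), fill::zeros);
    mat gbih(size(bih_m), fill::zeros), gbhh(size(bhh_m), fill::zeros);
    mat gwout(size(wout_m), fill::zeros);
    double gbout = 0.0;
    mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
    const double scale = 2.0 / (double)(T * B);
    for (uword t = T; t-- > 0;) {
      rowvec dy = scale * err.row(t);
      const mat& h_t = cc.H.slice(t);
      mat r = clamp(h_t, 0.0, datum::inf);
      gwout += r * dy.t();
      gbout += accu(dy);
      dh += (wout_m * dy) % conv_to<mat>::from(h_t > 0);
      const mat& c_t = cc.C.slice(t);
      mat tc = tanh(c_t);
      const mat& og = cc.O.slice(t);
      mat do_ = dh % tc;
      dc += dh % og % (1.0 - tc % tc);
      mat cprev = (t > 0) ? cc.C.slice(t - 1) : mat(H, B, fill::zeros);
      mat hprev = (t > 0) ? cc.H.slice(t - 1) : mat(H, B, fill::zeros);
      const mat& ig = cc.I_.slice(t);
      const mat& fg = cc.F.slice(t);
      const mat& gg = cc.G_.slice(t);
      mat da(4 * H, B);
      da.rows(0, H - 1)         = (dc % gg) % ig % (1.0 - ig);
      da.rows(H, 2 * H - 1)     = (dc % cprev) % fg % (1.0 - fg);
      da.rows(2 * H, 3 * H - 1) = (dc % ig) % (1.0 - gg % gg);
      da.rows(3 * H, 4 * H - 1) = do_ % og % (1.0 - og);
      gWih += da * X.slice(t).t();
      gWhh += da * hprev.t();
      mat dasum = sum(da, 1);
      gbih += dasum;
      gbhh += dasum;
      dh = Whh.t() * da;
      dc = dc % fg;
    }

    const double b1t = std::pow(beta1, (double)(it + 1));
    const double b2t = std::pow(beta2, (double)(it + 1));
    adam_step(Wih, mWih, vWih, gWih, lr, beta1, beta2, eps, b1t, b2t);
    adam_step(Whh, mWhh, vWhh, gWhh, lr, beta1, beta2, eps, b1t, b2t);
    adam_step(bih_m, mbih, vbih, gbih, lr, beta1, beta2, eps, b1t, b2t);
    adam_step(bhh_m, mbhh, vbhh, gbhh, lr, beta1, beta2, eps, b1t, b2t);
    adam_step(wout_m, mwout, vwout, gwout, lr, beta1, beta2, eps, b1t, b2t);
    mat gb(1, 1); gb(0, 0) = gbout;
    adam_step(bout_m, mbout, vbout, gb, lr, beta1, beta2, eps, b1t, b2t);
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("Wih") = Wih, Rcpp::Named("Whh") = Whh,
    Rcpp::Named("bih") = vec(bih_m), Rcpp::Named("bhh") = vec(bhh_m),
    Rcpp::Named("wout") = vec(wout_m), Rcpp::Named("bout") = bout_m(0, 0),
    Rcpp::Named("loss_trace") = loss_trace);
}

// Forward pass over all sequences; returns outputs (T x N) and the LSTM
// hidden state h_t for every timestep (H x N x T).
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& inputs,
                            const arma::mat& Wih, const arma::mat& Whh,
                            const arma::vec& bih, const arma::vec& bhh,
                            const arma::vec& wout, double bout) {
  const uword I = inputs.n_rows, T = inputs.n_cols, N = inputs.n_slices;
  cube X(I, N, T);
  for (uword s = 0; s < N; ++s)
    for (uword t = 0; t < T; ++t) X.slice(t).col(s) = inputs.slice(s).col(t);
  Cache cc;
  forward_batch(X, Wih, Whh, bih, bhh, wout, bout, cc);
  return Rcpp::List::create(
    Rcpp::Named("outputs") = cc.Y,
    Rcpp::Named("hidden") = cc.H);
}
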