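// Stacked-LSTM forward pass, backpropagation through time and prediction.
//
// Single precision throughout: the reference training setup for this filter
// family runs in float32, and float halves memory traffic on the sgemm-bound
// inner loop.  Parameters live in R as double matrices and are converted at
// the call boundary; gradients are returned as doubles.
//
// Gate column layout in every weight matrix: [input | forget | candidate |
// output], each `units` wide.  Architecture is fixed to three stacked LSTM
// layers plus a single linear output unit; the many-to-one head reads the
// last hidden state, the many-to-many head reads every timestep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

inline fmat sigmoidf(const fmat &x) { return 1.0f / (1.0f + exp(-x)); }

struct LayerCache {
  fcube Gi, Gf, Gg, Go;  // gate activations, B x U x T
  fcube C, H, Tc;        // cell state, hidden state, tanh(cell state)
};

struct LayerParams {
  fmat W;     // input -> gates, D x 4U
  fmat U;     // hidden -> gates, U x 4U
  frowvec b;  // gate bias, 4U
};

LayerParams as_layer(const List &params, int idx) {
  LayerParams lp;
  lp.W = conv_to<fmat>::from(Rcpp::as<mat>(params[idx]));
  lp.U = conv_to<fmat>::from(Rcpp::as<mat>(params[idx + 1]));
  lp.b = conv_to<frowvec>::from(Rcpp::as<rowvec>(params[idx + 2]));
  return lp;
}

// Forward one layer over all timesteps, filling the cache.
void layer_forward(const LayerParams &p, const fcube &in, LayerCache &cc) {
  const uword B = in.n_rows, T = in.n_slices;
  const uword U = p.U.n_rows;
  cc.Gi.set_size(B, U, T); cc.Gf.set_size(B, U, T);
  cc.Gg.set_size(B, U, T); cc.Go.set_size(B, U, T);
  cc.C.set_size(B, U, T);  cc.H.set_size(B, U, T);
  cc.Tc.set_size(B, U, T);
  fmat h(B, U, fill::zeros), c(B, U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    fmat a = in.slice(t) * p.W + h * p.U;
    a.each_row() += p.b;
    fmat gi = sigmoidf(a.cols(0, U - 1));
    fmat gf = sigmoidf(a.cols(U, 2 * U - 1));
    fmat gg = tanh(a.cols(2 * U, 3 * U - 1));
    fmat go = sigmoidf(a.cols(3 * U, 4 * U - 1));
    c = gf % c + gi % gg;
    fmat tc = tanh(c);
    h = go % tc;
    cc.Gi.slice(t) = gi; cc.Gf.slice(t) = gf;
    cc.Gg.slice(t) = gg; cc.Go.slice(t) = go;
    cc.C.slice(t) = c;   cc.H.slice(t) = h; cc.Tc.slice(t) = tc;
  }
}

// BPTT through one layer.  dH_out holds the loss gradient w.r.t. the layer's
// hidden state coming from above (head or next layer); recurrent gradients
// are accumulated internally.  Returns gradient w.r.t. the layer input.
void layer_backward(const LayerParams &p, const fcube &in,
                    const LayerCache &cc, const fcube &dH_out,
                    fmat &dW, fmat &dU, frowvec &db, fcube &dIn) {
  const uword B = in.n_rows, T = in.n_slices;
  const uword U = p.U.n_rows;
  dW.zeros(p.W.n_rows, p.W.n_cols);
  dU.zeros(U, 4 * U);
  db.zeros(4 * U);
  dIn.set_size(B, in.n_cols, T);
  fmat dh_next(B, U, fill::zeros), dc_next(B, U, fill::zeros);
  fmat da(B, 4 * U);
  for (uword ti = T; ti-- > 0;) {
    fmat dh = dH_out.slice(ti) + dh_next;
    const fmat &tc = cc.Tc.slice(ti);
    const fmat &go = cc.Go.slice(ti);
    fmat dc = dc_next + dh % go % (1.0f - tc % tc);
    const fmat &gi = cc.Gi.slice(ti);
    const fmat &gf = cc.Gf.slice(ti);
    const fmat &gg = cc.Gg.slice(ti);
    fmat dgo = dh % tc;
    fmat dgi = dc % gg;
    fmat dgg = dc % gi;
    fmat dgf(B, U, fill::zeros);
    if (ti > 0) dgf = dc % cc.C.slice(ti - 1);
    dc_next = dc % gf;
    da.cols(0, U - 1)         = dgi % gi % (1.0f - gi);
    da.cols(U, 2 * U - 1)     = dgf % gf % (1.0f - gf);
    da.cols(2 * U, 3 * U - 1) = dgg % (1.0f - gg % gg);
    da.cols(3 * U, 4 * U - 1) = dgo % go % (1.0f - go);
    dW += in.slice(ti).t() * da;
    if (ti > 0) dU += cc.H.slice(ti - 1).t() * da;
    db += sum(da, 0);
    dIn.slice(ti) = da * p.W.t();
    dh_next = da * p.U.t();
  }
}

fcube apply_mask(const fcube &h, const fmat &mask, float keep) {
  fcube out(size(h));
  for (uword t = 0; t < h.n_slices; ++t)
    out.slice(t) = h.slice(t) % mask / keep;
  return out;
}

}  // namespace

//' @title One gradient step worth of forward + backward over a minibatch
//' @noRd
// [[Rcpp::export(name = ".lstm_batch_grad")]]
List lstm_batch_grad(List params, arma::mat X, arma::mat G,
                     std::string approach,
                     arma::mat mask1, arma::mat mask2, double dropout) {
  const uword B = X.n_rows, T = X.n_cols;
  LayerParams p1 = as_layer(params, 0);
  LayerParams p2 = as_layer(params, 3);
  LayerParams p3 = as_layer(params, 6);
  fmat Wd = conv_to<fmat>::from(Rcpp::as<mat>(params[9]));
  float bd = static_cast<float>(Rcpp::as<double>(params[10]));
  const uword U = p1.U.n_rows;
  const bool mtm = (approach == "mtm");
  const float keep = static_cast<float>(1.0 - dropout);
  const bool use_drop = dropout > 0.0;

  fcube in1(B, 1, T);
  for (uword t = 0; t < T; ++t)
    in1.slice(t) = conv_to<fmat>::from(X.col(t));

  LayerCache c1, c2, c3;
  layer_forward(p1, in1, c1);
  fmat m1, m2;
  fcube in2, in3;
  if (use_drop) {
    m1 = conv_to<fmat>::from(mask1);
    m2 = conv_to<fmat>::from(mask2);
    in2 = apply_mask(c1.H, m1, keep);
  } else {
    in2 = c1.H;
  }
  layer_forward(p2, in2, c2);
  in3 = use_drop ? apply_mask(c2.H, m2, keep) : c2.H;
  layer_forward(p3, in3, c3);

  // Linear head, loss and head gradients.
  double loss = 0.0;
  fcube dH3(B, U, T, fill::zeros);
  fmat dWd(U, 1, fill::zeros);
  float dbd = 0.0f;
  fmat Gf_ = conv_to<fmat>::from(G);
  if (mtm) {
    const float inv = 1.0f / static_cast<float>(B * T);
    for (uword t = 0; t < T; ++t) {
      fmat yhat = c3.H.slice(t) * Wd + bd;
      fmat resid = yhat - Gf_.col(t);
      loss += accu(square(resid));
      fmat dy = 2.0f * inv * resid;            // B x 1
      dH3.slice(t) = dy * Wd.t();
      dWd += c3.H.slice(t).t() * dy;
      dbd += accu(dy);
    }
    loss /= static_cast<double>(B * T);
  } else {
    fmat yhat = c3.H.slice(T - 1) * Wd + bd;   // B x 1
    fmat resid = yhat - Gf_;                   // G is B x 1
    loss = accu(square(resid)) / static_cast<double>(B);
    fmat dy = (2.0f / static_cast<float>(B)) * resid;
    dH3.slice(T - 1) = dy * Wd.t();
    dWd = c3.H.slice(T - 1).t() * dy;
    dbd = accu(dy);
  }

  fmat dW3, dU3, dW2, dU2, dW1, dU1;
  frowvec db3, db2, db1;
  fcube dIn3, dIn2, dIn1;
  layer_backward(p3, in3, c3, dH3, dW3, dU3, db3, dIn3);
  fcube dH2 = use_drop ? apply_mask(dIn3, m2, keep) : dIn3;
  layer_backward(p2, in2, c2, dH2, dW2, dU2, db2, dIn2);
  fcube dH1 = use_drop ? apply_mask(dIn2, m1, keep) : dIn2;
  layer_backward(p1, in1, c1, dH1, dW1, dU1, db1, dIn1);

  return List::create(
      Named("loss") = loss,
      Named("grads") = List::create(
          conv_to<mat>::from(dW1), conv_to<mat>::from(dU1),
          conv_to<rowvec>::from(db1),
          conv_to<mat>::from(dW2), conv_to<mat>::from(dU2),
          conv_to<rowvec>::from(db2),
          conv_to<mat>::from(dW3), conv_to<mat>::from(dU3),
          conv_to<rowvec>::from(db3),
          conv_to<mat>::from(dWd), static_cast<double>(dbd)));
}

//' @title Streamed forward pass (no caches) over a batch of windows
//' @noRd
// [[Rcpp::export(name = ".lstm_predict")]]
arma::mat lstm_predict_cpp(List params, arma::mat X, std::string approach) {
  const uword B = X.n_rows, T = X.n_cols;
  LayerParams lp[3] = {as_layer(params, 0), as_layer(params, 3),
                       as_layer(params, 6)};
  fmat Wd = conv_to<fmat>::from(Rcpp::as<mat>(params[9]));
  float bd = static_cast<float>(Rcpp::as<double>(params[10]));
  const uword U = lp[0].U.n_rows;
  const bool mtm = (approach == "mtm");

  fmat h[3], c[3];
  for (int l = 0; l < 3; ++l) {
    h[l].zeros(B, U);
    c[l].zeros(B, U);
  }
  fmat Xf = conv_to<fmat>::from(X);
  fmat out(B, mtm ? T : 1);
  for (uword t = 0; t < T; ++t) {
    fmat x = Xf.col(t);
    for (int l = 0; l < 3; ++l) {
      fmat a = x * lp[l].W + h[l] * lp[l].U;
      a.each_row() += lp[l].b;
      fmat gi = sigmoidf(a.cols(0, U - 1));
      fmat gf = sigmoidf(a.cols(U, 2 * U - 1));
      fmat gg = tanh(a.cols(2 * U, 3 * U - 1));
      fmat go = sigmoidf(a.cols(3 * U, 4 * U - 1));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % tanh(c[l]);
      x = h[l];
    }
    if (mtm) out.col(t) = h[2] * Wd + bd;
  }
  if (!mtm) out = h[2] * Wd + bd;
  return conv_to<mat>::from(out);
}
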