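// Native bidirectional recurrent sequence classifier.
//
// A two-layer bidirectional LSTM (or GRU) over batches of padded (x, y, z)
// sequences, with a per-frame linear head + logistic output and a masked
// binary cross-entropy objective.  Forward and full backpropagation through
// time are implemented here; the optimizer (Adam) lives on the R side and
// consumes the gradient list returned by cpp_rnn_run().  Analytic gradients
// are verified against finite differences in the test suite.
//
// Parameter list layout (names fixed, shared with R):
//   l{1,2}{f,b}_Wx  input-to-hidden weights   (I x 4H lstm / I x 3H gru)
//   l{1,2}{f,b}_Wh  hidden-to-hidden weights  (H x 4H lstm / H x 3H gru)
//   l{1,2}{f,b}_b   combined bias, LSTM only  (4H)
//   l{1,2}{f,b}_bi / _bh  input/hidden biases, GRU only (3H each; the hidden
//                   bias of the candidate gate sits inside the reset gate)
//   head_W (2H), head_b (scalar)
// Gate order: LSTM [i f g o], GRU [r z n] (both as used by common DL stacks).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ----------------------------------------------------------------- LSTM ----

static void lstm_dir_forward(const cube& X, const mat& Wx, const mat& Wh,
                             const rowvec& b, bool rev, cube& H, cube& G,
                             cube& C) {
  const arma::uword B = X.n_rows, T = X.n_slices, hid = Wh.n_rows;
  mat h(B, hid, arma::fill::zeros), c(B, hid, arma::fill::zeros);
  for (arma::uword k = 0; k < T; ++k) {
    arma::uword t = rev ? T - 1 - k : k;
    mat Z = X.slice(t) * Wx + h * Wh;
    Z.each_row() += b;
    mat i = sigm(Z.cols(0, hid - 1));
    mat f = sigm(Z.cols(hid, 2 * hid - 1));
    mat g = arma::tanh(Z.cols(2 * hid, 3 * hid - 1));
    mat o = sigm(Z.cols(3 * hid, 4 * hid - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    G.slice(t) = arma::join_rows(i, f, g, o);
    C.slice(t) = c;
    H.slice(t) = h;
  }
}

static void lstm_dir_backward(const cube& X, const mat& Wx, const mat& Wh,
                              bool rev, const cube& H, const cube& G,
                              const cube& C, const cube& dH, mat& dWx,
                              mat& dWh, rowvec& db, cube& dX) {
  const arma::uword B = X.n_rows, T = X.n_slices, hid = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * hid);
  mat dh_rec(B, hid, arma::fill::zeros), dc_rec(B, hid, arma::fill::zeros);
  for (arma::uword k = T; k-- > 0;) {
    arma::uword t = rev ? T - 1 - k : k;
    mat i = G.slice(t).cols(0, hid - 1);
    mat f = G.slice(t).cols(hid, 2 * hid - 1);
    mat g = G.slice(t).cols(2 * hid, 3 * hid - 1);
    mat o = G.slice(t).cols(3 * hid, 4 * hid - 1);
    mat c = C.slice(t);
    mat c_prev(B, hid, arma::fill::zeros), h_prev(B, hid, arma::fill::zeros);
    if (k > 0) {
      arma::uword tp = rev ? t + 1 : t - 1;
      c_prev = C.slice(tp);
      h_prev = H.slice(tp);
    }
    mat tc = arma::tanh(c);
    mat dh = dH.slice(t) + dh_rec;
    mat dc = dh % o % (1.0 - tc % tc) + dc_rec;
    mat dzi = dc % g % i % (1.0 - i);
    mat dzf = dc % c_prev % f % (1.0 - f);
    mat dzg = dc % i % (1.0 - g % g);
    mat dzo = dh % tc % o % (1.0 - o);
    dc_rec = dc % f;
    mat dZ = arma::join_rows(dzi, dzf, dzg, dzo);
    dWx += X.slice(t).t() * dZ;
    dWh += h_prev.t() * dZ;
    db += arma::sum(dZ, 0);
    dh_rec = dZ * Wh.t();
    dX.slice(t) += dZ * Wx.t();
  }
}

// ------------------------------------------------------------------ GRU ----

static void gru_dir_forward(const cube& X, const mat& Wx, const mat& Wh,
                            const rowvec& bi, const rowvec& bh, bool rev,
                            cube& H, cube& G, cube& HN) {
  const arma::uword B = X.n_rows, T = X.n_slices, hid = Wh.n_rows;
  mat h(B, hid, arma::fill::zeros);
  for (arma::uword k = 0; k < T; ++k) {
    arma::uword t = rev ? T - 1 - k : k;
    mat Zi = X.slice(t) * Wx;
    Zi.each_row() += bi;
    mat Zh = h * Wh;
    Zh.each_row() += bh;
    mat r = sigm(Zi.cols(0, hid - 1) + Zh.cols(0, hid - 1));
    mat z = sigm(Zi.cols(hid, 2 * hid - 1) + Zh.cols(hid, 2 * hid - 1));
    mat hn_lin = Zh.cols(2 * hid, 3 * hid - 1);
    mat n = arma::tanh(Zi.cols(2 * hid, 3 * hid - 1) + r % hn_lin);
    mat h_prev = h;
    h = (1.0 - z) % n + z % h_prev;
    G.slice(t) = arma::join_rows(r, z, n);
    HN.slice(t) = hn_lin;
    H.slice(t) = h;
  }
}

static void gru_dir_backward(const cube& X, const mat& Wx, const mat& Wh,
                             bool rev, const cube& H, const cube& G,
                             const cube& HN, const cube& dH, mat& dWx,
                             mat& dWh, rowvec& dbi, rowvec& dbh, cube& dX) {
  const arma::uword B = X.n_rows, T = X.n_slices, hid = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  dbi.zeros(3 * hid);
  dbh.zeros(3 * hid);
  mat dh_rec(B, hid, arma::fill::zeros);
  for (arma::uword k = T; k-- > 0;) {
    arma::uword t = rev ? T - 1 - k : k;
    mat r = G.slice(t).cols(0, hid - 1);
    mat z = G.slice(t).cols(hid, 2 * hid - 1);
    mat n = G.slice(t).cols(2 * hid, 3 * hid - 1);
    mat hn_lin = HN.slice(t);
    mat h_prev(B, hid, arma::fill::zeros);
    if (k > 0) {
      arma::uword tp = rev ? t + 1 : t - 1;
      h_prev = H.slice(tp);
    }
    mat dh = dH.slice(t) + dh_rec;
    mat dz = dh % (h_prev - n);
    mat dn = dh % (1.0 - z);
    mat dh_prev = dh % z;
    mat da_n = dn % (1.0 - n % n);
    mat da_hn = da_n % r;          // grad into (h_prev Wh_n + bh_n)
    mat dr = da_n % hn_lin;
    mat da_r = dr % r % (1.0 - r);
    mat da_z = dz % z % (1.0 - z);
    mat dZi = arma::join_rows(da_r, da_z, da_n);
    mat dZh = arma::join_rows(da_r, da_z, da_hn);
    dWx += X.slice(t).t() * dZi;
    dWh += h_prev.t() * dZh;
    dbi += arma::sum(dZi, 0);
    dbh += arma::sum(dZh, 0);
    dh_rec = dh_prev + dZh * Wh.t();
    dX.slice(t) += dZi * Wx.t();
  }
}

// ------------------------------------------------------------- network -----

struct DirParams {
  mat Wx, Wh;
  rowvec b, bi, bh;
};

static DirParams dir_params(const List& params, const std::string& pre,
                            bool gru) {
  DirParams p;
  p.Wx = as<mat>(params[pre + "_Wx"]);
  p.Wh = as<mat>(params[pre + "_Wh"]);
  if (gru) {
    p.bi = as<rowvec>(params[pre + "_bi"]);
    p.bh = as<rowvec>(params[pre + "_bh"]);
  } else {
    p.b = as<rowvec>(params[pre + "_b"]);
  }
  return p;
}

// one bidirectional layer forward; outputs B x 2H x T (fwd cols 0..H-1)
static void bidir_forward(const cube& X, const DirParams& pf,
                          const DirParams& pb, bool gru, cube& Hcat,
                          cube& Hf, cube& Hb, cube& Gf, cube& Gb, cube& Cf,
                          cube& Cb) {
  const arma::uword B = X.n_rows, T = X.n_slices, hid = pf.Wh.n_rows;
  Hf.set_size(B, hid, T);
  Hb.set_size(B, hid, T);
  if (gru) {
    Gf.set_size(B, 3 * hid, T);
    Gb.set_size(B, 3 * hid, T);
    Cf.set_size(B, hid, T); // candidate linear terms
    Cb.set_size(B, hid, T);
    gru_dir_forward(X, pf.Wx, pf.Wh, pf.bi, pf.bh, false, Hf, Gf, Cf);
    gru_dir_forward(X, pb.Wx, pb.Wh, pb.bi, pb.bh, true, Hb, Gb, Cb);
  } else {
    Gf.set_size(B, 4 * hid, T);
    Gb.set_size(B, 4 * hid, T);
    Cf.set_size(B, hid, T);
    Cb.set_size(B, hid, T);
    lstm_dir_forward(X, pf.Wx, pf.Wh, pf.b, false, Hf, Gf, Cf);
    lstm_dir_forward(X, pb.Wx, pb.Wh, pb.b, true, Hb, Gb, Cb);
  }
  Hcat.set_size(B, 2 * hid, T);
  for (arma::uword t = 0; t < T; ++t)
    Hcat.slice(t) = arma::join_rows(Hf.slice(t), Hb.slice(t));
}

// [[Rcpp::export]]
List cpp_rnn_run(List params, NumericVector x, NumericMatrix y,
                 NumericMatrix w, NumericVector dropmask,
                 std::string cell, bool training, bool want_grad) {
  const bool gru = (cell == "gru");
  IntegerVector xd = x.attr("dim");
  const arma::uword B = xd[0], I = xd[1], T = xd[2];
  const cube X(x.begin(), B, I, T, false);
  const mat Y(y.begin(), B, T, false);
  const mat M(w.begin(), B, T, false);

  DirParams l1f = dir_params(params, "l1f", gru);
  DirParams l1b = dir_params(params, "l1b", gru);
  DirParams l2f = dir_params(params, "l2f", gru);
  DirParams l2b = dir_params(params, "l2b", gru);
  vec headW = as<vec>(params["head_W"]);
  double headb = as<double>(params["head_b"]);
  const arma::uword hid = l1f.Wh.n_rows;

  cube H1, H1f, H1b, G1f, G1b, C1f, C1b;
  bidir_forward(X, l1f, l1b, gru, H1, H1f, H1b, G1f, G1b, C1f, C1b);

  // inter-layer dropout (mask pre-scaled by 1/(1-p) on the R side)
  cube D;
  if (training && dropmask.size() > 0) {
    D = cube(dropmask.begin(), B, 2 * hid, T, false);
    H1 %= D;
  }

  cube H2, H2f, H2b, G2f, G2b, C2f, C2b;
  bidir_forward(H1, l2f, l2b, gru, H2, H2f, H2b, G2f, G2b, C2f, C2b);

  mat logits(B, T);
  for (arma::uword t = 0; t < T; ++t)
    logits.col(t) = H2.slice(t) * headW + headb;
  mat P = sigm(logits);

  const double eps = 1e-7;
  mat Pc = arma::clamp(P, eps, 1.0 - eps);
  double msum = arma::accu(M);
  double loss = arma::accu(M % (-(Y % arma::log(Pc) +
                                  (1.0 - Y) % arma::log(1.0 - Pc)))) / msum;

  List out = List::create(_["probs"] = wrap(P), _["loss"] = loss);
  if (!want_grad) return out;

  // gradient of masked BCE wrt logits
  mat dlogits = M % (P - Y) / msum;

  vec d_headW(2 * hid, arma::fill::zeros);
  double d_headb = arma::accu(dlogits);
  cube dH2(B, 2 * hid, T);
  for (arma::uword t = 0; t < T; ++t) {
    d_headW += H2.slice(t).t() * dlogits.col(t);
    dH2.slice(t) = dlogits.col(t) * headW.t();
  }

  cube dH2f = dH2.cols(0, hid - 1);
  cube dH2b = dH2.cols(hid, 2 * hid - 1);
  cube dH1(B, 2 * hid, T, arma::fill::zeros);
  mat dWx2f, dWh2f, dWx2b, dWh2b, dWx1f, dWh1f, dWx1b, dWh1b;
  rowvec db2f, db2f_h, db2b, db2b_h, db1f, db1f_h, db1b, db1b_h;
  if (gru) {
    gru_dir_backward(H1, l2f.Wx, l2f.Wh, false, H2f, G2f, C2f, dH2f, dWx2f,
                     dWh2f, db2f, db2f_h, dH1);
    gru_dir_backward(H1, l2b.Wx, l2b.Wh, true, H2b, G2b, C2b, dH2b, dWx2b,
                     dWh2b, db2b, db2b_h, dH1);
  } else {
    lstm_dir_backward(H1, l2f.Wx, l2f.Wh, false, H2f, G2f, C2f, dH2f, dWx2f,
                      dWh2f, db2f, dH1);
    lstm_dir_backward(H1, l2b.Wx, l2b.Wh, true, H2b, G2b, C2b, dH2b, dWx2b,
                      dWh2b, db2b, dH1);
  }
  if (training && dropmask.size() > 0) dH1 %= D;

  cube dH1f = dH1.cols(0, hid - 1);
  cube dH1b = dH1.cols(hid, 2 * hid - 1);
  cube dX(B, I, T, arma::fill::zeros);
  if (gru) {
    gru_dir_backward(X, l1f.Wx, l1f.Wh, false, H1f, G1f, C1f, dH1f, dWx1f,
                     dWh1f, db1f, db1f_h, dX);
    gru_dir_backward(X, l1b.Wx, l1b.Wh, true, H1b, G1b, C1b, dH1b, dWx1b,
                     dWh1b, db1b, db1b_h, dX);
  } else {
    lstm_dir_backward(X, l1f.Wx, l1f.Wh, false, H1f, G1f, C1f, dH1f, dWx1f,
                      dWh1f, db1f, dX);
    lstm_dir_backward(X, l1b.Wx, l1b.Wh, true, H1b, G1b, C1b, dH1b, dWx1b,
                      dWh1b, db1b, dX);
  }

  List grads;
  if (gru) {
    grads = List::create(
        _["l1f_Wx"] = dWx1f, _["l1f_Wh"] = dWh1f,
        _["l1f_bi"] = NumericVector(db1f.begin(), db1f.end()),
        _["l1f_bh"] = NumericVector(db1f_h.begin(), db1f_h.end()),
        _["l1b_Wx"] = dWx1b, _["l1b_Wh"] = dWh1b,
        _["l1b_bi"] = NumericVector(db1b.begin(), db1b.end()),
        _["l1b_bh"] = NumericVector(db1b_h.begin(), db1b_h.end()),
        _["l2f_Wx"] = dWx2f, _["l2f_Wh"] = dWh2f,
        _["l2f_bi"] = NumericVector(db2f.begin(), db2f.end()),
        _["l2f_bh"] = NumericVector(db2f_h.begin(), db2f_h.end()),
        _["l2b_Wx"] = dWx2b, _["l2b_Wh"] = dWh2b,
        _["l2b_bi"] = NumericVector(db2b.begin(), db2b.end()),
        _["l2b_bh"] = NumericVector(db2b_h.begin(), db2b_h.end()),
        _["head_W"] = NumericVector(d_headW.begin(), d_headW.end()),
        _["head_b"] = d_headb);
  } else {
    grads = List::create(
        _["l1f_Wx"] = dWx1f, _["l1f_Wh"] = dWh1f,
        _["l1f_b"] = NumericVector(db1f.begin(), db1f.end()),
        _["l1b_Wx"] = dWx1b, _["l1b_Wh"] = dWh1b,
        _["l1b_b"] = NumericVector(db1b.begin(), db1b.end()),
        _["l2f_Wx"] = dWx2f, _["l2f_Wh"] = dWh2f,
        _["l2f_b"] = NumericVector(db2f.begin(), db2f.end()),
        _["l2b_Wx"] = dWx2b, _["l2b_Wh"] = dWh2b,
        _["l2b_b"] = NumericVector(db2b.begin(), db2b.end()),
        _["head_W"] = NumericVector(d_headW.begin(), d_headW.end()),
        _["head_b"] = d_headb);
  }
  out["grads"] = grads;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rnn_predict(List params, NumericVector x,
                              std::string cell) {
  IntegerVector xd = x.attr("dim");
  NumericMatrix y(xd[0], xd[2]), m(xd[0], xd[2]);
  std::fill(m.begin(), m.end(), 1.0);
  List res = cpp_rnn_run(params, x, y, m, NumericVector(0), cell, false,
                         false);
  return as<NumericMatrix>(res["probs"]);
}
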