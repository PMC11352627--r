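// Fused numerical kernels for the hot inner loops of the encoders:
// per-graph GCN propagation, grouped max pooling, and the batched
// scaled-dot-product attention core. Shapes follow the R-side tape ops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Block-diagonal propagation: rows of h are grouped into blocks of `sizes`
// rows; mats[i] is the (symmetric) support matrix of block i.
// [[Rcpp::export]]
arma::mat gcn_prop_fwd(const arma::mat& h, const List& mats, const IntegerVector& sizes) {
  arma::mat out(h.n_rows, h.n_cols);
  arma::uword off = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    arma::uword n = sizes[i];
    const arma::mat A = as<arma::mat>(mats[i]);
    out.rows(off, off + n - 1) = A * h.rows(off, off + n - 1);
    off += n;
  }
  return out;
}

// Column-wise max over each row block; also returns 1-based argmax row indices
// (into the stacked matrix) for the backward scatter.
// [[Rcpp::export]]
List group_max_fwd(const arma::mat& h, const IntegerVector& sizes) {
  int G = sizes.size();
  arma::mat val(G, h.n_cols);
  arma::umat arg(G, h.n_cols);
  arma::uword off = 0;
  for (int g = 0; g < G; ++g) {
    arma::uword n = sizes[g];
    for (arma::uword j = 0; j < h.n_cols; ++j) {
      arma::uword best = off;
      double bv = h(off, j);
      for (arma::uword r = off + 1; r < off + n; ++r) {
        if (h(r, j) > bv) { bv = h(r, j); best = r; }
      }
      val(g, j) = bv;
      arg(g, j) = best + 1;  // 1-based
    }
    off += n;
  }
  return List::create(_["value"] = val, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::mat group_max_bwd(const arma::mat& g, const arma::umat& argmax, int nrow) {
  arma::mat out(nrow, g.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < g.n_rows; ++i)
    for (arma::uword j = 0; j < g.n_cols; ++j)
      out(argmax(i, j) - 1, j) += g(i, j);
  return out;
}

// Attention core over nb blocks: q is (nb*lq) x (heads*dk), k is
// (nb*lk) x (heads*dk), v is (nb*lk) x (heads*dv). Per block and head:
// out = softmax(Q K^T / sqrt(dk)) V. Heads live in contiguous column slabs.
// Returns the stacked output and the softmax probabilities (for backward).
// [[Rcpp::export]]
List attn_fwd(const arma::mat& q, const arma::mat& k, const arma::mat& v,
              int nb, int lq, int lk, int heads, int dk, int dv) {
  double scale = 1.0 / std::sqrt((double)dk);
  arma::mat out(nb * lq, heads * dv);
  arma::cube probs(lq, lk, nb * heads);
  for (int b = 0; b < nb; ++b) {
    arma::uword q0 = (arma::uword)b * lq, k0 = (arma::uword)b * lk;
    for (int h = 0; h < heads; ++h) {
      arma::mat Q = q.submat(q0, h * dk, q0 + lq - 1, (h + 1) * dk - 1);
      arma::mat K = k.submat(k0, h * dk, k0 + lk - 1, (h + 1) * dk - 1);
      arma::mat V = v.submat(k0, h * dv, k0 + lk - 1, (h + 1) * dv - 1);
      arma::mat S = Q * K.t() * scale;
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      arma::vec rs = arma::sum(S, 1);
      S.each_col() /= rs;
      probs.slice(b * heads + h) = S;
      out.submat(q0, h * dv, q0 + lq - 1, (h + 1) * dv - 1) = S * V;
    }
  }
  return List::create(_["out"] = out, _["probs"] = probs);
}

// [[Rcpp::export]]
List attn_bwd(const arma::mat& gout, const arma::mat& q, const arma::mat& k,
              const arma::mat& v, const arma::cube& probs,
              int nb, int lq, int lk, int heads, int dk, int dv) {
  double scale = 1.0 / std::sqrt((double)dk);
  arma::mat gq(arma::size(q), arma::fill::zeros);
  arma::mat gk(arma::size(k), arma::fill::zeros);
  arma::mat gv(arma::size(v), arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    arma::uword q0 = (arma::uword)b * lq, k0 = (arma::uword)b * lk;
    for (int h = 0; h < heads; ++h) {
      arma::mat Q = q.submat(q0, h * dk, q0 + lq - 1, (h + 1) * dk - 1);
      arma::mat K = k.submat(k0, h * dk, k0 + lk - 1, (h + 1) * dk - 1);
      arma::mat V = v.submat(k0, h * dv, k0 + lk - 1, (h + 1) * dv - 1);
      const arma::mat& S = probs.slice(b * heads + h);
      arma::mat gO = gout.submat(q0, h * dv, q0 + lq - 1, (h + 1) * dv - 1);
      gv.submat(k0, h * dv, k0 + lk - 1, (h + 1) * dv - 1) += S.t() * gO;
      arma::mat gS = gO * V.t();
      arma::mat gZ = S % (gS.each_col() - arma::sum(gS % S, 1));
      gq.submat(q0, h * dk, q0 + lq - 1, (h + 1) * dk - 1) += gZ * K * scale;
      gk.submat(k0, h * dk, k0 + lk - 1, (h + 1) * dk - 1) += gZ.t() * Q * scale;
    }
  }
  return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv);
}

// ---- fused bidirectional LSTM ----------------------------------------------
// x: (nb*L) x C sequence-major (rows of sequence b are b*L .. b*L+L-1),
// padded at the end; lens gives true lengths. Gate order in the 4H columns of
// the weights: input, forget, output, cell. Returns the (nb*L) x 2H output
// (forward states in the first H columns, backward in the last H; padded rows
// zero) plus the saved activations needed for the backward sweep.

static void lstm_dir(const arma::mat& x, const IntegerVector& lens, int L,
                     const arma::mat& wx, const arma::mat& wh,
                     const arma::vec& b, bool reverse,
                     arma::cube& gates, arma::cube& cs, arma::cube& hs) {
  int nb = x.n_rows / L;
  int H = wh.n_rows;
  arma::mat h(nb, H, arma::fill::zeros), c(nb, H, arma::fill::zeros);
  arma::uvec rows(nb);
  for (int s = 0; s < L; ++s) {
    int t = reverse ? (L - 1 - s) : s;
    for (int bb = 0; bb < nb; ++bb) rows[bb] = (arma::uword)bb * L + t;
    arma::mat xt = x.rows(rows);
    arma::mat pre = xt * wx + h * wh;
    pre.each_row() += b.t();
    arma::mat ig = 1.0 / (1.0 + arma::exp(-pre.cols(0, H - 1)));
    arma::mat fg = 1.0 / (1.0 + arma::exp(-pre.cols(H, 2 * H - 1)));
    arma::mat og = 1.0 / (1.0 + arma::exp(-pre.cols(2 * H, 3 * H - 1)));
    arma::mat gg = arma::tanh(pre.cols(3 * H, 4 * H - 1));
    arma::mat cn = fg % c + ig % gg;
    arma::mat hn = og % arma::tanh(cn);
    for (int bb = 0; bb < nb; ++bb) {
      if (t >= lens[bb]) {  // padded position: carry state
        cn.row(bb) = c.row(bb);
        hn.row(bb) = h.row(bb);
        ig.row(bb).zeros(); fg.row(bb).zeros();
        og.row(bb).zeros(); gg.row(bb).zeros();
      }
    }
    gates.slice(s) = arma::join_rows(arma::join_rows(ig, fg),
                                     arma::join_rows(og, gg));
    cs.slice(s) = cn;
    hs.slice(s) = hn;
    h = hn; c = cn;
  }
}

// [[Rcpp::export]]
List bilstm_fwd(const arma::mat& x, const IntegerVector& lens, int L,
                const arma::mat& wxf, const arma::mat& whf, const arma::vec& bf,
                const arma::mat& wxb, const arma::mat& whb, const arma::vec& bb) {
  int nb = x.n_rows / L;
  int H = whf.n_rows;
  arma::cube gf(nb, 4 * H, L), cf(nb, H, L), hf(nb, H, L);
  arma::cube gb(nb, 4 * H, L), cb(nb, H, L), hb(nb, H, L);
  lstm_dir(x, lens, L, wxf, whf, bf, false, gf, cf, hf);
  lstm_dir(x, lens, L, wxb, whb, bb, true, gb, cb, hb);
  arma::mat out(x.n_rows, 2 * H, arma::fill::zeros);
  for (int s = 0; s < L; ++s) {
    for (int b2 = 0; b2 < nb; ++b2) {
      if (s < lens[b2]) {
        out.submat(b2 * L + s, 0, b2 * L + s, H - 1) = hf.slice(s).row(b2);
      }
      int t = L - 1 - s;  // backward direction processed step s at time t
      if (t < lens[b2]) {
        out.submat(b2 * L + t, H, b2 * L + t, 2 * H - 1) = hb.slice(s).row(b2);
      }
    }
  }
  return List::create(_["out"] = out, _["gf"] = gf, _["cf"] = cf, _["hf"] = hf,
                      _["gb"] = gb, _["cb"] = cb, _["hb"] = hb);
}

static void lstm_dir_bwd(const arma::mat& gout, const arma::mat& x,
                         const IntegerVector& lens, int L,
                         const arma::mat& wx, const arma::mat& wh,
                         bool reverse, int col0,
                         const arma::cube& gates, const arma::cube& cs,
                         const arma::cube& hs,
                         arma::mat& gx, arma::mat& gwx, arma::mat& gwh,
                         arma::vec& gb) {
  int nb = x.n_rows / L;
  int H = wh.n_rows;
  arma::mat dh(nb, H, arma::fill::zeros), dc(nb, H, arma::fill::zeros);
  arma::uvec rows(nb);
  for (int s = L - 1; s >= 0; --s) {
    int t = reverse ? (L - 1 - s) : s;
    for (int bb = 0; bb < nb; ++bb) rows[bb] = (arma::uword)bb * L + t;
    // incoming gradient from the output at this time position
    for (int bb = 0; bb < nb; ++bb) {
      if (t < lens[bb])
        dh.row(bb) += gout.submat(rows[bb], col0, rows[bb], col0 + H - 1);
    }
    arma::mat ig = gates.slice(s).cols(0, H - 1);
    arma::mat fg = gates.slice(s).cols(H, 2 * H - 1);
    arma::mat og = gates.slice(s).cols(2 * H, 3 * H - 1);
    arma::mat gg = gates.slice(s).cols(3 * H, 4 * H - 1);
    arma::mat cprev = (s == 0) ? arma::mat(nb, H, arma::fill::zeros)
                               : cs.slice(s - 1);
    arma::mat hprev = (s == 0) ? arma::mat(nb, H, arma::fill::zeros)
                               : hs.slice(s - 1);
    arma::mat tc = arma::tanh(cs.slice(s));
    arma::mat dcl = dc + dh % og % (1.0 - tc % tc);
    arma::mat dpre(nb, 4 * H);
    dpre.cols(0, H - 1) = dcl % gg % ig % (1.0 - ig);
    dpre.cols(H, 2 * H - 1) = dcl % cprev % fg % (1.0 - fg);
    dpre.cols(2 * H, 3 * H - 1) = dh % tc % og % (1.0 - og);
    dpre.cols(3 * H, 4 * H - 1) = dcl % ig % (1.0 - gg % gg);
    arma::mat dh_prev = dpre * wh.t();
    arma::mat dc_prev = dcl % fg;
    for (int bb = 0; bb < nb; ++bb) {
      if (t >= lens[bb]) {  // padded: state carried, gradients pass through
        dpre.row(bb).zeros();
        dh_prev.row(bb) = dh.row(bb);
        dc_prev.row(bb) = dc.row(bb);
      }
    }
    arma::mat xt = x.rows(rows);
    gwx += xt.t() * dpre;
    gwh += hprev.t() * dpre;
    gb += arma::sum(dpre, 0).t();
    arma::mat dxt = dpre * wx.t();
    for (int bb = 0; bb < nb; ++bb) gx.row(rows[bb]) += dxt.row(bb);
    dh = dh_prev;
    dc = dc_prev;
  }
}

// [[Rcpp::export]]
List bilstm_bwd(const arma::mat& gout, const arma::mat& x,
                const IntegerVector& lens, int L,
                const arma::mat& wxf, const arma::mat& whf, const arma::vec& bf,
                const arma::mat& wxb, const arma::mat& whb, const arma::vec& bb,
                const List& fw) {
  int H = whf.n_rows;
  arma::mat gx(x.n_rows, x.n_cols, arma::fill::zeros);
  arma::mat gwxf(arma::size(wxf), arma::fill::zeros);
  arma::mat gwhf(arma::size(whf), arma::fill::zeros);
  arma::vec gbf(4 * H, arma::fill::zeros);
  arma::mat gwxb(arma::size(wxb), arma::fill::zeros);
  arma::mat gwhb(arma::size(whb), arma::fill::zeros);
  arma::vec gbb(4 * H, arma::fill::zeros);
  lstm_dir_bwd(gout, x, lens, L, wxf, whf, false, 0,
               as<arma::cube>(fw["gf"]), as<arma::cube>(fw["cf"]),
               as<arma::cube>(fw["hf"]), gx, gwxf, gwhf, gbf);
  lstm_dir_bwd(gout, x, lens, L, wxb, whb, true, H,
               as<arma::cube>(fw["gb"]), as<arma::cube>(fw["cb"]),
               as<arma::cube>(fw["hb"]), gx, gwxb, gwhb, gbb);
  return List::create(_["gx"] = gx, _["gwxf"] = gwxf, _["gwhf"] = gwhf,
                      _["gbf"] = gbf, _["gwxb"] = gwxb, _["gwhb"] = gwhb,
                      _["gbb"] = gbb);
}
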