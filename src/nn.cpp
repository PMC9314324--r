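// Neural network core: 1D residual conv blocks -> (bi)GRU -> per-position
// fully connected layer -> per-sample softmax over 4 classes.
//
// Forward and backward passes are written out analytically (no autodiff is
// available); correctness is pinned down by finite-difference gradient
// checks in the test suite. Float32 arithmetic throughout.
//
// Layouts: conv activations are cubes (L, C, B) — time x channels x batch,
// one slice per batch element, so each convolution is an im2col + one GEMM
// per slice. The recurrent/FC tail uses flattened (C, L*B) matrices with
// column index t*B + b, so the input/output projections and the FC layer
// are single large GEMMs; only the hidden-to-hidden step is sequential.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

static fmat pget(const List& p, const std::string& nm) {
  return as<fmat>(p[nm]);
}
static fvec pgetv(const List& p, const std::string& nm) {
  return as<fvec>(p[nm]);
}

// ---------- convolution ----------

// im2col for "same" padded 1D convolution: col(l, c*K + k) = x(l + k - P, c)
static void im2col(const fmat& x, int K, fmat& col) {
  const int L = x.n_rows, C = x.n_cols, P = K / 2;
  col.zeros(L, C * K);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - P;
      const int lo = std::max(0, -shift);
      const int hi = std::min(L, L - shift);
      if (hi > lo) {
        col.submat(lo, c * K + k, hi - 1, c * K + k) =
            x.submat(lo + shift, c, hi - 1 + shift, c);
      }
    }
  }
}

static void col2im_add(const fmat& dcol, int K, fmat& dx) {
  const int L = dx.n_rows, C = dx.n_cols, P = K / 2;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - P;
      const int lo = std::max(0, -shift);
      const int hi = std::min(L, L - shift);
      if (hi > lo) {
        dx.submat(lo + shift, c, hi - 1 + shift, c) +=
            dcol.submat(lo, c * K + k, hi - 1, c * K + k);
      }
    }
  }
}

static void conv_fwd(const fcube& x, const fmat& W, const fvec& b, int K,
                     fcube& out, fmat& colbuf) {
  const int L = x.n_rows, B = x.n_slices, Cout = W.n_cols;
  out.set_size(L, Cout, B);
  for (int s = 0; s < B; ++s) {
    im2col(x.slice(s), K, colbuf);
    fmat o = colbuf * W;
    o.each_row() += b.t();
    out.slice(s) = o;
  }
}

static void conv_bwd(const fcube& x, const fmat& W, int K, const fcube& dout,
                     fcube& dx, fmat& dW, fvec& db, fmat& colbuf,
                     bool need_dx) {
  const int B = x.n_slices;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_cols);
  if (need_dx) dx.zeros(x.n_rows, x.n_cols, x.n_slices);
  for (int s = 0; s < B; ++s) {
    im2col(x.slice(s), K, colbuf);
    dW += colbuf.t() * dout.slice(s);
    db += arma::sum(dout.slice(s), 0).t();
    if (need_dx) {
      fmat dcol = dout.slice(s) * W.t();
      col2im_add(dcol, K, dx.slice(s));
    }
  }
}

// ---------- batch normalization (per channel over L x B) ----------

static void bn_fwd(fcube& a, const fvec& g, const fvec& bb, fvec& rm, fvec& rv,
                   bool training, fcube& xhat, fvec& istd) {
  const int L = a.n_rows, C = a.n_cols, B = a.n_slices;
  const double N = double(L) * double(B);
  xhat.set_size(L, C, B);
  istd.set_size(C);
  for (int c = 0; c < C; ++c) {
    float m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b) {
        const fvec col = a.slice(b).col(c);
        s += arma::accu(col);
        s2 += arma::dot(col, col);
      }
      m = float(s / N);
      double vv = s2 / N - double(m) * double(m);
      v = float(vv > 0 ? vv : 0);
      rm(c) = (1.0f - BN_MOM) * rm(c) + BN_MOM * m;
      rv(c) = (1.0f - BN_MOM) * rv(c) + BN_MOM * v;
    } else {
      m = rm(c);
      v = rv(c);
    }
    const float is = 1.0f / std::sqrt(v + BN_EPS);
    istd(c) = is;
    for (int b = 0; b < B; ++b) {
      fvec xh = (a.slice(b).col(c) - m) * is;
      xhat.slice(b).col(c) = xh;
      a.slice(b).col(c) = g(c) * xh + bb(c);
    }
  }
}

static void bn_bwd(const fcube& xhat, const fvec& g, const fvec& istd,
                   const fcube& dy, fcube& dx, fvec& dg, fvec& dbv) {
  const int L = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  const double N = double(L) * double(B);
  dx.set_size(L, C, B);
  dg.zeros(C);
  dbv.zeros(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int b = 0; b < B; ++b) {
      sdy += arma::accu(dy.slice(b).col(c));
      sdyx += arma::dot(dy.slice(b).col(c), xhat.slice(b).col(c));
    }
    dg(c) = float(sdyx);
    dbv(c) = float(sdy);
    const float mdy = float(sdy / N), mdyx = float(sdyx / N);
    const float scale = g(c) * istd(c);
    for (int b = 0; b < B; ++b) {
      dx.slice(b).col(c) =
          scale * (dy.slice(b).col(c) - mdy - xhat.slice(b).col(c) * mdyx);
    }
  }
}

// ---------- caches ----------

struct BlockCache {
  fcube xin, xhat1, r1, xhat2, out;
  fvec istd1, istd2;
};

struct GruCache {
  // processing-order slices (H x B), step s in 0..L-1
  fcube r, z, n, ghn, h;
  bool reverse;
};

// Flatten conv features (L, C, B) to (C, L*B) with column index t*B + b.
static void cube_to_flat(const fcube& F, fmat& X) {
  const int L = F.n_rows, C = F.n_cols, B = F.n_slices;
  X.set_size(C, size_t(L) * B);
  fmat Ft;
  for (int b = 0; b < B; ++b) {
    Ft = F.slice(b).t();   // (C, L), contiguous columns per time point
    for (int t = 0; t < L; ++t) X.col(size_t(t) * B + b) = Ft.col(t);
  }
}

static void flat_to_cube_add(const fmat& X, fcube& F) {
  const int L = F.n_rows, C = F.n_cols, B = F.n_slices;
  fmat Ft(C, L);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < L; ++t) Ft.col(t) = X.col(size_t(t) * B + b);
    F.slice(b) += Ft.t();
  }
}

// ---------- GRU (one direction) over flattened input ----------
// Xall: (C, L*B); Hcat: (Htot, L*B), rows [row0, row0+H) receive output.

static void gru_fwd(const fmat& Xall, int L, int B, const fmat& Wx,
                    const fmat& Wh, const fvec& bx, const fvec& bh, int H,
                    bool reverse, GruCache& gc, fmat& Hcat, int row0) {
  gc.reverse = reverse;
  gc.r.set_size(H, B, L);
  gc.z.set_size(H, B, L);
  gc.n.set_size(H, B, L);
  gc.ghn.set_size(H, B, L);
  gc.h.set_size(H, B, L);
  fmat GX = Wx * Xall;          // one large GEMM
  GX.each_col() += bx;
  fmat h(H, B, arma::fill::zeros);
  for (int s = 0; s < L; ++s) {
    const int tt = reverse ? (L - 1 - s) : s;
    const size_t c0 = size_t(tt) * B;
    fmat gx = GX.cols(c0, c0 + B - 1);
    fmat gh = Wh * h;
    gh.each_col() += bh;
    fmat r = 1.0f / (1.0f + arma::exp(-(gx.rows(0, H - 1) + gh.rows(0, H - 1))));
    fmat z = 1.0f / (1.0f + arma::exp(-(gx.rows(H, 2 * H - 1) + gh.rows(H, 2 * H - 1))));
    fmat ghn = gh.rows(2 * H, 3 * H - 1);
    fmat n = arma::tanh(gx.rows(2 * H, 3 * H - 1) + r % ghn);
    h = (1.0f - z) % n + z % h;
    gc.r.slice(s) = r;
    gc.z.slice(s) = z;
    gc.n.slice(s) = n;
    gc.ghn.slice(s) = ghn;
    gc.h.slice(s) = h;
    Hcat.submat(row0, c0, row0 + H - 1, c0 + B - 1) = h;
  }
}

static void gru_bwd(const fmat& Xall, int L, int B, const fmat& Wx,
                    const fmat& Wh, int H, const GruCache& gc,
                    const fmat& dHcat, int row0, fmat& dXall, fmat& dWx,
                    fmat& dWh, fvec& dbx, fvec& dbh) {
  fmat dGX(3 * H, size_t(L) * B);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  fmat carry(H, B, arma::fill::zeros);
  fmat dgh(3 * H, B);
  for (int s = L - 1; s >= 0; --s) {
    const int tt = gc.reverse ? (L - 1 - s) : s;
    const size_t c0 = size_t(tt) * B;
    fmat dh = carry + dHcat.submat(row0, c0, row0 + H - 1, c0 + B - 1);
    const fmat& r = gc.r.slice(s);
    const fmat& z = gc.z.slice(s);
    const fmat& n = gc.n.slice(s);
    const fmat& ghn = gc.ghn.slice(s);
    fmat hprev = (s > 0) ? gc.h.slice(s - 1) : fmat(H, B, arma::fill::zeros);
    fmat dzp = (dh % (hprev - n)) % z % (1.0f - z);
    fmat dnp = (dh % (1.0f - z)) % (1.0f - n % n);
    fmat drp = (dnp % ghn) % r % (1.0f - r);
    dGX.submat(0, c0, H - 1, c0 + B - 1) = drp;
    dGX.submat(H, c0, 2 * H - 1, c0 + B - 1) = dzp;
    dGX.submat(2 * H, c0, 3 * H - 1, c0 + B - 1) = dnp;
    dgh.rows(0, H - 1) = drp;
    dgh.rows(H, 2 * H - 1) = dzp;
    dgh.rows(2 * H, 3 * H - 1) = dnp % r;
    dWh += dgh * hprev.t();
    carry = dh % z + Wh.t() * dgh;
    if (s == L - 1) dbh.zeros(3 * H);
    dbh += arma::sum(dgh, 1);
  }
  dWx = dGX * Xall.t();          // one large GEMM
  dbx = arma::sum(dGX, 1);
  dXall += Wx.t() * dGX;         // one large GEMM
}

// Round doubles through float32: used when serializing checkpoints so that
// the decimal text round-trip (accurate to ~1 double ulp) cannot move any
// value across a float32 rounding boundary, keeping save -> load -> infer
// bit-identical.
// [[Rcpp::export]]
NumericVector to_float32_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = double(float(x[i]));
  return y;
}

// ---------- full network ----------

// [[Rcpp::export]]
List nn_run_cpp(List params, List state, NumericMatrix Xr,
                IntegerMatrix Yr, bool training, bool want_grads,
                bool want_probs, int kernel, IntegerVector channels,
                int hidden, bool bidir) {
  const int B = Xr.nrow(), L = Xr.ncol();
  const int nb = channels.size();
  const int K = kernel;
  const int H = hidden;
  const bool have_y = (Yr.nrow() == B && Yr.ncol() == L);
  const size_t NB = size_t(L) * B;

  fcube act(L, 1, B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l) act(l, 0, b) = float(Xr(b, l));

  fmat colbuf;
  std::vector<BlockCache> bc(nb);
  List new_state = clone(state);

  // ---- conv blocks forward ----
  for (int ib = 0; ib < nb; ++ib) {
    const std::string pre = "b" + std::to_string(ib + 1) + "_";
    const int Cin = (ib == 0) ? 1 : channels[ib - 1];
    const int Cout = channels[ib];
    BlockCache& c = bc[ib];
    c.xin = act;
    fmat W1 = pget(params, pre + "c1_W");
    fvec b1 = pgetv(params, pre + "c1_b");
    fcube a1;
    conv_fwd(c.xin, W1, b1, K, a1, colbuf);
    fvec g1 = pgetv(params, pre + "bn1_g"), be1 = pgetv(params, pre + "bn1_b");
    fvec rm1 = pgetv(state, pre + "bn1_rm"), rv1 = pgetv(state, pre + "bn1_rv");
    bn_fwd(a1, g1, be1, rm1, rv1, training, c.xhat1, c.istd1);
    if (training) {
      new_state[pre + "bn1_rm"] = rm1;
      new_state[pre + "bn1_rv"] = rv1;
    }
    c.r1 = arma::clamp(a1, 0.0f, std::numeric_limits<float>::max());
    fmat W2 = pget(params, pre + "c2_W");
    fvec b2 = pgetv(params, pre + "c2_b");
    fcube a2;
    conv_fwd(c.r1, W2, b2, K, a2, colbuf);
    fvec g2 = pgetv(params, pre + "bn2_g"), be2 = pgetv(params, pre + "bn2_b");
    fvec rm2 = pgetv(state, pre + "bn2_rm"), rv2 = pgetv(state, pre + "bn2_rv");
    bn_fwd(a2, g2, be2, rm2, rv2, training, c.xhat2, c.istd2);
    if (training) {
      new_state[pre + "bn2_rm"] = rm2;
      new_state[pre + "bn2_rv"] = rv2;
    }
    if (Cin != Cout) {
      fmat Wp = pget(params, pre + "proj_W");
      fvec bp = pgetv(params, pre + "proj_b");
      for (int b = 0; b < B; ++b) {
        fmat s = c.xin.slice(b) * Wp;
        s.each_row() += bp.t();
        a2.slice(b) += s;
      }
    } else {
      for (int b = 0; b < B; ++b) a2.slice(b) += c.xin.slice(b);
    }
    c.out = arma::clamp(a2, 0.0f, std::numeric_limits<float>::max());
    act = c.out;
  }

  // ---- GRU forward (flattened tail) ----
  const int Htot = bidir ? 2 * H : H;
  fmat Xall;
  cube_to_flat(act, Xall);
  fmat Hcat(Htot, NB);
  GruCache gfw, gbw;
  gru_fwd(Xall, L, B, pget(params, "gru_Wx"), pget(params, "gru_Wh"),
          pgetv(params, "gru_bx"), pgetv(params, "gru_bh"), H, false, gfw,
          Hcat, 0);
  if (bidir) {
    gru_fwd(Xall, L, B, pget(params, "gru2_Wx"), pget(params, "gru2_Wh"),
            pgetv(params, "gru2_bx"), pgetv(params, "gru2_bh"), H, true, gbw,
            Hcat, H);
  }

  // ---- FC + softmax ----
  fmat Wfc = pget(params, "fc_W");   // (Htot x nclass)
  fvec bfc = pgetv(params, "fc_b");
  const int NC = Wfc.n_cols;
  fmat probs = Wfc.t() * Hcat;       // (NC, L*B)
  probs.each_col() += bfc;
  probs.each_row() -= arma::max(probs, 0);
  probs = arma::exp(probs);
  probs.each_row() /= arma::sum(probs, 0);

  double loss = NA_REAL, acc = NA_REAL;
  List out;
  if (have_y) {
    double ls = 0.0;
    long correct = 0;
    for (int b = 0; b < B; ++b) {
      for (int l = 0; l < L; ++l) {
        const size_t cc = size_t(l) * B + b;
        const int y = Yr(b, l);
        ls -= std::log(std::max(probs(y, cc), 1e-12f));
        arma::uword am;
        probs.col(cc).max(am);
        if (int(am) == y) ++correct;
      }
    }
    loss = ls / double(NB);
    acc = double(correct) / double(NB);
  }

  if (want_grads && have_y) {
    const float inv = 1.0f / float(NB);
    fmat dlg = probs;
    for (int b = 0; b < B; ++b)
      for (int l = 0; l < L; ++l) dlg(Yr(b, l), size_t(l) * B + b) -= 1.0f;
    dlg *= inv;

    List grads;
    grads["fc_W"] = fmat(Hcat * dlg.t());
    grads["fc_b"] = fvec(arma::sum(dlg, 1));
    fmat dHcat = Wfc * dlg;    // (Htot, L*B)

    fmat dXall(act.n_cols, NB, arma::fill::zeros);
    {
      fmat dWx, dWh;
      fvec dbx, dbh;
      gru_bwd(Xall, L, B, pget(params, "gru_Wx"), pget(params, "gru_Wh"), H,
              gfw, dHcat, 0, dXall, dWx, dWh, dbx, dbh);
      grads["gru_Wx"] = dWx;
      grads["gru_Wh"] = dWh;
      grads["gru_bx"] = dbx;
      grads["gru_bh"] = dbh;
    }
    if (bidir) {
      fmat dWx, dWh;
      fvec dbx, dbh;
      gru_bwd(Xall, L, B, pget(params, "gru2_Wx"), pget(params, "gru2_Wh"), H,
              gbw, dHcat, H, dXall, dWx, dWh, dbx, dbh);
      grads["gru2_Wx"] = dWx;
      grads["gru2_Wh"] = dWh;
      grads["gru2_bx"] = dbx;
      grads["gru2_bh"] = dbh;
    }
    fcube dact(L, act.n_cols, B, arma::fill::zeros);
    flat_to_cube_add(dXall, dact);

    // conv blocks backward
    for (int ib = nb - 1; ib >= 0; --ib) {
      const std::string pre = "b" + std::to_string(ib + 1) + "_";
      const int Cin = (ib == 0) ? 1 : channels[ib - 1];
      const int Cout = channels[ib];
      BlockCache& c = bc[ib];
      fcube dsum = dact;
      for (int b = 0; b < B; ++b)
        dsum.slice(b) %= arma::conv_to<fmat>::from(c.out.slice(b) > 0);
      fcube dxin(L, Cin, B, arma::fill::zeros);
      if (Cin != Cout) {
        fmat Wp = pget(params, pre + "proj_W");
        fmat dWp(Cin, Cout, arma::fill::zeros);
        fvec dbp(Cout, arma::fill::zeros);
        for (int b = 0; b < B; ++b) {
          dWp += c.xin.slice(b).t() * dsum.slice(b);
          dbp += arma::sum(dsum.slice(b), 0).t();
          dxin.slice(b) += dsum.slice(b) * Wp.t();
        }
        grads[pre + "proj_W"] = dWp;
        grads[pre + "proj_b"] = dbp;
      } else {
        dxin += dsum;
      }
      fvec g2 = pgetv(params, pre + "bn2_g");
      fcube da2;
      fvec dg2, dbe2;
      bn_bwd(c.xhat2, g2, c.istd2, dsum, da2, dg2, dbe2);
      grads[pre + "bn2_g"] = dg2;
      grads[pre + "bn2_b"] = dbe2;
      fmat W2 = pget(params, pre + "c2_W");
      fcube dr1;
      fmat dW2;
      fvec db2;
      conv_bwd(c.r1, W2, K, da2, dr1, dW2, db2, colbuf, true);
      grads[pre + "c2_W"] = dW2;
      grads[pre + "c2_b"] = db2;
      for (int b = 0; b < B; ++b)
        dr1.slice(b) %= arma::conv_to<fmat>::from(c.r1.slice(b) > 0);
      fvec g1 = pgetv(params, pre + "bn1_g");
      fcube da1;
      fvec dg1, dbe1;
      bn_bwd(c.xhat1, g1, c.istd1, dr1, da1, dg1, dbe1);
      grads[pre + "bn1_g"] = dg1;
      grads[pre + "bn1_b"] = dbe1;
      fmat W1 = pget(params, pre + "c1_W");
      fcube dx1;
      fmat dW1;
      fvec db1;
      conv_bwd(c.xin, W1, K, da1, dx1, dW1, db1, colbuf, ib > 0);
      grads[pre + "c1_W"] = dW1;
      grads[pre + "c1_b"] = db1;
      if (ib > 0) dact = dxin + dx1;
    }
    out["grads"] = grads;
  }

  if (want_probs) {
    arma::cube pr(NC, L, B);
    for (int b = 0; b < B; ++b)
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < NC; ++k)
          pr(k, l, b) = double(probs(k, size_t(l) * B + b));
    out["probs"] = pr;
  }
  out["loss"] = loss;
  out["accuracy"] = acc;
  out["state"] = new_state;
  return out;
}
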