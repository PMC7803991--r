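// Graph convolutional regression network: forward pass, backpropagation and
// Adam training loop. Architecture per molecule:
//   [conv -> batchnorm -> ReLU -> neighbor max-pool] x L
//   -> atomwise dense (ReLU, dropout) -> sum-gather with tanh -> linear out
// Convolution: z_v = W_self' h_v + W_nbr' sum_{u in N(v)} h_u + b.
// Pooling: elementwise max over the closed neighborhood {v} u N(v).
// Atom states are stored one per column (feature dim x n_atoms) so that all
// per-atom operations touch contiguous memory. Single precision internally;
// the R interface is double.

#include <RcppArmadillo.h>
#include <algorithm>
#include <numeric>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr float BN_EPS = 1e-5f;
constexpr float BN_MOMENTUM = 0.9f;

struct GraphData {
  fmat X;                 // 75 x n_atoms
  uvec mol_ptr;           // n_mols + 1 atom offsets
  uvec nbr_ptr, nbr_idx;  // CSR adjacency over all atoms
  fvec y;                 // n_mols (may be empty for predict)
  uword n_mols() const { return mol_ptr.n_elem - 1; }
};

GraphData unpack_data(const Rcpp::NumericMatrix& X,
                      const Rcpp::IntegerVector& mol_ptr,
                      const Rcpp::IntegerMatrix& edges,
                      const Rcpp::NumericVector& y) {
  GraphData g;
  g.X = conv_to<fmat>::from(Rcpp::as<mat>(X)).t();  // transpose to dim x atoms
  g.mol_ptr = conv_to<uvec>::from(Rcpp::as<ivec>(mol_ptr));
  uword n_atoms = g.X.n_cols;
  uvec deg(n_atoms, fill::zeros);
  uword n_e = edges.nrow();
  for (uword k = 0; k < n_e; ++k) deg(edges(k, 0))++;
  g.nbr_ptr.set_size(n_atoms + 1);
  g.nbr_ptr(0) = 0;
  for (uword v = 0; v < n_atoms; ++v) g.nbr_ptr(v + 1) = g.nbr_ptr(v) + deg(v);
  g.nbr_idx.set_size(n_e);
  uvec cursor = g.nbr_ptr.head(n_atoms);
  for (uword k = 0; k < n_e; ++k) {
    uword s = edges(k, 0);
    g.nbr_idx(cursor(s)++) = edges(k, 1);
  }
  g.y = conv_to<fvec>::from(Rcpp::as<vec>(y));
  return g;
}

struct Params {
  std::vector<fmat> w;      // trainable tensors in fixed order
  std::vector<fmat> rstats; // running mean/var, 2 per conv layer
  uword n_conv;
  // order per conv layer l: w[5l]=Wself (din x dout), w[5l+1]=Wnbr,
  // w[5l+2]=b, w[5l+3]=gamma, w[5l+4]=beta (all 1 x dout);
  // then Wd (conv x dense), bd, wo (dense x 1), bo
  fmat& Wself(uword l) { return w[5 * l]; }
  fmat& Wnbr(uword l) { return w[5 * l + 1]; }
  fvec bconv(uword l) { return w[5 * l + 2].t(); }
  fvec gammav(uword l) { return w[5 * l + 3].t(); }
  fvec betav(uword l) { return w[5 * l + 4].t(); }
  fmat& Wd() { return w[5 * n_conv]; }
  fvec bd() { return w[5 * n_conv + 1].t(); }
  fmat& wo() { return w[5 * n_conv + 2]; }
  float bo() { return w[5 * n_conv + 3](0, 0); }
  fmat& rmean(uword l) { return rstats[2 * l]; }
  fmat& rvar(uword l) { return rstats[2 * l + 1]; }
};

Params unpack_params(const Rcpp::List& weights, const Rcpp::List& rstats,
                     int n_conv) {
  Params p;
  p.n_conv = n_conv;
  for (int i = 0; i < weights.size(); ++i)
    p.w.push_back(conv_to<fmat>::from(Rcpp::as<mat>(weights[i])));
  for (int i = 0; i < rstats.size(); ++i)
    p.rstats.push_back(conv_to<fmat>::from(Rcpp::as<mat>(rstats[i])));
  return p;
}

Rcpp::List pack_mats(const std::vector<fmat>& v) {
  Rcpp::List out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = Rcpp::wrap(conv_to<mat>::from(v[i]));
  return out;
}

// Column v of out = sum of columns of H over N(v).
fmat neighbor_sum(const fmat& H, const uvec& ptr, const uvec& idx) {
  fmat out(H.n_rows, H.n_cols, fill::zeros);
  for (uword v = 0; v < H.n_cols; ++v) {
    float* o = out.colptr(v);
    for (uword k = ptr(v); k < ptr(v + 1); ++k) {
      const float* h = H.colptr(idx(k));
      for (uword r = 0; r < H.n_rows; ++r) o[r] += h[r];
    }
  }
  return out;
}

struct LayerCache {
  fmat Hin, AH, xhat, relu_out;
  fvec invstd;
  umat argmax;
};

// One conv block. train=true uses batch statistics and updates running ones.
fmat conv_block(const fmat& H, Params& p, uword l, const uvec& ptr,
                const uvec& idx, bool train, LayerCache* cache) {
  fmat AH = neighbor_sum(H, ptr, idx);
  fmat Z = p.Wself(l).t() * H + p.Wnbr(l).t() * AH;
  Z.each_col() += p.bconv(l);
  fvec mu, var;
  if (train) {
    mu = mean(Z, 1);
    var = mean(square(Z), 1) - square(mu);
    var.elem(find(var < 0)).zeros();
    p.rmean(l) = BN_MOMENTUM * p.rmean(l) + (1 - BN_MOMENTUM) * fmat(mu.t());
    p.rvar(l) = BN_MOMENTUM * p.rvar(l) + (1 - BN_MOMENTUM) * fmat(var.t());
  } else {
    mu = p.rmean(l).t();
    var = p.rvar(l).t();
  }
  fvec invstd = 1.0f / sqrt(var + BN_EPS);
  fmat xhat = Z;
  xhat.each_col() -= mu;
  xhat.each_col() %= invstd;
  fmat Y = xhat;
  Y.each_col() %= p.gammav(l);
  Y.each_col() += p.betav(l);
  fmat R = Y;
  R.elem(find(R < 0)).zeros();
  // closed-neighborhood max pool over columns
  fmat P = R;
  umat amax(R.n_rows, R.n_cols);
  for (uword v = 0; v < R.n_cols; ++v) {
    uword* am = amax.colptr(v);
    float* pc = P.colptr(v);
    for (uword r = 0; r < R.n_rows; ++r) am[r] = v;
    for (uword k = ptr(v); k < ptr(v + 1); ++k) {
      uword u = idx(k);
      const float* rc = R.colptr(u);
      for (uword r = 0; r < R.n_rows; ++r) {
        if (rc[r] > pc[r]) { pc[r] = rc[r]; am[r] = u; }
      }
    }
  }
  if (cache) {
    cache->Hin = H; cache->AH = std::move(AH); cache->xhat = std::move(xhat);
    cache->relu_out = std::move(R); cache->invstd = std::move(invstd);
    cache->argmax = std::move(amax);
  }
  return P;
}

// Full forward pass; returns per-molecule predictions.
fvec forward(const fmat& X, Params& p, const uvec& mol_ptr, const uvec& ptr,
             const uvec& idx, bool train, const fmat* dropmask,
             std::vector<LayerCache>* caches, fmat* dense_pre,
             fmat* gathered, fmat* Hpool_out) {
  fmat H = X;
  for (uword l = 0; l < p.n_conv; ++l) {
    LayerCache* c = caches ? &((*caches)[l]) : nullptr;
    H = conv_block(H, p, l, ptr, idx, train, c);
  }
  if (Hpool_out) *Hpool_out = H;
  fmat Dpre = p.Wd().t() * H;
  Dpre.each_col() += p.bd();
  fmat Ddrop = Dpre;
  Ddrop.elem(find(Ddrop < 0)).zeros();
  if (train && dropmask) Ddrop %= *dropmask;
  uword n_mols = mol_ptr.n_elem - 1;
  fmat G(Ddrop.n_rows, n_mols);
  for (uword m = 0; m < n_mols; ++m) {
    G.col(m) = sum(Ddrop.cols(mol_ptr(m), mol_ptr(m + 1) - 1), 1);
  }
  G = tanh(G);
  fvec yhat = (p.wo().t() * G).t() + p.bo();
  if (dense_pre) *dense_pre = std::move(Dpre);
  if (gathered) *gathered = G;
  return yhat;
}

void eval_metrics(const fvec& y, const fvec& f, double& mae, double& r2,
                  double& trmae) {
  vec yd = conv_to<vec>::from(y), fd = conv_to<vec>::from(f);
  mae = mean(abs(fd - yd));
  double tss = accu(square(yd - mean(yd)));
  r2 = tss > 1e-12 ? 1.0 - accu(square(yd - fd)) / tss : datum::nan;
  trmae = (r2 - mae) + r2;
}

struct Adam {
  std::vector<fmat> m, v;
  long t = 0;
  void step(std::vector<fmat>& w, const std::vector<fmat>& g, float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < w.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * square(g[i]);
      w[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// Subgraph of one batch of molecules (local re-indexing). `g2l` is a
// reusable global->local scratch buffer of size n_atoms_total.
struct Batch {
  fmat X;
  uvec mol_ptr, ptr, idx;
  fvec y;
};

Batch make_batch(const GraphData& g, const std::vector<uword>& mols,
                 std::vector<uword>& g2l) {
  Batch b;
  uword n_atoms = 0, n_e = 0;
  for (uword m : mols) {
    n_atoms += g.mol_ptr(m + 1) - g.mol_ptr(m);
    n_e += g.nbr_ptr(g.mol_ptr(m + 1)) - g.nbr_ptr(g.mol_ptr(m));
  }
  b.X.set_size(g.X.n_rows, n_atoms);
  b.mol_ptr.set_size(mols.size() + 1);
  b.y.set_size(mols.size());
  b.ptr.set_size(n_atoms + 1);
  b.idx.set_size(n_e);
  uword a = 0;
  b.mol_ptr(0) = 0;
  for (size_t i = 0; i < mols.size(); ++i) {
    uword m = mols[i];
    uword lo = g.mol_ptr(m), hi = g.mol_ptr(m + 1);
    b.X.cols(a, a + (hi - lo) - 1) = g.X.cols(lo, hi - 1);
    for (uword v = lo; v < hi; ++v) g2l[v] = a++;
    b.mol_ptr(i + 1) = a;
    b.y(i) = g.y.n_elem ? g.y(m) : 0.0f;
  }
  uword e = 0;
  b.ptr(0) = 0;
  a = 0;
  for (size_t i = 0; i < mols.size(); ++i) {
    uword m = mols[i];
    for (uword v = g.mol_ptr(m); v < g.mol_ptr(m + 1); ++v) {
      for (uword k = g.nbr_ptr(v); k < g.nbr_ptr(v + 1); ++k)
        b.idx(e++) = g2l[g.nbr_idx(k)];
      b.ptr(++a) = e;
    }
  }
  return b;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_gcn_init(int n_in, int n_conv, int conv_size, int dense_size,
                        int seed) {
  std::mt19937_64 rng(seed);
  auto glorot = [&](uword r, uword c) {
    float lim = std::sqrt(6.0f / (r + c));
    std::uniform_real_distribution<float> u(-lim, lim);
    fmat m(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) m(i, j) = u(rng);
    return m;
  };
  std::vector<fmat> w, rstats;
  uword in = n_in;
  for (int l = 0; l < n_conv; ++l) {
    w.push_back(glorot(in, conv_size));
    w.push_back(glorot(in, conv_size));
    w.push_back(fmat(1, conv_size, fill::zeros));  // b
    w.push_back(fmat(1, conv_size, fill::ones));   // gamma
    w.push_back(fmat(1, conv_size, fill::zeros));  // beta
    rstats.push_back(fmat(1, conv_size, fill::zeros));
    rstats.push_back(fmat(1, conv_size, fill::ones));
    in = conv_size;
  }
  w.push_back(glorot(conv_size, dense_size));
  w.push_back(fmat(1, dense_size, fill::zeros));
  w.push_back(glorot(dense_size, 1));
  w.push_back(fmat(1, 1, fill::zeros));
  return Rcpp::List::create(Rcpp::Named("weights") = pack_mats(w),
                            Rcpp::Named("rstats") = pack_mats(rstats));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gcn_predict(const Rcpp::List& weights,
                                    const Rcpp::List& rstats, int n_conv,
                                    const Rcpp::NumericMatrix& X,
                                    const Rcpp::IntegerVector& mol_ptr,
                                    const Rcpp::IntegerMatrix& edges) {
  Params p = unpack_params(weights, rstats, n_conv);
  GraphData g = unpack_data(X, mol_ptr, edges,
                            Rcpp::NumericVector(mol_ptr.size() - 1));
  fvec yhat = forward(g.X, p, g.mol_ptr, g.nbr_ptr, g.nbr_idx, false,
                      nullptr, nullptr, nullptr, nullptr, nullptr);
  return Rcpp::wrap(conv_to<vec>::from(yhat));
}

// [[Rcpp::export]]
Rcpp::List cpp_gcn_train(const Rcpp::List& weights, const Rcpp::List& rstats,
                         Rcpp::Nullable<Rcpp::List> opt_state, int n_conv,
                         const Rcpp::NumericMatrix& X,
                         const Rcpp::IntegerVector& mol_ptr,
                         const Rcpp::IntegerMatrix& edges,
                         const Rcpp::NumericVector& y,
                         const Rcpp::NumericMatrix& Xv,
                         const Rcpp::IntegerVector& mol_ptrv,
                         const Rcpp::IntegerMatrix& edgesv,
                         const Rcpp::NumericVector& yv, double lr,
                         double dropout, int batch_size, int n_epochs,
                         int seed) {
  Params p = unpack_params(weights, rstats, n_conv);
  GraphData tr = unpack_data(X, mol_ptr, edges, y);
  GraphData va = unpack_data(Xv, mol_ptrv, edgesv, yv);
  uword n_mols = tr.n_mols();

  Adam adam;
  if (opt_state.isNotNull()) {
    Rcpp::List os(opt_state);
    Rcpp::List m = os["m"], v = os["v"];
    for (int i = 0; i < m.size(); ++i) {
      adam.m.push_back(conv_to<fmat>::from(Rcpp::as<mat>(m[i])));
      adam.v.push_back(conv_to<fmat>::from(Rcpp::as<mat>(v[i])));
    }
    adam.t = (long)Rcpp::as<double>(os["t"]);
  } else {
    for (auto& wi : p.w) {
      adam.m.push_back(fmat(size(wi), fill::zeros));
      adam.v.push_back(fmat(size(wi), fill::zeros));
    }
  }

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  std::vector<uword> order(n_mols);
  std::iota(order.begin(), order.end(), 0);
  std::vector<uword> g2l(tr.X.n_cols);

  Rcpp::NumericVector v_mae(n_epochs), v_r2(n_epochs), v_trmae(n_epochs);
  std::vector<fmat> best_w, best_rs;
  double best_trmae = -datum::inf;
  int best_epoch = -1;
  bool diverged = false;
  std::vector<LayerCache> caches(n_conv);

  for (int ep = 0; ep < n_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < n_mols; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, n_mols);
      std::vector<uword> mols(order.begin() + start, order.begin() + stop);
      Batch b = make_batch(tr, mols, g2l);

      fmat dropmask;
      if (dropout > 0) {
        dropmask.set_size(p.Wd().n_cols, b.X.n_cols);
        float keep = 1.0f - (float)dropout;
        for (uword j = 0; j < dropmask.n_cols; ++j)
          for (uword i = 0; i < dropmask.n_rows; ++i)
            dropmask(i, j) = unif(rng) < keep ? 1.0f / keep : 0.0f;
      }
      fmat Dpre, G, Hpool;
      fvec yhat = forward(b.X, p, b.mol_ptr, b.ptr, b.idx, true,
                          dropout > 0 ? &dropmask : nullptr, &caches, &Dpre,
                          &G, &Hpool);
      if (!yhat.is_finite()) { diverged = true; break; }

      // ---- backward ----
      uword M = b.mol_ptr.n_elem - 1, Na = b.X.n_cols;
      fvec dyhat = 2.0f * (yhat - b.y) / (float)M;
      std::vector<fmat> grad(p.w.size());
      grad[5 * n_conv + 2] = G * dyhat;                            // wo
      grad[5 * n_conv + 3] = fmat(1, 1, fill::value(accu(dyhat))); // bo
      fmat dG = p.wo() * dyhat.t();                                // D x M
      fmat dS = dG % (1.0f - square(G));
      fmat dDdrop(dS.n_rows, Na);
      for (uword m = 0; m < M; ++m)
        dDdrop.cols(b.mol_ptr(m), b.mol_ptr(m + 1) - 1) =
            repmat(dS.col(m), 1, b.mol_ptr(m + 1) - b.mol_ptr(m));
      if (dropout > 0) dDdrop %= dropmask;
      fmat relu_mask = conv_to<fmat>::from(Dpre > 0);
      fmat dDpre = dDdrop % relu_mask;
      grad[5 * n_conv] = Hpool * dDpre.t();                        // Wd
      grad[5 * n_conv + 1] = sum(dDpre, 1).t();                    // bd
      fmat dH = p.Wd() * dDpre;

      for (int l = n_conv - 1; l >= 0; --l) {
        LayerCache& c = caches[l];
        // pool backward (scatter to argmax source)
        fmat dR(size(c.relu_out), fill::zeros);
        for (uword vtx = 0; vtx < Na; ++vtx) {
          const float* dcol = dH.colptr(vtx);
          const uword* am = c.argmax.colptr(vtx);
          for (uword r = 0; r < dH.n_rows; ++r) dR(r, am[r]) += dcol[r];
        }
        // relu backward
        dR %= conv_to<fmat>::from(c.relu_out > 0);
        // batchnorm backward
        fvec gam = p.gammav(l);
        grad[5 * l + 3] = sum(dR % c.xhat, 1).t();  // gamma
        grad[5 * l + 4] = sum(dR, 1).t();           // beta
        fmat dxhat = dR;
        dxhat.each_col() %= gam;
        fvec sum_dx = sum(dxhat, 1);
        fvec sum_dxx = sum(dxhat % c.xhat, 1);
        fmat dZ = dxhat * (float)Na;
        dZ.each_col() -= sum_dx;
        fmat xs = c.xhat;
        xs.each_col() %= sum_dxx;
        dZ -= xs;
        dZ.each_col() %= c.invstd / (float)Na;
        grad[5 * l] = c.Hin * dZ.t();               // Wself
        grad[5 * l + 1] = c.AH * dZ.t();            // Wnbr
        grad[5 * l + 2] = sum(dZ, 1).t();           // b
        if (l > 0) {
          dH = p.Wself(l) * dZ +
               neighbor_sum(p.Wnbr(l) * dZ, b.ptr, b.idx);
        }
      }
      adam.step(p.w, grad, (float)lr);
    }
    if (diverged) break;

    // validation metrics in eval mode
    fvec fv = forward(va.X, p, va.mol_ptr, va.nbr_ptr, va.nbr_idx, false,
                      nullptr, nullptr, nullptr, nullptr, nullptr);
    double mae, r2, trmae;
    eval_metrics(va.y, fv, mae, r2, trmae);
    v_mae[ep] = mae; v_r2[ep] = r2; v_trmae[ep] = trmae;
    if (std::isfinite(trmae) && trmae > best_trmae) {
      best_trmae = trmae;
      best_epoch = ep + 1;  // 1-based within this call
      best_w = p.w;
      best_rs = p.rstats;
    }
  }

  Rcpp::List opt = Rcpp::List::create(
      Rcpp::Named("m") = pack_mats(adam.m),
      Rcpp::Named("v") = pack_mats(adam.v),
      Rcpp::Named("t") = (double)adam.t);
  return Rcpp::List::create(
      Rcpp::Named("weights") = pack_mats(p.w),
      Rcpp::Named("rstats") = pack_mats(p.rstats),
      Rcpp::Named("opt") = opt,
      Rcpp::Named("val_mae") = v_mae, Rcpp::Named("val_r2") = v_r2,
      Rcpp::Named("val_trmae") = v_trmae,
      Rcpp::Named("best_weights") =
          best_epoch > 0 ? pack_mats(best_w) : Rcpp::List(),
      Rcpp::Named("best_rstats") =
          best_epoch > 0 ? pack_mats(best_rs) : Rcpp::List(),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_trmae") = best_trmae,
      Rcpp::Named("diverged") = diverged);
}
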