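// Batched peephole-LSTM kernels: stacked-layer rollout, softmax head and
// full backpropagation through time. Gate rows are stacked as
// [input; forget; output; candidate], matching the R-level layout.
// X enters as a (channels x time x batch) cube and is repacked so each
// time step is one contiguous (channels x batch) slice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LayerCache {
  mat in_mat;                  // (in, B*T) layer input, step-major
  cube I, F, O, g, c, tc, hs;  // (H, B, T)
};

struct LayerParams {
  mat W, U;
  vec b, vI, vF, vO;
};

static std::vector<LayerParams> unpack_layers(const List& layers) {
  std::vector<LayerParams> out;
  for (R_xlen_t j = 0; j < layers.size(); ++j) {
    List P = layers[j];
    LayerParams lp;
    lp.W = Rcpp::as<mat>(P["W"]);
    lp.U = Rcpp::as<mat>(P["U"]);
    lp.b = Rcpp::as<vec>(P["b"]);
    lp.vI = Rcpp::as<vec>(P["vI"]);
    lp.vF = Rcpp::as<vec>(P["vF"]);
    lp.vO = Rcpp::as<vec>(P["vO"]);
    out.push_back(lp);
  }
  return out;
}

// repack (in, T, B) -> (in, B, T)
static cube step_major(const cube& X) {
  const uword in = X.n_rows, T = X.n_cols, B = X.n_slices;
  cube out(in, B, T);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < T; ++t)
      out.slice(t).col(b) = X.slice(b).col(t);
  return out;
}

static mat rollout(const std::vector<LayerParams>& ps, const cube& Xs,
                   std::vector<LayerCache>* caches) {
  const uword B = Xs.n_cols, T = Xs.n_slices;
  cube input = Xs;
  mat h_final;
  for (size_t j = 0; j < ps.size(); ++j) {
    const LayerParams& P = ps[j];
    const uword H = P.b.n_elem / 4;
    const uword in = input.n_rows;
    mat in_mat(const_cast<double*>(input.memptr()), in, B * T, true, false);
    mat Wx = P.W * in_mat;
    Wx.each_col() += P.b;
    mat h(H, B, fill::zeros), c(H, B, fill::zeros);
    cube I(H, B, T), F(H, B, T), O(H, B, T), g(H, B, T), cc(H, B, T),
        tc(H, B, T), hs(H, B, T);
    for (uword t = 0; t < T; ++t) {
      mat a = Wx.cols(t * B, (t + 1) * B - 1) + P.U * h;
      mat It = sigmoid(a.rows(0, H - 1) + c.each_col() % P.vI);
      mat Ft = sigmoid(a.rows(H, 2 * H - 1) + c.each_col() % P.vF);
      mat gt = tanh(a.rows(3 * H, 4 * H - 1));
      c = Ft % c + It % gt;
      mat Ot = sigmoid(a.rows(2 * H, 3 * H - 1) + c.each_col() % P.vO);
      mat tct = tanh(c);
      h = Ot % tct;
      I.slice(t) = It; F.slice(t) = Ft; O.slice(t) = Ot; g.slice(t) = gt;
      cc.slice(t) = c; tc.slice(t) = tct; hs.slice(t) = h;
    }
    if (caches) {
      LayerCache lc;
      lc.in_mat = in_mat;
      lc.I = I; lc.F = F; lc.O = O; lc.g = g; lc.c = cc; lc.tc = tc;
      lc.hs = hs;
      (*caches).push_back(std::move(lc));
    }
    h_final = h;
    input = hs;
  }
  return h_final;
}

static mat softmax_cols_cpp(mat z) {
  z.each_row() -= max(z, 0);
  mat e = exp(z);
  e.each_row() /= sum(e, 0);
  return e;
}

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
arma::mat lstm_forward_cpp(List layers, const arma::mat& headW,
                           const arma::vec& headb, const arma::cube& X) {
  std::vector<LayerParams> ps = unpack_layers(layers);
  cube Xs = step_major(X);
  mat h_final = rollout(ps, Xs, nullptr);
  mat logits = headW * h_final;
  logits.each_col() += headb;
  return softmax_cols_cpp(logits);
}

// [[Rcpp::export(name = ".lstm_loss_grads_cpp")]]
List lstm_loss_grads_cpp(List layers, const arma::mat& headW,
                         const arma::vec& headb, const arma::cube& X,
                         const arma::uvec& y) {
  std::vector<LayerParams> ps = unpack_layers(layers);
  const uword B = X.n_slices, T = X.n_cols;
  cube Xs = step_major(X);
  std::vector<LayerCache> caches;
  caches.reserve(ps.size());
  mat h_final = rollout(ps, Xs, &caches);

  mat logits = headW * h_final;
  logits.each_col() += headb;
  mat probs = softmax_cols_cpp(logits);
  double loss = 0.0;
  mat dlogits = probs;
  for (uword b = 0; b < B; ++b) {
    const uword cls = y(b) - 1;
    loss -= std::log(std::max(probs(cls, b), 1e-300));
    dlogits(cls, b) -= 1.0;
  }
  loss /= B;
  dlogits /= B;

  List grads;
  grads["head.W"] = dlogits * h_final.t();
  grads["head.b"] = vec(sum(dlogits, 1));
  mat dh_final = headW.t() * dlogits;

  cube dx_above;            // (in_above = H, B, T)
  for (int j = ps.size() - 1; j >= 0; --j) {
    const LayerParams& P = ps[j];
    const LayerCache& lc = caches[j];
    const uword H = P.b.n_elem / 4;
    const bool top = (size_t)j == ps.size() - 1;
    mat Ut = P.U.t();
    mat da_all(4 * H, B * T);
    mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dh_t = dh;
      if (top) {
        if ((uword)t == T - 1) dh_t += dh_final;
      } else {
        dh_t += dx_above.slice(t);
      }
      const mat& I = lc.I.slice(t);
      const mat& F = lc.F.slice(t);
      const mat& O = lc.O.slice(t);
      const mat& g = lc.g.slice(t);
      const mat& tc = lc.tc.slice(t);
      mat c_prev = (t > 0) ? lc.c.slice(t - 1) : mat(H, B, fill::zeros);
      mat dO = dh_t % tc;
      mat daO = dO % O % (1.0 - O);
      mat dc_t = dh_t % O % (1.0 - tc % tc) + dc + daO.each_col() % P.vO;
      mat daI = dc_t % g % I % (1.0 - I);
      mat daF = dc_t % c_prev % F % (1.0 - F);
      mat daC = dc_t % I % (1.0 - g % g);
      da_all.submat(0, t * B, H - 1, (t + 1) * B - 1) = daI;
      da_all.submat(H, t * B, 2 * H - 1, (t + 1) * B - 1) = daF;
      da_all.submat(2 * H, t * B, 3 * H - 1, (t + 1) * B - 1) = daO;
      da_all.submat(3 * H, t * B, 4 * H - 1, (t + 1) * B - 1) = daC;
      dh = Ut * join_cols(daI, daF, daO, daC);
      dc = dc_t % F + daI.each_col() % P.vI + daF.each_col() % P.vF;
    }
    // previous-step h and c over all steps (zeros at t = 0)
    mat hprev(H, B * T, fill::zeros), cprev(H, B * T, fill::zeros);
    for (uword t = 1; t < T; ++t) {
      hprev.cols(t * B, (t + 1) * B - 1) = lc.hs.slice(t - 1);
      cprev.cols(t * B, (t + 1) * B - 1) = lc.c.slice(t - 1);
    }
    mat c_all(const_cast<double*>(lc.c.memptr()), H, B * T, false, false);
    const std::string pre = "L" + std::to_string(j + 1) + ".";
    grads[pre + "W"] = da_all * lc.in_mat.t();
    grads[pre + "U"] = da_all * hprev.t();
    grads[pre + "b"] = vec(sum(da_all, 1));
    grads[pre + "vI"] = vec(sum(da_all.rows(0, H - 1) % cprev, 1));
    grads[pre + "vF"] = vec(sum(da_all.rows(H, 2 * H - 1) % cprev, 1));
    grads[pre + "vO"] = vec(sum(da_all.rows(2 * H, 3 * H - 1) % c_all, 1));
    if (j > 0) {
      mat dx = P.W.t() * da_all;     // (in, B*T)
      dx_above = cube(dx.memptr(), dx.n_rows, B, T);
    }
  }
  return List::create(Named("loss") = loss, Named("probs") = probs,
                      Named("grads") = grads);
}
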