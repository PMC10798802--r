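// Minimal dense-network trainer for the expanded-data likelihood losses.
// Two hidden ReLU layers, linear output h, Adam optimiser, minibatch SGD,
// early stopping on a validation loss with best-weights restoration.
//
// loss_type 0: per-row  exp(clip(h)) * width - h * delta   (discretised
//              negative log likelihood; rows are expanded-table rows)
// loss_type 1: per-row  (h - target)^2                     (L2 baseline;
//              `delta` carries the target, `width` is ignored)

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat W1, W2;
  rowvec b1, b2;
  vec w3;
  double b3;
};

void forward(const Params& p, const mat& X, mat& H1, mat& H2, vec& h) {
  H1 = X * p.W1;
  H1.each_row() += p.b1;
  H1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  H2 = H1 * p.W2;
  H2.each_row() += p.b2;
  H2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  h = H2 * p.w3 + p.b3;
}

// Row losses and d(loss)/dh in place.
void row_loss_grad(int loss_type, const vec& h, const vec& width,
                   const vec& delta, double clo, double chi,
                   vec& loss, vec& grad) {
  const uword n = h.n_elem;
  loss.set_size(n);
  grad.set_size(n);
  if (loss_type == 0) {
    for (uword k = 0; k < n; ++k) {
      double hc = h[k] < clo ? clo : (h[k] > chi ? chi : h[k]);
      double eh = std::exp(hc) * width[k];
      loss[k] = eh - h[k] * delta[k];
      grad[k] = (h[k] > clo && h[k] < chi ? eh : 0.0) - delta[k];
    }
  } else {
    for (uword k = 0; k < n; ++k) {
      double r = h[k] - delta[k];
      loss[k] = r * r;
      grad[k] = 2.0 * r;
    }
  }
}

double total_loss(const Params& p, int loss_type, const mat& X,
                  const vec& width, const vec& delta, double clo, double chi) {
  // Chunked full-data evaluation to bound memory.
  const uword n = X.n_rows, chunk = 65536;
  double acc = 0.0;
  mat H1, H2;
  vec h, l, g;
  for (uword s = 0; s < n; s += chunk) {
    uword e = std::min(s + chunk, n) - 1;
    forward(p, X.rows(s, e), H1, H2, h);
    row_loss_grad(loss_type, h, width.subvec(s, e), delta.subvec(s, e),
                  clo, chi, l, g);
    acc += accu(l);
  }
  return acc;
}

struct AdamState {
  mat mW1, vW1, mW2, vW2;
  rowvec mb1, vb1, mb2, vb2;
  vec mw3, vw3;
  double mb3 = 0.0, vb3 = 0.0;
  double b1p = 1.0, b2p = 1.0;  // running beta powers
};

inline void adam_mat(mat& w, mat& m, mat& v, const mat& g, double lr_t,
                     double beta1, double beta2, double eps) {
  m = beta1 * m + (1.0 - beta1) * g;
  v = beta2 * v + (1.0 - beta2) * square(g);
  w -= lr_t * m / (sqrt(v) + eps);
}
inline void adam_row(rowvec& w, rowvec& m, rowvec& v, const rowvec& g,
                     double lr_t, double beta1, double beta2, double eps) {
  m = beta1 * m + (1.0 - beta1) * g;
  v = beta2 * v + (1.0 - beta2) * square(g);
  w -= lr_t * m / (sqrt(v) + eps);
}
inline void adam_vec(vec& w, vec& m, vec& v, const vec& g, double lr_t,
                     double beta1, double beta2, double eps) {
  m = beta1 * m + (1.0 - beta1) * g;
  v = beta2 * v + (1.0 - beta2) * square(g);
  w -= lr_t * m / (sqrt(v) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector nn_forward_cpp(const Rcpp::List& weights,
                                   const arma::mat& X) {
  Params p;
  p.W1 = Rcpp::as<mat>(weights["W1"]);
  p.b1 = Rcpp::as<rowvec>(weights["b1"]);
  p.W2 = Rcpp::as<mat>(weights["W2"]);
  p.b2 = Rcpp::as<rowvec>(weights["b2"]);
  p.w3 = Rcpp::as<vec>(weights["w3"]);
  p.b3 = Rcpp::as<double>(weights["b3"]);
  mat H1, H2;
  vec h;
  const uword n = X.n_rows, chunk = 65536;
  vec out(n);
  for (uword s = 0; s < n; s += chunk) {
    uword e = std::min(s + chunk, n) - 1;
    forward(p, X.rows(s, e), H1, H2, h);
    out.subvec(s, e) = h;
  }
  return Rcpp::NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(const arma::mat& Xtr, const arma::vec& wtr,
                        const arma::vec& dtr, const arma::mat& Xva,
                        const arma::vec& wva, const arma::vec& dva,
                        const Rcpp::List& init, int loss_type, double lr,
                        int batch, int patience, int max_epochs,
                        double clamp_lo, double clamp_hi, int seed) {
  Params p;
  p.W1 = Rcpp::as<mat>(init["W1"]);
  p.b1 = Rcpp::as<rowvec>(init["b1"]);
  p.W2 = Rcpp::as<mat>(init["W2"]);
  p.b2 = Rcpp::as<rowvec>(init["b2"]);
  p.w3 = Rcpp::as<vec>(init["w3"]);
  p.b3 = Rcpp::as<double>(init["b3"]);

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  AdamState st;
  st.mW1.zeros(size(p.W1)); st.vW1.zeros(size(p.W1));
  st.mW2.zeros(size(p.W2)); st.vW2.zeros(size(p.W2));
  st.mb1.zeros(size(p.b1)); st.vb1.zeros(size(p.b1));
  st.mb2.zeros(size(p.b2)); st.vb2.zeros(size(p.b2));
  st.mw3.zeros(size(p.w3)); st.vw3.zeros(size(p.w3));

  const uword n = Xtr.n_rows;
  if (n == 0) Rcpp::stop("empty training table");
  const uword nb = std::max<uword>(1, std::min<uword>(batch, n));

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> idx(n);
  std::iota(idx.begin(), idx.end(), 0);

  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, stopped = max_epochs;
  std::vector<double> hist_tr, hist_va;

  mat H1, H2;
  vec h, l, g;
  mat Xb(nb, Xtr.n_cols);
  vec wb(nb), db(nb);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double tr_acc = 0.0;
    for (uword s = 0; s < n; s += nb) {
      uword m = std::min(s + nb, n) - s;
      if (Xb.n_rows != m) { Xb.set_size(m, Xtr.n_cols); wb.set_size(m); db.set_size(m); }
      for (uword k = 0; k < m; ++k) {
        Xb.row(k) = Xtr.row(idx[s + k]);
        wb[k] = wtr[idx[s + k]];
        db[k] = dtr[idx[s + k]];
      }
      forward(p, Xb, H1, H2, h);
      row_loss_grad(loss_type, h, wb, db, clamp_lo, clamp_hi, l, g);
      tr_acc += accu(l);
      g /= static_cast<double>(m);  // mean loss over the minibatch

      // Backward pass.
      double gb3 = accu(g);
      vec gw3 = H2.t() * g;
      mat dH2 = g * p.w3.t();
      dH2.elem(find(H2 <= 0.0)).zeros();
      rowvec gb2 = sum(dH2, 0);
      mat gW2 = H1.t() * dH2;
      mat dH1 = dH2 * p.W2.t();
      dH1.elem(find(H1 <= 0.0)).zeros();
      rowvec gb1 = sum(dH1, 0);
      mat gW1 = Xb.t() * dH1;

      st.b1p *= beta1;
      st.b2p *= beta2;
      double lr_t = lr * std::sqrt(1.0 - st.b2p) / (1.0 - st.b1p);
      adam_mat(p.W1, st.mW1, st.vW1, gW1, lr_t, beta1, beta2, eps);
      adam_row(p.b1, st.mb1, st.vb1, gb1, lr_t, beta1, beta2, eps);
      adam_mat(p.W2, st.mW2, st.vW2, gW2, lr_t, beta1, beta2, eps);
      adam_row(p.b2, st.mb2, st.vb2, gb2, lr_t, beta1, beta2, eps);
      adam_vec(p.w3, st.mw3, st.vw3, gw3, lr_t, beta1, beta2, eps);
      st.mb3 = beta1 * st.mb3 + (1.0 - beta1) * gb3;
      st.vb3 = beta2 * st.vb3 + (1.0 - beta2) * gb3 * gb3;
      p.b3 -= lr_t * st.mb3 / (std::sqrt(st.vb3) + eps);
    }
    if (!std::isfinite(tr_acc))
      Rcpp::stop("training loss became non-finite at epoch %d", epoch);

    double va = total_loss(p, loss_type, Xva, wva, dva, clamp_lo, clamp_hi);
    hist_tr.push_back(tr_acc);
    hist_va.push_back(va);
    if (!std::isfinite(va))
      Rcpp::stop("validation loss became non-finite at epoch %d", epoch);

    if (va < best_val) {
      best_val = va;
      best = p;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      stopped = epoch;
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (wait < patience) stopped = static_cast<int>(hist_tr.size());

  return Rcpp::List::create(
      Rcpp::Named("W1") = best.W1, Rcpp::Named("b1") = best.b1,
      Rcpp::Named("W2") = best.W2, Rcpp::Named("b2") = best.b2,
      Rcpp::Named("w3") = best.w3, Rcpp::Named("b3") = best.b3,
      Rcpp::Named("train_loss") = hist_tr, Rcpp::Named("val_loss") = hist_va,
      Rcpp::Named("best_val") = best_val, Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("stopped_epoch") = stopped);
}
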