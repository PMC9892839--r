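#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dual coordinate descent for the L2-regularised, L1-loss (hinge) linear SVM:
//   min_w 1/2 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// The bias is carried as an augmented constant column appended here, i.e. it
// is (weakly) regularised, as in the standard large-scale linear-SVM solvers.
// Coordinate order is shuffled with a private mt19937 stream so results are
// a deterministic function of the `seed` argument only.
static void dcd_svm(const arma::mat& Xt, const arma::vec& y, double C,
                    int max_pass, double tol, std::mt19937& rng,
                    const arma::vec& Q, arma::vec& alpha, arma::vec& w) {
  // Xt holds one training sample per COLUMN (contiguous access)
  const arma::uword n = Xt.n_cols, p = Xt.n_rows;

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;
  double* wp = w.memptr();

  for (int pass = 0; pass < max_pass; ++pass) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_pg = 0.0;
    for (arma::uword k = 0; k < n; ++k) {
      const arma::uword i = idx[k];
      if (Q(i) <= 0.0) continue;
      const double* xi = Xt.colptr(i);
      double dot = 0.0;
      for (arma::uword j = 0; j < p; ++j) dot += wp[j] * xi[j];
      const double G = y(i) * dot - 1.0;
      double PG = G;
      if (alpha(i) <= 0.0)      PG = std::min(G, 0.0);
      else if (alpha(i) >= C)   PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha(i);
        double a_new = a_old - G / Q(i);
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C)   a_new = C;
        alpha(i) = a_new;
        const double step = (a_new - a_old) * y(i);
        for (arma::uword j = 0; j < p; ++j) wp[j] += step * xi[j];
      }
    }
    if (max_pg < tol) break;
  }
}

//' Solve a linear SVM over a grid of cost values and return decision values.
//'
//' @param Xtr training matrix (no intercept column), ytr labels in {-1,+1},
//'   Xte test matrix, Cgrid cost values. Returns decision-value matrices for
//'   test and training rows, one column per cost value.
//' @noRd
// [[Rcpp::export(name = ".svm_dcd_grid")]]
List svm_dcd_grid(const arma::mat& Xtr, const arma::vec& ytr,
                  const arma::mat& Xte, const arma::vec& Cgrid,
                  int max_pass = 1000, double tol = 1e-4, int seed = 0) {
  const arma::uword p = Xtr.n_cols;
  // bias handled as an augmented constant column with a large scale so the
  // intercept is only weakly regularised (liblinear's bias-scaling device)
  const double bias_scale = 4.0;
  arma::mat Xa = arma::join_rows(Xtr, bias_scale * arma::ones(Xtr.n_rows, 1));
  arma::mat Xta = arma::join_rows(Xte, bias_scale * arma::ones(Xte.n_rows, 1));
  arma::mat dec_te(Xte.n_rows, Cgrid.n_elem);
  arma::mat dec_tr(Xtr.n_rows, Cgrid.n_elem);
  arma::mat W(p + 1, Cgrid.n_elem);
  arma::mat Xat = Xa.t();
  arma::vec Q(Xa.n_rows);
  for (arma::uword i = 0; i < Xa.n_rows; ++i) {
    Q(i) = arma::dot(Xat.col(i), Xat.col(i));
  }
  // ascending-C order allows warm starts: the previous solution's alpha is
  // feasible for any larger box
  arma::uvec ord = arma::sort_index(Cgrid);
  arma::vec alpha(Xa.n_rows, arma::fill::zeros);
  arma::vec w(p + 1, arma::fill::zeros);
  for (arma::uword k = 0; k < Cgrid.n_elem; ++k) {
    const arma::uword c = ord(k);
    std::mt19937 rng(static_cast<unsigned>(seed) + 7919u * c);
    dcd_svm(Xat, ytr, Cgrid(c), max_pass, tol, rng, Q, alpha, w);
    dec_te.col(c) = Xta * w;
    dec_tr.col(c) = Xa * w;
    W.col(c) = w;
  }
  return List::create(_["test_decision"] = dec_te,
                      _["train_decision"] = dec_tr,
                      _["weights"] = W);
}

// min-max scale columns of Xt-layout (p x n) blocks: stats from the
// training block, applied to both; constant training columns map to 0.
static void minmax_cols(arma::mat& Xtr_t, arma::mat& Xte_t) {
  const arma::uword p = Xtr_t.n_rows - 1; // last row is the bias, untouched
  for (arma::uword j = 0; j < p; ++j) {
    const double lo = Xtr_t.row(j).min();
    const double hi = Xtr_t.row(j).max();
    if (hi - lo <= 0.0) {
      Xtr_t.row(j).zeros();
      Xte_t.row(j).zeros();
    } else {
      Xtr_t.row(j) = (Xtr_t.row(j) - lo) / (hi - lo);
      Xte_t.row(j) = (Xte_t.row(j) - lo) / (hi - lo);
    }
  }
}

// extract samples `idx` of X (n x p) into transposed layout (p+1 x k) with
// the bias column appended (scale bs)
static arma::mat take_t_aug(const arma::mat& X, const arma::uvec& idx,
                            double bs) {
  arma::mat out(X.n_cols + 1, idx.n_elem);
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    for (arma::uword j = 0; j < X.n_cols; ++j) out(j, k) = X(idx(k), j);
    out(X.n_cols, k) = bs;
  }
  return out;
}

static double bac_counts(double tp, double fn, double tn, double fp) {
  const bool has_T = tp + fn > 0, has_N = tn + fp > 0;
  if (has_T && has_N) return (tp / (tp + fn) + tn / (tn + fp)) / 2.0;
  if (has_T) return tp / (tp + fn);
  if (has_N) return tn / (tn + fp);
  return NA_REAL;
}

//' Nested-CV linear-SVM balanced accuracy for a batch of label vectors.
//'
//' Mirrors the R engine exactly for the min-max-only preparation recipe:
//' per outer fold, each inner fold is min-max scaled on its training rows,
//' the cost grid (ascending, warm-started) is scored by inner balanced
//' accuracy, the first maximum (= smallest cost) wins, the winner is refit
//' on the min-max-scaled outer training set, and outer-test predictions
//' accumulate into the confusion counts. One balanced accuracy per column
//' of the 0/1 label matrix. All index vectors are 1-based.
//' @noRd
// [[Rcpp::export(name = ".svm_nested_bac_batch")]]
arma::vec svm_nested_bac_batch(const arma::mat& X, const arma::mat& Ymat,
                               const List& outer_train,
                               const List& outer_test,
                               const List& inner_train,
                               const List& inner_val,
                               const arma::vec& Cgrid,
                               int max_pass = 150, double tol = 0.05,
                               int seed = 0) {
  const double bias_scale = 4.0;
  const int nouter = outer_train.size();
  const arma::uword nC = Cgrid.n_elem;
  arma::vec out(Ymat.n_cols);

  // pre-extract index vectors and transposed feature blocks (label-free,
  // shared across the whole batch)
  std::vector<arma::uvec> otr(nouter), ote(nouter);
  std::vector<std::vector<arma::uvec>> itr(nouter), ivl(nouter);
  std::vector<arma::mat> otr_X(nouter), ote_X(nouter);
  std::vector<std::vector<arma::mat>> itr_X(nouter), ivl_X(nouter);
  for (int o = 0; o < nouter; ++o) {
    otr[o] = as<arma::uvec>(outer_train[o]) - 1;
    ote[o] = as<arma::uvec>(outer_test[o]) - 1;
    arma::mat a = take_t_aug(X, otr[o], bias_scale);
    arma::mat b = take_t_aug(X, ote[o], bias_scale);
    minmax_cols(a, b);
    otr_X[o] = a; ote_X[o] = b;
    List tl = inner_train[o], vl = inner_val[o];
    for (int f = 0; f < tl.size(); ++f) {
      arma::uvec ti = as<arma::uvec>(tl[f]) - 1;
      arma::uvec vi = as<arma::uvec>(vl[f]) - 1;
      arma::mat at = take_t_aug(X, ti, bias_scale);
      arma::mat av = take_t_aug(X, vi, bias_scale);
      minmax_cols(at, av);
      itr[o].push_back(ti); ivl[o].push_back(vi);
      itr_X[o].push_back(at); ivl_X[o].push_back(av);
    }
  }

  for (arma::uword b = 0; b < Ymat.n_cols; ++b) {
    arma::vec ypm = 2.0 * Ymat.col(b) - 1.0;
    double tp = 0, fn = 0, tn = 0, fp = 0;
    for (int o = 0; o < nouter; ++o) {
      const int nin = (int)itr[o].size();
      arma::vec acc(nC, arma::fill::zeros);
      for (int f = 0; f < nin; ++f) {
        const arma::mat& Xt = itr_X[o][f];
        const arma::mat& Xv = ivl_X[o][f];
        const arma::vec yt = ypm.elem(itr[o][f]);
        const arma::vec yv = ypm.elem(ivl[o][f]);
        arma::vec Q(Xt.n_cols);
        for (arma::uword i = 0; i < Xt.n_cols; ++i) {
          Q(i) = arma::dot(Xt.col(i), Xt.col(i));
        }
        arma::vec alpha(Xt.n_cols, arma::fill::zeros);
        arma::vec w(Xt.n_rows, arma::fill::zeros);
        for (arma::uword c = 0; c < nC; ++c) { // Cgrid ascending
          std::mt19937 rng(static_cast<unsigned>(seed) + 7919u * c);
          dcd_svm(Xt, yt, Cgrid(c), max_pass, tol, rng, Q, alpha, w);
          double itp = 0, ifn = 0, itn = 0, ifp = 0;
          for (arma::uword j = 0; j < Xv.n_cols; ++j) {
            const bool pred_T = arma::dot(w, Xv.col(j)) > 0;
            if (yv(j) > 0) { if (pred_T) itp++; else ifn++; }
            else           { if (pred_T) ifp++; else itn++; }
          }
          acc(c) += bac_counts(itp, ifn, itn, ifp); // summed in fold order, as colMeans does
        }
      }
      const arma::uword cbest = acc.index_max(); // first max on ties
      // refit: fresh solve of the winning cost on the outer training set
      const arma::mat& Xt = otr_X[o];
      const arma::vec yt = ypm.elem(otr[o]);
      arma::vec Q(Xt.n_cols);
      for (arma::uword i = 0; i < Xt.n_cols; ++i) {
        Q(i) = arma::dot(Xt.col(i), Xt.col(i));
      }
      arma::vec alpha(Xt.n_cols, arma::fill::zeros);
      arma::vec w(Xt.n_rows, arma::fill::zeros);
      std::mt19937 rng(static_cast<unsigned>(seed));
      dcd_svm(Xt, yt, Cgrid(cbest), max_pass, tol, rng, Q, alpha, w);
      for (arma::uword j = 0; j < ote_X[o].n_cols; ++j) {
        const bool pred_T = arma::dot(w, ote_X[o].col(j)) > 0;
        if (ypm(ote[o](j)) > 0) { if (pred_T) tp++; else fn++; }
        else                    { if (pred_T) fp++; else tn++; }
      }
    }
    out(b) = bac_counts(tp, fn, tn, fp);
  }
  return out;
}

// IRLS for the two-parameter (intercept + slope) logistic fit; x constant
// degenerates to the intercept-only fit.
static void logistic_1d(const arma::vec& x, const arma::vec& y,
                        double& b0, double& b1) {
  const arma::uword n = x.n_elem;
  if (arma::var(x) <= 0.0) {
    double p = arma::mean(y);
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    b0 = std::log(p / (1.0 - p));
    b1 = 0.0;
    return;
  }
  b0 = 0.0; b1 = 0.0;
  double dev_old = R_PosInf;
  for (int it = 0; it < 25; ++it) {
    arma::vec eta = b0 + b1 * x;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec wv = mu % (1.0 - mu);
    wv.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / wv;
    // weighted normal equations for [1, x]
    const double sw = arma::sum(wv);
    const double swx = arma::dot(wv, x);
    const double swxx = arma::dot(wv, x % x);
    const double swz = arma::dot(wv, z);
    const double swxz = arma::sum(wv % x % z);
    const double det = sw * swxx - swx * swx;
    if (std::fabs(det) < 1e-300) break;
    const double nb0 = (swxx * swz - swx * swxz) / det;
    const double nb1 = (sw * swxz - swx * swz) / det;
    b0 = nb0; b1 = nb1;
    arma::vec mu2 = 1.0 / (1.0 + arma::exp(-(b0 + b1 * x)));
    mu2.transform([](double v) {
      if (v < 1e-12) return 1e-12;
      if (v > 1.0 - 1e-12) return 1.0 - 1e-12;
      return v;
    });
    double dev = -2.0 * arma::sum(y % arma::log(mu2) +
                                  (1.0 - y) % arma::log(1.0 - mu2));
    if (std::fabs(dev - dev_old) < 1e-8 * (std::fabs(dev) + 0.1)) break;
    dev_old = dev;
    (void)n;
  }
}

//' Balanced accuracy of the simple LPO logistic path for a batch of label
//' vectors (columns of Ymat; the first is typically the observed labels,
//' the rest permutations). Fold index vectors are 1-based.
//' @noRd
// [[Rcpp::export(name = ".lpo_logistic_bac_batch")]]
arma::vec lpo_logistic_bac_batch(const arma::vec& x, const arma::mat& Ymat,
                                 const List& train_idx, const List& test_idx,
                                 double threshold = 0.5) {
  const int nfold = train_idx.size();
  arma::vec out(Ymat.n_cols);
  for (arma::uword b = 0; b < Ymat.n_cols; ++b) {
    const arma::vec y = Ymat.col(b);
    double tp = 0, fn = 0, tn = 0, fp = 0;
    for (int f = 0; f < nfold; ++f) {
      const arma::uvec tr =
        as<arma::uvec>(train_idx[f]) - 1;
      const arma::uvec te =
        as<arma::uvec>(test_idx[f]) - 1;
      double b0, b1;
      logistic_1d(x.elem(tr), y.elem(tr), b0, b1);
      for (arma::uword j = 0; j < te.n_elem; ++j) {
        const double prob =
          1.0 / (1.0 + std::exp(-(b0 + b1 * x(te(j)))));
        const bool pred_T = prob > threshold;
        if (y(te(j)) > 0.5) { if (pred_T) tp++; else fn++; }
        else               { if (pred_T) fp++; else tn++; }
      }
    }
    const double se = tp + fn > 0 ? tp / (tp + fn) : NA_REAL;
    const double sp = tn + fp > 0 ? tn / (tn + fp) : NA_REAL;
    out(b) = (se + sp) / 2.0;
  }
  return out;
}

//' Logistic regression by iteratively reweighted least squares.
//'
//' @param X design matrix including the intercept column; y in {0,1}.
//'   Returns the coefficient vector. Mirrors glm.fit's IRLS with a fixed
//'   iteration cap; under complete separation the coefficients diverge
//'   slowly, exactly as glm's do, and the fitted class side is stable.
//' @noRd
// [[Rcpp::export(name = ".logistic_irls")]]
arma::vec logistic_irls(const arma::mat& X, const arma::vec& y,
                        int max_iter = 25, double tol = 1e-8) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double dev_old = R_PosInf;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec wv = mu % (1.0 - mu);
    wv.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / wv;
    arma::mat Xw = X.each_col() % wv;
    arma::mat H = X.t() * Xw;
    arma::vec b = X.t() * (wv % z);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, H, b, arma::solve_opts::no_approx);
    if (!ok) {
      beta_new = arma::pinv(H) * b;
    }
    arma::vec eta_new = X * beta_new;
    arma::vec mu_new = 1.0 / (1.0 + arma::exp(-eta_new));
    mu_new.transform([](double v) {
      if (v < 1e-12) return 1e-12;
      if (v > 1.0 - 1e-12) return 1.0 - 1e-12;
      return v;
    });
    double dev = -2.0 * arma::sum(y % arma::log(mu_new) +
                                  (1.0 - y) % arma::log(1.0 - mu_new));
    beta = beta_new;
    if (std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) break;
    dev_old = dev;
  }
  return beta;
}
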