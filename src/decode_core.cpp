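// Core numerical routines for the searchlight ECOC/SVM decoder.
//
// The leave-one-trial-out (LOTO) cross-validation with nested searchlight
// scoring requires on the order of 10^5 small SVM fits per ROI decode, so the
// soft-margin C-SVC dual is solved here directly on precomputed Gram matrices
// with an SMO solver (second-order working-set selection).  Trial counts are
// small (tens), so each fit is a tiny dense QP.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// SMO solver for the C-SVC dual:
//   min  1/2 a' Q a - e' a   s.t.  0 <= a_i <= C,  y' a = 0
// with Q_ij = y_i y_j K_ij.  Decision value f(x) = sum_i a_i y_i K(x, i) - rho.
// Working-set selection and the two-variable update follow the standard
// second-order (maximal violating pair) scheme.
// ---------------------------------------------------------------------------
struct SvmFit {
  arma::vec alpha;   // length m (training points)
  double rho;        // f(x) = sum a y K - rho
  int iters;
};

static const double TAU = 1e-12;

static SvmFit smo_solve(const arma::mat& K, const arma::ivec& y,
                        double C, double eps = 1e-4, int max_iter = 20000,
                        const arma::vec* warm = nullptr) {
  const int m = K.n_rows;
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec G(m, arma::fill::value(-1.0));   // gradient of dual objective
  if (warm != nullptr) {
    alpha = *warm;
    // G = Q alpha - 1 with Q_ij = y_i y_j K_ij
    arma::vec ya(m);
    for (int t = 0; t < m; ++t) ya[t] = alpha[t] * y[t];
    arma::vec Kya = K * ya;
    for (int t = 0; t < m; ++t) G[t] = y[t] * Kya[t] - 1.0;
  }
  int it = 0;

  for (; it < max_iter; ++it) {
    // select i: maximal -y_t G_t over I_up
    int i = -1;
    double Gmax = -arma::datum::inf;
    for (int t = 0; t < m; ++t) {
      if (y[t] == 1) {
        if (alpha[t] < C && -G[t] >= Gmax) { Gmax = -G[t]; i = t; }
      } else {
        if (alpha[t] > 0 &&  G[t] >= Gmax) { Gmax =  G[t]; i = t; }
      }
    }
    if (i < 0) break;

    // select j: second-order minimal objective among violating I_low
    int j = -1;
    double Gmax2 = -arma::datum::inf;
    double obj_min = arma::datum::inf;
    for (int t = 0; t < m; ++t) {
      if (y[t] == 1) {
        if (alpha[t] > 0) {
          double grad_diff = Gmax + G[t];
          if (G[t] >= Gmax2) Gmax2 = G[t];
          if (grad_diff > 0) {
            // curvature along the feasible direction: ||phi(x_i)-phi(x_t)||^2
            double quad = K(i, i) + K(t, t) - 2.0 * K(i, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; }
          }
        }
      } else {
        if (alpha[t] < C) {
          double grad_diff = Gmax - G[t];
          if (-G[t] >= Gmax2) Gmax2 = -G[t];
          if (grad_diff > 0) {
            double quad = K(i, i) + K(t, t) - 2.0 * K(i, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; }
          }
        }
      }
    }
    if (j < 0 || Gmax + Gmax2 < eps) break;

    // two-variable analytic update with box clipping
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    // gradient update: G_t += Q_ti * dai + Q_tj * daj
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < m; ++t) {
        G[t] += (y[t] * y[i] * K(t, i)) * dai + (y[t] * y[j] * K(t, j)) * daj;
      }
    }
  }

  // rho from KKT conditions (mean y_t G_t over free SVs, else bound midpoint)
  double ub = arma::datum::inf, lb = -arma::datum::inf, sum_free = 0;
  int nr_free = 0;
  for (int t = 0; t < m; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1)  ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  SvmFit fit;
  fit.alpha = alpha;
  fit.rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
  fit.iters = it;
  return fit;
}

// Decision value for point p given a fit trained on rows `tr` of full Gram K.
static double decision_value(const arma::mat& K, const arma::uvec& tr,
                             const arma::ivec& ytr, const SvmFit& fit,
                             arma::uword p) {
  double f = 0;
  for (arma::uword s = 0; s < tr.n_elem; ++s)
    f += fit.alpha[s] * ytr[s] * K(p, tr[s]);
  return f - fit.rho;
}

// ---------------------------------------------------------------------------
// ECOC helpers.  code: n_classes x n_dichotomies matrix of +1/-1.
// Labels are 1-based class indices.  Hamming ties -> lowest class label.
// Decision value 0 maps to bit +1 (fixed convention).
// ---------------------------------------------------------------------------
static int hamming_decode(const arma::vec& decvals, const arma::imat& code) {
  const int Kc = code.n_rows, D = code.n_cols;
  int best = 0, best_d = D + 1;
  for (int k = 0; k < Kc; ++k) {
    int d = 0;
    for (int j = 0; j < D; ++j) {
      int bit = decvals[j] >= 0 ? 1 : -1;
      if (bit != code(k, j)) ++d;
    }
    if (d < best_d) { best_d = d; best = k; }
  }
  return best + 1;
}

// Train ECOC on rows `tr`, predict labels of rows `te`.  Returns 0 for all
// test rows if some dichotomy has an empty side (degenerate training set).
static bool ecoc_fit_predict(const arma::mat& K, const arma::ivec& y,
                             const arma::imat& code, double C,
                             const arma::uvec& tr, const arma::uvec& te,
                             arma::ivec& out) {
  const int D = code.n_cols;
  const arma::uword m = tr.n_elem;
  arma::mat Ktr(m, m);
  for (arma::uword a = 0; a < m; ++a)
    for (arma::uword b = 0; b < m; ++b) Ktr(a, b) = K(tr[a], tr[b]);

  arma::mat dec(te.n_elem, D);
  arma::ivec ybin(m);
  for (int j = 0; j < D; ++j) {
    bool pos = false, neg = false;
    for (arma::uword a = 0; a < m; ++a) {
      ybin[a] = code(y[tr[a]] - 1, j);
      if (ybin[a] > 0) pos = true; else neg = true;
    }
    if (!pos || !neg) return false;
    SvmFit fit = smo_solve(Ktr, ybin, C);
    for (arma::uword p = 0; p < te.n_elem; ++p)
      dec(p, j) = decision_value(K, tr, ybin, fit, te[p]);
  }
  for (arma::uword p = 0; p < te.n_elem; ++p)
    out[p] = hamming_decode(dec.row(p).t(), code);
  return true;
}

static arma::uvec complement_of(arma::uword n, const arma::uvec& drop) {
  std::vector<bool> keep(n, true);
  for (arma::uword i = 0; i < drop.n_elem; ++i) keep[drop[i]] = false;
  arma::uvec out(n - drop.n_elem);
  arma::uword k = 0;
  for (arma::uword t = 0; t < n; ++t) if (keep[t]) out[k++] = t;
  return out;
}

// [[Rcpp::export]]
List cpp_svm_train(const arma::mat& X, const arma::ivec& y, double C,
                   double eps = 1e-6, int max_iter = 100000) {
  arma::mat K = X * X.t();
  SvmFit fit = smo_solve(K, y, C, eps, max_iter);
  arma::vec w(X.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    if (fit.alpha[i] > 0) w += fit.alpha[i] * y[i] * X.row(i).t();
  return List::create(_["weights"] = w, _["bias"] = -fit.rho,
                      _["alpha"] = fit.alpha, _["iterations"] = fit.iters);
}

// Plain leave-one-trial-out ECOC prediction on one pattern set.
// Returns integer predictions per trial; 0 where the fold was skipped
// because a dichotomy lost one side of its bipartition.
// [[Rcpp::export]]
IntegerVector cpp_loto_predict(const arma::mat& X, const arma::ivec& y,
                               const arma::imat& code, double C) {
  const arma::uword n = X.n_rows;
  arma::mat K = X * X.t();
  IntegerVector pred(n);
  for (arma::uword u = 0; u < n; ++u) {
    arma::uvec drop(1); drop[0] = u;
    arma::uvec tr = complement_of(n, drop);
    arma::uvec te(1); te[0] = u;
    arma::ivec out(1);
    pred[u] = ecoc_fit_predict(K, y, code, C, tr, te, out) ? out[0] : 0;
  }
  return pred;
}

// ---------------------------------------------------------------------------
// Full ROI decode: leave-one-trial-out with per-fold searchlight selection.
//
// For each sphere the predictions of every leave-two-out model are cached:
// pairpred(t, u) = predicted label of trial u from an ECOC model trained on
// all trials except {t, u}.  The nested LOTO score of sphere s for outer fold
// t is then mean_u != t [pairpred(t, u) == y_u]; no quantity involving trial
// t's features enters fold t's selection or training (no test leakage).
// score_mode: 0 = nested LOTO (default), 1 = training-set accuracy.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_decode_roi(const arma::mat& X, const arma::ivec& y,
                    const List& sphere_members, const arma::imat& code,
                    double C, int score_mode = 0) {
  const arma::uword n = X.n_rows;
  const int V = sphere_members.size();
  arma::mat scores(V, n);  // sphere x outer fold

  std::vector<arma::mat> Kspheres(V);
  for (int s = 0; s < V; ++s) {
    arma::uvec mem = as<arma::uvec>(sphere_members[s]) - 1;  // 1-based from R
    arma::mat Xs = X.cols(mem);
    Kspheres[s] = Xs * Xs.t();
  }

  for (int s = 0; s < V; ++s) {
    const arma::mat& K = Kspheres[s];
    if (score_mode == 0) {
      // leave-two-out pair cache; each pair model is warm-started from the
      // all-trials solution of its dichotomy (equality constraint repaired
      // after dropping the two trials), which it typically refines in a
      // handful of SMO iterations
      const int D = code.n_cols;
      std::vector<arma::vec> afull(D);
      std::vector<arma::ivec> ybin_all(D);
      for (int j = 0; j < D; ++j) {
        ybin_all[j].set_size(n);
        for (arma::uword a = 0; a < n; ++a)
          ybin_all[j][a] = code(y[a] - 1, j);
        SvmFit f = smo_solve(K, ybin_all[j], C, 1e-3);
        afull[j] = f.alpha;
      }
      arma::imat pairpred(n, n, arma::fill::zeros);
      arma::uvec drop(2), te(2);
      const arma::uword m = n - 2;
      arma::mat Ktr(m, m);
      arma::ivec ybin(m);
      arma::vec a0(m);
      for (arma::uword t = 0; t < n; ++t) {
        for (arma::uword u = t + 1; u < n; ++u) {
          drop[0] = t; drop[1] = u;
          arma::uvec tr = complement_of(n, drop);
          for (arma::uword a = 0; a < m; ++a)
            for (arma::uword b = 0; b < m; ++b) Ktr(a, b) = K(tr[a], tr[b]);
          arma::mat dec(2, D);
          bool ok = true;
          for (int j = 0; j < D && ok; ++j) {
            bool pos = false, neg = false;
            for (arma::uword a = 0; a < m; ++a) {
              ybin[a] = ybin_all[j][tr[a]];
              a0[a] = afull[j][tr[a]];
              if (ybin[a] > 0) pos = true; else neg = true;
            }
            if (!pos || !neg) { ok = false; break; }
            // repair sum(alpha * y) = 0 after dropping trials t and u
            double cur = 0;
            for (arma::uword a = 0; a < m; ++a) cur += a0[a] * ybin[a];
            for (arma::uword a = 0; a < m && std::abs(cur) > 1e-12; ++a) {
              if (cur > 0) {
                if (ybin[a] > 0 && a0[a] > 0) {
                  double d = std::min(a0[a], cur); a0[a] -= d; cur -= d;
                } else if (ybin[a] < 0 && a0[a] < C) {
                  double d = std::min(C - a0[a], cur); a0[a] += d; cur -= d;
                }
              } else {
                if (ybin[a] < 0 && a0[a] > 0) {
                  double d = std::min(a0[a], -cur); a0[a] -= d; cur += d;
                } else if (ybin[a] > 0 && a0[a] < C) {
                  double d = std::min(C - a0[a], -cur); a0[a] += d; cur += d;
                }
              }
            }
            SvmFit fit = smo_solve(Ktr, ybin, C, 1e-3, 20000, &a0);
            for (int p = 0; p < 2; ++p) {
              arma::uword pt = p == 0 ? t : u;
              double f = 0;
              for (arma::uword a = 0; a < m; ++a)
                f += fit.alpha[a] * ybin[a] * K(pt, tr[a]);
              dec(p, j) = f - fit.rho;
            }
          }
          if (ok) {
            pairpred(u, t) = hamming_decode(dec.row(0).t(), code);
            pairpred(t, u) = hamming_decode(dec.row(1).t(), code);
          }
        }
      }
      for (arma::uword t = 0; t < n; ++t) {
        int ok = 0, tot = 0;
        for (arma::uword u = 0; u < n; ++u) {
          if (u == t || pairpred(t, u) == 0) continue;
          ++tot;
          if (pairpred(t, u) == y[u]) ++ok;
        }
        scores(s, t) = tot > 0 ? (double)ok / tot : -1.0;
      }
    } else {
      // training-set accuracy of the fold-t model
      for (arma::uword t = 0; t < n; ++t) {
        arma::uvec drop(1); drop[0] = t;
        arma::uvec tr = complement_of(n, drop);
        arma::ivec out(tr.n_elem);
        if (ecoc_fit_predict(K, y, code, C, tr, tr, out)) {
          int ok = 0;
          for (arma::uword a = 0; a < tr.n_elem; ++a)
            if (out[a] == y[tr[a]]) ++ok;
          scores(s, t) = (double)ok / tr.n_elem;
        } else scores(s, t) = -1.0;
      }
    }
  }

  // per outer fold: argmax sphere (ties -> lowest sphere index), then
  // train ECOC on the n-1 remaining trials and predict the held-out trial
  IntegerVector selected(n), predicted(n);
  for (arma::uword t = 0; t < n; ++t) {
    int best = 0;
    for (int s = 1; s < V; ++s)
      if (scores(s, t) > scores(best, t)) best = s;
    selected[t] = best + 1;
    arma::uvec drop(1); drop[0] = t;
    arma::uvec tr = complement_of(n, drop);
    arma::uvec te(1); te[0] = t;
    arma::ivec out(1);
    predicted[t] = ecoc_fit_predict(Kspheres[best], y, code, C, tr, te, out)
                     ? out[0] : 0;
  }
  return List::create(_["selected"] = selected, _["predicted"] = predicted,
                      _["scores"] = scores);
}

// ---------------------------------------------------------------------------
// Separable 3-D Gaussian smoothing of a 4-D run (x, y, z, volume) with
// nearest-neighbour (replicate) boundary handling.  Kernel truncated at
// ceil(3.5 * sigma) and normalised to unit sum; sigma in voxel units.
// ---------------------------------------------------------------------------
static void smooth_axis(const arma::cube& in, arma::cube& out,
                        const arma::vec& kern, int axis) {
  const int R = (kern.n_elem - 1) / 2;
  const int nx = in.n_rows, ny = in.n_cols, nz = in.n_slices;
  for (int z = 0; z < nz; ++z)
    for (int yy = 0; yy < ny; ++yy)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int k = -R; k <= R; ++k) {
          int xi = x, yi = yy, zi = z;
          if (axis == 0) xi = std::min(std::max(x + k, 0), nx - 1);
          else if (axis == 1) yi = std::min(std::max(yy + k, 0), ny - 1);
          else zi = std::min(std::max(z + k, 0), nz - 1);
          acc += kern[k + R] * in(xi, yi, zi);
        }
        out(x, yy, z) = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_smooth_gaussian(NumericVector arr, double sigma_vox) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 4) stop("expected a 4-D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  if (sigma_vox <= 0) return clone(arr);

  int R = (int)std::ceil(3.5 * sigma_vox);
  arma::vec kern(2 * R + 1);
  for (int k = -R; k <= R; ++k)
    kern[k + R] = std::exp(-0.5 * (k * k) / (sigma_vox * sigma_vox));
  kern /= arma::accu(kern);

  NumericVector res(arr.size());
  res.attr("dim") = dims;
  arma::cube vol(nx, ny, nz), tmp(nx, ny, nz);
  const R_xlen_t vsize = (R_xlen_t)nx * ny * nz;
  for (int t = 0; t < nt; ++t) {
    std::copy(arr.begin() + t * vsize, arr.begin() + (t + 1) * vsize,
              vol.memptr());
    smooth_axis(vol, tmp, kern, 0);
    smooth_axis(tmp, vol, kern, 1);
    smooth_axis(vol, tmp, kern, 2);
    std::copy(tmp.memptr(), tmp.memptr() + vsize, res.begin() + t * vsize);
  }
  return res;
}
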