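// Split-half cross-validated similarity of regularized-LDA communication
// directions. Hot loop of the similarity engine: every random partition
// re-estimates one direction per window from each half of the trials, so a
// permutation test or a 100-repeat null simulation runs this thousands of
// times. Uses R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// pooled within-class covariance, df-weighted
static arma::mat pooled_cov(const arma::mat& a, const arma::mat& b) {
  arma::mat ca = a.each_row() - arma::mean(a, 0);
  arma::mat cb = b.each_row() - arma::mean(b, 0);
  return (ca.t() * ca + cb.t() * cb) / double(a.n_rows + b.n_rows - 2);
}

// regularized LDA direction; returns false on failure
static bool lda_direction(const arma::mat& a, const arma::mat& b,
                          double gamma, double delta, arma::vec& out) {
  if (a.n_rows < 2 || b.n_rows < 2) return false;
  arma::mat S = pooled_cov(a, b);
  arma::mat Sg = (1.0 - gamma) * S + gamma * arma::diagmat(S);
  arma::vec dmu = arma::mean(a, 0).t() - arma::mean(b, 0).t();
  arma::vec w;
  if (!arma::solve(w, Sg, dmu, arma::solve_opts::no_approx)) return false;
  if (!w.is_finite()) return false;
  if (delta > 0) {
    double mx = arma::abs(w).max();
    w.elem(arma::find(arma::abs(w) < delta * mx)).zeros();
  }
  double nw = arma::norm(w);
  if (nw == 0) return false;
  out = w / nw;
  return true;
}

// random half-partition of 0..n-1 using R's RNG
static void half_split(int n, arma::uvec& h1, arma::uvec& h2) {
  IntegerVector idx = sample(n, n, false); // 1..n permuted
  int n1 = n / 2;
  h1.set_size(n1);
  h2.set_size(n - n1);
  for (int i = 0; i < n1; ++i) h1[i] = idx[i] - 1;
  for (int i = n1; i < n; ++i) h2[i - n1] = idx[i] - 1;
}

// directions for all windows from one half of the trials, NaN-padded;
// control trials are shared across windows (one count matrix per window,
// rows aligned), so one control split serves every window
static arma::mat half_directions(const List& ctrl,
                                 const List& sil,
                                 const List& active,
                                 const arma::uvec& ctrl_rows,
                                 const std::vector<arma::uvec>& sil_rows,
                                 double gamma, double delta, int p) {
  int n_w = sil.size();
  arma::mat D(n_w, p);
  D.fill(arma::datum::nan);
  for (int w = 0; w < n_w; ++w) {
    arma::uvec act = as<arma::uvec>(active[w]); // 0-based active columns
    if (act.n_elem < 2) continue;
    const arma::mat& cw = as<arma::mat>(ctrl[w]);
    const arma::mat& sw = as<arma::mat>(sil[w]);
    arma::mat a = cw.submat(ctrl_rows, act);
    arma::mat b = sw.submat(sil_rows[w], act);
    arma::vec v;
    if (!lda_direction(a, b, gamma, delta, v)) continue;
    for (arma::uword j = 0; j < act.n_elem; ++j) D(w, act[j]) = v[j];
  }
  return D;
}

// NaN-aware cosine between two coefficient vectors on common support
static double nan_cosine(const arma::rowvec& u, const arma::rowvec& v) {
  double uv = 0, uu = 0, vv = 0;
  int n_ok = 0;
  for (arma::uword i = 0; i < u.n_elem; ++i) {
    if (std::isfinite(u[i]) && std::isfinite(v[i])) {
      uv += u[i] * v[i];
      uu += u[i] * u[i];
      vv += v[i] * v[i];
      ++n_ok;
    }
  }
  if (n_ok < 2 || uu == 0 || vv == 0) return arma::datum::nan;
  return uv / std::sqrt(uu * vv);
}

//' @noRd
// [[Rcpp::export(name = ".cd_sim_kernel")]]
arma::mat cd_sim_kernel(const List& ctrl, const List& sil,
                        const List& active, double gamma, double delta,
                        int n_splits) {
  int n_w = sil.size();
  int p = as<arma::mat>(ctrl[0]).n_cols;
  int n_ctrl = as<arma::mat>(ctrl[0]).n_rows;
  arma::mat acc(n_w, n_w, arma::fill::zeros);
  arma::imat cnt(n_w, n_w, arma::fill::zeros);
  for (int s = 0; s < n_splits; ++s) {
    arma::uvec c1, c2;
    half_split(n_ctrl, c1, c2);
    std::vector<arma::uvec> s1(n_w), s2(n_w);
    for (int w = 0; w < n_w; ++w) {
      const arma::mat& sw = as<arma::mat>(sil[w]);
      half_split(sw.n_rows, s1[w], s2[w]);
    }
    arma::mat D1 = half_directions(ctrl, sil, active, c1, s1, gamma,
                                   delta, p);
    arma::mat D2 = half_directions(ctrl, sil, active, c2, s2, gamma,
                                   delta, p);
    for (int i = 0; i < n_w; ++i) {
      for (int j = 0; j < n_w; ++j) {
        double m12 = nan_cosine(D1.row(i), D2.row(j));
        double m21 = nan_cosine(D2.row(i), D1.row(j));
        double m;
        if (std::isfinite(m12) && std::isfinite(m21)) {
          m = 0.5 * (m12 + m21);
        } else if (std::isfinite(m12)) {
          m = m12;
        } else if (std::isfinite(m21)) {
          m = m21;
        } else {
          continue;
        }
        acc(i, j) += m;
        cnt(i, j) += 1;
      }
    }
  }
  arma::mat out(n_w, n_w);
  for (int i = 0; i < n_w; ++i) {
    for (int j = 0; j < n_w; ++j) {
      out(i, j) = cnt(i, j) > 0 ? acc(i, j) / cnt(i, j)
                                : arma::datum::nan;
    }
  }
  return out;
}
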