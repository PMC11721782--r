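#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- sequence weights ---------------------------------------------------

// Per-sequence neighbor counts m_j = #{ s : identity(s_j, s) >= thr }
// (self included). X: N x L integer codes 1..21, 21 = gap.
// [[Rcpp::export]]
NumericVector neighbor_counts_cpp(IntegerMatrix X, double thr,
                                  bool exclude_double_gaps) {
  const int N = X.nrow(), L = X.ncol();
  NumericVector m(N, 0.0);
  for (int a = 0; a < N; ++a) {
    m[a] += 1.0;  // self
    for (int b = a + 1; b < N; ++b) {
      int match = 0, denom = 0;
      for (int k = 0; k < L; ++k) {
        int xa = X(a, k), xb = X(b, k);
        if (exclude_double_gaps && xa == 21 && xb == 21) continue;
        ++denom;
        if (xa == xb) ++match;
      }
      double id = denom > 0 ? (double)match / denom : 1.0;
      if (id >= thr) { m[a] += 1.0; m[b] += 1.0; }
    }
  }
  return m;
}

// ---- Potts pseudo-likelihood -------------------------------------------

// pair index for 0-based i < j among L sites
static inline int pair_index(int i, int j, int L) {
  return i * L - i * (i + 1) / 2 + (j - i - 1);
}

// J value for sites i < j, states a (at i), b (at j); column-major block,
// a fastest: Jflat[p*q*q + b*q + a]
static inline double jval(const double *J, int p, int a, int b, int q) {
  return J[(size_t)p * q * q + (size_t)b * q + a];
}

// Weighted joint pseudo-log-likelihood of a symmetric Potts model, with
// analytic gradient. X: N x L codes in 1..q. h: L x q. Jflat: npair*q*q.
// Value = sum_n w_n sum_i log P(x_ni | x_n,-i) - lambda_h*||h||^2
//         - lambda_J*||J||^2.
// [[Rcpp::export]]
List joint_pll_cpp(IntegerMatrix X, NumericVector w, NumericMatrix h,
                   NumericVector Jflat, double lambda_h, double lambda_J) {
  const int N = X.nrow(), L = X.ncol(), q = h.ncol();
  const double *J = Jflat.begin();
  NumericMatrix gh(L, q);
  NumericVector gJ(Jflat.size());
  std::vector<double> e(q), p(q);
  double val = 0.0;

  for (int n = 0; n < N; ++n) {
    const double wn = w[n];
    for (int i = 0; i < L; ++i) {
      const int si = X(n, i) - 1;
      for (int a = 0; a < q; ++a) e[a] = h(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        const int sj = X(n, j) - 1;
        if (i < j) {
          const int pi = pair_index(i, j, L);
          for (int a = 0; a < q; ++a) e[a] += jval(J, pi, a, sj, q);
        } else {
          const int pi = pair_index(j, i, L);
          for (int a = 0; a < q; ++a) e[a] += jval(J, pi, sj, a, q);
        }
      }
      double m = e[0];
      for (int a = 1; a < q; ++a) if (e[a] > m) m = e[a];
      double z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(e[a] - m); z += p[a]; }
      for (int a = 0; a < q; ++a) p[a] /= z;
      val += wn * (e[si] - m - std::log(z));
      for (int a = 0; a < q; ++a) {
        const double g = wn * (((a == si) ? 1.0 : 0.0) - p[a]);
        gh(i, a) += g;
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          const int sj = X(n, j) - 1;
          if (i < j)
            gJ[(size_t)pair_index(i, j, L) * q * q + (size_t)sj * q + a] += g;
          else
            gJ[(size_t)pair_index(j, i, L) * q * q + (size_t)a * q + sj] += g;
        }
      }
    }
  }
  // L2 penalties
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < q; ++a) {
      val -= lambda_h * h(i, a) * h(i, a);
      gh(i, a) -= 2.0 * lambda_h * h(i, a);
    }
  for (R_xlen_t k = 0; k < Jflat.size(); ++k) {
    val -= lambda_J * Jflat[k] * Jflat[k];
    gJ[k] -= 2.0 * lambda_J * Jflat[k];
  }
  return List::create(_["value"] = val, _["grad_h"] = gh, _["grad_J"] = gJ);
}

// Per-site conditional pseudo-log-likelihood (asymmetric plmDCA fit) with
// analytic gradient. par layout: h_i (q entries) then, for each other site j
// in ascending order, a q x q block K_j with entry K_j(a, b) at offset
// q + jj*q*q + b*q + a (a = state at site i, b = state at j).
// [[Rcpp::export]]
List site_pll_cpp(IntegerMatrix X, NumericVector w, int site,
                  NumericVector par, double lambda_h, double lambda_J,
                  int q) {
  const int N = X.nrow(), L = X.ncol(), i = site;
  const double *P = par.begin();
  NumericVector grad(par.size());
  std::vector<double> e(q), p(q);
  std::vector<int> others;
  others.reserve(L - 1);
  for (int j = 0; j < L; ++j) if (j != i) others.push_back(j);
  double val = 0.0;

  for (int n = 0; n < N; ++n) {
    const double wn = w[n];
    const int si = X(n, i) - 1;
    for (int a = 0; a < q; ++a) e[a] = P[a];
    for (size_t jj = 0; jj < others.size(); ++jj) {
      const int sj = X(n, others[jj]) - 1;
      const double *K = P + q + jj * q * q + (size_t)sj * q;
      for (int a = 0; a < q; ++a) e[a] += K[a];
    }
    double m = e[0];
    for (int a = 1; a < q; ++a) if (e[a] > m) m = e[a];
    double z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(e[a] - m); z += p[a]; }
    for (int a = 0; a < q; ++a) p[a] /= z;
    val += wn * (e[si] - m - std::log(z));
    for (int a = 0; a < q; ++a) {
      const double g = wn * (((a == si) ? 1.0 : 0.0) - p[a]);
      grad[a] += g;
      for (size_t jj = 0; jj < others.size(); ++jj) {
        const int sj = X(n, others[jj]) - 1;
        grad[q + jj * q * q + (size_t)sj * q + a] += g;
      }
    }
  }
  for (int a = 0; a < q; ++a) {
    val -= lambda_h * P[a] * P[a];
    grad[a] -= 2.0 * lambda_h * P[a];
  }
  for (R_xlen_t k = q; k < par.size(); ++k) {
    val -= lambda_J * P[k] * P[k];
    grad[k] -= 2.0 * lambda_J * P[k];
  }
  return List::create(_["value"] = val, _["grad"] = grad);
}

// ---- Gibbs sampler ------------------------------------------------------

// Sequential-sweep Gibbs sampler for P(S) propto exp(sum h + sum J).
// Uses R's RNG so draws are reproducible via set.seed(). Returns
// nsamples x L matrix of codes 1..q.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix h, NumericVector Jflat,
                               int nsamples, int burn_in, int thin,
                               IntegerVector start) {
  const int L = h.nrow(), q = h.ncol();
  const double *J = Jflat.begin();
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = start[i] - 1;
  IntegerMatrix out(nsamples, L);
  std::vector<double> e(q), p(q);

  auto sweep = [&]() {
    for (int i = 0; i < L; ++i) {
      for (int a = 0; a < q; ++a) e[a] = h(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        if (i < j) {
          const int pi = pair_index(i, j, L);
          for (int a = 0; a < q; ++a) e[a] += jval(J, pi, a, s[j], q);
        } else {
          const int pi = pair_index(j, i, L);
          for (int a = 0; a < q; ++a) e[a] += jval(J, pi, s[j], a, q);
        }
      }
      double m = e[0];
      for (int a = 1; a < q; ++a) if (e[a] > m) m = e[a];
      double z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(e[a] - m); z += p[a]; }
      double u = unif_rand() * z, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) {
        c += p[a];
        if (u <= c) { pick = a; break; }
      }
      s[i] = pick;
    }
  };

  GetRNGstate();
  for (int b = 0; b < burn_in; ++b) sweep();
  for (int n = 0; n < nsamples; ++n) {
    if (n > 0) for (int t = 0; t < thin; ++t) sweep();
    for (int i = 0; i < L; ++i) out(n, i) = s[i] + 1;
  }
  PutRNGstate();
  return out;
}

// ---- SASA point test ----------------------------------------------------

// For each of the n test points (rows of pts), return TRUE if it lies
// outside every neighbor sphere (centers nb, squared radii r2).
// [[Rcpp::export]]
LogicalVector points_accessible_cpp(NumericMatrix pts, NumericMatrix nb,
                                    NumericVector r2) {
  const int np = pts.nrow(), nn = nb.nrow();
  LogicalVector acc(np, true);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    for (int j = 0; j < nn; ++j) {
      const double dx = x - nb(j, 0), dy = y - nb(j, 1), dz = z - nb(j, 2);
      if (dx * dx + dy * dy + dz * dz < r2[j]) { acc[p] = false; break; }
    }
  }
  return acc;
}
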