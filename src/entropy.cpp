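#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// exp(-z) for z >= 0 via Cody-Waite range reduction and a degree-12
// Taylor polynomial; relative accuracy ~1e-15, adequate for entropy sums
// compared against a reference implementation at 1e-10.
static inline double exp_neg(double z) {
  if (z > 745.0) return 0.0;
  static const double INV_LN2 = 1.4426950408889634074;
  static const double LN2_HI = 6.93147180369123816490e-01;
  static const double LN2_LO = 1.90821492927058770002e-10;
  const double kd = std::nearbyint(z * INV_LN2);
  const double f = (z - kd * LN2_HI) - kd * LN2_LO;  // |f| <= 0.3466
  const double x = -f;
  double p = 1.0 / 479001600.0;  // 1/12!
  p = p * x + 1.0 / 39916800.0;
  p = p * x + 1.0 / 3628800.0;
  p = p * x + 1.0 / 362880.0;
  p = p * x + 1.0 / 40320.0;
  p = p * x + 1.0 / 5040.0;
  p = p * x + 1.0 / 720.0;
  p = p * x + 1.0 / 120.0;
  p = p * x + 1.0 / 24.0;
  p = p * x + 1.0 / 6.0;
  p = p * x + 0.5;
  p = p * x + 1.0;
  p = p * x + 1.0;
  // scale by 2^-k through the exponent bits (k in [0, 1075]); below the
  // normal range fall back to ldexp for correct subnormal rounding
  const int k = (int)kd;
  if (k < 1000) {
    union { double d; unsigned long long u; } s;
    s.u = (unsigned long long)(1023 - k) << 52;
    return p * s.d;
  }
  return std::ldexp(p, -k);
}

static inline double pown(double u, double n, bool cubic) {
  return cubic ? u * u * u : std::pow(u, n);
}

// indices 0..k-1 sorted by ascending v
static std::vector<int> sort_index(const double* v, int k) {
  std::vector<int> idx(k);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

// Template-match counts for sample entropy (Chebyshev distance, self-
// matches excluded; both counts over the first N-m templates, Richman &
// Moorman convention).  Pairs are enumerated through the templates sorted
// by first coordinate, so only pairs within tolerance in that coordinate
// are inspected; the counts are exactly those of the naive double loop.
// Returns c(A, B): matches at length m+1 and at length m.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;
  double A = 0.0, B = 0.0;
  std::vector<int> idx = sort_index(REAL(x), nt);
  std::vector<double> tpl((size_t)nt * (m + 1));
  for (int s = 0; s < nt; ++s)
    for (int t = 0; t <= m; ++t)
      tpl[(size_t)s * (m + 1) + t] = x[idx[s] + t];
  for (int si = 0; si < nt - 1; ++si) {
    const double* a = &tpl[(size_t)si * (m + 1)];
    for (int sj = si + 1; sj < nt; ++sj) {
      const double* b = &tpl[(size_t)sj * (m + 1)];
      if (b[0] - a[0] > r) break;
      bool ok = true;
      for (int t = 1; t < m; ++t)
        if (std::fabs(a[t] - b[t]) > r) { ok = false; break; }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(a[m] - b[m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Shared tail of the fuzzy estimators: truncation threshold for membership
// terms.  Terms below max_term * 1e-13 / npairs are dropped; the summed
// error is then below 1e-13 of the final phi, far inside the 1e-10
// agreement required of the estimator.  max_term is lower-bounded from a
// candidate near-minimal-distance pair found via the sorted first
// coordinate, so the cut is always conservative.
static inline double dist_cut(double max_term_lb, double npairs,
                              double r, double n, bool cubic) {
  double z = -std::log(std::max(max_term_lb, 1e-300)) +
             std::log(npairs) + 13.0 * std::log(10.0);
  z = std::min(z, 745.0);
  return r * (cubic ? std::cbrt(z) : std::pow(z, 1.0 / n));
}

// Mean fuzzy memberships exp(-(d/r)^n) over template pairs at embedding
// lengths m and m+1, with the whole-window mean removed by the caller
// (global variant) or each template's own mean removed (local variant).
// Returns c(phi_m, phi_m1).
//
// For the local variant with m = 2 the baseline-removed Chebyshev
// distances have closed forms in the first differences p[i] = x[i]-x[i+1]:
//   d_m  = |p_i - p_j| / 2
//   d_m1 = max(|2a+b|, |a-b|, |a+2b|) / 3,  a = p_i-p_j, b = p_{i+1}-p_{j+1}
// and both satisfy d >= |a|/2, so sorting templates by p gives an exact
// neighbour cut-off.  Other m fall back to the naive pair loop.
// [[Rcpp::export]]
NumericVector fuzzen_phi_cpp(NumericVector x, int m, double r, double n,
                             bool local) {
  const int N = x.size();
  const int nt = N - m;
  const double npairs = 0.5 * (double)nt * (nt - 1);
  const bool cubic = (n == 3.0);
  double phi_m = 0.0, phi_m1 = 0.0;

  if (local && m == 2) {
    std::vector<double> p(N - 1);
    for (int i = 0; i < N - 1; ++i) p[i] = x[i] - x[i + 1];
    std::vector<int> idx = sort_index(p.data(), nt);
    // contiguous copies in sorted order: ps[s] = p at sorted template s,
    // qs[s] = the following first difference of the same template
    std::vector<double> ps(nt), qs(nt);
    for (int s = 0; s < nt; ++s) {
      ps[s] = p[idx[s]];
      qs[s] = p[idx[s] + 1];
    }
    // lower-bound the maximal memberships over a small sorted
    // neighbourhood (near-minimal |a| pairs contain the near-minimal
    // distances at both orders)
    double t2 = 0.0, t3 = 0.0;
    for (int s = 0; s < nt - 1; ++s) {
      const int jmax = std::min(s + 8, nt - 1);
      for (int sj = s + 1; sj <= jmax; ++sj) {
        const double a = ps[s] - ps[sj], b = qs[s] - qs[sj];
        const double d2 = 0.5 * std::fabs(a);
        const double d3 = std::max({std::fabs(2 * a + b), std::fabs(a - b),
                                    std::fabs(a + 2 * b)}) / 3.0;
        t2 = std::max(t2, exp_neg(pown(d2 / r, n, cubic)));
        t3 = std::max(t3, exp_neg(pown(d3 / r, n, cubic)));
      }
    }
    const double cut2 = dist_cut(t2, npairs, r, n, cubic);
    const double cut3 = dist_cut(t3, npairs, r, n, cubic);
    const double zcut2 = pown(cut2 / r, n, cubic);
    const double zcut3 = pown(cut3 / r, n, cubic);
    const double scan = 2.0 * std::max(cut2, cut3);  // both d >= |a|/2
    const double invr = 1.0 / r;
    // two-pass per template: a branch-free vectorizable distance pass into
    // buffers, then the membership summation; the scan end pointer is
    // monotone in si (two-pointer over the sorted first differences)
    std::vector<double> z2buf(nt), z3buf(nt);
    int e = 1;
    for (int si = 0; si < nt - 1; ++si) {
      const double pi_ = ps[si], qi = qs[si];
      if (e <= si) e = si + 1;
      while (e < nt && ps[e] - pi_ <= scan) ++e;
      const int len = e - (si + 1);
      const double* pj = &ps[si + 1];
      const double* qj = &qs[si + 1];
      for (int u = 0; u < len; ++u) {
        const double a = (pi_ - pj[u]) * invr;
        const double b = (qi - qj[u]) * invr;
        const double d2 = 0.5 * std::fabs(a);
        double d3 = std::fabs(2 * a + b);
        d3 = std::max(d3, std::fabs(a - b));
        d3 = std::max(d3, std::fabs(a + 2 * b));
        d3 /= 3.0;
        z2buf[u] = cubic ? d2 * d2 * d2 : std::pow(d2, n);
        z3buf[u] = cubic ? d3 * d3 * d3 : std::pow(d3, n);
      }
      for (int u = 0; u < len; ++u)
        if (z2buf[u] <= zcut2) phi_m += exp_neg(z2buf[u]);
      for (int u = 0; u < len; ++u)
        if (z3buf[u] <= zcut3) phi_m1 += exp_neg(z3buf[u]);
    }
    return NumericVector::create(phi_m / npairs, phi_m1 / npairs);
  }

  if (!local) {
    // global variant: Chebyshev distance over raw (pre-centered) samples;
    // every distance is >= the first-coordinate gap, so a sorted scan on
    // x[i] is exact.  Templates are copied contiguously in sorted order.
    std::vector<int> idx = sort_index(REAL(x), nt);
    std::vector<double> tpl((size_t)nt * (m + 1));
    for (int s = 0; s < nt; ++s)
      for (int t = 0; t <= m; ++t)
        tpl[(size_t)s * (m + 1) + t] = x[idx[s] + t];
    double t2 = 0.0, t3 = 0.0;
    for (int s = 0; s < nt - 1; ++s) {
      const int jmax = std::min(s + 8, nt - 1);
      for (int sj = s + 1; sj <= jmax; ++sj) {
        const double* a = &tpl[(size_t)s * (m + 1)];
        const double* b = &tpl[(size_t)sj * (m + 1)];
        double d2 = 0.0;
        for (int t = 0; t < m; ++t) d2 = std::max(d2, std::fabs(a[t] - b[t]));
        const double d3 = std::max(d2, std::fabs(a[m] - b[m]));
        t2 = std::max(t2, exp_neg(pown(d2 / r, n, cubic)));
        t3 = std::max(t3, exp_neg(pown(d3 / r, n, cubic)));
      }
    }
    const double cut2 = dist_cut(t2, npairs, r, n, cubic);
    const double cut3 = dist_cut(t3, npairs, r, n, cubic);
    const double scan = std::max(cut2, cut3);
    for (int si = 0; si < nt - 1; ++si) {
      const double* a = &tpl[(size_t)si * (m + 1)];
      for (int sj = si + 1; sj < nt; ++sj) {
        const double* b = &tpl[(size_t)sj * (m + 1)];
        if (b[0] - a[0] > scan) break;
        double dm = 0.0;
        for (int t = 0; t < m; ++t) dm = std::max(dm, std::fabs(a[t] - b[t]));
        if (dm <= cut2) phi_m += exp_neg(pown(dm / r, n, cubic));
        const double dm1 = std::max(dm, std::fabs(a[m] - b[m]));
        if (dm1 <= cut3) phi_m1 += exp_neg(pown(dm1 / r, n, cubic));
      }
    }
    return NumericVector::create(phi_m / npairs, phi_m1 / npairs);
  }

  // generic local variant (m != 2): naive pair loop with rolling means
  std::vector<double> mu_m(nt), mu_m1(nt);
  {
    double s = 0.0;
    for (int t = 0; t < m; ++t) s += x[t];
    for (int i = 0; i < nt; ++i) {
      mu_m[i] = s / m;
      mu_m1[i] = (s + x[i + m]) / (m + 1);
      if (i + 1 < nt) s += x[i + m] - x[i];
    }
  }
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      const double del_m = mu_m[i] - mu_m[j];
      const double del_m1 = mu_m1[i] - mu_m1[j];
      double dm = 0.0, dm1 = 0.0;
      for (int t = 0; t < m; ++t) {
        const double diff = x[i + t] - x[j + t];
        dm = std::max(dm, std::fabs(diff - del_m));
        dm1 = std::max(dm1, std::fabs(diff - del_m1));
      }
      dm1 = std::max(dm1, std::fabs(x[i + m] - x[j + m] - del_m1));
      phi_m += exp_neg(pown(dm / r, n, cubic));
      phi_m1 += exp_neg(pown(dm1 / r, n, cubic));
    }
  }
  return NumericVector::create(phi_m / npairs, phi_m1 / npairs);
}

// Bubble-sort swap counts (= inversion counts, strict >) of each embedded
// vector of length m.
// [[Rcpp::export]]
IntegerVector swap_counts_cpp(NumericVector x, int m) {
  const int nt = x.size() - m + 1;
  IntegerVector out(nt);
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int a = 0; a < m - 1; ++a)
      for (int b = a + 1; b < m; ++b)
        if (x[i + a] > x[i + b]) ++c;
    out[i] = c;
  }
  return out;
}
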