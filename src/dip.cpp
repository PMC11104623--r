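// Hartigan's dip statistic: the minimal sup-norm distance between the
// empirical CDF of a sample and the class of unimodal CDFs (convex below the
// mode, concave above it, possibly with an atom at the mode).
//
// The computation runs a bisection on the band half-width d and decides, for
// each d, whether some unimodal CDF fits inside the band
// [F - d, F + d] around the empirical CDF. Writing g_t for the candidate CDF
// value at the t-th distinct sample point (cumulative count c_t out of n),
// the sup-norm constraint is exactly c_t/n - d <= g_t <= c_{t-1}/n + d, and
// unimodality means: g is convex up to some split, concave after it (with the
// values at the two sides of the split compatible), or has an atom at the
// modal sample point, which relaxes one band bound there. Convexity of a
// sequence within a band is decided exactly via the greatest convex minorant
// (lower hull) of the upper bounds; concavity by mirroring. Compatibility
// across the split is decided exactly via the attainable end-value intervals
// (bisection on a capped bound).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double FEPS = 1e-11;

// Existence of a convex sequence g_i on abscissae x[i], i in [a, b], with
// L[i] <= g_i <= U[i]; if capIdx is in range, U[capIdx] is lowered to capVal.
static bool convex_band_feasible(const std::vector<double>& x,
                                 const std::vector<double>& U,
                                 const std::vector<double>& L,
                                 int a, int b, int capIdx = -1,
                                 double capVal = 0.0) {
  if (a > b) return true;
  int m = b - a + 1;
  std::vector<double> Ue(m);
  for (int i = 0; i < m; ++i) Ue[i] = U[a + i];
  if (capIdx >= a && capIdx <= b && capVal < Ue[capIdx - a])
    Ue[capIdx - a] = capVal;
  if (m == 1) return Ue[0] >= L[a] - FEPS;
  // lower convex hull of (x[a+i], Ue[i]): edge slopes strictly increase
  std::vector<int> st;
  st.reserve(m);
  for (int i = 0; i < m; ++i) {
    while (st.size() >= 2) {
      int p = st[st.size() - 1], q = st[st.size() - 2];
      double lhs = (Ue[i] - Ue[p]) * (x[a + p] - x[a + q]);
      double rhs = (Ue[p] - Ue[q]) * (x[a + i] - x[a + p]);
      if (lhs <= rhs) st.pop_back(); else break;
    }
    st.push_back(i);
  }
  size_t seg = 0;
  for (int i = 0; i < m; ++i) {
    while (seg + 1 < st.size() && st[seg + 1] <= i) ++seg;
    double v;
    if (st[seg] == i) {
      v = Ue[i];
    } else {
      int u = st[seg], w = st[seg + 1];
      v = Ue[u] + (Ue[w] - Ue[u]) * (x[a + i] - x[a + u]) / (x[a + w] - x[a + u]);
    }
    if (v < L[a + i] - FEPS) return false;
  }
  return true;
}

// Existence of a concave sequence within the band; if floorIdx is in range,
// L[floorIdx] is raised to floorVal.
static bool concave_band_feasible(const std::vector<double>& x,
                                  const std::vector<double>& U,
                                  const std::vector<double>& L,
                                  int a, int b, int floorIdx = -1,
                                  double floorVal = 0.0) {
  if (a > b) return true;
  std::vector<double> U2(x.size()), L2(x.size());
  for (int i = a; i <= b; ++i) { U2[i] = -L[i]; L2[i] = -U[i]; }
  double cap = (floorIdx >= a && floorIdx <= b) ? -floorVal : 0.0;
  return convex_band_feasible(x, U2, L2, a, b,
                              (floorIdx >= a && floorIdx <= b) ? floorIdx : -1,
                              cap);
}

// Minimal attainable g[at] over convex in-band sequences on [a, b]
// (assumes the uncapped problem is feasible).
static double convex_min_at(const std::vector<double>& x,
                            const std::vector<double>& U,
                            const std::vector<double>& L,
                            int a, int b, int at) {
  double lo = L[at], hi = U[at];
  if (convex_band_feasible(x, U, L, a, b, at, lo)) return lo;
  for (int it = 0; it < 45 && hi - lo > 1e-13; ++it) {
    double mid = 0.5 * (lo + hi);
    if (convex_band_feasible(x, U, L, a, b, at, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

// Maximal attainable g[at] over concave in-band sequences on [a, b].
static double concave_max_at(const std::vector<double>& x,
                             const std::vector<double>& U,
                             const std::vector<double>& L,
                             int a, int b, int at) {
  double lo = L[at], hi = U[at];
  if (concave_band_feasible(x, U, L, a, b, at, hi)) return hi;
  for (int it = 0; it < 45 && hi - lo > 1e-13; ++it) {
    double mid = 0.5 * (lo + hi);
    if (concave_band_feasible(x, U, L, a, b, at, mid)) lo = mid; else hi = mid;
  }
  return lo;
}

// Does some unimodal CDF fit in the +/- d band around the ECDF?
// x: distinct sorted sample values; cum: cumulative counts; n: sample size.
static bool unimodal_feasible(const std::vector<double>& x,
                              const std::vector<double>& cum, int n,
                              double d) {
  int m = (int) x.size();
  std::vector<double> lo(m), hi(m);
  for (int t = 0; t < m; ++t) {
    lo[t] = cum[t] / n - d;
    hi[t] = (t ? cum[t - 1] : 0.0) / n + d;
  }
  // number of leading points on the convex side: j in 0..m
  auto Lfeas = [&](int j) {
    return convex_band_feasible(x, hi, lo, 0, j - 1);
  };
  auto Rfeas = [&](int k) {
    return concave_band_feasible(x, hi, lo, k, m - 1);
  };
  if (Lfeas(m)) return true;   // mode at/after the last point
  if (Rfeas(0)) return true;   // mode at/before the first point
  int loj = 0, hij = m;        // Lfeas(0) true, Lfeas(m) false
  while (hij - loj > 1) {
    int mid = (loj + hij) / 2;
    if (Lfeas(mid)) loj = mid; else hij = mid;
  }
  int Jmax = loj;
  int lok = 0, hik = m;        // Rfeas(0) false, Rfeas(m) true
  while (hik - lok > 1) {
    int mid = (lok + hik) / 2;
    if (Rfeas(mid)) hik = mid; else lok = mid;
  }
  int Kmin = hik;
  int j0 = std::max(1, Kmin), j1 = std::min(Jmax, m - 1);
  // mode strictly between points j-1 and j: need compatible end values
  for (int j = j1; j >= j0; --j) {
    if (convex_band_feasible(x, hi, lo, 0, j - 1, j - 1, lo[j - 1]))
      return true; // left side can end as low as its own lower band
    if (concave_band_feasible(x, hi, lo, j, m - 1, j, hi[j]))
      return true; // right side can start as high as its own upper band
  }
  for (int j = j1; j >= j0; --j) {
    double amin = convex_min_at(x, hi, lo, 0, j - 1, j - 1);
    double bmax = concave_max_at(x, hi, lo, j, m - 1, j);
    if (amin <= bmax + FEPS) return true;
  }
  // atom at the mode point t: the left limit of the CDF at x[t] replaces the
  // lower band bound there (convex side); the value at x[t] replaces the
  // upper bound on the concave side.
  // atom at t implies convex feasibility on 0..t-1 and concave on t+1..m-1,
  // so only t in [Kmin-1, Jmax+1] can work
  int t0 = std::max(0, Kmin - 1), t1 = std::min(m - 1, Jmax + 1);
  std::vector<double> loL = lo, hiR = hi;
  for (int t = t0; t <= t1; ++t) {
    double cprev = (t ? cum[t - 1] : 0.0) / n;
    double cthis = cum[t] / n;
    loL[t] = cprev - d;          // relax lower bound for the left limit
    hiR[t] = cthis + d;          // relax upper bound for the value at x[t]
    bool okL = convex_band_feasible(x, hi, loL, 0, t);
    bool okR = okL && concave_band_feasible(x, hiR, lo, t, m - 1);
    if (okR) {
      if (convex_band_feasible(x, hi, loL, 0, t, t, lo[t])) {
        loL[t] = lo[t]; hiR[t] = hi[t];
        return true;
      }
      if (concave_band_feasible(x, hiR, lo, t, m - 1, t, hi[t])) {
        loL[t] = lo[t]; hiR[t] = hi[t];
        return true;
      }
      double amin = convex_min_at(x, hi, loL, 0, t, t);
      double bmax = concave_max_at(x, hiR, lo, t, m - 1, t);
      if (amin <= bmax + FEPS) {
        loL[t] = lo[t]; hiR[t] = hi[t];
        return true;
      }
    }
    loL[t] = lo[t];
    hiR[t] = hi[t];
  }
  return false;
}

static double dip_of_sorted(const std::vector<double>& v) {
  int n = (int) v.size();
  std::vector<double> x, cum;
  x.reserve(n); cum.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (!x.empty() && v[i] == x.back()) cum.back() += 1.0;
    else { x.push_back(v[i]); cum.push_back(cum.empty() ? 1.0 : cum.back() + 1.0); }
  }
  if (x.size() <= 1) return 0.0;
  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 50 && hi - lo > 1e-13; ++it) {
    double mid = 0.5 * (lo + hi);
    if (unimodal_feasible(x, cum, n, mid)) hi = mid; else lo = mid;
  }
  return hi;
}

// [[Rcpp::export]]
double dip_cpp(NumericVector xs) {
  std::vector<double> v = as<std::vector<double>>(xs);
  if (v.empty()) stop("empty sample");
  for (double z : v) if (!std::isfinite(z)) stop("non-finite sample value");
  std::sort(v.begin(), v.end());
  return dip_of_sorted(v);
}

// Dip statistics of `reps` uniform(0,1) samples of size n (uses R's RNG).
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int reps) {
  NumericVector out(reps);
  std::vector<double> v(n);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) v[i] = R::runif(0.0, 1.0);
    std::sort(v.begin(), v.end());
    out[r] = dip_of_sorted(v);
  }
  return out;
}
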