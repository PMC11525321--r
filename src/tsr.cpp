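// Trapezoidal segmented regression (TSR): least-squares fit of a continuous
// piecewise-linear signal whose segments strictly alternate between zero
// slope (flat) and free slope (sloped), with breakpoints restricted to
// sample positions.
//
// Two engines share one evaluator:
//  * exact enumeration over breakpoint placements (small search spaces);
//  * a dynamic program over (position, discretized breakpoint value) states,
//    followed by an exact least-squares re-solve of the levels given the DP
//    breakpoints and coordinate-descent refinement of breakpoint positions.
//
// Indexing is 0-based internally; breakpoints are p[0]=0 < ... < p[T]=N-1.
// Segment j (1..T) owns samples [p[j-1], p[j]-1], the last segment also owns
// sample N-1; continuity makes the prediction at a breakpoint identical from
// both sides, so this half-open ownership counts every sample exactly once.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Prefix {
  std::vector<double> s1, s2, si; // prefix sums of v, v^2, i*v
  int N;
  void init(const NumericVector& v) {
    N = v.size();
    s1.assign(N + 1, 0.0); s2.assign(N + 1, 0.0); si.assign(N + 1, 0.0);
    for (int i = 0; i < N; ++i) {
      s1[i + 1] = s1[i] + v[i];
      s2[i + 1] = s2[i] + v[i] * v[i];
      si[i + 1] = si[i] + double(i) * v[i];
    }
  }
  // inclusive range [a, m]
  double S1(int a, int m) const { return s1[m + 1] - s1[a]; }
  double S2(int a, int m) const { return s2[m + 1] - s2[a]; }
  double SI(int a, int m) const { return si[m + 1] - si[a]; }
};

inline double sumIdx(int a, int m) { // sum of i over [a, m]
  return 0.5 * (double(a) + m) * (m - a + 1);
}
inline double sumIdx2(int a, int m) { // sum of i^2 over [a, m]
  auto f = [](double x) { return x * (x + 1) * (2 * x + 1) / 6.0; };
  return f(m) - f(a - 1.0);
}

// Quadratic coefficients of a sloped segment from breakpoint a (value ua) to
// breakpoint b (value ub), owning inclusive samples [a, m]:
// cost = A ua^2 + B ub^2 + 2C ua ub - 2D ua - 2E ub + F
struct SlopedQ { double A, B, C, D, E, F; };

SlopedQ slopedQ(const Prefix& P, int a, int b, int m) {
  double L = double(b) - a;
  double n = double(m) - a + 1;
  double W1 = (sumIdx(a, m) - double(a) * n) / L;
  double W2 = (sumIdx2(a, m) - 2.0 * a * sumIdx(a, m) + double(a) * a * n) / (L * L);
  double S1 = P.S1(a, m), S2 = P.S2(a, m);
  double Sw = (P.SI(a, m) - double(a) * S1) / L;
  SlopedQ q;
  q.A = n - 2 * W1 + W2;
  q.B = W2;
  q.C = W1 - W2;
  q.D = S1 - Sw;
  q.E = Sw;
  q.F = S2;
  return q;
}

// kind of segment j (1-based) under parity: parity 0 = first segment flat.
inline bool isFlat(int j, int parity) {
  return (j % 2 == 1) == (parity == 0);
}

// Dense symmetric solve (Gaussian elimination with partial pivoting).
bool solveDense(std::vector<std::vector<double>>& H, std::vector<double>& g) {
  int n = g.size();
  for (int k = 0; k < n; ++k) {
    int piv = k;
    for (int i = k + 1; i < n; ++i)
      if (std::fabs(H[i][k]) > std::fabs(H[piv][k])) piv = i;
    if (std::fabs(H[piv][k]) < 1e-12) {
      H[k][k] += 1e-9; // harmless ridge for a data-untouched variable
      if (std::fabs(H[k][k]) < 1e-12) return false;
    } else if (piv != k) {
      std::swap(H[piv], H[k]);
      std::swap(g[piv], g[k]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = H[i][k] / H[k][k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) H[i][j] -= f * H[k][j];
      g[i] -= f * g[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = g[k];
    for (int j = k + 1; j < n; ++j) s -= H[k][j] * g[j];
    g[k] = s / H[k][k];
  }
  return true;
}

// Exact least-squares levels for fixed breakpoints and parity.
// Returns sse; fills u (values at breakpoints).
double solveGivenBreaks(const Prefix& P, const std::vector<int>& p, int parity,
                        std::vector<double>& u) {
  int T = p.size() - 1;
  std::vector<int> var(T + 1);
  int nv = 1;
  var[0] = 0;
  for (int j = 1; j <= T; ++j)
    var[j] = isFlat(j, parity) ? var[j - 1] : nv++;
  std::vector<std::vector<double>> H(nv, std::vector<double>(nv, 0.0));
  std::vector<double> g(nv, 0.0);
  double c0 = 0.0;
  for (int j = 1; j <= T; ++j) {
    int a = p[j - 1], b = p[j];
    int m = (j == T) ? b : b - 1;
    if (isFlat(j, parity)) {
      double n = double(m) - a + 1;
      int k = var[j];
      H[k][k] += n;
      g[k] += P.S1(a, m);
      c0 += P.S2(a, m);
    } else {
      SlopedQ q = slopedQ(P, a, b, m);
      int ka = var[j - 1], kb = var[j];
      H[ka][ka] += q.A; H[kb][kb] += q.B;
      H[ka][kb] += q.C; H[kb][ka] += q.C;
      g[ka] += q.D; g[kb] += q.E;
      c0 += q.F;
    }
  }
  std::vector<double> gs = g;
  if (!solveDense(H, gs)) return INF;
  double sse = c0;
  for (int k = 0; k < nv; ++k) sse -= g[k] * gs[k];
  if (sse < 0 && sse > -1e-8) sse = 0.0;
  u.resize(T + 1);
  for (int j = 0; j <= T; ++j) u[j] = gs[var[j]];
  return sse;
}

struct FitResult {
  std::vector<int> p;
  std::vector<double> u;
  int parity = 0;
  double sse = INF;
};

// Exhaustive enumeration over interior breakpoints for one parity.
void exactParity(const Prefix& P, int T, int parity, FitResult& best) {
  int N = P.N;
  std::vector<int> p(T + 1);
  p[0] = 0; p[T] = N - 1;
  std::vector<int> c(T - 1); // interior breakpoints, values in [1, N-2]
  for (int i = 0; i < T - 1; ++i) c[i] = i + 1;
  std::vector<double> u;
  while (true) {
    for (int i = 0; i < T - 1; ++i) p[i + 1] = c[i];
    double sse = solveGivenBreaks(P, p, parity, u);
    if (sse < best.sse) { best.sse = sse; best.p = p; best.u = u; best.parity = parity; }
    // next combination
    int i = T - 2;
    while (i >= 0 && c[i] == N - 2 - (T - 2 - i)) --i;
    if (i < 0) break;
    ++c[i];
    for (int k = i + 1; k < T - 1; ++k) c[k] = c[k - 1] + 1;
  }
}

// Coordinate descent on interior breakpoint positions with exact level
// re-solves; refines in place.
void refineBreaks(const Prefix& P, FitResult& r, int max_sweeps = 10) {
  int T = r.p.size() - 1;
  if (T < 2) return;
  std::vector<double> u;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool improved = false;
    for (int j = 1; j <= T - 1; ++j) {
      int lo = r.p[j - 1] + 1, hi = r.p[j + 1] - 1;
      int bestPos = r.p[j];
      double bestSse = r.sse;
      std::vector<int> q = r.p;
      for (int pos = lo; pos <= hi; ++pos) {
        if (pos == r.p[j]) continue;
        q[j] = pos;
        double sse = solveGivenBreaks(P, q, r.parity, u);
        if (sse < bestSse - 1e-12) { bestSse = sse; bestPos = pos; }
      }
      if (bestPos != r.p[j]) {
        r.p[j] = bestPos;
        r.sse = solveGivenBreaks(P, r.p, r.parity, r.u);
        improved = true;
      }
    }
    if (!improved) break;
  }
}

// DP over (position, discretized breakpoint value) for one parity.
void dpParity(const Prefix& P, int T, int parity, const NumericVector& levels,
              FitResult& best) {
  int N = P.N, L = levels.size();
  // V[p][l]: min cost of first j segments ending at breakpoint p with value
  // levels[l]; rolling over j with backpointers for reconstruction.
  std::vector<double> Vprev(N * L, INF), Vcur(N * L, INF);
  std::vector<std::vector<int>> fromPos(T + 1), fromLev(T + 1);
  for (int l = 0; l < L; ++l) Vprev[0 * L + l] = 0.0;
  for (int j = 1; j <= T; ++j) {
    std::fill(Vcur.begin(), Vcur.end(), INF);
    fromPos[j].assign(N * L, -1);
    fromLev[j].assign(N * L, -1);
    bool flat = isFlat(j, parity);
    int qlo = j, qhi = N - 1 - (T - j);
    if (j == T) qlo = qhi = N - 1;
    for (int q = qlo; q <= qhi; ++q) {
      int m = (j == T) ? q : q - 1;
      for (int p = j - 1; p <= q - 1; ++p) {
        // prune unreachable predecessors
        bool any = false;
        for (int l = 0; l < L; ++l) if (Vprev[p * L + l] < INF) { any = true; break; }
        if (!any) continue;
        if (flat) {
          double n = double(m) - p + 1;
          double S1 = P.S1(p, m), S2 = P.S2(p, m);
          for (int l = 0; l < L; ++l) {
            double vp = Vprev[p * L + l];
            if (!(vp < INF)) continue;
            double c = levels[l];
            double cost = n * c * c - 2 * S1 * c + S2;
            double cand = vp + cost;
            if (cand < Vcur[q * L + l]) {
              Vcur[q * L + l] = cand;
              fromPos[j][q * L + l] = p;
              fromLev[j][q * L + l] = l;
            }
          }
        } else {
          SlopedQ qq = slopedQ(P, p, q, m);
          for (int l = 0; l < L; ++l) {
            double vp = Vprev[p * L + l];
            if (!(vp < INF)) continue;
            double ua = levels[l];
            double base = vp + qq.A * ua * ua - 2 * qq.D * ua + qq.F;
            double lin = 2 * qq.C * ua - 2 * qq.E;
            for (int l2 = 0; l2 < L; ++l2) {
              double ub = levels[l2];
              double cand = base + qq.B * ub * ub + lin * ub;
              if (cand < Vcur[q * L + l2]) {
                Vcur[q * L + l2] = cand;
                fromPos[j][q * L + l2] = p;
                fromLev[j][q * L + l2] = l;
              }
            }
          }
        }
      }
    }
    std::swap(Vprev, Vcur);
  }
  int bl = -1;
  double bv = INF;
  for (int l = 0; l < L; ++l)
    if (Vprev[(N - 1) * L + l] < bv) { bv = Vprev[(N - 1) * L + l]; bl = l; }
  if (bl < 0) return; // infeasible (should not happen when N >= T+1)
  // backtrack breakpoints
  std::vector<int> p(T + 1);
  p[T] = N - 1;
  int pos = N - 1, lev = bl;
  for (int j = T; j >= 1; --j) {
    int pp = fromPos[j][pos * L + lev];
    int pl = fromLev[j][pos * L + lev];
    p[j - 1] = pp;
    pos = pp; lev = pl;
  }
  FitResult r;
  r.p = p; r.parity = parity;
  r.sse = solveGivenBreaks(P, p, parity, r.u);
  refineBreaks(P, r);
  if (r.sse < best.sse) best = r;
}

} // namespace

// [[Rcpp::export(name = ".tsr_fit_cpp")]]
List tsr_fit_cpp(NumericVector values, int T, NumericVector levels,
                 double exact_limit) {
  int N = values.size();
  if (N < T + 1) stop("segment budget too large: T = %d needs at least %d samples", T, T + 1);
  Prefix P;
  P.init(values);
  FitResult best;
  if (T == 1) {
    // single-segment trapezoidal signal: the least-squares constant
    std::vector<int> p = {0, N - 1};
    best.p = p;
    best.parity = 0;
    best.sse = solveGivenBreaks(P, p, 0, best.u);
  } else {
    // log-scale count of breakpoint placements: C(N-2, T-1)
    double lc = 0.0;
    for (int i = 1; i <= T - 1; ++i)
      lc += std::log(double(N - 2 - (T - 1) + i)) - std::log(double(i));
    bool exact = 2.0 * std::exp(lc) <= exact_limit;
    for (int parity = 0; parity <= 1; ++parity) {
      if (exact) exactParity(P, T, parity, best);
      else dpParity(P, T, parity, levels, best);
    }
  }
  if (!(best.sse < INF)) stop("TSR fit failed");
  return List::create(
    _["breakpoints"] = IntegerVector(best.p.begin(), best.p.end()),
    _["values"] = NumericVector(best.u.begin(), best.u.end()),
    _["parity"] = best.parity,
    _["sse"] = best.sse,
    _["exact"] = 2.0 * R::choose(double(N - 2), double(T - 1)) <= exact_limit || T == 1);
}

// [[Rcpp::export(name = ".tsr_solve_breaks_cpp")]]
List tsr_solve_breaks_cpp(NumericVector values, IntegerVector breakpoints,
                          int parity) {
  Prefix P;
  P.init(values);
  std::vector<int> p(breakpoints.begin(), breakpoints.end());
  std::vector<double> u;
  double sse = solveGivenBreaks(P, p, parity, u);
  return List::create(_["values"] = NumericVector(u.begin(), u.end()),
                      _["sse"] = sse);
}
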