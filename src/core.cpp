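// Core combinatorial engine for grid-diagram topology.
//
// A grid diagram of size n is a pair of permutations (xs, os) of {0..n-1}:
// xs[c] / os[c] are the rows of the X / O marking in column c (row 0 at the
// bottom).  Column c carries a vertical segment between its two markings,
// row r a horizontal segment; vertical segments always overpass.
//
// Knot invariants are computed from the winding-number (grid) matrix
// M(t)[a][b] = t^{w(a,b)}, whose determinant equals
// +- t^k (1-t)^(n-1) Delta(t) for a knot with Alexander polynomial Delta.
// Determinants are evaluated with modular arithmetic (61/62-bit primes) and
// lifted exactly; Hadamard bounds keep lifts exact at the grid sizes used.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <functional>

using namespace Rcpp;

typedef long long ll;
typedef unsigned long long ull;
typedef __int128 lll;
typedef unsigned __int128 ulll;

static const ull P1 = 2305843009213693951ULL;  // 2^61 - 1 (Mersenne)
static const ull P2 = 2305843009213693967ULL;  // prime
static const ull P3 = 4611686018427387847ULL;  // prime (62-bit), spare

static inline ull mulmod(ull a, ull b, ull p) {
  return (ull)(((ulll)a * b) % p);
}
static inline ull addmod(ull a, ull b, ull p) { ull s = a + b; return s >= p ? s - p : s; }
static inline ull submod(ull a, ull b, ull p) { return a >= b ? a - b : a + p - b; }
static inline ull powmod(ull a, ull e, ull p) {
  ull r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}
static inline ull invmod(ull a, ull p) { return powmod(a % p, p - 2, p); }
// symmetric lift of residue r mod p into (-p/2, p/2]
static inline ll symlift(ull r, ull p) { return (r > p / 2) ? (ll)r - (ll)p : (ll)r; }

// ---------------------------------------------------------------------------
// basic structure

static int comp_count(const std::vector<int>& xs, const std::vector<int>& os) {
  // cycles of the row permutation sending os[c] -> xs[c]
  int n = (int)xs.size();
  std::vector<int> nxt(n);
  for (int c = 0; c < n; ++c) nxt[os[c]] = xs[c];
  std::vector<char> seen(n, 0);
  int cycles = 0;
  for (int r = 0; r < n; ++r) {
    if (seen[r]) continue;
    ++cycles;
    int cur = r;
    while (!seen[cur]) { seen[cur] = 1; cur = nxt[cur]; }
  }
  return cycles;
}

// winding-number matrix exponents, rebalanced so each row's minimum is 0.
// w(a,b) = sum over columns c < a of s_c * [min_c < b <= max_c],
// s_c = +1 if the vertical segment in column c is oriented upward (X -> O).
static void winding_exponents(const std::vector<int>& xs, const std::vector<int>& os,
                              std::vector<std::vector<int> >& E) {
  int n = (int)xs.size();
  E.assign(n, std::vector<int>(n, 0));
  std::vector<int> cum(n, 0);  // winding at current column line, per row line b
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) E[a][b] = cum[b];
    int lo = std::min(xs[a], os[a]), hi = std::max(xs[a], os[a]);
    int s = (os[a] > xs[a]) ? 1 : -1;
    for (int b = lo + 1; b <= hi; ++b) cum[b] += s;
  }
  for (int a = 0; a < n; ++a) {
    int mn = E[a][0];
    for (int b = 1; b < n; ++b) mn = std::min(mn, E[a][b]);
    for (int b = 0; b < n; ++b) E[a][b] -= mn;
  }
}

// determinant mod p of the matrix with entries tval^E[i][j]
static ull det_exp_mod(const std::vector<std::vector<int> >& E, ull tval, ull p) {
  int n = (int)E.size();
  int emax = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) emax = std::max(emax, E[i][j]);
  std::vector<ull> tp(emax + 1);
  tp[0] = 1;
  for (int e = 1; e <= emax; ++e) tp[e] = mulmod(tp[e - 1], tval % p, p);
  std::vector<std::vector<ull> > M(n, std::vector<ull>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) M[i][j] = tp[E[i][j]];
  ull det = 1; int sign = 1;
  for (int c = 0; c < n; ++c) {
    int piv = -1;
    for (int r = c; r < n; ++r) if (M[r][c] != 0) { piv = r; break; }
    if (piv < 0) return 0;
    if (piv != c) { std::swap(M[piv], M[c]); sign = -sign; }
    det = mulmod(det, M[c][c], p);
    ull inv = invmod(M[c][c], p);
    for (int r = c + 1; r < n; ++r) {
      if (M[r][c] == 0) continue;
      ull f = mulmod(M[r][c], inv, p);
      for (int j = c; j < n; ++j) M[r][j] = submod(M[r][j], mulmod(f, M[c][j], p), p);
    }
  }
  if (sign < 0) det = (det == 0) ? 0 : p - det;
  return det;
}

// exact determinant of the +-1 / power-of-2 winding matrices via modular
// lift (single prime for n <= 7, CRT of two primes for n = 8).
static bool det_exact(const std::vector<std::vector<int> >& E, ull tval, lll& out) {
  int n = (int)E.size();
  ull r1 = det_exp_mod(E, tval % P1, P1);
  if (n <= 7) { out = symlift(r1, P1); return true; }
  if (n > 8) return false;
  ull r2 = det_exp_mod(E, tval % P2, P2);
  // CRT: x = r1 + P1 * ((r2 - r1) * inv(P1) mod P2), lift symmetric
  ull d = submod(r2 % P2, r1 % P2, P2);
  ull k = mulmod(d, invmod(P1 % P2, P2), P2);
  ulll x = (ulll)r1 + (ulll)P1 * k;
  ulll mod = (ulll)P1 * P2;
  if (x > mod / 2) out = (lll)x - (lll)mod; else out = (lll)x;
  return true;
}

// fingerprint for exhaustive censuses (n <= 8):
//   det  = |Delta(-1)|   (the knot determinant)
//   odd2 = odd part of |Delta(2)| (0 if Delta(2) = 0)
// both well defined despite the +-t^k unit ambiguity.
static bool fingerprint(const std::vector<int>& xs, const std::vector<int>& os,
                        ll& det, ll& odd2) {
  int n = (int)xs.size();
  std::vector<std::vector<int> > E;
  winding_exponents(xs, os, E);
  lll dm1, d2;
  if (!det_exact(E, P1 - 1, dm1)) return false;   // t = -1 mod p
  if (!det_exact(E, 2, d2)) return false;
  lll a = dm1 < 0 ? -dm1 : dm1;
  for (int i = 0; i < n - 1; ++i) {
    if (a & 1) return false;  // must be divisible by 2^(n-1)
    a >>= 1;
  }
  det = (ll)a;
  lll b = d2 < 0 ? -d2 : d2;
  if (b == 0) { odd2 = 0; return true; }
  while (!(b & 1)) b >>= 1;
  if (b > (lll)1 << 62) return false;
  odd2 = (ll)b;
  return true;
}

// ---------------------------------------------------------------------------
// label table for the census fast path (everything realizable at GN <= 8)

static const int N_LAB = 12;  // 11 named + "other"
static const int LAB_OTHER = 11;
static const char* LAB_NAMES[N_LAB] = {
  "0_1", "3_1", "4_1", "5_1", "5_2", "6_1", "6_2", "6_3", "8_19", "8_20", "8_21",
  "other"
};
static const ll LAB_DET[N_LAB - 1]  = {1, 3, 5, 5, 7, 9, 11, 13, 3, 9, 15};
static const ll LAB_ODD2[N_LAB - 1] = {1, 3, 1, 11, 1, 0, 1, 7, 39, 9, 3};

static int label_of(ll det, ll odd2) {
  for (int k = 0; k < N_LAB - 1; ++k)
    if (LAB_DET[k] == det && LAB_ODD2[k] == odd2) return k;
  return LAB_OTHER;
}

// ---------------------------------------------------------------------------
// moves and juxtaposition geometry

struct Juxt {
  bool interleaved;
  int cls;   // 0 free, 1 mixed, 2 hooked (valid only if interleaved)
  int area;  // valid only if hooked
};

// classify the adjacent pair (i, i+1); axis 0 = columns, axis 1 = rows.
// xinv/oinv are the inverse permutations (row -> column of X / O marking).
static Juxt classify_pair(const std::vector<int>& xs, const std::vector<int>& os,
                          const std::vector<int>& xinv, const std::vector<int>& oinv,
                          int axis, int i) {
  Juxt J; J.interleaved = false; J.cls = -1; J.area = 0;
  int e1a, e1b, e2a, e2b;
  if (axis == 0) { e1a = xs[i]; e1b = os[i]; e2a = xs[i + 1]; e2b = os[i + 1]; }
  else           { e1a = xinv[i]; e1b = oinv[i]; e2a = xinv[i + 1]; e2b = oinv[i + 1]; }
  int lo1 = std::min(e1a, e1b), hi1 = std::max(e1a, e1b);
  int lo2 = std::min(e2a, e2b), hi2 = std::max(e2a, e2b);
  int y1, y2;  // inner endpoints: y1 on line i (inside the other interval), y2 on line i+1
  if (lo1 < lo2 && lo2 < hi1 && hi1 < hi2)      { y1 = hi1; y2 = lo2; }
  else if (lo2 < lo1 && lo1 < hi2 && hi2 < hi1) { y1 = lo1; y2 = hi2; }
  else return J;
  J.interleaved = true;
  // partner line of the perpendicular segment attached at each inner endpoint
  int d, e;
  if (axis == 0) {
    d = (xinv[y1] == i) ? oinv[y1] : xinv[y1];           // row y1's other column
    e = (xinv[y2] == i + 1) ? oinv[y2] : xinv[y2];       // row y2's other column
  } else {
    d = (xs[y1] == i) ? os[y1] : xs[y1];                 // column y1's other row
    e = (xs[y2] == i + 1) ? os[y2] : xs[y2];
  }
  bool in1 = d > i + 1;   // extends across the neighbouring line
  bool in2 = e < i;
  if (in1 && in2) { J.cls = 2; J.area = std::abs(y1 - y2); }
  else if (!in1 && !in2) J.cls = 0;
  else J.cls = 1;
  return J;
}

static void commute_inplace(std::vector<int>& xs, std::vector<int>& os, int axis, int i) {
  int n = (int)xs.size();
  if (axis == 0) {
    std::swap(xs[i], xs[i + 1]);
    std::swap(os[i], os[i + 1]);
  } else {
    for (int c = 0; c < n; ++c) {
      if (xs[c] == i) xs[c] = i + 1; else if (xs[c] == i + 1) xs[c] = i;
      if (os[c] == i) os[c] = i + 1; else if (os[c] == i + 1) os[c] = i;
    }
  }
}

static inline bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] < b[i]) return true;
    if (a[i] > b[i]) return false;
  }
  return false;
}

static ull pack_key(const std::vector<int>& xs, const std::vector<int>& os) {
  ull k = 0;
  for (size_t i = 0; i < xs.size(); ++i) k = (k << 3) | (ull)xs[i];
  for (size_t i = 0; i < os.size(); ++i) k = (k << 3) | (ull)os[i];
  return k;
}

// one destabilization, if any 2x2 block holds three markings.  Scan order is
// deterministic (rows from bottom, then columns).  Returns false if none.
static bool destabilize_inplace(std::vector<int>& xs, std::vector<int>& os) {
  int n = (int)xs.size();
  if (n <= 2) return false;
  for (int r = 0; r < n - 1; ++r) {
    for (int c = 0; c < n - 1; ++c) {
      int cnt = 0;
      cnt += (xs[c] == r) + (xs[c] == r + 1) + (os[c] == r) + (os[c] == r + 1);
      int cnt2 = (xs[c + 1] == r) + (xs[c + 1] == r + 1) + (os[c + 1] == r) + (os[c + 1] == r + 1);
      if (cnt + cnt2 != 3) continue;
      // pair column cp holds both block markings; co holds one (M1)
      int cp = (cnt == 2) ? c : c + 1;
      int co = (cnt == 2) ? c + 1 : c;
      int rm = (xs[co] == r || os[co] == r) ? r : r + 1;  // M1's row
      int re = (rm == r) ? r + 1 : r;                     // empty cell's row
      if (xs[co] == rm) xs[co] = re; else os[co] = re;
      // delete column cp and row rm
      std::vector<int> nx, no;
      nx.reserve(n - 1); no.reserve(n - 1);
      for (int cc = 0; cc < n; ++cc) {
        if (cc == cp) continue;
        int xr = xs[cc], orr = os[cc];
        nx.push_back(xr > rm ? xr - 1 : xr);
        no.push_back(orr > rm ? orr - 1 : orr);
      }
      xs.swap(nx); os.swap(no);
      return true;
    }
  }
  return false;
}

// xorshift64* PRNG (deterministic across platforms)
struct XRng {
  ull s;
  explicit XRng(ull seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  ull next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int m) { return (int)(next() % (ull)m); }
};

// ---------------------------------------------------------------------------
// exported: structure and invariants

// [[Rcpp::export]]
int gk_component_count(IntegerVector x, IntegerVector o) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  return comp_count(xs, os);
}

// [[Rcpp::export]]
IntegerMatrix gk_crossings(IntegerVector x, IntegerVector o) {
  int n = x.size();
  std::vector<int> xinv(n), oinv(n);
  for (int c = 0; c < n; ++c) { xinv[x[c]] = c; oinv[o[c]] = c; }
  std::vector<std::pair<int,int> > cr;
  for (int c = 0; c < n; ++c) {
    int lo = std::min(x[c], o[c]), hi = std::max(x[c], o[c]);
    for (int r = lo + 1; r < hi; ++r) {
      int cl = std::min(xinv[r], oinv[r]), ch = std::max(xinv[r], oinv[r]);
      if (cl < c && c < ch) cr.push_back(std::make_pair(c, r));
    }
  }
  IntegerMatrix out((int)cr.size(), 2);
  for (size_t k = 0; k < cr.size(); ++k) { out(k, 0) = cr[k].first; out(k, 1) = cr[k].second; }
  colnames(out) = CharacterVector::create("col", "row");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix gk_winding_matrix(IntegerVector x, IntegerVector o) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  int n = (int)xs.size();
  // un-rebalanced winding numbers, for inspection/tests
  IntegerMatrix W(n, n);
  std::vector<int> cum(n, 0);
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) W(a, b) = cum[b];
    int lo = std::min(xs[a], os[a]), hi = std::max(xs[a], os[a]);
    int s = (os[a] > xs[a]) ? 1 : -1;
    for (int b = lo + 1; b <= hi; ++b) cum[b] += s;
  }
  return W;
}

// [[Rcpp::export]]
NumericVector gk_fingerprint(IntegerVector x, IntegerVector o) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  ll det, odd2;
  if (!fingerprint(xs, os, det, odd2))
    stop("fingerprint unavailable (grid number too large or overflow)");
  return NumericVector::create(_["det"] = (double)det, _["odd2"] = (double)odd2);
}

// Exact Alexander polynomial: centered coefficient vector (t^-d .. t^d),
// normalized symmetric with Delta(1) = 1.  ok = FALSE flags any failed
// exactness/shape check (caller should treat the knot as unidentified).
// [[Rcpp::export]]
List gk_alexander(IntegerVector x, IntegerVector o) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  int n = (int)xs.size();
  std::vector<std::vector<int> > E;
  winding_exponents(xs, os, E);
  int D = 0;
  for (int a = 0; a < n; ++a) {
    int mx = 0;
    for (int b = 0; b < n; ++b) mx = std::max(mx, E[a][b]);
    D += mx;
  }
  int npts = D + 1;
  std::vector<std::vector<ll> > lifts(2);
  ull primes[2] = {P1, P2};
  for (int ip = 0; ip < 2; ++ip) {
    ull p = primes[ip];
    std::vector<ull> ts(npts), ys(npts);
    for (int j = 0; j < npts; ++j) {
      ts[j] = (ull)(j + 2);
      ys[j] = det_exp_mod(E, ts[j], p);
    }
    // Lagrange interpolation: coefficients of the degree <= D polynomial
    std::vector<ull> prod(npts + 1, 0);  // prod(x) = Π (x - t_j)
    prod[0] = 1;
    int plen = 1;
    for (int j = 0; j < npts; ++j) {
      // multiply by (x - t_j)
      for (int k = plen; k >= 1; --k)
        prod[k] = submod(prod[k - 1], mulmod(prod[k], ts[j], p), p);
      prod[0] = mulmod(prod[0], p - ts[j], p);
      ++plen;
    }
    std::vector<ull> coef(npts, 0);
    std::vector<ull> q(npts);
    for (int j = 0; j < npts; ++j) {
      // q = prod / (x - t_j), synthetic division
      ull carry = prod[npts];
      for (int k = npts - 1; k >= 0; --k) {
        q[k] = carry;
        carry = addmod(prod[k], mulmod(carry, ts[j], p), p);
      }
      ull denom = 1;
      for (int k = 0; k < npts; ++k)
        if (k != j) denom = mulmod(denom, submod(ts[j], ts[k], p), p);
      ull w = mulmod(ys[j], invmod(denom, p), p);
      for (int k = 0; k < npts; ++k)
        coef[k] = addmod(coef[k], mulmod(q[k], w, p), p);
    }
    // divide by (t - 1)^(n-1); each remainder must vanish
    std::vector<ull> cur(coef);
    int len = npts;
    for (int rep = 0; rep < n - 1; ++rep) {
      ull carry = 0;
      for (int k = len - 1; k >= 1; --k) {
        carry = addmod(cur[k], carry, p);
        cur[k] = carry;  // quotient coefficient for x^(k-1)
      }
      ull rem = addmod(cur[0], carry, p);
      if (rem != 0) return List::create(_["coeffs"] = NumericVector(0), _["ok"] = false);
      for (int k = 0; k < len - 1; ++k) cur[k] = cur[k + 1];
      --len;
      cur[len] = 0;
    }
    if ((n - 1) % 2 == 1)  // (1-t)^(n-1) = (-1)^(n-1) (t-1)^(n-1)
      for (int k = 0; k < len; ++k) cur[k] = (cur[k] == 0) ? 0 : p - cur[k];
    cur.resize(len);
    std::vector<ll> lift(len);
    for (int k = 0; k < len; ++k) lift[k] = symlift(cur[k], p);
    lifts[ip] = lift;
  }
  if (lifts[0] != lifts[1])
    return List::create(_["coeffs"] = NumericVector(0), _["ok"] = false);
  std::vector<ll>& v = lifts[0];
  // strip the t^m unit factor
  int lo = 0, hi = (int)v.size() - 1;
  while (lo <= hi && v[lo] == 0) ++lo;
  while (hi >= lo && v[hi] == 0) --hi;
  if (lo > hi) return List::create(_["coeffs"] = NumericVector(0), _["ok"] = false);
  std::vector<ll> c(v.begin() + lo, v.begin() + hi + 1);
  // shape checks: odd span, palindromic, Delta(1) = +-1
  bool ok = (c.size() % 2 == 1);
  ll s = 0;
  for (size_t k = 0; k < c.size(); ++k) {
    s += c[k];
    if (c[k] != c[c.size() - 1 - k]) ok = false;
  }
  if (s == -1) { for (size_t k = 0; k < c.size(); ++k) c[k] = -c[k]; s = 1; }
  if (s != 1) ok = false;
  NumericVector out(c.size());
  for (size_t k = 0; k < c.size(); ++k) out[k] = (double)c[k];
  return List::create(_["coeffs"] = out, _["ok"] = ok);
}

// ---------------------------------------------------------------------------
// exported: moves

// [[Rcpp::export]]
List gk_commute(IntegerVector x, IntegerVector o, int axis, int i) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  commute_inplace(xs, os, axis, i);
  return List::create(_["x"] = IntegerVector(xs.begin(), xs.end()),
                      _["o"] = IntegerVector(os.begin(), os.end()));
}

// classify all adjacent pairs on both axes
// [[Rcpp::export]]
DataFrame gk_classify_pairs(IntegerVector x, IntegerVector o) {
  int n = x.size();
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  std::vector<int> xinv(n), oinv(n);
  for (int c = 0; c < n; ++c) { xinv[xs[c]] = c; oinv[os[c]] = c; }
  int m = 2 * (n - 1);
  CharacterVector axis(m), cls(m);
  IntegerVector idx(m), area(m);
  LogicalVector inter(m);
  int k = 0;
  for (int ax = 0; ax <= 1; ++ax) {
    for (int i = 0; i < n - 1; ++i, ++k) {
      Juxt J = classify_pair(xs, os, xinv, oinv, ax, i);
      axis[k] = (ax == 0) ? "column" : "row";
      idx[k] = i;
      inter[k] = J.interleaved;
      if (!J.interleaved) { cls[k] = "not-interleaved"; area[k] = NA_INTEGER; }
      else {
        cls[k] = (J.cls == 2) ? "hooked" : (J.cls == 1 ? "mixed" : "free");
        area[k] = (J.cls == 2) ? J.area : NA_INTEGER;
      }
    }
  }
  return DataFrame::create(_["axis"] = axis, _["index"] = idx,
                           _["interleaved"] = inter, _["class"] = cls,
                           _["area"] = area, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List gk_destabilize_once(IntegerVector x, IntegerVector o) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  if (!destabilize_inplace(xs, os)) return List::create(_["found"] = false);
  return List::create(_["found"] = true,
                      _["x"] = IntegerVector(xs.begin(), xs.end()),
                      _["o"] = IntegerVector(os.begin(), os.end()));
}

// greedy simplification: destabilize whenever possible, otherwise walk over
// random topology-preserving (non-interleaved) commutations.
// [[Rcpp::export]]
List gk_simplify(IntegerVector x, IntegerVector o, int max_steps, double seed) {
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  XRng rng((ull)seed);
  int steps = 0;
  while (steps < max_steps) {
    if (destabilize_inplace(xs, os)) { ++steps; continue; }
    int n = (int)xs.size();
    if (n <= 3) break;
    bool reduced = false;
    int walk = 50 * n;
    std::vector<int> xinv(n), oinv(n);
    for (int k = 0; k < walk && steps < max_steps; ++k) {
      int ax = rng.below(2), i = rng.below(n - 1);
      for (int c = 0; c < n; ++c) { xinv[xs[c]] = c; oinv[os[c]] = c; }
      Juxt J = classify_pair(xs, os, xinv, oinv, ax, i);
      if (J.interleaved) continue;  // would be a strand passage, skip
      commute_inplace(xs, os, ax, i);
      ++steps;
      if (destabilize_inplace(xs, os)) { ++steps; reduced = true; break; }
    }
    if (!reduced) break;
  }
  return List::create(_["x"] = IntegerVector(xs.begin(), xs.end()),
                      _["o"] = IntegerVector(os.begin(), os.end()),
                      _["steps"] = steps);
}

// ---------------------------------------------------------------------------
// exported: enumeration, census, passage events

// iterate all canonical single-component grids of size n, calling f
template <typename F>
static void enumerate_canonical(int n, F f) {
  std::vector<int> xs(n), q(n - 1);
  for (int i = 0; i < n - 1; ++i) q[i] = i + 1;
  std::vector<int> sinv(n), os(n);
  // outer loop: n-cycles sigma = (0 q0 q1 ... q_{n-2}); os = sigma^{-1} o xs
  do {
    sinv[q[0]] = 0;
    for (int i = 1; i < n - 1; ++i) sinv[q[i]] = q[i - 1];
    sinv[0] = q[n - 2];
    for (int i = 0; i < n; ++i) xs[i] = i;
    do {
      for (int i = 0; i < n; ++i) os[i] = sinv[xs[i]];
      if (lex_less(xs, os)) f(xs, os);
    } while (std::next_permutation(xs.begin(), xs.end()));
  } while (std::next_permutation(q.begin(), q.end()));
}

// [[Rcpp::export]]
List gk_enumerate(int n) {
  if (n < 3 || n > 7) stop("exhaustive enumeration supports 3 <= n <= 7");
  std::vector<int> X, O;
  enumerate_canonical(n, [&](const std::vector<int>& xs, const std::vector<int>& os) {
    X.insert(X.end(), xs.begin(), xs.end());
    O.insert(O.end(), os.begin(), os.end());
  });
  int m = (int)(X.size() / n);
  IntegerMatrix MX(m, n), MO(m, n);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < n; ++c) { MX(r, c) = X[(size_t)r * n + c]; MO(r, c) = O[(size_t)r * n + c]; }
  return List::create(_["x"] = MX, _["o"] = MO);
}

struct GnDict {
  std::vector<ull> keys;
  std::vector<uint8_t> labels;
  std::vector<double> counts;  // per label
};

static void build_dict(int n, GnDict& D, bool store_keys = true) {
  D.counts.assign(N_LAB, 0.0);
  std::vector<std::pair<ull, uint8_t> > recs;
  enumerate_canonical(n, [&](const std::vector<int>& xs, const std::vector<int>& os) {
    ll det, odd2;
    if (!fingerprint(xs, os, det, odd2)) stop("fingerprint failed during census");
    int lab = label_of(det, odd2);
    if (store_keys) recs.push_back(std::make_pair(pack_key(xs, os), (uint8_t)lab));
    D.counts[lab] += 1.0;
  });
  std::sort(recs.begin(), recs.end());
  D.keys.resize(recs.size());
  D.labels.resize(recs.size());
  for (size_t i = 0; i < recs.size(); ++i) { D.keys[i] = recs[i].first; D.labels[i] = recs[i].second; }
}

static int dict_lookup(const GnDict& D, ull key) {
  std::vector<ull>::const_iterator it = std::lower_bound(D.keys.begin(), D.keys.end(), key);
  if (it == D.keys.end() || *it != key) return -1;
  return D.labels[it - D.keys.begin()];
}

// [[Rcpp::export]]
DataFrame gk_census(int nmin, int nmax) {
  if (nmin < 3 || nmax > 8 || nmin > nmax) stop("census supports 3 <= gn <= 8");
  std::vector<int> gn_out; std::vector<std::string> lab_out; std::vector<double> cnt_out;
  for (int n = nmin; n <= nmax; ++n) {
    GnDict D;
    // n = 8 is expert-mode: counts only, no lookup dictionary (memory)
    build_dict(n, D, n <= 7);
    for (int k = 0; k < N_LAB; ++k) {
      if (D.counts[k] > 0) {
        gn_out.push_back(n);
        lab_out.push_back(LAB_NAMES[k]);
        cnt_out.push_back(D.counts[k]);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["gn"] = gn_out, _["knot"] = lab_out, _["count"] = cnt_out,
                           _["stringsAsFactors"] = false);
}

// Strand-passage events aggregated by gn, from-label, to-label, geometry
// class, and hooked area.  With dedup = FALSE every (diagram, interleaved
// adjacent pair) counts one event.  With dedup = TRUE events are directed
// edges of the diagram network: for each diagram, distinct resulting
// canonical diagrams count once, classified by the minimal hooked area over
// the sites producing them ("free"/"mixed" when no hooked site does; the
// smaller class is kept when both occur at the minimal-area tie level).
// [[Rcpp::export]]
DataFrame gk_passage_events(int nmin, int nmax, bool dedup) {
  if (nmin < 3 || nmax > 7 || nmin > nmax) stop("passage scan supports 3 <= gn <= 7");
  std::vector<int> gn_out, area_out;
  std::vector<std::string> from_out, to_out, cat_out;
  std::vector<double> cnt_out;
  for (int n = nmin; n <= nmax; ++n) {
    GnDict D;
    build_dict(n, D);
    // buckets: 0 free, 1 mixed, 2+a hooked with area a (a in 1..n-2)
    int nb = 2 + (n - 1);
    std::vector<double> acc((size_t)nb * N_LAB * N_LAB, 0.0);
    std::vector<int> xs(n), os(n), cx(n), co(n), xinv(n), oinv(n);
    std::vector<std::pair<ull,int> > results;  // (result key, bucket), per diagram
    for (size_t di = 0; di < D.keys.size(); ++di) {
      ull key = D.keys[di];
      for (int i = 2 * n - 1; i >= 0; --i) {
        int v = (int)(key & 7ULL);
        key >>= 3;
        if (i >= n) os[i - n] = v; else xs[i] = v;
      }
      int from = D.labels[di];
      for (int c = 0; c < n; ++c) { xinv[xs[c]] = c; oinv[os[c]] = c; }
      results.clear();
      for (int ax = 0; ax <= 1; ++ax) {
        for (int i = 0; i < n - 1; ++i) {
          Juxt J = classify_pair(xs, os, xinv, oinv, ax, i);
          if (!J.interleaved) continue;
          cx = xs; co = os;
          commute_inplace(cx, co, ax, i);
          ull k2 = lex_less(cx, co) ? pack_key(cx, co) : pack_key(co, cx);
          int bucket = (J.cls == 0) ? 0 : (J.cls == 1 ? 1 : 1 + J.area);
          if (!dedup) {
            int to = dict_lookup(D, k2);
            if (to < 0) stop("passage result missing from census dictionary");
            acc[((size_t)bucket * N_LAB + from) * N_LAB + to] += 1.0;
          } else {
            results.push_back(std::make_pair(k2, bucket));
          }
        }
      }
      if (dedup && !results.empty()) {
        std::sort(results.begin(), results.end());
        size_t j = 0;
        while (j < results.size()) {
          ull k2 = results[j].first;
          // hooked buckets (>= 2) dominate free/mixed; among hooked the
          // minimal area wins; among non-hooked, free (0) precedes mixed (1)
          int best = results[j].second;
          size_t j2 = j;
          while (j2 < results.size() && results[j2].first == k2) {
            int b = results[j2].second;
            bool bh = b >= 2, besth = best >= 2;
            if ((bh && !besth) || (bh == besth && b < best)) best = b;
            ++j2;
          }
          int to = dict_lookup(D, k2);
          if (to < 0) stop("passage result missing from census dictionary");
          acc[((size_t)best * N_LAB + from) * N_LAB + to] += 1.0;
          j = j2;
        }
      }
      if ((di & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    for (int b = 0; b < nb; ++b)
      for (int f = 0; f < N_LAB; ++f)
        for (int t = 0; t < N_LAB; ++t) {
          double v = acc[((size_t)b * N_LAB + f) * N_LAB + t];
          if (v == 0) continue;
          gn_out.push_back(n);
          from_out.push_back(LAB_NAMES[f]);
          to_out.push_back(LAB_NAMES[t]);
          cat_out.push_back(b == 0 ? "free" : (b == 1 ? "mixed" : "hooked"));
          area_out.push_back(b >= 2 ? b - 1 : NA_INTEGER);
          cnt_out.push_back(v);
        }
  }
  return DataFrame::create(_["gn"] = gn_out, _["from"] = from_out, _["to"] = to_out,
                           _["category"] = cat_out, _["area"] = area_out,
                           _["count"] = cnt_out, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// exported: Kauffman bracket / Jones polynomial

// [[Rcpp::export]]
List gk_jones(IntegerVector x, IntegerVector o, int max_crossings) {
  int n = x.size();
  std::vector<int> xs(x.begin(), x.end()), os(o.begin(), o.end());
  if (comp_count(xs, os) != 1) stop("Jones polynomial requires a single component");
  std::vector<int> xinv(n), oinv(n);
  for (int c = 0; c < n; ++c) { xinv[xs[c]] = c; oinv[os[c]] = c; }
  // crossings with ids
  std::vector<std::vector<std::pair<int,int> > > colcr(n), rowcr(n);  // (pos, id)
  int nc = 0;
  for (int c = 0; c < n; ++c) {
    int lo = std::min(xs[c], os[c]), hi = std::max(xs[c], os[c]);
    for (int r = lo + 1; r < hi; ++r) {
      int cl = std::min(xinv[r], oinv[r]), ch = std::max(xinv[r], oinv[r]);
      if (cl < c && c < ch) {
        colcr[c].push_back(std::make_pair(r, nc));
        rowcr[r].push_back(std::make_pair(c, nc));
        ++nc;
      }
    }
  }
  if (nc == 0)
    return List::create(_["tmin"] = 0, _["coeffs"] = NumericVector::create(1.0), _["ok"] = true);
  if (nc > max_crossings)
    return List::create(_["tmin"] = 0, _["coeffs"] = NumericVector(0), _["ok"] = false);
  for (int i = 0; i < n; ++i) {
    std::sort(colcr[i].begin(), colcr[i].end());
    std::sort(rowcr[i].begin(), rowcr[i].end());
  }
  // traverse: vertical X -> O, horizontal O -> X; record passages
  // nodes per crossing k: N=4k, S=4k+1, E=4k+2, W=4k+3
  std::vector<std::pair<int,int> > pass;  // (enter, exit)
  int wr = 0;
  int c0 = 0;
  int c = c0;
  do {
    // vertical segment in column c, from xs[c] to os[c]
    int dy = (os[c] > xs[c]) ? 1 : -1;
    std::vector<std::pair<int,int> >& vc = colcr[c];
    if (dy > 0) for (size_t k = 0; k < vc.size(); ++k)
      pass.push_back(std::make_pair(4 * vc[k].second + 1, 4 * vc[k].second + 0));
    else for (size_t k = vc.size(); k-- > 0; )
      pass.push_back(std::make_pair(4 * vc[k].second + 0, 4 * vc[k].second + 1));
    // horizontal segment in row r = os[c], from column c (O) to xinv[r] (X)
    int r = os[c];
    int cx = xinv[r];
    int dx = (cx > c) ? 1 : -1;
    std::vector<std::pair<int,int> >& hr = rowcr[r];
    if (dx > 0) for (size_t k = 0; k < hr.size(); ++k)
      pass.push_back(std::make_pair(4 * hr[k].second + 3, 4 * hr[k].second + 2));
    else for (size_t k = hr.size(); k-- > 0; )
      pass.push_back(std::make_pair(4 * hr[k].second + 2, 4 * hr[k].second + 3));
    // writhe: crossing sign = +1 iff under (dx) and over (dy of crossed column) agree
    for (size_t k = 0; k < hr.size(); ++k) {
      int cc = hr[k].first;
      int dyo = (os[cc] > xs[cc]) ? 1 : -1;
      wr += (dx == dyo) ? 1 : -1;
    }
    c = cx;
  } while (c != c0);
  if ((int)pass.size() != 2 * nc) stop("internal error: traversal mismatch");
  int nn = 4 * nc;
  std::vector<int> base(nn);
  for (int i = 0; i < nn; ++i) base[i] = i;
  std::vector<int> par(nn);
  // arcs: exit of passage j joins enter of passage j+1
  std::vector<std::pair<int,int> > arcs(pass.size());
  for (size_t j = 0; j < pass.size(); ++j)
    arcs[j] = std::make_pair(pass[j].second, pass[(j + 1) % pass.size()].first);
  // delta^L = (-A^2 - A^-2)^L, exponent range -2L..2L step 4
  std::vector<std::vector<ll> > dpow(nc + 1);
  dpow[0] = std::vector<ll>(1, 1);
  {
    // unsigned binomials by Pascal's rule, then the (-1)^L sign
    std::vector<std::vector<ll> > binom(nc + 1);
    binom[0] = std::vector<ll>(1, 1);
    for (int L = 1; L <= nc; ++L) {
      binom[L].assign(L + 1, 1);
      for (int j2 = 1; j2 < L; ++j2)
        binom[L][j2] = binom[L - 1][j2 - 1] + binom[L - 1][j2];
      dpow[L] = binom[L];
      if (L % 2 == 1) for (int j2 = 0; j2 <= L; ++j2) dpow[L][j2] = -dpow[L][j2];
    }
  }
  // bracket accumulator over exponents of A, offset
  int off = 3 * nc;
  std::vector<ll> bracket(6 * nc + 1, 0);
  std::function<int(int)> find = [&](int v) {
    while (par[v] != v) { par[v] = par[par[v]]; v = par[v]; }
    return v;
  };
  for (ull st = 0; st < (1ULL << nc); ++st) {
    for (int i = 0; i < nn; ++i) par[i] = i;
    for (size_t j = 0; j < arcs.size(); ++j) {
      int a = find(arcs[j].first), b = find(arcs[j].second);
      if (a != b) par[a] = b;
    }
    int na = 0;
    for (int k = 0; k < nc; ++k) {
      int N = 4 * k, S = 4 * k + 1, Ee = 4 * k + 2, Wd = 4 * k + 3;
      int u1, v1, u2, v2;
      if (st & (1ULL << k)) { ++na; u1 = N; v1 = Wd; u2 = S; v2 = Ee; }  // A-smoothing
      else { u1 = N; v1 = Ee; u2 = S; v2 = Wd; }                         // B-smoothing
      int a = find(u1), b = find(v1);
      if (a != b) par[a] = b;
      a = find(u2); b = find(v2);
      if (a != b) par[a] = b;
    }
    int loops = 0;
    for (int i = 0; i < nn; ++i) if (find(i) == i) ++loops;
    int e = 2 * na - nc;           // #A - #B
    int L = loops - 1;
    for (int j2 = 0; j2 <= L; ++j2) {
      int expo = e + 2 * L - 4 * j2;
      bracket[expo + off] += dpow[L][j2];
    }
    if ((st & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  // V(A) = (-A)^{-3w} * bracket; then t = A^{-4}
  ll sgn = (wr % 2 == 0) ? 1 : -1;
  std::vector<std::pair<int,ll> > terms;
  for (int i = 0; i < (int)bracket.size(); ++i) {
    if (bracket[i] == 0) continue;
    int aexp = i - off - 3 * wr;
    if (aexp % 4 != 0) stop("internal error: bracket exponent not divisible by 4");
    terms.push_back(std::make_pair(-aexp / 4, sgn * bracket[i]));
  }
  std::sort(terms.begin(), terms.end());
  int tmin = terms.front().first, tmax = terms.back().first;
  NumericVector coef(tmax - tmin + 1, 0.0);
  for (size_t k = 0; k < terms.size(); ++k) coef[terms[k].first - tmin] = (double)terms[k].second;
  return List::create(_["tmin"] = tmin, _["coeffs"] = coef, _["ok"] = true);
}
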