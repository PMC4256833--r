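// Finite-domain search core for cyclic ITS identification.
//
// Variables: k educt-side cycle positions and k product-side positions.
// Constraints (basic model): all-different per side, positionwise label
// equality, lone-pair change per layout, degree compatibility, exact
// bond-order change on every cycle edge (pseudo edges present and unchanged),
// and an order-based rotation/direction symmetry breaking for rotation-
// symmetric layouts. Extended model adds domain pruning (sibling hydrogens),
// per-label cardinality lower bounds, and neighborhood-signature containment
// checked at assignment completion.
//
// Search: depth-first with forward checking; branching picks the unassigned
// variable with the smallest current domain (ties: lowest variable index,
// educt side first) and tries non-hydrogen values in ascending atom id
// before hydrogens. Domains are 64-bit masks, so at most 64 atoms per side.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

typedef uint64_t mask_t;

inline int popcnt(mask_t m) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(m);
#else
  int c = 0; while (m) { m &= m - 1; ++c; } return c;
#endif
}

struct Problem {
  int n, k, nvar;
  std::vector<int> adjI, adjO;             // n*n bond orders
  std::vector<int> labI, labO;             // 1-based label codes
  std::vector<int> lpI, lpO, degI, degO;
  std::vector<bool> hI, hO;
  std::vector<int> c, d;                   // layout, length k
  bool symBreak;
  bool firstOnly;
  // masks
  std::vector<mask_t> ordI, ordO;          // [ord*n + v] partners with that order
  std::vector<mask_t> existI, existO;      // [e*n + v] same-side partners for edge e
  std::vector<mask_t> compIO, compOI;      // [pos*n + v] cross-side compatibility
  std::vector<mask_t> ltMask, gtMask;      // values <v, >v
  mask_t allowedI, allowedO, hMaskI, hMaskO;
  // extended
  std::vector<int> reqLab;                 // per label code (1-based), may be empty
  std::vector<mask_t> labMaskI;
  std::vector<int> sigI, sigO;             // 1-based signature codes
  std::vector<int> reqSigIid, reqSigIcnt, reqSigOid, reqSigOcnt;
  // results
  std::vector<int> sols;
  long long nodes = 0;
  long long maxSol;
  bool stopped = false;

  int aI(int u, int v) const { return adjI[u * n + v]; }
  int aO(int u, int v) const { return adjO[u * n + v]; }
};

// order range admissible on the educt side for an edge with change c
inline void educt_range(int c, int &lo, int &hi) {
  if (c == 0) { lo = 1; hi = 3; return; }      // pseudo: present, unchanged
  lo = c < 0 ? -c : 0;
  hi = c > 0 ? 3 - c : 3;
}
inline void product_range(int c, int &lo, int &hi) {
  if (c == 0) { lo = 1; hi = 3; return; }
  lo = c > 0 ? c : 0;
  hi = c < 0 ? 3 + c : 3;
}

void precompute(Problem &P) {
  const int n = P.n, k = P.k;
  P.ordI.assign(4 * n, 0); P.ordO.assign(4 * n, 0);
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v) {
      if (u == v) continue;
      P.ordI[P.aI(u, v) * n + u] |= mask_t(1) << v;
      P.ordO[P.aO(u, v) * n + u] |= mask_t(1) << v;
    }
  P.existI.assign(k * n, 0); P.existO.assign(k * n, 0);
  for (int e = 0; e < k; ++e) {
    int lo, hi;
    educt_range(P.c[e], lo, hi);
    for (int u = 0; u < n; ++u) {
      mask_t m = 0;
      for (int o = lo; o <= hi; ++o) m |= P.ordI[o * n + u];
      P.existI[e * n + u] = m;
    }
    product_range(P.c[e], lo, hi);
    for (int w = 0; w < n; ++w) {
      mask_t m = 0;
      for (int o = lo; o <= hi; ++o) m |= P.ordO[o * n + w];
      P.existO[e * n + w] = m;
    }
  }
  P.compIO.assign(k * n, 0); P.compOI.assign(k * n, 0);
  for (int i = 0; i < k; ++i)
    for (int u = 0; u < n; ++u)
      for (int w = 0; w < n; ++w) {
        bool ok = P.labI[u] == P.labO[w] &&
                  P.lpO[w] - P.lpI[u] == P.d[i] &&
                  std::abs(P.degI[u] - P.degO[w]) <= 1;
        if (ok) {
          P.compIO[i * n + u] |= mask_t(1) << w;
          P.compOI[i * n + w] |= mask_t(1) << u;
        }
      }
  P.ltMask.assign(n, 0); P.gtMask.assign(n, 0);
  for (int v = 0; v < n; ++v) {
    for (int u = 0; u < v; ++u) P.ltMask[v] |= mask_t(1) << u;
    for (int u = v + 1; u < n; ++u) P.gtMask[v] |= mask_t(1) << u;
  }
  P.hMaskI = P.hMaskO = 0;
  for (int v = 0; v < n; ++v) {
    if (P.hI[v]) P.hMaskI |= mask_t(1) << v;
    if (P.hO[v]) P.hMaskO |= mask_t(1) << v;
  }
  if (!P.reqLab.empty()) {
    int L = (int)P.reqLab.size();
    P.labMaskI.assign(L + 1, 0);
    for (int v = 0; v < n; ++v) P.labMaskI[P.labI[v]] |= mask_t(1) << v;
  }
}

// exact re-check of a complete assignment (belt and braces; also carries the
// leaf-only extended constraints)
bool leaf_ok(const Problem &P, const std::vector<int> &as) {
  const int k = P.k;
  for (int i = 0; i < k; ++i) {
    int u = as[i], w = as[k + i];
    if (P.labI[u] != P.labO[w]) return false;
    if (P.lpO[w] - P.lpI[u] != P.d[i]) return false;
    if (std::abs(P.degI[u] - P.degO[w]) > 1) return false;
  }
  for (int e = 0; e < k; ++e) {
    int p = e, q = (e + 1) % k;
    int oi = P.aI(as[p], as[q]);
    int oo = P.aO(as[k + p], as[k + q]);
    if (oo - oi != P.c[e]) return false;
    if (P.c[e] == 0 && oi < 1) return false;
  }
  if (P.symBreak)
    for (int i = 1; i < k; ++i)
      if (as[0] >= as[i]) return false;
  if (!P.reqLab.empty()) {
    std::vector<int> cnt(P.reqLab.size() + 1, 0);
    for (int i = 0; i < k; ++i) cnt[P.labI[as[i]]]++;
    for (size_t l = 1; l <= P.reqLab.size(); ++l)
      if (cnt[l] < P.reqLab[l - 1]) return false;
  }
  if (!P.reqSigIid.empty()) {
    for (size_t t = 0; t < P.reqSigIid.size(); ++t) {
      int have = 0;
      for (int i = 0; i < k; ++i) if (P.sigI[as[i]] == P.reqSigIid[t]) ++have;
      if (have < P.reqSigIcnt[t]) return false;
    }
  }
  if (!P.reqSigOid.empty()) {
    for (size_t t = 0; t < P.reqSigOid.size(); ++t) {
      int have = 0;
      for (int i = 0; i < k; ++i) if (P.sigO[as[k + i]] == P.reqSigOid[t]) ++have;
      if (have < P.reqSigOcnt[t]) return false;
    }
  }
  return true;
}

// Recompute the domain of every unassigned variable by forward checking
// against all constraints whose other participants are assigned. Returns
// false on a wipe-out or a violated cardinality bound.
bool recompute(const Problem &P, const std::vector<int> &as,
               std::vector<mask_t> &dom) {
  const int n = P.n, k = P.k;
  mask_t usedI = 0, usedO = 0;
  for (int i = 0; i < k; ++i) {
    if (as[i] >= 0) usedI |= mask_t(1) << as[i];
    if (as[k + i] >= 0) usedO |= mask_t(1) << as[k + i];
  }
  for (int var = 0; var < 2 * k; ++var) {
    if (as[var] >= 0) { dom[var] = 0; continue; }
    bool educt = var < k;
    int i = educt ? var : var - k;
    mask_t m = educt ? (P.allowedI & ~usedI) : (P.allowedO & ~usedO);
    // cross-side pairing
    int partner = educt ? k + i : i;
    if (as[partner] >= 0)
      m &= educt ? P.compOI[i * n + as[partner]] : P.compIO[i * n + as[partner]];
    // the two incident cycle edges
    const int einc[2] = { (i + k - 1) % k, i };     // edge (i-1,i), edge (i,i+1)
    for (int t = 0; t < 2; ++t) {
      int e = einc[t];
      int j = (t == 0) ? (i + k - 1) % k : (i + 1) % k;   // other position
      int p = e, q = (e + 1) % k;                          // edge endpoints
      if (educt) {
        if (as[j] >= 0) m &= P.existI[e * n + as[j]];
        // exact-order filter when the opposite side of the edge is known
        if (as[j] >= 0 && as[k + p] >= 0 && as[k + q] >= 0) {
          int need = P.aO(as[k + p], as[k + q]) - P.c[e];
          if (need < 0 || need > 3) return false;
          m &= P.ordI[need * n + as[j]];
        }
      } else {
        if (as[k + j] >= 0) m &= P.existO[e * n + as[k + j]];
        if (as[k + j] >= 0 && as[p] >= 0 && as[q] >= 0) {
          int need = P.aI(as[p], as[q]) + P.c[e];
          if (need < 0 || need > 3) return false;
          m &= P.ordO[need * n + as[k + j]];
        }
      }
    }
    // symmetry breaking: X^I_1 strictly smallest among educt variables
    if (P.symBreak && educt) {
      if (i == 0) {
        for (int j = 1; j < k; ++j)
          if (as[j] >= 0) m &= P.ltMask[as[j]];
      } else if (as[0] >= 0) {
        m &= P.gtMask[as[0]];
      }
    }
    dom[var] = m;
    if (m == 0) return false;
  }
  // cardinality lower bounds on educt labels
  if (!P.reqLab.empty()) {
    for (size_t l = 1; l <= P.reqLab.size(); ++l) {
      int need = P.reqLab[l - 1];
      if (need == 0) continue;
      int have = 0, open = 0;
      for (int i = 0; i < k; ++i) {
        if (as[i] >= 0) { if (P.labI[as[i]] == (int)l) ++have; }
        else if (dom[i] & P.labMaskI[l]) ++open;
      }
      if (have + open < need) return false;
    }
  }
  return true;
}

void dfs(Problem &P, std::vector<int> &as, int unassigned) {
  if (P.stopped) return;
  ++P.nodes;
  if (unassigned == 0) {
    if (leaf_ok(P, as)) {
      for (int v = 0; v < 2 * P.k; ++v) P.sols.push_back(as[v]);
      if (P.firstOnly || (long long)P.sols.size() / (2 * P.k) >= P.maxSol)
        P.stopped = true;
    }
    return;
  }
  std::vector<mask_t> dom(2 * P.k, 0);
  if (!recompute(P, as, dom)) return;
  int best = -1, bestSize = 1 << 30;
  for (int v = 0; v < 2 * P.k; ++v) {
    if (as[v] >= 0) continue;
    int s = popcnt(dom[v]);
    if (s < bestSize) { bestSize = s; best = v; }
  }
  bool educt = best < P.k;
  mask_t hmask = educt ? P.hMaskI : P.hMaskO;
  for (int pass = 0; pass < 2; ++pass) {
    mask_t m = pass == 0 ? (dom[best] & ~hmask) : (dom[best] & hmask);
    while (m) {
      int v = __builtin_ctzll(m);
      m &= m - 1;
      as[best] = v;
      dfs(P, as, unassigned - 1);
      as[best] = -1;
      if (P.stopped) return;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List csp_enumerate_cpp(IntegerMatrix adjI, IntegerMatrix adjO,
                       IntegerVector labI, IntegerVector labO,
                       IntegerVector lpI, IntegerVector lpO,
                       IntegerVector degI, IntegerVector degO,
                       LogicalVector isHI, LogicalVector isHO,
                       LogicalVector allowedI, LogicalVector allowedO,
                       IntegerVector cvec, IntegerVector dvec,
                       bool symBreak,
                       IntegerVector reqLab,
                       IntegerVector sigI, IntegerVector sigO,
                       IntegerVector reqSigIid, IntegerVector reqSigIcnt,
                       IntegerVector reqSigOid, IntegerVector reqSigOcnt,
                       bool firstOnly, double maxSolutions) {
  Problem P;
  P.n = adjI.nrow();
  P.k = cvec.size();
  if (P.n > 64) stop("search core supports at most 64 atoms per side");
  if (adjO.nrow() != P.n) stop("educt/product atom counts differ");
  P.nvar = 2 * P.k;
  P.adjI.assign(adjI.begin(), adjI.end());   // column-major == row-major (symmetric)
  P.adjO.assign(adjO.begin(), adjO.end());
  P.labI.assign(labI.begin(), labI.end());
  P.labO.assign(labO.begin(), labO.end());
  P.lpI.assign(lpI.begin(), lpI.end());
  P.lpO.assign(lpO.begin(), lpO.end());
  P.degI.assign(degI.begin(), degI.end());
  P.degO.assign(degO.begin(), degO.end());
  P.hI.resize(P.n); P.hO.resize(P.n);
  P.allowedI = P.allowedO = 0;
  for (int v = 0; v < P.n; ++v) {
    P.hI[v] = isHI[v]; P.hO[v] = isHO[v];
    if (allowedI[v]) P.allowedI |= mask_t(1) << v;
    if (allowedO[v]) P.allowedO |= mask_t(1) << v;
  }
  P.c.assign(cvec.begin(), cvec.end());
  P.d.assign(dvec.begin(), dvec.end());
  P.symBreak = symBreak;
  P.firstOnly = firstOnly;
  P.maxSol = maxSolutions >= 9e15 ? (1LL << 62) : (long long)maxSolutions;
  P.reqLab.assign(reqLab.begin(), reqLab.end());
  P.sigI.assign(sigI.begin(), sigI.end());
  P.sigO.assign(sigO.begin(), sigO.end());
  P.reqSigIid.assign(reqSigIid.begin(), reqSigIid.end());
  P.reqSigIcnt.assign(reqSigIcnt.begin(), reqSigIcnt.end());
  P.reqSigOid.assign(reqSigOid.begin(), reqSigOid.end());
  P.reqSigOcnt.assign(reqSigOcnt.begin(), reqSigOcnt.end());

  precompute(P);
  std::vector<int> as(P.nvar, -1);
  dfs(P, as, P.nvar);

  int nsol = (int)(P.sols.size() / P.nvar);
  IntegerMatrix edu(P.k, nsol), pro(P.k, nsol);
  for (int s = 0; s < nsol; ++s)
    for (int i = 0; i < P.k; ++i) {
      edu(i, s) = P.sols[s * P.nvar + i] + 1;
      pro(i, s) = P.sols[s * P.nvar + P.k + i] + 1;
    }
  return List::create(_["educt"] = edu, _["product"] = pro,
                      _["nodes"] = (double)P.nodes);
}
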