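// Determinant full CI for few-electron systems.  Spin orbitals are indexed
// 0..n-1 (alpha) and n..2n-1 (beta) over n spatial orbitals; determinants are
// 64-bit occupation masks, so n <= 32.  Spatial two-electron integrals are
// supplied in chemist (PQ|RS) order.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct SoInts {
  int n;
  const double *h;    // n x n
  const double *eri;  // n^4, chemist (PQ|RS), column-major idx P+Q*n+R*n2+S*n3
  size_t n2, n3;
  int sp(int p) const { return p < n ? p : p - n; }
  int spin(int p) const { return p < n ? 0 : 1; }
  double hso(int p, int q) const {
    if (spin(p) != spin(q)) return 0.0;
    return h[sp(p) + n * sp(q)];
  }
  double chem(int P, int Q, int R, int S) const {
    return eri[P + Q * (size_t)n + R * n2 + S * n3];
  }
  // antisymmetrized <pq||rs> (physicist)
  double anti(int p, int q, int r, int s) const {
    double v = 0.0;
    if (spin(p) == spin(r) && spin(q) == spin(s))
      v += chem(sp(p), sp(r), sp(q), sp(s));
    if (spin(p) == spin(s) && spin(q) == spin(r))
      v -= chem(sp(p), sp(s), sp(q), sp(r));
    return v;
  }
};

inline int popcnt(uint64_t x) {
#if defined(__GNUC__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// phase for removing/adding orbital p from mask (count occupied below p)
inline int phase_below(uint64_t mask, int p) {
  uint64_t below = mask & ((p == 0) ? 0ULL : ((1ULL << p) - 1ULL));
  return (popcnt(below) % 2) ? -1 : 1;
}

void occ_list(uint64_t mask, std::vector<int> &occ) {
  occ.clear();
  while (mask) {
    int p = __builtin_ctzll(mask);
    occ.push_back(p);
    mask &= mask - 1;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix fci_hamiltonian(NumericVector alpha_mask, NumericVector beta_mask,
                              NumericMatrix h, NumericVector eri, int n) {
  // alpha/beta occupation masks passed as doubles (each fits in n <= 31 bits)
  int nd = alpha_mask.size();
  std::vector<uint64_t> dets(nd);
  for (int i = 0; i < nd; ++i)
    dets[i] = (uint64_t)(alpha_mask[i]) | ((uint64_t)(beta_mask[i]) << n);
  SoInts I;
  I.n = n; I.h = h.begin(); I.eri = eri.begin();
  I.n2 = (size_t)n * n; I.n3 = I.n2 * n;

  NumericMatrix H(nd, nd);
  std::vector<int> occI, occJ, common, onlyI, onlyJ;
  for (int a = 0; a < nd; ++a) {
    for (int b = a; b < nd; ++b) {
      uint64_t x = dets[a] ^ dets[b];
      int deg = popcnt(x) / 2;
      if (deg > 2) continue;
      double val = 0.0;
      if (deg == 0) {
        occ_list(dets[a], occI);
        for (size_t i = 0; i < occI.size(); ++i) {
          val += I.hso(occI[i], occI[i]);
          for (size_t j = i + 1; j < occI.size(); ++j)
            val += I.anti(occI[i], occI[j], occI[i], occI[j]);
        }
      } else if (deg == 1) {
        occ_list(dets[a] & x, onlyI);
        occ_list(dets[b] & x, onlyJ);
        int p = onlyI[0], q = onlyJ[0];
        uint64_t comm = dets[a] & dets[b];
        double s = phase_below(dets[a], p) * phase_below(dets[b], q);
        double v = I.hso(p, q);
        occ_list(comm, common);
        for (int r : common) v += I.anti(p, r, q, r);
        val = s * v;
      } else {
        occ_list(dets[a] & x, onlyI);
        occ_list(dets[b] & x, onlyJ);
        int p = onlyI[0], q = onlyI[1], r = onlyJ[0], s_ = onlyJ[1];
        // phases: remove q then p from a; remove s then r from b
        uint64_t ma = dets[a];
        int sa = phase_below(ma, q); ma &= ~(1ULL << q);
        sa *= phase_below(ma, p);
        uint64_t mb = dets[b];
        int sb = phase_below(mb, s_); mb &= ~(1ULL << s_);
        sb *= phase_below(mb, r);
        val = sa * sb * I.anti(p, q, r, s_);
      }
      H(a, b) = val;
      H(b, a) = val;
    }
  }
  return H;
}

// Spin-blocked spatial two-particle density in Mulliken pairing:
// G[sigma sigma'][P,Q,R,S] = < a+_{P sigma} a+_{R sigma'} a_{S sigma'} a_{Q sigma} >
// Returns list(aa, bb, ab, ba) of n^4 arrays plus one-particle densities.
// [[Rcpp::export]]
List fci_rdm(NumericVector alpha_mask, NumericVector beta_mask,
             NumericVector civec, int n, int nel) {
  int nd = alpha_mask.size();
  std::vector<uint64_t> dets(nd);
  std::unordered_map<uint64_t, int> index;
  index.reserve(nd * 2);
  for (int i = 0; i < nd; ++i) {
    dets[i] = (uint64_t)(alpha_mask[i]) | ((uint64_t)(beta_mask[i]) << n);
    index[dets[i]] = i;
  }
  size_t n2 = (size_t)n * n, n3 = n2 * n, n4 = n3 * n;
  NumericVector Gaa(n4), Gbb(n4), Gab(n4), Gba(n4);
  NumericMatrix Da(n, n), Db(n, n);
  const double *C = civec.begin();
  int nso = 2 * n;

  std::vector<int> occ;
  for (int J = 0; J < nd; ++J) {
    double cJ = C[J];
    if (cJ == 0.0) continue;
    occ_list(dets[J], occ);
    // one-particle: a+_p a_q
    for (int q : occ) {
      uint64_t m1 = dets[J];
      int s1 = phase_below(m1, q);
      m1 &= ~(1ULL << q);
      for (int p = 0; p < nso; ++p) {
        if ((p < n) != (q < n)) continue;
        if (m1 & (1ULL << p)) continue;
        uint64_t m2 = m1 | (1ULL << p);
        auto it = index.find(m2);
        if (it == index.end()) continue;
        double contrib = cJ * C[it->second] * s1 * phase_below(m1, p);
        int P = p < n ? p : p - n, Q = q < n ? q : q - n;
        if (q < n) Da(P, Q) += contrib; else Db(P, Q) += contrib;
      }
    }
    // two-particle: a+_p a+_r a_s a_q  (q removed first, then s)
    for (int q : occ) {
      uint64_t m1 = dets[J];
      int s1 = phase_below(m1, q);
      m1 &= ~(1ULL << q);
      for (int s_ : occ) {
        if (s_ == q) continue;
        uint64_t m2 = m1;
        int s2 = s1 * phase_below(m2, s_);
        m2 &= ~(1ULL << s_);
        for (int r = 0; r < nso; ++r) {
          if ((r < n) != (s_ < n)) continue;  // spin conservation per pairing
          if (m2 & (1ULL << r)) continue;
          uint64_t m3 = m2 | (1ULL << r);
          int s3 = s2 * phase_below(m2, r);
          for (int p = 0; p < nso; ++p) {
            if ((p < n) != (q < n)) continue;
            if (m3 & (1ULL << p)) continue;
            uint64_t m4 = m3 | (1ULL << p);
            auto it = index.find(m4);
            if (it == index.end()) continue;
            double contrib = cJ * C[it->second] * s3 * phase_below(m3, p);
            int P = p < n ? p : p - n, Q = q < n ? q : q - n;
            int R = r < n ? r : r - n, S = s_ < n ? s_ : s_ - n;
            size_t id = P + Q * (size_t)n + R * n2 + S * n3;
            bool qa = q < n, sa = s_ < n;
            if (qa && sa) Gaa[id] += contrib;
            else if (!qa && !sa) Gbb[id] += contrib;
            else if (qa && !sa) Gab[id] += contrib;
            else Gba[id] += contrib;
          }
        }
      }
    }
  }
  IntegerVector dim4 = IntegerVector::create(n, n, n, n);
  Gaa.attr("dim") = dim4; Gbb.attr("dim") = dim4;
  Gab.attr("dim") = dim4; Gba.attr("dim") = dim4;
  return List::create(_["aa"] = Gaa, _["bb"] = Gbb, _["ab"] = Gab,
                      _["ba"] = Gba, _["Da"] = Da, _["Db"] = Db,
                      _["nel"] = nel);
}
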