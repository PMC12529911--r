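// Gaussian-basis one- and two-electron integrals over contracted Cartesian
// shells, McMurchie-Davidson scheme (Hermite expansion + Hermite Coulomb
// recursion).  Shells carry raw Cartesian monomials x^i y^j z^k exp(-a r^2);
// primitive normalization is folded into the contraction coefficients on the
// R side and contracted functions are renormalized there as well.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---- Boys function F_m(T), m = 0..mmax ------------------------------------
static void boys(int mmax, double T, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    // upward recursion, stable for large T
    F[0] = 0.5 * std::sqrt(PI / T);
    double expT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
    return;
  }
  // series for F_mmax, then downward recursion
  double expT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int k = 1; k < 500; ++k) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + expT) / (2.0 * m - 1.0);
}

// ---- Hermite expansion coefficients E_t^{ij} for one dimension -------------
// E[(i*(jmax+1)+j)*(tmax+1)+t]; tmax = imax+jmax
struct ETable {
  int imax, jmax, tdim;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
  }
};

static void build_E(int imax, int jmax, double a, double b, double AB,
                    ETable &E) {
  // AB = A - B along this dimension
  double p = a + b, mu = a * b / p;
  double XPA = -b / p * AB;  // P - A = -(b/p)(A-B)
  double XPB = a / p * AB;   // P - B
  E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
  E.v.assign((size_t)(imax + 1) * (jmax + 1) * E.tdim, 0.0);
  auto set = [&](int i, int j, int t, double val) {
    E.v[(size_t)(i * (jmax + 1) + j) * E.tdim + t] = val;
  };
  set(0, 0, 0, std::exp(-mu * AB * AB));
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (j == 0) {
          val = 1.0 / (2.0 * p) * E.at(i - 1, 0, t - 1)
              + XPA * E.at(i - 1, 0, t)
              + (t + 1.0) * E.at(i - 1, 0, t + 1);
        } else {
          val = 1.0 / (2.0 * p) * E.at(i, j - 1, t - 1)
              + XPB * E.at(i, j - 1, t)
              + (t + 1.0) * E.at(i, j - 1, t + 1);
        }
        set(i, j, t, val);
      }
    }
  }
}

// ---- Hermite Coulomb integrals R_{tuv} (n = 0 slice) -----------------------
struct RTable {
  int tmax, umax, vmax;
  std::vector<double> v;
  double at(int t, int u, int v_) const {
    if (t < 0 || u < 0 || v_ < 0) return 0.0;
    return v[(size_t)(t * (umax + 1) + u) * (vmax + 1) + v_];
  }
};

static void build_R(int tmax, int umax, int vmax, double p,
                    double PCx, double PCy, double PCz, RTable &R) {
  int Ntot = tmax + umax + vmax;
  double T = p * (PCx * PCx + PCy * PCy + PCz * PCz);
  std::vector<double> F;
  boys(Ntot, T, F);
  // Rn[n][t][u][v], filled level by level
  size_t dim = (size_t)(tmax + 1) * (umax + 1) * (vmax + 1);
  std::vector<std::vector<double>> Rn(Ntot + 1, std::vector<double>(dim, 0.0));
  auto idx = [&](int t, int u, int v_) {
    return (size_t)(t * (umax + 1) + u) * (vmax + 1) + v_;
  };
  double m2p = 1.0;
  for (int n = 0; n <= Ntot; ++n) { Rn[n][idx(0, 0, 0)] = m2p * F[n]; m2p *= -2.0 * p; }
  for (int L = 1; L <= Ntot; ++L) {
    for (int n = 0; n <= Ntot - L; ++n) {
      for (int t = 0; t <= std::min(L, tmax); ++t)
        for (int u = 0; u <= std::min(L - t, umax); ++u) {
          int v_ = L - t - u;
          if (v_ > vmax) continue;
          double val;
          if (t > 0) {
            val = (t - 1) * (t - 2 >= 0 ? Rn[n + 1][idx(t - 2, u, v_)] : 0.0)
                + PCx * Rn[n + 1][idx(t - 1, u, v_)];
          } else if (u > 0) {
            val = (u - 1) * (u - 2 >= 0 ? Rn[n + 1][idx(t, u - 2, v_)] : 0.0)
                + PCy * Rn[n + 1][idx(t, u - 1, v_)];
          } else {
            val = (v_ - 1) * (v_ - 2 >= 0 ? Rn[n + 1][idx(t, u, v_ - 2)] : 0.0)
                + PCz * Rn[n + 1][idx(t, u, v_ - 1)];
          }
          Rn[n][idx(t, u, v_)] = val;
        }
    }
  }
  R.tmax = tmax; R.umax = umax; R.vmax = vmax;
  R.v = Rn[0];
}

// ---- shell bookkeeping -----------------------------------------------------
struct Shell {
  int l, atom;                 // atom: 0-based
  double x, y, z;
  std::vector<double> expn, coef;  // coef includes primitive norms
  std::vector<std::array<int,3>> cart;  // component monomials
  int ncart() const { return (int)cart.size(); }
};

static std::vector<Shell> parse_shells(const List &shells,
                                       const NumericMatrix &coords) {
  int ns = shells.size();
  std::vector<Shell> out(ns);
  for (int s = 0; s < ns; ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    S.atom = as<int>(sh["atom"]) - 1;
    S.x = coords(S.atom, 0); S.y = coords(S.atom, 1); S.z = coords(S.atom, 2);
    S.expn = as<std::vector<double>>(sh["exponents"]);
    S.coef = as<std::vector<double>>(sh["coefficients"]);
    for (int lx = S.l; lx >= 0; --lx)
      for (int ly = S.l - lx; ly >= 0; --ly)
        S.cart.push_back({lx, ly, S.l - lx - ly});
    out[s] = S;
  }
  return out;
}

// ---- one-electron integrals ------------------------------------------------
// [[Rcpp::export]]
List md_one_electron(List shells, NumericMatrix coords, NumericVector charges) {
  std::vector<Shell> sh = parse_shells(shells, coords);
  int ns = sh.size();
  std::vector<int> off(ns, 0);
  int nbf = 0;
  for (int s = 0; s < ns; ++s) { off[s] = nbf; nbf += sh[s].ncart(); }
  NumericMatrix S(nbf, nbf), T(nbf, nbf), V(nbf, nbf);
  int natom = coords.nrow();

  for (int A = 0; A < ns; ++A) {
    for (int B = A; B < ns; ++B) {
      const Shell &sa = sh[A], &sb = sh[B];
      double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
      int na = sa.ncart(), nb = sb.ncart();
      std::vector<double> blS((size_t)na * nb, 0.0), blT((size_t)na * nb, 0.0),
          blV((size_t)na * nb, 0.0);
      for (size_t pa = 0; pa < sa.expn.size(); ++pa) {
        for (size_t pb = 0; pb < sb.expn.size(); ++pb) {
          double a = sa.expn[pa], b = sb.expn[pb];
          double cc = sa.coef[pa] * sb.coef[pb];
          double p = a + b;
          double Px = (a * sa.x + b * sb.x) / p;
          double Py = (a * sa.y + b * sb.y) / p;
          double Pz = (a * sa.z + b * sb.z) / p;
          ETable Ex, Ey, Ez;
          build_E(sa.l, sb.l + 2, a, b, ABx, Ex);
          build_E(sa.l, sb.l + 2, a, b, ABy, Ey);
          build_E(sa.l, sb.l + 2, a, b, ABz, Ez);
          double sfac = std::sqrt(PI / p);
          // Hermite Coulomb tables per nucleus
          std::vector<RTable> Rc(natom);
          for (int c = 0; c < natom; ++c)
            build_R(sa.l + sb.l, sa.l + sb.l, sa.l + sb.l, p,
                    Px - coords(c, 0), Py - coords(c, 1), Pz - coords(c, 2),
                    Rc[c]);
          for (int ia = 0; ia < na; ++ia) {
            int l1 = sa.cart[ia][0], m1 = sa.cart[ia][1], n1 = sa.cart[ia][2];
            for (int ib = 0; ib < nb; ++ib) {
              int l2 = sb.cart[ib][0], m2 = sb.cart[ib][1], n2 = sb.cart[ib][2];
              double sx = Ex.at(l1, l2, 0) * sfac;
              double sy = Ey.at(m1, m2, 0) * sfac;
              double sz = Ez.at(n1, n2, 0) * sfac;
              blS[ia * nb + ib] += cc * sx * sy * sz;
              // kinetic: -1/2 d^2/dx^2 acting on ket
              auto kin1d = [&](const ETable &E, int i, int j, double s0) {
                double sm2 = (j >= 2) ? E.at(i, j - 2, 0) * sfac : 0.0;
                double sp2 = E.at(i, j + 2, 0) * sfac;
                return -0.5 * (j * (j - 1) * sm2 - 2.0 * b * (2.0 * j + 1.0) * s0
                               + 4.0 * b * b * sp2);
              };
              double tx = kin1d(Ex, l1, l2, sx);
              double ty = kin1d(Ey, m1, m2, sy);
              double tz = kin1d(Ez, n1, n2, sz);
              blT[ia * nb + ib] += cc * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              // nuclear attraction
              double vsum = 0.0;
              for (int c = 0; c < natom; ++c) {
                double vc = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int v_ = 0; v_ <= n1 + n2; ++v_)
                      vc += Ex.at(l1, l2, t) * Ey.at(m1, m2, u) *
                            Ez.at(n1, n2, v_) * Rc[c].at(t, u, v_);
                vsum += -charges[c] * vc;
              }
              blV[ia * nb + ib] += cc * (2.0 * PI / p) * vsum;
            }
          }
        }
      }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int I = off[A] + ia, J = off[B] + ib;
          S(I, J) = blS[ia * nb + ib]; S(J, I) = S(I, J);
          T(I, J) = blT[ia * nb + ib]; T(J, I) = T(I, J);
          V(I, J) = blV[ia * nb + ib]; V(J, I) = V(I, J);
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V, _["nbf"] = nbf);
}

// ---- two-electron integrals ------------------------------------------------
// [[Rcpp::export]]
NumericVector md_eri(List shells, NumericMatrix coords) {
  std::vector<Shell> sh = parse_shells(shells, coords);
  int ns = sh.size();
  std::vector<int> off(ns, 0);
  int nbf = 0;
  for (int s = 0; s < ns; ++s) { off[s] = nbf; nbf += sh[s].ncart(); }
  NumericVector out((size_t)nbf * nbf * nbf * nbf);
  std::fill(out.begin(), out.end(), 0.0);
  size_t n1 = nbf, n2 = n1 * nbf, n3 = n2 * nbf;
  auto put = [&](int i, int j, int k, int l, double val) {
    out[i + j * n1 + k * n2 + l * n3] = val;
  };

  for (int A = 0; A < ns; ++A)
  for (int B = 0; B <= A; ++B)
  for (int C = 0; C <= A; ++C)
  for (int D = 0; D <= (C == A ? B : C); ++D) {
    const Shell &sa = sh[A], &sb = sh[B], &sc = sh[C], &sd = sh[D];
    int na = sa.ncart(), nb = sb.ncart(), nc = sc.ncart(), nd = sd.ncart();
    std::vector<double> block((size_t)na * nb * nc * nd, 0.0);
    int Lb = sa.l + sb.l, Lk = sc.l + sd.l;
    double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
    double CDx = sc.x - sd.x, CDy = sc.y - sd.y, CDz = sc.z - sd.z;
    for (size_t pa = 0; pa < sa.expn.size(); ++pa)
    for (size_t pb = 0; pb < sb.expn.size(); ++pb) {
      double a = sa.expn[pa], b = sb.expn[pb], p = a + b;
      double Px = (a * sa.x + b * sb.x) / p, Py = (a * sa.y + b * sb.y) / p,
             Pz = (a * sa.z + b * sb.z) / p;
      ETable Exb, Eyb, Ezb;
      build_E(sa.l, sb.l, a, b, ABx, Exb);
      build_E(sa.l, sb.l, a, b, ABy, Eyb);
      build_E(sa.l, sb.l, a, b, ABz, Ezb);
      double cab = sa.coef[pa] * sb.coef[pb];
      for (size_t pc = 0; pc < sc.expn.size(); ++pc)
      for (size_t pd = 0; pd < sd.expn.size(); ++pd) {
        double c = sc.expn[pc], d = sd.expn[pd], q = c + d;
        double Qx = (c * sc.x + d * sd.x) / q, Qy = (c * sc.y + d * sd.y) / q,
               Qz = (c * sc.z + d * sd.z) / q;
        ETable Exk, Eyk, Ezk;
        build_E(sc.l, sd.l, c, d, CDx, Exk);
        build_E(sc.l, sd.l, c, d, CDy, Eyk);
        build_E(sc.l, sd.l, c, d, CDz, Ezk);
        double alpha = p * q / (p + q);
        RTable R;
        build_R(Lb + Lk, Lb + Lk, Lb + Lk, alpha, Px - Qx, Py - Qy, Pz - Qz, R);
        double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
        double cfac = cab * sc.coef[pc] * sd.coef[pd] * pref;
        for (int ia = 0; ia < na; ++ia) {
          int l1 = sa.cart[ia][0], m1 = sa.cart[ia][1], o1 = sa.cart[ia][2];
          for (int ib = 0; ib < nb; ++ib) {
            int l2 = sb.cart[ib][0], m2 = sb.cart[ib][1], o2 = sb.cart[ib][2];
            // pre-collect bra Hermite coefficients
            for (int ic = 0; ic < nc; ++ic) {
              int l3 = sc.cart[ic][0], m3 = sc.cart[ic][1], o3 = sc.cart[ic][2];
              for (int id = 0; id < nd; ++id) {
                int l4 = sd.cart[id][0], m4 = sd.cart[id][1], o4 = sd.cart[id][2];
                double val = 0.0;
                for (int t = 0; t <= l1 + l2; ++t) {
                  double ext = Exb.at(l1, l2, t);
                  if (ext == 0.0) continue;
                  for (int u = 0; u <= m1 + m2; ++u) {
                    double eyu = Eyb.at(m1, m2, u);
                    if (eyu == 0.0) continue;
                    for (int v_ = 0; v_ <= o1 + o2; ++v_) {
                      double ezv = Ezb.at(o1, o2, v_);
                      if (ezv == 0.0) continue;
                      double bra = ext * eyu * ezv;
                      double ksum = 0.0;
                      for (int tt = 0; tt <= l3 + l4; ++tt) {
                        double ektt = Exk.at(l3, l4, tt);
                        if (ektt == 0.0) continue;
                        for (int uu = 0; uu <= m3 + m4; ++uu) {
                          double ekuu = Eyk.at(m3, m4, uu);
                          if (ekuu == 0.0) continue;
                          for (int vv = 0; vv <= o3 + o4; ++vv) {
                            double ekvv = Ezk.at(o3, o4, vv);
                            if (ekvv == 0.0) continue;
                            double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                            ksum += sgn * ektt * ekuu * ekvv *
                                    R.at(t + tt, u + uu, v_ + vv);
                          }
                        }
                      }
                      val += bra * ksum;
                    }
                  }
                }
                block[((size_t)ia * nb + ib) * nc * nd + (size_t)ic * nd + id]
                    += cfac * val;
              }
            }
          }
        }
      }
    }
    // scatter with 8-fold permutational symmetry
    for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib)
    for (int ic = 0; ic < nc; ++ic)
    for (int id = 0; id < nd; ++id) {
      double v = block[((size_t)ia * nb + ib) * nc * nd + (size_t)ic * nd + id];
      int i = off[A] + ia, j = off[B] + ib, k = off[C] + ic, l = off[D] + id;
      put(i, j, k, l, v); put(j, i, k, l, v);
      put(i, j, l, k, v); put(j, i, l, k, v);
      put(k, l, i, j, v); put(l, k, i, j, v);
      put(k, l, j, i, v); put(l, k, j, i, v);
    }
  }
  out.attr("dim") = IntegerVector::create(nbf, nbf, nbf, nbf);
  return out;
}
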