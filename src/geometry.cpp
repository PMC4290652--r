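#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- Voronoi facet test by bisector-plane clipping -------------------------
//
// Two atoms i and j share a Voronoi facet iff the set
//   F = { x : |x-i| = |x-j| <= |x-k| for all k }
// has positive area. F lives on the bisector plane of (i,j); every other
// atom k contributes one halfplane in the plane's 2-D coordinates, so F is
// obtained exactly by Sutherland-Hodgman clipping of a large bounding square.
// The clipped polygon's area is returned (0 when the cells do not meet).

struct P2 { double s, t; };

static double polyArea(const std::vector<P2>& p) {
  const int n = p.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    const P2& u = p[i];
    const P2& v = p[(i + 1) % n];
    a += u.s * v.t - v.s * u.t;
  }
  return std::fabs(a) / 2.0;
}

// clip polygon by halfplane A*s + B*t <= C
static void clipHalfplane(std::vector<P2>& poly, double A, double B, double C) {
  const int n = poly.size();
  if (n == 0) return;
  std::vector<P2> out;
  out.reserve(n + 2);
  for (int i = 0; i < n; ++i) {
    const P2& cur = poly[i];
    const P2& nxt = poly[(i + 1) % n];
    const double fc = A * cur.s + B * cur.t - C;
    const double fn = A * nxt.s + B * nxt.t - C;
    if (fc <= 0) out.push_back(cur);
    if ((fc < 0 && fn > 0) || (fc > 0 && fn < 0)) {
      const double w = fc / (fc - fn);
      P2 x;
      x.s = cur.s + w * (nxt.s - cur.s);
      x.t = cur.t + w * (nxt.t - cur.t);
      out.push_back(x);
    }
  }
  poly.swap(out);
}

// [[Rcpp::export(name = ".cppFacetAreas")]]
NumericVector cppFacetAreas(NumericMatrix coords, IntegerMatrix pairs,
                            double halfWidth) {
  const int n = coords.nrow();
  const int m = pairs.nrow();
  NumericVector area(m);
  for (int p = 0; p < m; ++p) {
    const int i = pairs(p, 0) - 1;
    const int j = pairs(p, 1) - 1;
    double u0 = coords(j, 0) - coords(i, 0);
    double u1 = coords(j, 1) - coords(i, 1);
    double u2 = coords(j, 2) - coords(i, 2);
    const double L = std::sqrt(u0 * u0 + u1 * u1 + u2 * u2);
    if (L <= 0) stop("coincident atoms in facet test (pair %d)", p + 1);
    u0 /= L; u1 /= L; u2 /= L;
    // orthonormal basis of the bisector plane
    double a0 = 1, a1 = 0, a2 = 0;
    if (std::fabs(u0) > 0.9) { a0 = 0; a1 = 1; }
    double e10 = u1 * a2 - u2 * a1;
    double e11 = u2 * a0 - u0 * a2;
    double e12 = u0 * a1 - u1 * a0;
    const double eL = std::sqrt(e10 * e10 + e11 * e11 + e12 * e12);
    e10 /= eL; e11 /= eL; e12 /= eL;
    const double e20 = u1 * e12 - u2 * e11;
    const double e21 = u2 * e10 - u0 * e12;
    const double e22 = u0 * e11 - u1 * e10;
    const double m0 = (coords(i, 0) + coords(j, 0)) / 2.0;
    const double m1 = (coords(i, 1) + coords(j, 1)) / 2.0;
    const double m2 = (coords(i, 2) + coords(j, 2)) / 2.0;

    std::vector<P2> poly(4);
    poly[0].s = -halfWidth; poly[0].t = -halfWidth;
    poly[1].s =  halfWidth; poly[1].t = -halfWidth;
    poly[2].s =  halfWidth; poly[2].t =  halfWidth;
    poly[3].s = -halfWidth; poly[3].t =  halfWidth;

    for (int k = 0; k < n && !poly.empty(); ++k) {
      if (k == i || k == j) continue;
      const double d0 = coords(k, 0) - coords(i, 0);
      const double d1 = coords(k, 1) - coords(i, 1);
      const double d2 = coords(k, 2) - coords(i, 2);
      // |x-i|^2 <= |x-k|^2  <=>  2 (x - (i+k)/2) . d <= 0, x = m + s e1 + t e2
      const double c0 = m0 - (coords(i, 0) + coords(k, 0)) / 2.0;
      const double c1 = m1 - (coords(i, 1) + coords(k, 1)) / 2.0;
      const double c2 = m2 - (coords(i, 2) + coords(k, 2)) / 2.0;
      const double A = e10 * d0 + e11 * d1 + e12 * d2;
      const double B = e20 * d0 + e21 * d1 + e22 * d2;
      const double C = -(c0 * d0 + c1 * d1 + c2 * d2);
      if (std::fabs(A) < 1e-14 && std::fabs(B) < 1e-14) {
        if (C < 0) poly.clear();  // halfplane excludes the whole plane
        continue;
      }
      clipHalfplane(poly, A, B, C);
    }
    area[p] = polyArea(poly);
  }
  return area;
}

// ---- beta-skeleton forbidden region ----------------------------------------
//
// forbidden region of pair (i,j) is empty iff every other atom k subtends
// angle(i,k,j) strictly below the threshold; with 90 deg this is the empty
// diametral sphere (Gabriel) test.

// [[Rcpp::export(name = ".cppForbiddenEmpty")]]
LogicalVector cppForbiddenEmpty(NumericMatrix coords, IntegerMatrix pairs,
                                double cosThresh) {
  const int n = coords.nrow();
  const int m = pairs.nrow();
  LogicalVector empty(m);
  for (int p = 0; p < m; ++p) {
    const int i = pairs(p, 0) - 1;
    const int j = pairs(p, 1) - 1;
    bool ok = true;
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      const double a0 = coords(i, 0) - coords(k, 0);
      const double a1 = coords(i, 1) - coords(k, 1);
      const double a2 = coords(i, 2) - coords(k, 2);
      const double b0 = coords(j, 0) - coords(k, 0);
      const double b1 = coords(j, 1) - coords(k, 1);
      const double b2 = coords(j, 2) - coords(k, 2);
      const double na = std::sqrt(a0 * a0 + a1 * a1 + a2 * a2);
      const double nb = std::sqrt(b0 * b0 + b1 * b1 + b2 * b2);
      if (na <= 0 || nb <= 0)
        stop("atom coincident with a contact endpoint (pair %d)", p + 1);
      const double c = (a0 * b0 + a1 * b1 + a2 * b2) / (na * nb);
      // angle >= threshold  <=>  cos(angle) <= cos(threshold)
      if (c <= cosThresh) { ok = false; break; }
    }
    empty[p] = ok;
  }
  return empty;
}

// ---- distance-prefiltered cross pairs --------------------------------------

// [[Rcpp::export(name = ".cppCrossPairs")]]
DataFrame cppCrossPairs(NumericMatrix a, NumericMatrix b,
                        NumericVector ra, NumericVector rb, double td) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const double d0 = a(i, 0) - b(j, 0);
      const double d1 = a(i, 1) - b(j, 1);
      const double d2 = a(i, 2) - b(j, 2);
      const double d = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
      if (d < td + ra[i] + rb[j]) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(d);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd);
}

// all pairs within (cutoff_i + cutoff_j + tol), used for covalent bonds

// [[Rcpp::export(name = ".cppClosePairs")]]
DataFrame cppClosePairs(NumericMatrix x, NumericVector r, double tol) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const int n = x.nrow();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d0 = x(i, 0) - x(j, 0);
      const double d1 = x(i, 1) - x(j, 1);
      const double d2 = x(i, 2) - x(j, 2);
      const double lim = r[i] + r[j] + tol;
      const double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
      if (d2sum <= lim * lim) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2sum));
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd);
}

// ---- Shrake-Rupley SASA ----------------------------------------------------
//
// Deterministic golden-spiral lattice on each probe-inflated sphere; a lattice
// point is accessible when outside every neighbour's inflated sphere. Points
// exactly on a neighbour's surface (coincident-sphere degeneracy) are broken
// by atom index so each shared surface is counted once.

// [[Rcpp::export(name = ".cppSasa")]]
NumericVector cppSasa(NumericMatrix x, NumericVector radii, double probe,
                      int npoints) {
  const int n = x.nrow();
  NumericVector area(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  std::vector<double> ux(npoints), uy(npoints), uz(npoints);
  for (int k = 0; k < npoints; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double phi = ga * k;
    ux[k] = rho * std::cos(phi);
    uy[k] = rho * std::sin(phi);
    uz[k] = z;
  }
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double d0 = x(i, 0) - x(j, 0);
      const double d1 = x(i, 1) - x(j, 1);
      const double d2 = x(i, 2) - x(j, 2);
      const double lim = R[i] + R[j];
      if (d0 * d0 + d1 * d1 + d2 * d2 < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      const double px = x(i, 0) + R[i] * ux[k];
      const double py = x(i, 1) + R[i] * uy[k];
      const double pz = x(i, 2) + R[i] * uz[k];
      bool free = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double d0 = px - x(j, 0);
        const double d1 = py - x(j, 1);
        const double d2 = pz - x(j, 2);
        const double dd = d0 * d0 + d1 * d1 + d2 * d2;
        const double R2 = R[j] * R[j];
        if (dd < R2 * (1.0 - 1e-9) ||
            (dd <= R2 * (1.0 + 1e-9) && j < i)) { free = false; break; }
      }
      if (free) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / npoints;
  }
  return area;
}
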