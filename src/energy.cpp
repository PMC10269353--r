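// Vectorized gas-phase MM energy and analytic gradient kernel.
// Mirrors the term tables prepared by energy_context(): harmonic bonds and
// angles (k/2 conventions), cosine-series torsions/impropers, 12-6 LJ from
// (R_min/2, epsilon) and Coulomb over the precomputed scaled pair list.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".energy_eval_cpp")]]
List energy_eval_cpp(NumericMatrix x, NumericMatrix bond, NumericMatrix angle,
                     NumericMatrix proper, NumericMatrix improper,
                     IntegerVector nb_i, IntegerVector nb_j,
                     NumericVector nb_eps, NumericVector nb_rmin,
                     NumericVector nb_qq, LogicalVector term_on,
                     bool want_grad) {
  const int n = x.nrow();
  NumericVector e(6);  // bond, angle, proper, improper, vdw, elec
  NumericMatrix g;
  if (want_grad) g = NumericMatrix(n, 3);

  // bonds: k/2 (r - r0)^2
  if (term_on[0]) {
    for (int r = 0; r < bond.nrow(); ++r) {
      const int i = (int)bond(r, 0) - 1, j = (int)bond(r, 1) - 1;
      const double k = bond(r, 2), r0 = bond(r, 3);
      double d[3] = {x(i, 0) - x(j, 0), x(i, 1) - x(j, 1), x(i, 2) - x(j, 2)};
      const double rij = std::sqrt(dot3(d, d));
      const double dr = rij - r0;
      e[0] += 0.5 * k * dr * dr;
      if (want_grad) {
        const double f = k * dr / rij;
        for (int c = 0; c < 3; ++c) {
          g(i, c) += f * d[c];
          g(j, c) -= f * d[c];
        }
      }
    }
  }

  // angles: k/2 (theta - theta0)^2, theta0 in radians
  if (term_on[1]) {
    for (int r = 0; r < angle.nrow(); ++r) {
      const int i = (int)angle(r, 0) - 1, j = (int)angle(r, 1) - 1,
                k = (int)angle(r, 2) - 1;
      const double kth = angle(r, 3), th0 = angle(r, 4);
      double u[3] = {x(i, 0) - x(j, 0), x(i, 1) - x(j, 1), x(i, 2) - x(j, 2)};
      double v[3] = {x(k, 0) - x(j, 0), x(k, 1) - x(j, 1), x(k, 2) - x(j, 2)};
      const double nu = std::sqrt(dot3(u, u)), nv = std::sqrt(dot3(v, v));
      double cth = dot3(u, v) / (nu * nv);
      if (cth > 1.0) cth = 1.0;
      if (cth < -1.0) cth = -1.0;
      const double th = std::acos(cth);
      e[1] += 0.5 * kth * (th - th0) * (th - th0);
      if (want_grad) {
        double s2 = 1.0 - cth * cth;
        if (s2 < 1e-12) s2 = 1e-12;
        const double sth = std::sqrt(s2);
        const double dEdth = kth * (th - th0);
        for (int c = 0; c < 3; ++c) {
          const double du = -(v[c] / (nu * nv) - cth * u[c] / (nu * nu)) / sth;
          const double dv = -(u[c] / (nu * nv) - cth * v[c] / (nv * nv)) / sth;
          g(i, c) += dEdth * du;
          g(k, c) += dEdth * dv;
          g(j, c) -= dEdth * (du + dv);
        }
      }
    }
  }

  // torsions (proper idx 2, improper idx 3): K (1 + cos(n phi - gamma))
  for (int which = 0; which < 2; ++which) {
    if (!term_on[2 + which]) continue;
    const NumericMatrix& tab = which == 0 ? proper : improper;
    for (int r = 0; r < tab.nrow(); ++r) {
      const double K = tab(r, 4);
      if (K == 0.0) continue;
      const int i = (int)tab(r, 0) - 1, j = (int)tab(r, 1) - 1,
                k = (int)tab(r, 2) - 1, l = (int)tab(r, 3) - 1;
      const double nper = tab(r, 5), gamma = tab(r, 6);
      double b1[3] = {x(j, 0) - x(i, 0), x(j, 1) - x(i, 1), x(j, 2) - x(i, 2)};
      double b2[3] = {x(k, 0) - x(j, 0), x(k, 1) - x(j, 1), x(k, 2) - x(j, 2)};
      double b3[3] = {x(l, 0) - x(k, 0), x(l, 1) - x(k, 1), x(l, 2) - x(k, 2)};
      double n1[3], n2[3];
      cross3(b1, b2, n1);
      cross3(b2, b3, n2);
      const double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-10 || n2sq < 1e-10) continue;  // colinear arms
      const double b2sq = dot3(b2, b2), b2n = std::sqrt(b2sq);
      double b2u[3] = {b2[0] / b2n, b2[1] / b2n, b2[2] / b2n};
      double m1[3];
      cross3(n1, b2u, m1);
      const double phi = std::atan2(dot3(m1, n2), dot3(n1, n2));
      e[2 + which] += K * (1.0 + std::cos(nper * phi - gamma));
      if (want_grad) {
        const double dEdphi = -K * nper * std::sin(nper * phi - gamma);
        const double p = dot3(b1, b2) / b2sq, q = dot3(b3, b2) / b2sq;
        for (int c = 0; c < 3; ++c) {
          const double gi = b2n / n1sq * n1[c];
          const double gl = -b2n / n2sq * n2[c];
          const double gj = -(1.0 + p) * gi + q * gl;
          const double gk = p * gi - (1.0 + q) * gl;
          g(i, c) += dEdphi * gi;
          g(j, c) += dEdphi * gj;
          g(k, c) += dEdphi * gk;
          g(l, c) += dEdphi * gl;
        }
      }
    }
  }

  // nonbonded: 12-6 LJ (idx 4) and Coulomb (idx 5)
  const bool do_vdw = term_on[4], do_elec = term_on[5] && nb_qq.size() > 0;
  if (do_vdw || do_elec) {
    for (int r = 0; r < nb_i.size(); ++r) {
      const int i = nb_i[r] - 1, j = nb_j[r] - 1;
      double d[3] = {x(i, 0) - x(j, 0), x(i, 1) - x(j, 1), x(i, 2) - x(j, 2)};
      const double r2 = dot3(d, d);
      const double rij = std::sqrt(r2);
      double dEdr_over_r = 0.0;
      if (do_vdw) {
        const double rm2 = nb_rmin[r] * nb_rmin[r] / r2;
        const double s6 = rm2 * rm2 * rm2;
        e[4] += nb_eps[r] * (s6 * s6 - 2.0 * s6);
        if (want_grad) dEdr_over_r += nb_eps[r] * 12.0 * (s6 - s6 * s6) / r2;
      }
      if (do_elec) {
        e[5] += nb_qq[r] / rij;
        if (want_grad) dEdr_over_r += -nb_qq[r] / (r2 * rij);
      }
      if (want_grad && dEdr_over_r != 0.0) {
        for (int c = 0; c < 3; ++c) {
          g(i, c) += dEdr_over_r * d[c];
          g(j, c) -= dEdr_over_r * d[c];
        }
      }
    }
  }

  if (want_grad) return List::create(_["e"] = e, _["g"] = g);
  return List::create(_["e"] = e);
}
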