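// Fast overlap kernel: contracted spherical Gaussian AO overlaps via
// Obara-Saika 1-D recursion and solid-harmonic transformation.
//
// Positions are taken as complex numbers so that complex-step
// differentiation with respect to any coordinate flows through unchanged;
// real geometries simply carry zero imaginary parts. The solid-harmonic
// term tables duplicate the R-side convention (Racah-style, m = -l..+l,
// no Condon-Shortley phase) and are cross-checked against the R path and
// numerical quadrature in the test suite.

#include <Rcpp.h>
#include <complex>

using cplx = std::complex<double>;

struct Term { int i, j, k; double c; };

// Real solid harmonic monomial expansions, l = 0..3, m = -l..+l.
static const std::vector<std::vector<std::vector<Term>>> &harm_tables() {
  static std::vector<std::vector<std::vector<Term>>> T = [] {
    const double s3 = std::sqrt(3.0), s15 = std::sqrt(15.0);
    const double s58 = std::sqrt(5.0 / 8.0), s38 = std::sqrt(3.0 / 8.0);
    std::vector<std::vector<std::vector<Term>>> t(4);
    t[0] = {{{0, 0, 0, 1.0}}};
    t[1] = {{{0, 1, 0, 1.0}}, {{0, 0, 1, 1.0}}, {{1, 0, 0, 1.0}}};
    t[2] = {
        {{1, 1, 0, s3}},
        {{0, 1, 1, s3}},
        {{0, 0, 2, 1.0}, {2, 0, 0, -0.5}, {0, 2, 0, -0.5}},
        {{1, 0, 1, s3}},
        {{2, 0, 0, s3 / 2}, {0, 2, 0, -s3 / 2}}};
    t[3] = {
        {{2, 1, 0, 3 * s58}, {0, 3, 0, -s58}},
        {{1, 1, 1, s15}},
        {{0, 1, 2, 4 * s38}, {2, 1, 0, -s38}, {0, 3, 0, -s38}},
        {{0, 0, 3, 1.0}, {2, 0, 1, -1.5}, {0, 2, 1, -1.5}},
        {{1, 0, 2, 4 * s38}, {3, 0, 0, -s38}, {1, 2, 0, -s38}},
        {{2, 0, 1, s15 / 2}, {0, 2, 1, -s15 / 2}},
        {{3, 0, 0, s58}, {1, 2, 0, -3 * s58}}};
    return t;
  }();
  return T;
}

// 1-D Obara-Saika overlap table S[i][j] = <x_A^i | x_B^j>, i,j <= 3.
static void os_table(double a, double b, cplx Ax, cplx Bx, int imax, int jmax,
                     cplx S[4][4]) {
  const double p = a + b, mu = a * b / p, i2p = 0.5 / p;
  const cplx Px = (a * Ax + b * Bx) / p;
  const cplx XPA = Px - Ax, XPB = Px - Bx, XAB = Ax - Bx;
  S[0][0] = std::sqrt(M_PI / p) * std::exp(-mu * XAB * XAB);
  for (int i = 1; i <= imax; ++i) {
    S[i][0] = XPA * S[i - 1][0];
    if (i >= 2) S[i][0] += (double)(i - 1) * i2p * S[i - 2][0];
  }
  for (int j = 1; j <= jmax; ++j) {
    for (int i = 0; i <= imax; ++i) {
      cplx v = XPB * S[i][j - 1];
      if (i >= 1) v += (double)i * i2p * S[i - 1][j - 1];
      if (j >= 2) v += (double)(j - 1) * i2p * S[i][j - 2];
      S[i][j] = v;
    }
  }
}

// [[Rcpp::export(name = ".overlap_kernel")]]
Rcpp::ComplexMatrix overlap_kernel(
    Rcpp::ComplexMatrix pos,        // n_atoms x 3, Bohr
    Rcpp::IntegerVector shell_atom, // 1-based atom per shell
    Rcpp::IntegerVector shell_l,
    Rcpp::IntegerVector shell_off,  // 0-based first AO row per shell
    Rcpp::IntegerVector prim_start, // 0-based start into prim arrays
    Rcpp::IntegerVector prim_count,
    Rcpp::NumericVector prim_exp,
    Rcpp::NumericVector prim_wcoef, // contraction coeff * primitive norm
    Rcpp::NumericVector shell_norm, // contracted-shell normalisation
    int n_ao) {
  const auto &tables = harm_tables();
  const int nsh = shell_atom.size();
  Rcpp::ComplexMatrix Sout(n_ao, n_ao);
  std::vector<cplx> S(static_cast<size_t>(n_ao) * n_ao, cplx(0.0, 0.0));
  auto P = [&](int a, int d) {
    Rcomplex rc = pos(a, d);
    return cplx(rc.r, rc.i);
  };
  cplx Sx[4][4], Sy[4][4], Sz[4][4];
  for (int s1 = 0; s1 < nsh; ++s1) {
    const int l1 = shell_l[s1], a1 = shell_atom[s1] - 1;
    const cplx A0 = P(a1, 0), A1 = P(a1, 1), A2 = P(a1, 2);
    const auto &t1 = tables[l1];
    for (int s2 = s1; s2 < nsh; ++s2) {
      const int l2 = shell_l[s2], a2 = shell_atom[s2] - 1;
      const cplx B0 = P(a2, 0), B1 = P(a2, 1), B2 = P(a2, 2);
      const auto &t2 = tables[l2];
      const int d1 = 2 * l1 + 1, d2 = 2 * l2 + 1;
      std::vector<cplx> block(static_cast<size_t>(d1) * d2, cplx(0.0, 0.0));
      for (int p1 = 0; p1 < prim_count[s1]; ++p1) {
        const double ea = prim_exp[prim_start[s1] + p1];
        const double wa = prim_wcoef[prim_start[s1] + p1];
        for (int p2 = 0; p2 < prim_count[s2]; ++p2) {
          const double eb = prim_exp[prim_start[s2] + p2];
          const double w = wa * prim_wcoef[prim_start[s2] + p2];
          os_table(ea, eb, A0, B0, l1, l2, Sx);
          os_table(ea, eb, A1, B1, l1, l2, Sy);
          os_table(ea, eb, A2, B2, l1, l2, Sz);
          for (int m1 = 0; m1 < d1; ++m1) {
            for (int m2 = 0; m2 < d2; ++m2) {
              cplx acc(0.0, 0.0);
              for (const Term &u : t1[m1]) {
                for (const Term &v : t2[m2]) {
                  acc += u.c * v.c * Sx[u.i][v.i] * Sy[u.j][v.j] * Sz[u.k][v.k];
                }
              }
              block[m1 * d2 + m2] += w * acc;
            }
          }
        }
      }
      const double f = shell_norm[s1] * shell_norm[s2];
      for (int m1 = 0; m1 < d1; ++m1) {
        for (int m2 = 0; m2 < d2; ++m2) {
          const cplx v = f * block[m1 * d2 + m2];
          const int r = shell_off[s1] + m1, c = shell_off[s2] + m2;
          S[static_cast<size_t>(c) * n_ao + r] = v;
          S[static_cast<size_t>(r) * n_ao + c] = v;
        }
      }
    }
  }
  for (int c = 0; c < n_ao; ++c) {
    for (int r = 0; r < n_ao; ++r) {
      const cplx v = S[static_cast<size_t>(c) * n_ao + r];
      Sout(r, c) = Rcomplex{v.real(), v.imag()};
    }
  }
  return Sout;
}
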