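#pragma once
#include <cmath>

// Real, even-degree spherical harmonic basis, orthonormal on the sphere.
// Coefficient ordering: degrees l = 0, 2, ..., lmax; within each degree,
// m = -l ... +l.  m < 0 terms carry sqrt(2) * Pbar_l^|m| * sin(|m| phi),
// m = 0 terms Pbar_l^0, m > 0 terms sqrt(2) * Pbar_l^m * cos(m phi),
// where Pbar is the fully normalized associated Legendre function
// (Condon-Shortley phase included; irrelevant to orthonormality).

inline int sh_ncoef(int lmax) { return (lmax + 1) * (lmax + 2) / 2; }

#define SH_LMAX_CAP 12

// Evaluate all basis functions at one unit direction (x, y, z).
// out must hold sh_ncoef(lmax) doubles.
inline void sh_eval(int lmax, double x, double y, double z, double* out) {
  const double eps = 1e-14;
  double r = std::sqrt(x * x + y * y + z * z);
  if (r < eps) r = 1.0;
  x /= r; y /= r; z /= r;
  const double ct = z;
  const double st = std::sqrt(x * x + y * y);
  const double phi = (st < eps) ? 0.0 : std::atan2(y, x);

  // Pbar[l][m], l,m <= lmax
  double P[SH_LMAX_CAP + 1][SH_LMAX_CAP + 1];
  P[0][0] = std::sqrt(1.0 / (4.0 * M_PI));
  for (int m = 1; m <= lmax; ++m)
    P[m][m] = -std::sqrt((2.0 * m + 1.0) / (2.0 * m)) * st * P[m - 1][m - 1];
  for (int m = 0; m < lmax; ++m)
    P[m + 1][m] = std::sqrt(2.0 * m + 3.0) * ct * P[m][m];
  for (int m = 0; m <= lmax; ++m) {
    for (int l = m + 2; l <= lmax; ++l) {
      const double al = std::sqrt((4.0 * l * l - 1.0) / ((double)l * l - m * m));
      const double alm1 =
          std::sqrt((4.0 * (l - 1.0) * (l - 1.0) - 1.0) /
                    ((l - 1.0) * (l - 1.0) - m * m));
      P[l][m] = al * (ct * P[l - 1][m] - P[l - 2][m] / alm1);
    }
  }

  double cmphi[SH_LMAX_CAP + 1], smphi[SH_LMAX_CAP + 1];
  cmphi[0] = 1.0; smphi[0] = 0.0;
  if (lmax >= 1) { cmphi[1] = std::cos(phi); smphi[1] = std::sin(phi); }
  for (int m = 2; m <= lmax; ++m) {
    cmphi[m] = cmphi[m - 1] * cmphi[1] - smphi[m - 1] * smphi[1];
    smphi[m] = smphi[m - 1] * cmphi[1] + cmphi[m - 1] * smphi[1];
  }

  const double sq2 = std::sqrt(2.0);
  int pos = 0;
  for (int l = 0; l <= lmax; l += 2) {
    for (int m = -l; m <= l; ++m) {
      if (m < 0)      out[pos++] = sq2 * P[l][-m] * smphi[-m];
      else if (m == 0) out[pos++] = P[l][0];
      else            out[pos++] = sq2 * P[l][m] * cmphi[m];
    }
  }
}
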