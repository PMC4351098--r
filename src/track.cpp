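#include <RcppArmadillo.h>
#include "sh.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

// Probabilistic streamline propagation on a regular grid.
// Positions are world mm; masks are voxel grids addressed by 0-based
// indices through the inverse affine.  Fixed-step Euler integration;
// curvature enforced as a per-step cone (arc-chord relation applied in R).

struct Grid {
  int nx, ny, nz;
  mat w2v; // 4x4 world -> voxel (0-based, voxel-center) transform

  inline vec3 toVox(const vec3& w) const {
    vec3 v;
    for (int r = 0; r < 3; ++r)
      v(r) = w2v(r, 0) * w(0) + w2v(r, 1) * w(1) + w2v(r, 2) * w(2) + w2v(r, 3);
    return v;
  }
  inline bool nearest(const vec3& w, int& i, int& j, int& k) const {
    const vec3 v = toVox(w);
    i = (int)std::lround(v(0)); j = (int)std::lround(v(1));
    k = (int)std::lround(v(2));
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  inline int lin(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

static inline vec3 rand_sphere() {
  vec3 u;
  do { u = {norm_rand(), norm_rand(), norm_rand()}; } while (norm(u) < 1e-8);
  return u / norm(u);
}

// uniform direction within the spherical cap of half-angle acos(cos_cone)
// around t
static inline vec3 rand_cone(const vec3& t, double cos_cone) {
  const double cth = 1.0 - unif_rand() * (1.0 - cos_cone);
  const double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  const double phi = 2.0 * M_PI * unif_rand();
  vec3 a = std::fabs(t(0)) < 0.9 ? vec3({1, 0, 0}) : vec3({0, 1, 0});
  vec3 e1 = cross(t, a); e1 /= norm(e1);
  const vec3 e2 = cross(t, e1);
  return cth * t + sth * (std::cos(phi) * e1 + std::sin(phi) * e2);
}

// ---------------------------------------------------------------------------
// CSD: rejection sampling of the FOD amplitude

struct FodField {
  const double* coef; // nx*ny*nz*ncoef, R array layout
  const double* vmax; // per-voxel amplitude envelope
  const int* incl;
  Grid g;
  int ncoef, lmax;

  // trilinear interpolation of SH coefficients at world position
  bool interp(const vec3& w, double* out) const {
    const vec3 v = g.toVox(w);
    const int i0 = (int)std::floor(v(0)), j0 = (int)std::floor(v(1)),
              k0 = (int)std::floor(v(2));
    for (int c = 0; c < ncoef; ++c) out[c] = 0.0;
    double env = 0.0;
    const long nvox = (long)g.nx * g.ny * g.nz;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          const int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
            continue;
          const double wt = (di ? v(0) - i0 : 1 - (v(0) - i0)) *
                            (dj ? v(1) - j0 : 1 - (v(1) - j0)) *
                            (dk ? v(2) - k0 : 1 - (v(2) - k0));
          if (wt <= 0) continue;
          const long l = g.lin(i, j, k);
          for (int c = 0; c < ncoef; ++c) out[c] += wt * coef[l + nvox * c];
          env = std::max(env, vmax[l]);
        }
    return env > 0.0;
  }

  double envelope(const vec3& w) const {
    const vec3 v = g.toVox(w);
    const int i0 = (int)std::floor(v(0)), j0 = (int)std::floor(v(1)),
              k0 = (int)std::floor(v(2));
    double env = 0.0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          const int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz)
            continue;
          env = std::max(env, vmax[g.lin(i, j, k)]);
        }
    return env;
  }

  double amp(const double* c, const vec3& dir) const {
    double basis[64];
    sh_eval(lmax, dir(0), dir(1), dir(2), basis);
    double a = 0.0;
    for (int i = 0; i < ncoef; ++i) a += c[i] * basis[i];
    return a;
  }
};

// grow one side of a streamline; returns points appended to pts.
// first_exact: take the first step exactly along t (the initial direction
// already sampled from the model), so the two bidirectional halves meet at
// the seed within the curvature cone.
static int grow_csd(const FodField& F, vec3 p, vec3 t, double step,
                    double cos_cone, int max_steps, int max_trials,
                    double rel_cutoff, bool first_exact,
                    std::vector<double>& pts) {
  std::vector<double> c(F.ncoef);
  int nadd = 0;
  for (int s = 0; s < max_steps; ++s) {
    if (!F.interp(p, c.data())) break;
    const double vm = F.envelope(p);
    const double env = 1.1 * vm;
    if (env <= 0) break;
    bool ok = false;
    vec3 dir;
    if (s == 0 && first_exact) {
      dir = t; ok = true;
    } else {
      for (int tr = 0; tr < max_trials; ++tr) {
        dir = rand_cone(t, cos_cone);
        const double a = F.amp(c.data(), dir);
        if (a > rel_cutoff * vm && unif_rand() * env <= a) { ok = true; break; }
      }
    }
    if (!ok) break;
    const vec3 pn = p + step * dir;
    int i, j, k;
    if (!F.g.nearest(pn, i, j, k) || !F.incl[F.g.lin(i, j, k)]) break;
    pts.push_back(pn(0)); pts.push_back(pn(1)); pts.push_back(pn(2));
    p = pn; t = dir; ++nadd;
  }
  return nadd;
}

// [[Rcpp::export]]
List track_csd_cpp(const Rcpp::NumericVector& fod, const Rcpp::IntegerVector& dim3,
                   int lmax, const arma::mat& world2vox, const arma::mat& vox2world,
                   const Rcpp::IntegerVector& incl, const Rcpp::NumericVector& vmax,
                   const arma::imat& seeds, int per_seed, double step,
                   double cos_cone, double max_length, int max_trials,
                   double rel_cutoff) {
  FodField F;
  F.g.nx = dim3[0]; F.g.ny = dim3[1]; F.g.nz = dim3[2];
  F.g.w2v = world2vox;
  F.coef = fod.begin(); F.vmax = vmax.begin(); F.incl = incl.begin();
  F.ncoef = sh_ncoef(lmax); F.lmax = lmax;
  const int max_steps = (int)std::floor(max_length / step);

  List out(seeds.n_rows * per_seed);
  int n_init = 0;
  std::vector<double> c(F.ncoef);
  for (uword sv = 0; sv < seeds.n_rows; ++sv) {
    for (int r = 0; r < per_seed; ++r) {
      // jittered launch position within the seed voxel
      vec4 vx = {seeds(sv, 0) + unif_rand() - 0.5,
                 seeds(sv, 1) + unif_rand() - 0.5,
                 seeds(sv, 2) + unif_rand() - 0.5, 1.0};
      const vec4 w4 = vox2world * vx;
      const vec3 p0 = {w4(0), w4(1), w4(2)};
      ++n_init;

      // initial direction: FOD rejection sampling on the full sphere
      vec3 t0; bool ok = false;
      if (F.interp(p0, c.data())) {
        const double vm = F.envelope(p0);
        const double env = 1.1 * vm;
        for (int tr = 0; tr < 4 * max_trials && env > 0; ++tr) {
          t0 = rand_sphere();
          const double a = F.amp(c.data(), t0);
          if (a > rel_cutoff * vm && unif_rand() * env <= a) { ok = true; break; }
        }
      }
      std::vector<double> fwd, bwd;
      int n1 = 0, n2 = 0;
      if (ok) {
        n1 = grow_csd(F, p0, t0, step, cos_cone, max_steps, max_trials,
                      rel_cutoff, true, fwd);
        n2 = grow_csd(F, p0, -t0, step, cos_cone, max_steps - n1, max_trials,
                      rel_cutoff, false, bwd);
      }
      arma::mat pts(n1 + n2 + 1, 3);
      for (int i = 0; i < n2; ++i)
        for (int a = 0; a < 3; ++a)
          pts(i, a) = bwd[3 * (n2 - 1 - i) + a];
      for (int a = 0; a < 3; ++a) pts(n2, a) = p0(a);
      for (int i = 0; i < n1; ++i)
        for (int a = 0; a < 3; ++a) pts(n2 + 1 + i, a) = fwd[3 * i + a];
      out[sv * per_seed + r] = pts;
    }
  }
  return List::create(Rcpp::Named("points") = out,
                      Rcpp::Named("initiated") = n_init);
}

// ---------------------------------------------------------------------------
// Ball-and-stick: one posterior draw per step, nearest-voxel field

struct BsField {
  const double* dir;    // nvox x K x 3 x nsamp
  const double* meanf;  // nvox x K
  const int* incl;
  Grid g;
  int K, nsamp;
  long nvox;
  double f_thresh;

  // sample a direction given incoming t (or random for t=NULL semantics)
  bool sample(int lin, const vec3* t, vec3& out) const {
    const int s = std::min((int)(unif_rand() * nsamp), nsamp - 1);
    int best = -1; double bestdot = -1.0;
    int adm[8]; int nadm = 0;
    for (int k = 0; k < K; ++k)
      if (meanf[lin + nvox * k] >= f_thresh) adm[nadm++] = k;
    if (nadm == 0) return false;
    if (t == nullptr) {
      best = adm[std::min((int)(unif_rand() * nadm), nadm - 1)];
    } else {
      for (int a = 0; a < nadm; ++a) {
        const int k = adm[a];
        double dp = 0;
        for (int c = 0; c < 3; ++c)
          dp += (*t)(c) * dir[lin + nvox * (k + K * (c + 3 * s))];
        if (std::fabs(dp) > bestdot) { bestdot = std::fabs(dp); best = k; }
      }
    }
    vec3 v;
    for (int c = 0; c < 3; ++c) v(c) = dir[lin + nvox * (best + K * (c + 3 * s))];
    const double nv = norm(v);
    if (nv < 1e-8) return false;
    v /= nv;
    if (t != nullptr && dot(v, *t) < 0) v = -v;
    else if (t == nullptr && unif_rand() < 0.5) v = -v;
    out = v;
    return true;
  }
};

static int grow_bs(const BsField& F, vec3 p, vec3 t, double step,
                   double cos_cone, int max_steps, int max_trials,
                   bool first_exact, std::vector<double>& pts) {
  int nadd = 0;
  for (int s = 0; s < max_steps; ++s) {
    int i, j, k;
    if (!F.g.nearest(p, i, j, k)) break;
    const int lin = F.g.lin(i, j, k);
    vec3 dir; bool ok = false;
    if (s == 0 && first_exact) {
      dir = t; ok = true;
    } else {
      for (int tr = 0; tr < max_trials; ++tr) {
        if (!F.sample(lin, &t, dir)) break;
        if (dot(dir, t) >= cos_cone) { ok = true; break; }
      }
    }
    if (!ok) break;
    const vec3 pn = p + step * dir;
    int i2, j2, k2;
    if (!F.g.nearest(pn, i2, j2, k2) || !F.incl[F.g.lin(i2, j2, k2)]) break;
    pts.push_back(pn(0)); pts.push_back(pn(1)); pts.push_back(pn(2));
    p = pn; t = dir; ++nadd;
  }
  return nadd;
}

// [[Rcpp::export]]
List track_bs_cpp(const Rcpp::NumericVector& dirsamp, const Rcpp::IntegerVector& dim3,
                  int K, int nsamp, const Rcpp::NumericVector& meanf,
                  double f_thresh, const arma::mat& world2vox,
                  const arma::mat& vox2world, const Rcpp::IntegerVector& incl,
                  const arma::imat& seeds, int per_seed, double step,
                  double cos_cone, double max_length, int max_trials) {
  BsField F;
  F.g.nx = dim3[0]; F.g.ny = dim3[1]; F.g.nz = dim3[2];
  F.g.w2v = world2vox;
  F.dir = dirsamp.begin(); F.meanf = meanf.begin(); F.incl = incl.begin();
  F.K = K; F.nsamp = nsamp; F.f_thresh = f_thresh;
  F.nvox = (long)F.g.nx * F.g.ny * F.g.nz;
  const int max_steps = (int)std::floor(max_length / step);

  List out(seeds.n_rows * per_seed);
  int n_init = 0;
  for (uword sv = 0; sv < seeds.n_rows; ++sv) {
    for (int r = 0; r < per_seed; ++r) {
      vec4 vx = {seeds(sv, 0) + unif_rand() - 0.5,
                 seeds(sv, 1) + unif_rand() - 0.5,
                 seeds(sv, 2) + unif_rand() - 0.5, 1.0};
      const vec4 w4 = vox2world * vx;
      const vec3 p0 = {w4(0), w4(1), w4(2)};
      ++n_init;

      vec3 t0; bool ok = false;
      int i, j, k;
      if (F.g.nearest(p0, i, j, k)) ok = F.sample(F.g.lin(i, j, k), nullptr, t0);
      std::vector<double> fwd, bwd;
      int n1 = 0, n2 = 0;
      if (ok) {
        n1 = grow_bs(F, p0, t0, step, cos_cone, max_steps, max_trials, true,
                     fwd);
        n2 = grow_bs(F, p0, -t0, step, cos_cone, max_steps - n1, max_trials,
                     false, bwd);
      }
      arma::mat pts(n1 + n2 + 1, 3);
      for (int i2 = 0; i2 < n2; ++i2)
        for (int a = 0; a < 3; ++a) pts(i2, a) = bwd[3 * (n2 - 1 - i2) + a];
      for (int a = 0; a < 3; ++a) pts(n2, a) = p0(a);
      for (int i2 = 0; i2 < n1; ++i2)
        for (int a = 0; a < 3; ++a) pts(n2 + 1 + i2, a) = fwd[3 * i2 + a];
      out[sv * per_seed + r] = pts;
    }
  }
  return List::create(Rcpp::Named("points") = out,
                      Rcpp::Named("initiated") = n_init);
}
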