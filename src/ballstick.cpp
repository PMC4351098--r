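#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

// Metropolis-within-Gibbs sampler for the ball-and-stick model
//   S(g, b) = s0 [ (1 - sum_k f_k) exp(-b d) + sum_k f_k exp(-b d (g.v_k)^2) ]
// under iid Gaussian noise; sigma^2 is given a conjugate inverse-gamma
// update, all other parameters component-wise random-walk MH.  Orientation
// parameters (theta, phi) carry the sin(theta) area prior; d and f are
// uniform on (D_LO, D_HI) and the unit simplex respectively.
//
// Y     nvox x nmeas signals (all volumes, b0 included)
// G     nmeas x 3 unit gradient directions (rows for b0 arbitrary)
// bval  nmeas b-values (s/mm^2)
//
// Returns posterior draws kept every `thin` iterations after `burn_in`.

static const double D_LO = 1e-5, D_HI = 1e-2;

struct Prop { double scale; int acc, tot; };

static inline void adapt(Prop& p) {
  if (p.tot >= 40) {
    const double r = (double)p.acc / p.tot;
    if (r > 0.5) p.scale *= 1.1; else if (r < 0.3) p.scale *= 0.9;
    p.acc = 0; p.tot = 0;
  }
}

static inline vec sph2vec(double th, double ph) {
  return vec({std::sin(th) * std::cos(ph), std::sin(th) * std::sin(ph),
              std::cos(th)});
}

// [[Rcpp::export]]
List ballstick_mcmc_cpp(const arma::mat& Y, const arma::mat& G,
                        const arma::vec& bval, int n_sticks, int burn_in,
                        int n_keep, int thin) {
  const int nvox = Y.n_rows, n = Y.n_cols, K = n_sticks;
  if (burn_in < 0 || n_keep < 1 || thin < 1)
    Rcpp::stop("MCMC counts must be positive");
  const int total = burn_in + n_keep * thin;

  cube f_out(nvox, K, n_keep);
  Rcpp::IntegerVector dir_dim =
      Rcpp::IntegerVector::create(nvox, K, 3, n_keep);
  Rcpp::NumericVector dir_out((R_xlen_t)nvox * K * 3 * n_keep);
  dir_out.attr("dim") = dir_dim;
  mat d_out(nvox, n_keep), s0_out(nvox, n_keep), sig_out(nvox, n_keep);
  vec acc_out(nvox);

  const uvec idw = find(bval > 50.0);
  const uvec ib0 = find(bval <= 50.0);
  const vec b = bval;

  for (int v = 0; v < nvox; ++v) {
    const vec y = Y.row(v).t();

    // --- initialisation ---------------------------------------------------
    double s0 = ib0.n_elem > 0 ? mean(y(ib0)) : y.max();
    if (s0 <= 0) s0 = std::max(y.max(), 1e-3);
    double att = mean(y(idw)) / s0;
    att = std::min(std::max(att, 1e-4), 0.999);
    double d = -std::log(att) / mean(b(idw));
    d = std::min(std::max(d, 2e-4), 8e-3);
    vec f(K), th(K), ph(K);
    // sticks pointed along the most attenuated directions
    uvec ord = sort_index(y(idw));
    for (int k = 0; k < K; ++k) {
      const int im = idw(ord(std::min((int)idw.n_elem - 1, k * 3)));
      vec g = G.row(im).t();
      if (norm(g) < 0.5) g = {0, 0, 1};
      th(k) = std::acos(std::min(std::max(g(2) / norm(g), -1.0), 1.0));
      ph(k) = std::atan2(g(1), g(0));
      f(k) = 0.5 / K;
    }
    const double s0_hi = 10.0 * std::max(s0, 1e-3);

    // cached per-compartment attenuations
    vec aiso = exp(-b * d);
    mat ak(n, K);
    mat ck(n, K); // (g . v_k)^2
    for (int k = 0; k < K; ++k) {
      const vec vk = sph2vec(th(k), ph(k));
      ck.col(k) = square(G * vk);
      ak.col(k) = exp(-b % (d * ck.col(k)));
    }
    auto mix = [&](const vec& fv, const vec& ai, const mat& akm) {
      vec m = (1.0 - accu(fv)) * ai;
      for (int k = 0; k < K; ++k) m += fv(k) * akm.col(k);
      return m;
    };
    vec m = mix(f, aiso, ak);
    double SS = accu(square(y - s0 * m));
    double sig2 = std::max(SS / n, 1e-8);

    Prop p_s0{0.05 * s0, 0, 0}, p_d{0.1 * d, 0, 0};
    std::vector<Prop> p_f(K, Prop{0.05, 0, 0}), p_v(K, Prop{0.15, 0, 0});
    long acc_post = 0, tot_post = 0;
    int kept = 0;

    for (int it = 0; it < total; ++it) {
      const bool adapting = it < burn_in;

      // s0
      {
        const double s0p = s0 + p_s0.scale * norm_rand();
        p_s0.tot++;
        if (s0p > 0 && s0p < s0_hi) {
          const double SSp = accu(square(y - s0p * m));
          if (std::log(unif_rand()) < -(SSp - SS) / (2 * sig2)) {
            s0 = s0p; SS = SSp; p_s0.acc++;
          }
        }
        if (adapting) adapt(p_s0); else { tot_post++; acc_post += 0; }
      }
      // d
      {
        const double dp = d + p_d.scale * norm_rand();
        p_d.tot++;
        if (dp > D_LO && dp < D_HI) {
          const vec aisop = exp(-b * dp);
          mat akp(n, K);
          for (int k = 0; k < K; ++k) akp.col(k) = exp(-b % (dp * ck.col(k)));
          const vec mp = mix(f, aisop, akp);
          const double SSp = accu(square(y - s0 * mp));
          if (std::log(unif_rand()) < -(SSp - SS) / (2 * sig2)) {
            d = dp; aiso = aisop; ak = akp; m = mp; SS = SSp; p_d.acc++;
          }
        }
        if (adapting) adapt(p_d);
      }
      // stick orientations
      for (int k = 0; k < K; ++k) {
        const double thp = th(k) + p_v[k].scale * norm_rand();
        const double php = ph(k) + p_v[k].scale * norm_rand();
        p_v[k].tot++;
        const double sth = std::sin(th(k)), sthp = std::sin(thp);
        if (sthp > 1e-8 && thp > 0 && thp < M_PI) {
          const vec vk = sph2vec(thp, php);
          const vec ckp = square(G * vk);
          const vec akp = exp(-b % (d * ckp));
          vec mp = m + f(k) * (akp - ak.col(k));
          const double SSp = accu(square(y - s0 * mp));
          const double lr = -(SSp - SS) / (2 * sig2) +
                            std::log(sthp / std::max(sth, 1e-12));
          if (std::log(unif_rand()) < lr) {
            th(k) = thp; ph(k) = php; ck.col(k) = ckp; ak.col(k) = akp;
            m = mp; SS = SSp; p_v[k].acc++;
          }
        }
        if (adapting) adapt(p_v[k]);
      }
      // stick fractions
      for (int k = 0; k < K; ++k) {
        const double fp = f(k) + p_f[k].scale * norm_rand();
        p_f[k].tot++;
        const double fsum = accu(f) - f(k) + fp;
        if (fp > 0 && fp < 1 && fsum < 1) {
          const vec mp = m + (fp - f(k)) * (ak.col(k) - aiso);
          const double SSp = accu(square(y - s0 * mp));
          if (std::log(unif_rand()) < -(SSp - SS) / (2 * sig2)) {
            f(k) = fp; m = mp; SS = SSp; p_f[k].acc++;
          }
        }
        if (adapting) adapt(p_f[k]);
      }
      // sigma^2 | rest ~ InvGamma(a0 + n/2, b0 + SS/2)
      {
        const double shape = 1e-3 + 0.5 * n;
        const double rate = 1e-3 + 0.5 * SS;
        const double g = R::rgamma(shape, 1.0 / rate);
        sig2 = std::max(1.0 / std::max(g, 1e-300), 1e-12);
      }

      if (!adapting) {
        // pooled post-burn-in MH acceptance across parameter blocks
        tot_post = p_s0.tot + p_d.tot;
        acc_post = p_s0.acc + p_d.acc;
        for (int k = 0; k < K; ++k) {
          tot_post += p_f[k].tot + p_v[k].tot;
          acc_post += p_f[k].acc + p_v[k].acc;
        }
        const int since = it - burn_in + 1;
        if (since % thin == 0 && kept < n_keep) {
          for (int k = 0; k < K; ++k) {
            f_out(v, k, kept) = f(k);
            const vec vk = sph2vec(th(k), ph(k));
            for (int a = 0; a < 3; ++a)
              dir_out[v + nvox * (k + K * (a + 3 * kept))] = vk(a);
          }
          d_out(v, kept) = d;
          s0_out(v, kept) = s0;
          sig_out(v, kept) = std::sqrt(sig2);
          kept++;
        }
      }
    }
    acc_out(v) = tot_post > 0 ? (double)acc_post / tot_post : NA_REAL;
  }

  return List::create(Rcpp::Named("f") = f_out, Rcpp::Named("dir") = dir_out,
                      Rcpp::Named("d") = d_out, Rcpp::Named("s0") = s0_out,
                      Rcpp::Named("sigma") = sig_out,
                      Rcpp::Named("acceptance") = acc_out);
}
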