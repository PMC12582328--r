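#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical allometric regression, sampled by componentwise adaptive
// random-walk Metropolis. Scale parameters are sampled on the log scale
// (log-Jacobian included); group intercepts use the noncentered
// parameterization by default. The group-slope nonnegativity constraint is
// enforced by rejection (log posterior = -Inf outside the constraint).
//
// Parameter vector layout:
//   0                alpha_overall
//   1                log sigma_intercept
//   2 .. 1+G         z_g   (noncentered)  or alpha_g (centered)
//   2+G              beta_overall
//  [3+G              log sigma_delta      (full model only)
//   4+G .. 3+G+S     delta_s              (full model only)]
//   next             log sigma_gamma
//   next G           gamma_g
//   last             log sigma_obs

static double log_half_cauchy(double x, double scale) {
  // density of |Cauchy(0, scale)| for x > 0
  return std::log(2.0 / (M_PI * scale * (1.0 + (x / scale) * (x / scale))));
}

struct ModelSpec {
  int n, G, S;
  std::vector<double> x, y;
  std::vector<int> g;   // 0-based group per observation
  std::vector<int> sp;  // 0-based species per group
  bool has_species, centered, prior_only;
  int constraint;       // 0 = group slopes >= 0, 1 = beta_overall >= 0, 2 = none
  double a0_mean, a0_sd, sint_scale, b0_mean, b0_sd,
         sdelta_scale, sgamma_scale, sobs_scale;
  double sobs_fixed;    // > 0: likelihood uses this sd instead of the sampled one

  int npar() const {
    return 2 + G + 1 + (has_species ? 1 + S : 0) + 1 + G + 1;
  }

  double logpost(const std::vector<double>& th) const {
    int p = 0;
    double lp = 0.0;
    const double a0 = th[p++];
    lp += R::dnorm(a0, a0_mean, a0_sd, 1);
    const double u_int = th[p++];
    const double sint = std::exp(u_int);
    lp += log_half_cauchy(sint, sint_scale) + u_int;
    std::vector<double> alpha(G);
    for (int gg = 0; gg < G; ++gg) {
      const double v = th[p++];
      if (centered) {
        alpha[gg] = v;
        lp += R::dnorm(v, a0, sint, 1);
      } else {
        alpha[gg] = a0 + sint * v;
        lp += R::dnorm(v, 0.0, 1.0, 1);
      }
    }
    const double b0 = th[p++];
    lp += R::dnorm(b0, b0_mean, b0_sd, 1);
    std::vector<double> delta(S, 0.0);
    if (has_species) {
      const double u_d = th[p++];
      const double sdelta = std::exp(u_d);
      lp += log_half_cauchy(sdelta, sdelta_scale) + u_d;
      for (int s = 0; s < S; ++s) {
        delta[s] = th[p++];
        lp += R::dnorm(delta[s], 0.0, sdelta, 1);
      }
    }
    const double u_g = th[p++];
    const double sgamma = std::exp(u_g);
    lp += log_half_cauchy(sgamma, sgamma_scale) + u_g;
    std::vector<double> beta(G);
    for (int gg = 0; gg < G; ++gg) {
      const double gam = th[p++];
      lp += R::dnorm(gam, 0.0, sgamma, 1);
      beta[gg] = b0 + delta[sp[gg]] + gam;
    }
    const double u_o = th[p++];
    const double sobs = std::exp(u_o);
    lp += log_half_cauchy(sobs, sobs_scale) + u_o;

    if (constraint == 0) {
      for (int gg = 0; gg < G; ++gg)
        if (beta[gg] < 0.0) return R_NegInf;
    } else if (constraint == 1) {
      if (b0 < 0.0) return R_NegInf;
    }
    if (!prior_only) {
      const double s_lik = (sobs_fixed > 0.0) ? sobs_fixed : sobs;
      for (int i = 0; i < n; ++i) {
        const int gg = g[i];
        lp += R::dnorm(y[i], alpha[gg] + beta[gg] * x[i], s_lik, 1);
      }
    }
    return lp;
  }
};

// [[Rcpp::export(name = ".allometry_chain")]]
List allometry_chain(NumericVector x, NumericVector y, IntegerVector group,
                     IntegerVector species_of_group, bool has_species,
                     bool centered, bool prior_only, int constraint,
                     List prior, int iter, int warmup, int thin,
                     NumericVector init, double init_step,
                     double sobs_fixed) {
  ModelSpec m;
  m.n = x.size();
  m.G = species_of_group.size();
  m.S = 0;
  for (int gg = 0; gg < m.G; ++gg)
    m.S = std::max(m.S, (int)species_of_group[gg]);
  m.x.assign(x.begin(), x.end());
  m.y.assign(y.begin(), y.end());
  m.g.resize(m.n);
  for (int i = 0; i < m.n; ++i) m.g[i] = group[i] - 1;
  m.sp.resize(m.G);
  for (int gg = 0; gg < m.G; ++gg) m.sp[gg] = species_of_group[gg] - 1;
  m.has_species = has_species;
  m.centered = centered;
  m.prior_only = prior_only;
  m.constraint = constraint;
  m.a0_mean = as<double>(prior["alpha_mean"]);
  m.a0_sd = as<double>(prior["alpha_sd"]);
  m.sint_scale = as<double>(prior["sigma_intercept_scale"]);
  m.b0_mean = as<double>(prior["beta_mean"]);
  m.b0_sd = as<double>(prior["beta_sd"]);
  m.sdelta_scale = as<double>(prior["sigma_delta_scale"]);
  m.sgamma_scale = as<double>(prior["sigma_gamma_scale"]);
  m.sobs_scale = as<double>(prior["sigma_obs_scale"]);
  m.sobs_fixed = sobs_fixed;

  const int npar = m.npar();
  if (init.size() != npar) stop("init has wrong length");
  std::vector<double> th(init.begin(), init.end());
  double lp = m.logpost(th);
  if (!R_finite(lp)) stop("initial state has zero posterior density");

  std::vector<double> ls(npar, std::log(init_step));
  std::vector<int> acc_batch(npar, 0), acc_total(npar, 0);
  const int batch = 50;
  int nbatch = 0;

  const int nkeep = (iter - warmup + thin - 1) / thin;
  NumericMatrix draws(nkeep, npar);
  NumericVector lp_keep(nkeep);
  int kept = 0;

  // structured "interweaving" moves for the directions a componentwise walk
  // traverses slowly: translations along likelihood-invariant combinations
  // (overall level vs group deviations) and joint scale moves through the
  // hierarchical funnels. Each move is a deterministic map x' = T(x, eps)
  // with symmetric eps, accepted with the posterior ratio times |Jacobian|.
  const int p_a0 = 0, p_uint = 1, p_z0 = 2, p_b0 = 2 + m.G;
  const int p_ud = has_species ? 3 + m.G : -1;
  const int p_d0 = has_species ? 4 + m.G : -1;
  const int p_ug = has_species ? 4 + m.G + m.S : 3 + m.G;
  const int p_g0 = p_ug + 1;
  // moves: 0 shift-alpha, 1 shift-beta/gamma, 2 scale-int, 3 scale-gamma,
  //        4 scale-delta, 5 shift-beta/delta, 6.. shift-delta/gamma per
  //        species
  const int nmove = 4 + (has_species ? 2 + m.S : 0);
  std::vector<double> ls_m(nmove, std::log(0.5));
  std::vector<int> accm_batch(nmove, 0);

  std::vector<double> prop(npar);
  auto try_move = [&](int mv, int it) {
    const double eps = std::exp(ls_m[mv]) * norm_rand();
    prop = th;
    double logJ = 0.0;
    if (mv == 0) {                       // alpha_overall vs z_g (noncentered)
      if (centered) return;
      const double sint = std::exp(th[p_uint]);
      prop[p_a0] += eps;
      for (int gg = 0; gg < m.G; ++gg) prop[p_z0 + gg] -= eps / sint;
    } else if (mv == 1) {                // beta_overall vs gamma_g
      prop[p_b0] += eps;
      for (int gg = 0; gg < m.G; ++gg) prop[p_g0 + gg] -= eps;
    } else if (mv == 2) {                // sigma_intercept funnel
      if (centered) return;
      prop[p_uint] += eps;
      for (int gg = 0; gg < m.G; ++gg) prop[p_z0 + gg] *= std::exp(-eps);
      logJ = -m.G * eps;
    } else if (mv == 3) {                // sigma_gamma funnel
      prop[p_ug] += eps;
      for (int gg = 0; gg < m.G; ++gg) prop[p_g0 + gg] *= std::exp(-eps);
      logJ = -m.G * eps;
    } else if (mv == 4) {                // sigma_delta funnel
      prop[p_ud] += eps;
      for (int s = 0; s < m.S; ++s) prop[p_d0 + s] *= std::exp(-eps);
      logJ = -m.S * eps;
    } else if (mv == 5) {                // beta_overall vs delta_s
      prop[p_b0] += eps;
      for (int s = 0; s < m.S; ++s) prop[p_d0 + s] -= eps;
    } else {                             // delta_s vs gamma_g within species
      const int s = mv - 6;
      prop[p_d0 + s] += eps;
      for (int gg = 0; gg < m.G; ++gg)
        if (m.sp[gg] == s) prop[p_g0 + gg] -= eps;
    }
    const double lp_new = m.logpost(prop);
    if (R_finite(lp_new) &&
        std::log(unif_rand()) < lp_new - lp + logJ) {
      th = prop;
      lp = lp_new;
      ++accm_batch[mv];
    }
  };

  RNGScope scope;
  for (int it = 0; it < iter; ++it) {
    for (int j = 0; j < npar; ++j) {
      const double old = th[j];
      th[j] = old + std::exp(ls[j]) * norm_rand();
      const double lp_new = m.logpost(th);
      if (R_finite(lp_new) && std::log(unif_rand()) < lp_new - lp) {
        lp = lp_new;
        ++acc_batch[j];
        if (it >= warmup) ++acc_total[j];
      } else {
        th[j] = old;
      }
    }
    for (int mv = 0; mv < nmove; ++mv) try_move(mv, it);
    if (it < warmup && (it + 1) % batch == 0) {
      ++nbatch;
      const double adj = std::min(0.1, 1.0 / std::sqrt((double)nbatch));
      for (int j = 0; j < npar; ++j) {
        if (acc_batch[j] > 0.44 * batch) ls[j] += adj; else ls[j] -= adj;
        acc_batch[j] = 0;
      }
      for (int mv = 0; mv < nmove; ++mv) {
        if (accm_batch[mv] > 0.44 * batch) ls_m[mv] += adj;
        else ls_m[mv] -= adj;
        accm_batch[mv] = 0;
      }
    }
    if (it >= warmup && (it - warmup) % thin == 0) {
      for (int j = 0; j < npar; ++j) draws(kept, j) = th[j];
      lp_keep[kept] = lp;
      ++kept;
    }
  }
  NumericVector acc(npar);
  for (int j = 0; j < npar; ++j)
    acc[j] = acc_total[j] / (double)(iter - warmup);
  return List::create(_["draws"] = draws, _["lp"] = lp_keep,
                      _["accept"] = acc);
}
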