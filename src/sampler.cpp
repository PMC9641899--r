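// Hierarchical Metropolis-Hastings sampler for derivative-of-Gaussian
// bias-curve models of sequential estimation errors.
//
// Trial level:      y_it ~ vonMises(mu_it, kappa = 1/sigma_i_rad^2)
// Individual level: amplitudes / peak locations / noise SDs ~ vonMises
//                   (degree scale), centre mixtures (beta) ~ Normal
// Population level: broad priors on means, Gamma priors on SDs.
//
// Componentwise Gaussian random-walk proposals; step sizes adapted toward a
// 20-45% acceptance rate during burn-in and frozen afterwards. Likelihood
// evaluations cache the per-trial unit bias curves and the cosine sum so
// that amplitude and noise updates cost O(n) cosines or O(1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static double log_i0(double k) {
  if (k < 50.0) {
    double v = R::bessel_i(k, 0.0, 2.0); // exponentially scaled
    if (v > 0.0 && R_finite(v)) return k + std::log(v);
  }
  // uniform asymptotic expansion; relative error < 1e-6 for k >= 50
  double ik = 1.0 / k;
  double corr = 1.0 + ik / 8.0 + 9.0 * ik * ik / 128.0 +
                225.0 * ik * ik * ik / 3072.0;
  return k - 0.5 * std::log(2.0 * M_PI * k) + std::log(corr);
}

static inline double kappa_deg(double sd) {
  double s = sd * DEG;
  return 1.0 / (s * s);
}

static inline double wrap_s(double a) {
  double r = a - 360.0 * std::floor(a / 360.0); // [0, 360)
  if (r > 180.0) r -= 360.0;
  return r; // (-180, 180]
}

// unit-amplitude DoG: x * w * c * exp(-(w x)^2), w = 1/(sqrt(2) l)
static void unit_dog(const std::vector<double>& x, double l,
                     std::vector<double>& u) {
  const double w = 1.0 / (std::sqrt(2.0) * l);
  const double cc = std::sqrt(2.0) * std::exp(0.5);
  for (size_t i = 0; i < x.size(); ++i) {
    double wx = w * x[i];
    u[i] = x[i] * w * cc * std::exp(-wx * wx);
  }
}

// von Mises log-density on the degree scale (per-degree density)
static inline double vm_lp(double delta_deg, double kappa) {
  return kappa * std::cos(delta_deg * DEG) - std::log(2.0 * M_PI) -
         log_i0(kappa) + std::log(DEG);
}

// individual-level prior: type 3 (beta) Gaussian, others von Mises
static double ind_lp(double th, double mu, double tau, int type) {
  if (type == 3) return R::dnorm(th, mu, tau, 1);
  return vm_lp(th - mu, kappa_deg(tau));
}

struct Subj {
  std::vector<double> y, xs, xr, d; // data (degrees)
  std::vector<double> x1, x2;       // current curve inputs
  std::vector<double> u1, u2;       // unit curves at current widths
  std::vector<double> mu;           // current predicted mean
  double C;                         // sum cos(y - mu)
  int n;
};

struct Layout {
  int P;                      // params per subject
  std::vector<int> comp;      // 0 = none (sigma), 1, 2
  std::vector<int> role;      // 0 amp, 1 width, 2 beta, 3 sigma
  int amp[3], wid[3], bet[3]; // indices per component (1-based comp)
  int sig;
  int ncomp;
};

static Layout make_layout(int model_code) {
  Layout L;
  if (model_code == 1 || model_code == 2) {
    L.P = 3;
    L.comp = {1, 1, 0};
    L.role = {0, 1, 3};
    L.amp[1] = 0; L.wid[1] = 1; L.bet[1] = -1;
    L.sig = 2; L.ncomp = 1;
  } else if (model_code == 3) {
    L.P = 5;
    L.comp = {1, 1, 2, 2, 0};
    L.role = {0, 1, 0, 1, 3};
    L.amp[1] = 0; L.wid[1] = 1; L.bet[1] = -1;
    L.amp[2] = 2; L.wid[2] = 3; L.bet[2] = -1;
    L.sig = 4; L.ncomp = 2;
  } else {
    L.P = 7;
    L.comp = {1, 1, 1, 2, 2, 2, 0};
    L.role = {0, 1, 2, 0, 1, 2, 3};
    L.amp[1] = 0; L.wid[1] = 1; L.bet[1] = 2;
    L.amp[2] = 3; L.wid[2] = 4; L.bet[2] = 5;
    L.sig = 6; L.ncomp = 2;
  }
  return L;
}

static double cos_sum(const std::vector<double>& y,
                      const std::vector<double>& mu) {
  double s = 0.0;
  for (size_t i = 0; i < y.size(); ++i) s += std::cos((y[i] - mu[i]) * DEG);
  return s;
}

// rebuild all caches for one subject from its parameter vector
static void refresh_subj(Subj& S, const double* th, const Layout& L,
                         int model_code) {
  if (model_code == 1) S.x1 = S.xs;
  else if (model_code == 2) S.x1 = S.xr;
  else if (model_code == 3) { S.x1 = S.xs; S.x2 = S.xr; }
  else {
    S.x1.resize(S.n); S.x2.resize(S.n);
    double ba = th[L.bet[1]], br = th[L.bet[2]];
    for (int i = 0; i < S.n; ++i) {
      S.x1[i] = wrap_s(S.xs[i] + ba * S.d[i]);
      S.x2[i] = wrap_s(S.xs[i] + br * S.d[i]);
    }
  }
  S.u1.resize(S.n);
  unit_dog(S.x1, th[L.wid[1]], S.u1);
  S.mu.assign(S.n, 0.0);
  for (int i = 0; i < S.n; ++i) S.mu[i] = th[L.amp[1]] * S.u1[i];
  if (L.ncomp == 2) {
    S.u2.resize(S.n);
    unit_dog(S.x2, th[L.wid[2]], S.u2);
    for (int i = 0; i < S.n; ++i) S.mu[i] += th[L.amp[2]] * S.u2[i];
  }
  S.C = cos_sum(S.y, S.mu);
}

// [[Rcpp::export]]
List mh_chain_cpp(List subj_data, int model_code, List meta,
                  NumericVector init_ind, NumericVector init_mu,
                  NumericVector init_tau, int n_burn, int n_draw, int thin) {
  const Layout L = make_layout(model_code);
  const int P = L.P;
  const int nS = subj_data.size();

  IntegerVector ptype = meta["ptype"];
  NumericVector gshape = meta["gshape"], grate = meta["grate"];
  NumericVector mumean = meta["mumean"], musd = meta["musd"];
  NumericVector lower = meta["lower"], upper = meta["upper"];
  NumericVector mu_lower = meta["mu_lower"], mu_upper = meta["mu_upper"];

  std::vector<Subj> S(nS);
  for (int i = 0; i < nS; ++i) {
    List di = subj_data[i];
    S[i].y = as<std::vector<double>>(di["y"]);
    S[i].xs = as<std::vector<double>>(di["xs"]);
    S[i].xr = as<std::vector<double>>(di["xr"]);
    S[i].d = as<std::vector<double>>(di["d"]);
    S[i].n = S[i].y.size();
  }

  // state
  std::vector<std::vector<double>> th(nS, as<std::vector<double>>(init_ind));
  std::vector<double> mu = as<std::vector<double>>(init_mu);
  std::vector<double> tau = as<std::vector<double>>(init_tau);
  for (int i = 0; i < nS; ++i) refresh_subj(S[i], th[i].data(), L, model_code);

  // proposal step sizes and adaptation counters
  std::vector<std::vector<double>> step_ind(nS, std::vector<double>(P));
  std::vector<double> step_mu(P), step_tau(P);
  for (int j = 0; j < P; ++j) {
    double s0 = (ptype[j] == 3) ? 0.1 : (ptype[j] == 1 ? 2.0 : 1.0);
    for (int i = 0; i < nS; ++i) step_ind[i][j] = s0;
    step_mu[j] = s0;
    step_tau[j] = (ptype[j] == 3) ? 0.05 : 0.5;
  }
  std::vector<std::vector<int>> acc_ind(nS, std::vector<int>(P, 0));
  std::vector<int> acc_mu(P, 0), acc_tau(P, 0);
  int win = 0;
  const int adapt_every = 100;

  const int n_keep = n_draw / thin;
  const int n_par = nS * P + 2 * P;
  NumericMatrix draws(n_keep, n_par);
  int keep_row = 0;

  std::vector<double> mu_new, u_new, x_new;
  long long prop_total = 0, acc_total = 0;

  RNGScope scope;
  const int n_iter = n_burn + n_draw;
  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();

    // ---- individual-level updates -------------------------------------
    for (int i = 0; i < nS; ++i) {
      Subj& Si = S[i];
      for (int j = 0; j < P; ++j) {
        ++prop_total;
        double cur = th[i][j];
        double prop = cur + step_ind[i][j] * norm_rand();
        if (prop < lower[j] || prop > upper[j]) continue;
        double dlp = ind_lp(prop, mu[j], tau[j], ptype[j]) -
                     ind_lp(cur, mu[j], tau[j], ptype[j]);
        int role = L.role[j];
        if (role == 3) { // noise SD: cached cosine sum suffices
          double k0 = kappa_deg(cur), k1 = kappa_deg(prop);
          double dll = (k1 - k0) * Si.C - Si.n * (log_i0(k1) - log_i0(k0));
          if (std::log(unif_rand()) < dll + dlp) {
            th[i][j] = prop;
            ++acc_ind[i][j]; ++acc_total;
          }
          continue;
        }
        int c = L.comp[j];
        const std::vector<double>& u_old = (c == 1) ? Si.u1 : Si.u2;
        const std::vector<double>& x_old = (c == 1) ? Si.x1 : Si.x2;
        double a_c = th[i][L.amp[c]];
        mu_new.resize(Si.n);
        bool have_u = false;
        if (role == 0) { // amplitude: rescale component
          double da = prop - cur;
          for (int t = 0; t < Si.n; ++t) mu_new[t] = Si.mu[t] + da * u_old[t];
        } else if (role == 1) { // width: recompute unit curve
          u_new.resize(Si.n);
          unit_dog(x_old, prop, u_new);
          for (int t = 0; t < Si.n; ++t)
            mu_new[t] = Si.mu[t] + a_c * (u_new[t] - u_old[t]);
          have_u = true;
        } else { // beta: recompute curve input, then unit curve
          x_new.resize(Si.n);
          for (int t = 0; t < Si.n; ++t)
            x_new[t] = wrap_s(Si.xs[t] + prop * Si.d[t]);
          u_new.resize(Si.n);
          unit_dog(x_new, th[i][L.wid[c]], u_new);
          for (int t = 0; t < Si.n; ++t)
            mu_new[t] = Si.mu[t] + a_c * (u_new[t] - u_old[t]);
          have_u = true;
        }
        double C_new = cos_sum(Si.y, mu_new);
        double kap = kappa_deg(th[i][L.sig]);
        double dll = kap * (C_new - Si.C);
        if (std::log(unif_rand()) < dll + dlp) {
          th[i][j] = prop;
          Si.mu.swap(mu_new);
          Si.C = C_new;
          if (have_u) {
            if (c == 1) Si.u1.swap(u_new); else Si.u2.swap(u_new);
          }
          if (role == 2) {
            if (c == 1) Si.x1.swap(x_new); else Si.x2.swap(x_new);
          }
          ++acc_ind[i][j]; ++acc_total;
        }
      }
    }

    // ---- population-level updates -------------------------------------
    for (int j = 0; j < P; ++j) {
      // mean
      ++prop_total;
      double cur = mu[j];
      double prop = cur + step_mu[j] * norm_rand();
      if (prop >= mu_lower[j] && prop <= mu_upper[j]) {
        double dlp = 0.0;
        for (int i = 0; i < nS; ++i)
          dlp += ind_lp(th[i][j], prop, tau[j], ptype[j]) -
                 ind_lp(th[i][j], cur, tau[j], ptype[j]);
        if (R_finite(musd[j]))
          dlp += R::dnorm(prop, mumean[j], musd[j], 1) -
                 R::dnorm(cur, mumean[j], musd[j], 1);
        if (std::log(unif_rand()) < dlp) {
          mu[j] = prop;
          ++acc_mu[j]; ++acc_total;
        }
      }
      // SD
      ++prop_total;
      double curt = tau[j];
      double propt = curt + step_tau[j] * norm_rand();
      if (propt > 0.0) {
        double dlp = 0.0;
        for (int i = 0; i < nS; ++i)
          dlp += ind_lp(th[i][j], mu[j], propt, ptype[j]) -
                 ind_lp(th[i][j], mu[j], curt, ptype[j]);
        dlp += (gshape[j] - 1.0) * (std::log(propt) - std::log(curt)) -
               grate[j] * (propt - curt);
        if (std::log(unif_rand()) < dlp) {
          tau[j] = propt;
          ++acc_tau[j]; ++acc_total;
        }
      }
    }

    // ---- step-size adaptation during burn-in --------------------------
    ++win;
    if (iter < n_burn && win == adapt_every) {
      auto tune = [&](double& s, int& a) {
        double rate = (double)a / adapt_every;
        if (rate > 0.45) s *= 1.4;
        else if (rate < 0.20) s *= 0.7;
        a = 0;
      };
      for (int i = 0; i < nS; ++i)
        for (int j = 0; j < P; ++j) tune(step_ind[i][j], acc_ind[i][j]);
      for (int j = 0; j < P; ++j) { tune(step_mu[j], acc_mu[j]); tune(step_tau[j], acc_tau[j]); }
      win = 0;
    }
    if (win >= adapt_every) win = 0;

    // ---- record --------------------------------------------------------
    if (iter >= n_burn && (iter - n_burn) % thin == thin - 1 &&
        keep_row < n_keep) {
      int col = 0;
      for (int i = 0; i < nS; ++i)
        for (int j = 0; j < P; ++j) draws(keep_row, col++) = th[i][j];
      for (int j = 0; j < P; ++j) draws(keep_row, col++) = mu[j];
      for (int j = 0; j < P; ++j) draws(keep_row, col++) = tau[j];
      ++keep_row;
    }
  }

  double acc_rate = prop_total > 0 ? (double)acc_total / prop_total : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate);
}

// Full log joint density (likelihood + individual priors + population
// priors) at a given state; used to validate acceptance ratios against an
// independent re-implementation.
// [[Rcpp::export]]
double hb_log_posterior_cpp(List subj_data, int model_code, List meta,
                            NumericMatrix ind, NumericVector mu,
                            NumericVector tau) {
  const Layout L = make_layout(model_code);
  const int P = L.P;
  const int nS = subj_data.size();
  IntegerVector ptype = meta["ptype"];
  NumericVector gshape = meta["gshape"], grate = meta["grate"];
  NumericVector mumean = meta["mumean"], musd = meta["musd"];
  NumericVector lower = meta["lower"], upper = meta["upper"];
  NumericVector mu_lower = meta["mu_lower"], mu_upper = meta["mu_upper"];

  double lp = 0.0;
  for (int j = 0; j < P; ++j) {
    if (mu[j] < mu_lower[j] || mu[j] > mu_upper[j]) return R_NegInf;
    if (tau[j] <= 0.0) return R_NegInf;
    if (R_finite(musd[j])) lp += R::dnorm(mu[j], mumean[j], musd[j], 1);
    lp += (gshape[j] - 1.0) * std::log(tau[j]) - grate[j] * tau[j];
  }
  for (int i = 0; i < nS; ++i) {
    List di = subj_data[i];
    Subj Si;
    Si.y = as<std::vector<double>>(di["y"]);
    Si.xs = as<std::vector<double>>(di["xs"]);
    Si.xr = as<std::vector<double>>(di["xr"]);
    Si.d = as<std::vector<double>>(di["d"]);
    Si.n = Si.y.size();
    std::vector<double> thi(P);
    for (int j = 0; j < P; ++j) {
      thi[j] = ind(i, j);
      if (thi[j] < lower[j] || thi[j] > upper[j]) return R_NegInf;
      lp += ind_lp(thi[j], mu[j], tau[j], ptype[j]);
    }
    refresh_subj(Si, thi.data(), L, model_code);
    double kap = kappa_deg(thi[L.sig]);
    lp += kap * Si.C -
          Si.n * (std::log(2.0 * M_PI) + log_i0(kap) - std::log(DEG));
  }
  return lp;
}
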