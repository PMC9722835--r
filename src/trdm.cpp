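// Likelihood core for the timed racing diffusion model (TRDM) joint model.
// All first-passage terms are shifted-Wald (inverse-Gaussian) forms for a
// single-boundary diffusion; survivor functions are evaluated in log space
// to avoid overflow of exp(2*alpha*gamma/sigma^2).

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_BIG = -1e300;  // -Inf-representable sentinel

// log(1 - exp(x)) for x <= 0
static inline double lg1mexp(double x) {
  if (x >= 0.0) return R_NegInf;
  if (x > -M_LN2) return std::log(-std::expm1(x));
  return std::log1p(-std::exp(x));
}

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log density of the Wald first-passage time through threshold alpha for a
// diffusion with drift gamma >= 0 and diffusion SD sigma > 0
static inline double wald_lpdf(double t, double gamma, double sigma, double alpha) {
  if (t <= 0.0) return R_NegInf;
  double s2t = sigma * sigma * t;
  double dev = alpha - gamma * t;
  return std::log(alpha) - std::log(sigma)
    - 0.5 * std::log(2.0 * M_PI * t * t * t)
    - dev * dev / (2.0 * s2t);
}

// log survivor: log P(first passage > t)
static inline double wald_lsurv(double t, double gamma, double sigma, double alpha) {
  if (t <= 0.0) return 0.0;
  double srt = sigma * std::sqrt(t);
  double la = R::pnorm((alpha - gamma * t) / srt, 0.0, 1.0, 1, 1);
  double lb = 2.0 * alpha * gamma / (sigma * sigma)
    + R::pnorm(-(gamma * t + alpha) / srt, 0.0, 1.0, 1, 1);
  // survivor = exp(la) - exp(lb), with lb < la strictly for t > 0
  double d = lb - la;
  if (d >= 0.0) return R_NegInf;  // numerically degenerate: passage certain
  return la + lg1mexp(d);
}

struct TrdmPars {
  double ggg, ggn, gnn, gT, sE, sT, tauE, q;
  bool valid() const {
    return ggg >= 0 && ggn >= 0 && gnn >= 0 && gT >= 0 &&
      sE > 0 && sT > 0 && tauE >= 0 && q >= 0 && q <= 1;
  }
};

// log defective density of a go response at time t (from stimulus onset).
// stim_go selects the go-stimulus rates, else nogo-stimulus rates.
// Threshold alpha = 1 for all three accumulators; timing onset tau_T = 0.
static double go_ldens(double t, const TrdmPars &p, bool stim_go) {
  if (t <= 0.0) return R_NegInf;
  double g_go = stim_go ? p.ggg : p.ggn;
  double g_ng = stim_go ? 0.0 : p.gnn;  // gamma_nogo|go fixed at 0
  double te = t - p.tauE;
  // evidence-accumulator path: go accumulator wins the race
  double logA = R_NegInf;
  if (te > 0.0) {
    logA = wald_lpdf(te, g_go, p.sE, 1.0)
      + wald_lsurv(te, g_ng, p.sE, 1.0)
      + wald_lsurv(t, p.gT, p.sT, 1.0);
  }
  // timer path: timing accumulator wins and emits a go guess
  double logB = R_NegInf;
  if (p.q > 0.0) {
    logB = std::log(p.q) + wald_lpdf(t, p.gT, p.sT, 1.0);
    if (te > 0.0) {
      logB += wald_lsurv(te, g_go, p.sE, 1.0) + wald_lsurv(te, g_ng, p.sE, 1.0);
    }
  }
  return logsumexp2(logA, logB);
}

// 10-point Gauss-Legendre nodes/weights on [-1, 1]
static const double GLX[10] = {
  -0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
  -0.4333953941292472, -0.1488743389816312,  0.1488743389816312,
   0.4333953941292472,  0.6794095682990244,  0.8650633666889845,
   0.9739065285171717};
static const double GLW[10] = {
  0.0666713443086881, 0.1494513491505806, 0.2190863625159820,
  0.2692667193099963, 0.2955242247147529, 0.2955242247147529,
  0.2692667193099963, 0.2190863625159820, 0.1494513491505806,
  0.0666713443086881};

// Probability that the response is withheld: the nogo accumulator wins the
// race, plus (for guess_go_prob < 1) the timer winning with a nogo guess.
// Integration on u = log(t): heavy right tails at zero drift are handled by
// a wide fixed range with composite Gauss-Legendre panels.
// time by which an accumulator with drift gamma has all but ~1e-13 of its
// passage mass (zero drift: heavy tail, no useful bound)
static double upper_bound_t(double gamma, double sigma) {
  if (gamma <= 1e-8) return 1e9;
  double s7 = 7.5 * sigma;
  double rt = (s7 + std::sqrt(s7 * s7 + 4.0 * gamma)) / (2.0 * gamma);
  return rt * rt;
}

static double withheld_prob(const TrdmPars &p, bool stim_go) {
  double g_go = stim_go ? p.ggg : p.ggn;
  double g_ng = stim_go ? 0.0 : p.gnn;
  // integrand is negligible outside [t_lo, t_hi]: below t_lo the nogo pdf's
  // essential singularity kills it, above t_hi some racer has surely finished
  double t_hi = std::min(upper_bound_t(g_ng, p.sE),
                         std::min(upper_bound_t(g_go, p.sE),
                                  upper_bound_t(p.gT, p.sT))) + p.tauE;
  double t_lo = std::min(1.0 / (1200.0 * p.sE * p.sE),
                         1.0 / (1200.0 * p.sT * p.sT));
  t_lo = std::max(1e-7, std::min(t_lo, t_hi * 1e-3));
  const double lo = std::log(t_lo), hi = std::log(std::max(t_hi, t_lo * 10));
  // panel width tracks the sharpest first-passage peak (CV = sigma/sqrt(
  // gamma * alpha) on the log-time axis) so narrow timer densities are
  // resolved
  double cv = 0.75;
  if (g_ng > 1e-8) cv = std::min(cv, p.sE / std::sqrt(g_ng));
  if (g_go > 1e-8) cv = std::min(cv, p.sE / std::sqrt(g_go));
  if (p.gT > 1e-8) cv = std::min(cv, p.sT / std::sqrt(p.gT));
  double width = std::max(0.02, std::min(0.75, cv));
  int panels = (int)std::ceil((hi - lo) / width);
  if (panels < 8) panels = 8;
  if (panels > 300) panels = 300;
  double h = (hi - lo) / panels, total = 0.0;
  for (int pan = 0; pan < panels; ++pan) {
    double a = lo + pan * h, c = a + 0.5 * h;
    double acc = 0.0;
    for (int k = 0; k < 10; ++k) {
      double u = c + 0.5 * h * GLX[k];
      double t = std::exp(u);
      // nogo accumulator crosses at evidence time t (clock time t + tauE)
      double lf = wald_lpdf(t, g_ng, p.sE, 1.0)
        + wald_lsurv(t, g_go, p.sE, 1.0)
        + wald_lsurv(t + p.tauE, p.gT, p.sT, 1.0)
        + u;  // Jacobian dt = t du
      double val = (lf > -700.0) ? std::exp(lf) : 0.0;
      if (p.q < 1.0) {
        double te = t - p.tauE;
        double lg = std::log1p(-p.q) + wald_lpdf(t, p.gT, p.sT, 1.0) + u;
        if (te > 0.0) {
          lg += wald_lsurv(te, g_go, p.sE, 1.0) + wald_lsurv(te, g_ng, p.sE, 1.0);
        }
        // here t is clock time for the timer path
        if (lg > -700.0) val += std::exp(lg);
      }
      acc += GLW[k] * val;
    }
    total += 0.5 * h * acc;
  }
  if (total < 0.0) total = 0.0;
  if (total > 1.0) total = 1.0;
  return total;
}

// log(pnorm(b) - pnorm(a)) for a < b, stable in both tails
static double lnorm_interval(double a, double b) {
  if (!(a < b)) return R_NegInf;
  if (a == R_NegInf && b == R_PosInf) return 0.0;
  if (a == R_NegInf) return R::pnorm(b, 0.0, 1.0, 1, 1);
  if (b == R_PosInf) return R::pnorm(a, 0.0, 1.0, 0, 1);
  if (a + b > 0.0) {  // reflect into the lower tail for accuracy
    double tmp = a; a = -b; b = -tmp;
  }
  double lb = R::pnorm(b, 0.0, 1.0, 1, 1);
  double la = R::pnorm(a, 0.0, 1.0, 1, 1);
  return lb + lg1mexp(la - lb);
}

// log probabilities of the four ordinal probe responses given latent mean
// psi, latent SD eps and the three cut points
static void probe_lp4(double psi, double eps, const double *lam, double *out) {
  double c0 = R_NegInf;
  for (int k = 0; k < 4; ++k) {
    double c1 = (k < 3) ? (lam[k] - psi) / eps : R_PosInf;
    out[k] = lnorm_interval(c0, c1);
    c0 = c1;
  }
}

static TrdmPars row_pars(const NumericMatrix &pars, int i, double q) {
  TrdmPars p;
  p.ggg = pars(i, 0); p.ggn = pars(i, 1); p.gnn = pars(i, 2); p.gT = pars(i, 3);
  p.sE = pars(i, 4); p.sT = pars(i, 5); p.tauE = pars(i, 6); p.q = q;
  return p;
}

// Per-participant joint log-likelihood, split into the TRDM stream (column 1)
// and the thought-probe stream (column 2).
//
// data is a list packed once per dataset:
//   rt_go, off_go : concatenated go-response RTs on go stimuli + 0-based
//                   offsets (length n_participants + 1)
//   rt_ng, off_ng : same for go responses on nogo stimuli (commission errors)
//   wh_go, wh_ng  : per-participant counts of withheld go / nogo trials
//   probe_counts  : n x 4 matrix of probe-response counts
// pars: n x 7 matrix, columns (gamma_go_go, gamma_go_nogo, gamma_nogo_nogo,
//   gamma_timer, sigma_e, sigma_t, tau_e) on the natural scale.
// link_col: 0-based column of the linked parameter omega; psi = omega * beta.
// [[Rcpp::export]]
NumericMatrix cpp_joint_logliks(List data, NumericMatrix pars, double beta,
                                NumericVector lambda, int link_col,
                                double q, double eps) {
  NumericVector rt_go = data["rt_go"], rt_ng = data["rt_ng"];
  IntegerVector off_go = data["off_go"], off_ng = data["off_ng"];
  IntegerVector wh_go = data["wh_go"], wh_ng = data["wh_ng"];
  IntegerMatrix pc = data["probe_counts"];
  int n = pars.nrow();
  NumericMatrix out(n, 2);
  double lam[3] = {lambda[0], lambda[1], lambda[2]};
  for (int i = 0; i < n; ++i) {
    TrdmPars p = row_pars(pars, i, q);
    if (!p.valid() || !(lam[0] < lam[1] && lam[1] < lam[2]) || eps <= 0) {
      out(i, 0) = NEG_BIG; out(i, 1) = NEG_BIG;
      continue;
    }
    double ll = 0.0;
    for (int j = off_go[i]; j < off_go[i + 1]; ++j) {
      double l = go_ldens(rt_go[j], p, true);
      ll += (l == R_NegInf) ? NEG_BIG : l;
    }
    for (int j = off_ng[i]; j < off_ng[i + 1]; ++j) {
      double l = go_ldens(rt_ng[j], p, false);
      ll += (l == R_NegInf) ? NEG_BIG : l;
    }
    if (wh_go[i] > 0) {
      double pw = withheld_prob(p, true);
      ll += (pw > 0.0) ? wh_go[i] * std::log(pw) : NEG_BIG;
    }
    if (wh_ng[i] > 0) {
      double pw = withheld_prob(p, false);
      ll += (pw > 0.0) ? wh_ng[i] * std::log(pw) : NEG_BIG;
    }
    if (ll < NEG_BIG) ll = NEG_BIG;
    out(i, 0) = ll;

    double psi = pars(i, link_col) * beta;
    double lp[4];
    probe_lp4(psi, eps, lam, lp);
    double lpr = 0.0;
    for (int k = 0; k < 4; ++k) {
      if (pc(i, k) > 0) {
        lpr += (lp[k] == R_NegInf) ? NEG_BIG : pc(i, k) * lp[k];
      }
    }
    if (lpr < NEG_BIG) lpr = NEG_BIG;
    out(i, 1) = lpr;
  }
  return out;
}

// Thought-probe stream only (used by the group-level beta/cut-point update)
// [[Rcpp::export]]
NumericVector cpp_probe_logliks(IntegerMatrix probe_counts, NumericVector omega,
                                double beta, NumericVector lambda, double eps) {
  int n = probe_counts.nrow();
  NumericVector out(n);
  double lam[3] = {lambda[0], lambda[1], lambda[2]};
  for (int i = 0; i < n; ++i) {
    if (!(lam[0] < lam[1] && lam[1] < lam[2]) || eps <= 0) {
      out[i] = NEG_BIG;
      continue;
    }
    double lp[4];
    probe_lp4(omega[i] * beta, eps, lam, lp);
    double lpr = 0.0;
    for (int k = 0; k < 4; ++k) {
      if (probe_counts(i, k) > 0) {
        lpr += (lp[k] == R_NegInf) ? NEG_BIG : probe_counts(i, k) * lp[k];
      }
    }
    out[i] = (lpr < NEG_BIG) ? NEG_BIG : lpr;
  }
  return out;
}

// vectorized go-response defective density (clock time t), C++ path
// [[Rcpp::export]]
NumericVector cpp_go_density(NumericVector t, NumericVector pars, bool stim_go,
                             double q) {
  TrdmPars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5], pars[6], q};
  int m = t.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double l = go_ldens(t[j], p, stim_go);
    out[j] = (l == R_NegInf) ? 0.0 : std::exp(l);
  }
  return out;
}

// withheld-response probability, C++ quadrature path
// [[Rcpp::export]]
double cpp_withheld_prob(NumericVector pars, bool stim_go, double q) {
  TrdmPars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5], pars[6], q};
  return withheld_prob(p, stim_go);
}

// one Wald first-passage draw; zero drift is the Levy (driftless) case
static double rwald1(double gamma, double sigma, double alpha) {
  if (gamma <= 0.0) {
    double z;
    do { z = norm_rand(); } while (z == 0.0);
    double r = alpha / (sigma * z);
    return r * r;
  }
  double mu = alpha / gamma, lam = (alpha * alpha) / (sigma * sigma);
  double nu = norm_rand(), y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lam)
    - mu / (2.0 * lam) * std::sqrt(4.0 * mu * lam * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
NumericVector cpp_rwald(int n, double gamma, double sigma, double alpha) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rwald1(gamma, sigma, alpha);
  return out;
}

// Simulate n TRDM trials of one stimulus class. Returns response (1 = go,
// 0 = withheld) and rt (NA for withheld). Exact ties between accumulators
// (measure zero) are broken uniformly at random.
// [[Rcpp::export]]
List cpp_simulate_trials(int n, NumericVector pars, bool stim_go, double q) {
  RNGScope scope;
  TrdmPars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5], pars[6], q};
  double g_go = stim_go ? p.ggg : p.ggn;
  double g_ng = stim_go ? 0.0 : p.gnn;
  IntegerVector resp(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    double t_go = p.tauE + rwald1(g_go, p.sE, 1.0);
    double t_ng = p.tauE + rwald1(g_ng, p.sE, 1.0);
    double t_tm = rwald1(p.gT, p.sT, 1.0);
    double m = std::min(t_go, std::min(t_ng, t_tm));
    int winner;  // 0 go-evidence, 1 nogo-evidence, 2 timer
    if (t_go == m && t_ng == m && t_tm == m) {
      winner = (int)std::floor(unif_rand() * 3.0);
    } else if (t_go == m && t_ng == m) {
      winner = (unif_rand() < 0.5) ? 0 : 1;
    } else if (t_go == m && t_tm == m) {
      winner = (unif_rand() < 0.5) ? 0 : 2;
    } else if (t_ng == m && t_tm == m) {
      winner = (unif_rand() < 0.5) ? 1 : 2;
    } else if (t_go == m) {
      winner = 0;
    } else if (t_ng == m) {
      winner = 1;
    } else {
      winner = 2;
    }
    if (winner == 0) {
      resp[i] = 1; rt[i] = t_go;
    } else if (winner == 1) {
      resp[i] = 0; rt[i] = NA_REAL;
    } else {
      if (unif_rand() <= q) {
        resp[i] = 1; rt[i] = t_tm;
      } else {
        resp[i] = 0; rt[i] = NA_REAL;
      }
    }
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}
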