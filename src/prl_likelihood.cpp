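// Hot loops for the reversal-learning model family: trial-wise likelihoods,
// MAP objective/derivatives in unconstrained space, and agent simulation.
// Parameter layout (constrained): EWA family  {phi, rho, beta, alpha_f},
//                                 hybrid family {eta, kappa, beta, alpha_f};
// alpha_f = 0 recovers the no-forgetting variants exactly.
#include <Rcpp.h>
using namespace Rcpp;

static const int MODEL_EWA = 1;
static const int MODEL_HYBRID = 2;

static inline double sigmoid_c(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// beta is exp-transformed; clamp the exponent so the objective stays finite
// far out in the tails where the prior dominates anyway.
static inline double exp_clamped(double x) {
  return std::exp(x > 25.0 ? 25.0 : x);
}

// log softmax probability of `choice` (0-based) given values and beta
static double log_softmax_choice(const std::vector<double>& V, double beta,
                                 int choice) {
  int K = (int)V.size();
  double m = -INFINITY;
  for (int j = 0; j < K; ++j) m = std::max(m, beta * V[j]);
  double s = 0.0;
  for (int j = 0; j < K; ++j) s += std::exp(beta * V[j] - m);
  return beta * V[choice] - m - std::log(s);
}

// One session's negative log likelihood. choices are 1-based role indices.
static double nll_core(const IntegerVector& choices,
                       const NumericVector& outcomes, int n_options,
                       int model, double p1, double p2, double beta,
                       double alpha_f) {
  int T = choices.size();
  std::vector<double> V(n_options, 0.0);
  std::vector<double> n(n_options, 1.0);  // EWA experience weights
  std::vector<double> a(n_options, 1.0);  // hybrid associability
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    int c = choices[t] - 1;
    nll -= log_softmax_choice(V, beta, c);
    double lam = outcomes[t];
    if (model == MODEL_EWA) {
      double phi = p1, rho = p2;
      double n_new = n[c] * rho + 1.0;
      V[c] = (V[c] * phi * n[c] + lam) / n_new;
      n[c] = n_new;
    } else {
      double eta = p1, kappa = p2;
      double delta = lam - V[c];
      V[c] += eta * a[c] * delta;
      a[c] = (1.0 - kappa) * a[c] + kappa * std::fabs(delta);
    }
    if (alpha_f > 0.0) {
      for (int j = 0; j < n_options; ++j)
        if (j != c) V[j] *= (1.0 - alpha_f);
    }
  }
  return nll;
}

// [[Rcpp::export]]
double nll_ewa_cpp(IntegerVector choices, NumericVector outcomes,
                   double phi, double rho, double beta, double alpha_f,
                   int n_options = 3) {
  return nll_core(choices, outcomes, n_options, MODEL_EWA, phi, rho, beta,
                  alpha_f);
}

// [[Rcpp::export]]
double nll_hybrid_cpp(IntegerVector choices, NumericVector outcomes,
                      double eta, double kappa, double beta, double alpha_f,
                      int n_options = 3) {
  return nll_core(choices, outcomes, n_options, MODEL_HYBRID, eta, kappa, beta,
                  alpha_f);
}

// Map unconstrained x to the 4-slot constrained vector for one session.
// base_n is 3 (no forgetting) or 4; split_index (0-based, -1 = none) names the
// base slot replaced by x[base_n] on drug (MPH) sessions.
static void constrain_params(const NumericVector& x, int base_n,
                             int split_index, int drug, double out[4]) {
  out[3] = 0.0;
  for (int i = 0; i < base_n; ++i) {
    double xi = x[i];
    if (split_index == i && drug == 1) xi = x[base_n];
    out[i] = (i == 2) ? exp_clamped(xi) : sigmoid_c(xi);
  }
}

// MAP objective: summed session NLLs plus Gaussian negative log prior on the
// unconstrained scale.
// [[Rcpp::export]]
double map_objective_cpp(NumericVector x, List choices_list,
                         List outcomes_list, IntegerVector drug, int model,
                         int base_n, int split_index,
                         NumericVector prior_mean, NumericVector prior_var,
                         int n_options = 3) {
  double obj = 0.0;
  int S = choices_list.size();
  double p[4];
  for (int s = 0; s < S; ++s) {
    IntegerVector ch = choices_list[s];
    NumericVector oc = outcomes_list[s];
    constrain_params(x, base_n, split_index, drug[s], p);
    obj += nll_core(ch, oc, n_options, model, p[0], p[1], p[2], p[3]);
  }
  int d = x.size();
  for (int i = 0; i < d; ++i) {
    double z = x[i] - prior_mean[i];
    obj += 0.5 * (z * z / prior_var[i] + std::log(2.0 * M_PI * prior_var[i]));
  }
  return obj;
}

// [[Rcpp::export]]
NumericVector map_gradient_cpp(NumericVector x, List choices_list,
                               List outcomes_list, IntegerVector drug,
                               int model, int base_n, int split_index,
                               NumericVector prior_mean,
                               NumericVector prior_var, int n_options = 3,
                               double h = 1e-5) {
  int d = x.size();
  NumericVector g(d), xp = clone(x);
  for (int i = 0; i < d; ++i) {
    double hi = h * (1.0 + std::fabs(x[i]));
    xp[i] = x[i] + hi;
    double fp = map_objective_cpp(xp, choices_list, outcomes_list, drug, model,
                                  base_n, split_index, prior_mean, prior_var,
                                  n_options);
    xp[i] = x[i] - hi;
    double fm = map_objective_cpp(xp, choices_list, outcomes_list, drug, model,
                                  base_n, split_index, prior_mean, prior_var,
                                  n_options);
    xp[i] = x[i];
    g[i] = (fp - fm) / (2.0 * hi);
  }
  return g;
}

// Simulate one agent in role space: the first choice is role 1 (R-P) by the
// task's first-choice role-assignment rule; later choices are softmax draws.
// schedule is T x K with entries in {-1, +1}.
// [[Rcpp::export]]
List simulate_session_cpp(NumericMatrix schedule, int model,
                          NumericVector params) {
  int T = schedule.nrow(), K = schedule.ncol();
  double p1 = params[0], p2 = params[1], beta = params[2],
         alpha_f = params[3];
  std::vector<double> V(K, 0.0), n(K, 1.0), a(K, 1.0);
  IntegerVector choices(T);
  NumericVector outcomes(T);
  for (int t = 0; t < T; ++t) {
    int c = 0;
    if (t > 0) {
      double m = -INFINITY;
      for (int j = 0; j < K; ++j) m = std::max(m, beta * V[j]);
      double s = 0.0;
      std::vector<double> w(K);
      for (int j = 0; j < K; ++j) {
        w[j] = std::exp(beta * V[j] - m);
        s += w[j];
      }
      double u = R::unif_rand() * s, cum = 0.0;
      c = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += w[j];
        if (u <= cum) { c = j; break; }
      }
    }
    double lam = schedule(t, c);
    choices[t] = c + 1;
    outcomes[t] = lam;
    if (model == MODEL_EWA) {
      double n_new = n[c] * p2 + 1.0;
      V[c] = (V[c] * p1 * n[c] + lam) / n_new;
      n[c] = n_new;
    } else {
      double delta = lam - V[c];
      V[c] += p1 * a[c] * delta;
      a[c] = (1.0 - p2) * a[c] + p2 * std::fabs(delta);
    }
    if (alpha_f > 0.0) {
      for (int j = 0; j < K; ++j)
        if (j != c) V[j] *= (1.0 - alpha_f);
    }
  }
  return List::create(_["choices"] = choices, _["outcomes"] = outcomes);
}

// Choice-proportion matrix (T x K) over n_agents independent simulations.
// [[Rcpp::export]]
NumericMatrix simulate_agents_cpp(NumericMatrix schedule, int model,
                                  NumericVector params, int n_agents) {
  int T = schedule.nrow(), K = schedule.ncol();
  NumericMatrix counts(T, K);
  for (int g = 0; g < n_agents; ++g) {
    List sim = simulate_session_cpp(schedule, model, params);
    IntegerVector ch = sim["choices"];
    for (int t = 0; t < T; ++t) counts(t, ch[t] - 1) += 1.0;
  }
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < K; ++j) counts(t, j) /= n_agents;
  return counts;
}
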