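#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial runner for the similarity-based generalization model.
//
// Orientations are indexed into `grid` (the unique orientations a subject can
// encounter); E and I hold the excitatory / inhibitory association strength
// at each grid orientation. Per trial t with presented orientation k:
//   V_t   = sum_j E_j * eS(j,k) - I_j * iS(j,k)
//   P(+)  = 1 / (1 + exp(-beta * (V_t - a)))
//   delta = R_t - V_t
//   delta > 0: E_k += alpha * delta;  delta < 0: I_k -= alpha * delta
// with alpha = alpha_train or alpha_test by phase. Kernels:
//   gaussian:    S(j,k) = exp(-(xj-xk)^2 / (2 s^2))
//   exponential: S(j,k) = exp(-|xj-xk| / (2 s^2))
// Log-probabilities are accumulated in numerically stable form so extreme
// slopes do not produce -Inf through catastrophic rounding of P(+).
//
// [[Rcpp::export]]
List run_trials_cpp(IntegerVector ori, NumericVector grid, NumericVector R,
                    IntegerVector is_test, IntegerVector resp_plus,
                    IntegerVector lik_include, IntegerVector do_update,
                    double s_i, double s_e, double beta, double offset_a,
                    double alpha_train, double alpha_test, int kernel_exp,
                    NumericVector E0, NumericVector I0,
                    bool generative, NumericVector u) {
  const int n = ori.size();
  const int G = grid.size();
  NumericMatrix eS(G, G), iS(G, G);
  for (int j = 0; j < G; ++j) {
    for (int k = 0; k < G; ++k) {
      double d = std::abs(grid[j] - grid[k]);
      if (kernel_exp == 0) {
        eS(j, k) = std::exp(-d * d / (2.0 * s_e * s_e));
        iS(j, k) = std::exp(-d * d / (2.0 * s_i * s_i));
      } else {
        eS(j, k) = std::exp(-d / (2.0 * s_e * s_e));
        iS(j, k) = std::exp(-d / (2.0 * s_i * s_i));
      }
    }
  }
  NumericVector E = clone(E0), I = clone(I0);
  NumericVector V(n), p(n), delta(n), ll(n, NA_REAL);
  IntegerVector resp_out(n);
  double total = 0.0;
  for (int t = 0; t < n; ++t) {
    const int k = ori[t];
    double v = 0.0;
    for (int j = 0; j < G; ++j) v += E[j] * eS(j, k) - I[j] * iS(j, k);
    const double z = beta * (v - offset_a);
    const double pt = 1.0 / (1.0 + std::exp(-z));
    int rp;
    if (generative) {
      rp = (u[t] < pt) ? 1 : 0;
    } else {
      rp = resp_plus[t];  // may be NA when the trial is excluded
    }
    resp_out[t] = rp;
    if (lik_include[t] == 1) {
      // log P(+) = -log1p(exp(-z)); log P(not +) = -z - log1p(exp(-z))
      double lse = (z > 0) ? std::log1p(std::exp(-z))
                           : -z + std::log1p(std::exp(z));
      double term = (rp == 1) ? -lse : -z - lse;
      ll[t] = term;
      total += term;
    }
    const double d = R[t] - v;
    if (do_update[t] == 1) {
      const double alpha = (is_test[t] == 1) ? alpha_test : alpha_train;
      if (d > 0) E[k] += alpha * d;
      else if (d < 0) I[k] -= alpha * d;
    }
    V[t] = v;
    p[t] = pt;
    delta[t] = d;
  }
  return List::create(_["V"] = V, _["p_plus"] = p, _["delta"] = delta,
                      _["loglik_term"] = ll, _["resp_plus"] = resp_out,
                      _["E"] = E, _["I"] = I, _["total_loglik"] = total);
}

// Pooled negative log-likelihood over a cohort: subjects' trials are
// concatenated (offsets in `subj_start`, length n_subjects + 1) and indexed
// into one shared orientation grid; associative state resets at each
// subject boundary. Kernel matrices are computed once per call.
//
// [[Rcpp::export]]
double pooled_nll_cpp(IntegerVector ori, NumericVector grid, NumericVector R,
                      IntegerVector is_test, IntegerVector resp_plus,
                      IntegerVector lik_include, IntegerVector do_update,
                      IntegerVector subj_start,
                      double s_i, double s_e, double beta, double offset_a,
                      double alpha_train, double alpha_test, int kernel_exp) {
  const int G = grid.size();
  NumericMatrix eS(G, G), iS(G, G);
  for (int j = 0; j < G; ++j) {
    for (int k = 0; k < G; ++k) {
      double d = std::abs(grid[j] - grid[k]);
      if (kernel_exp == 0) {
        eS(j, k) = std::exp(-d * d / (2.0 * s_e * s_e));
        iS(j, k) = std::exp(-d * d / (2.0 * s_i * s_i));
      } else {
        eS(j, k) = std::exp(-d / (2.0 * s_e * s_e));
        iS(j, k) = std::exp(-d / (2.0 * s_i * s_i));
      }
    }
  }
  std::vector<double> E(G), I(G);
  double total = 0.0;
  const int n_subj = subj_start.size() - 1;
  for (int s = 0; s < n_subj; ++s) {
    std::fill(E.begin(), E.end(), 0.0);
    std::fill(I.begin(), I.end(), 0.0);
    for (int t = subj_start[s]; t < subj_start[s + 1]; ++t) {
      const int k = ori[t];
      double v = 0.0;
      for (int j = 0; j < G; ++j) v += E[j] * eS(j, k) - I[j] * iS(j, k);
      if (lik_include[t] == 1) {
        const double z = beta * (v - offset_a);
        double lse = (z > 0) ? std::log1p(std::exp(-z))
                             : -z + std::log1p(std::exp(z));
        total += (resp_plus[t] == 1) ? -lse : -z - lse;
      }
      const double d = R[t] - v;
      if (do_update[t] == 1) {
        const double alpha = (is_test[t] == 1) ? alpha_test : alpha_train;
        if (d > 0) E[k] += alpha * d;
        else if (d < 0) I[k] -= alpha * d;
      }
    }
  }
  return -total;
}
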