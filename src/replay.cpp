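#include <Rcpp.h>
using namespace Rcpp;

// Model codes (kept in sync with MODEL_NAMES on the R side):
// 1 ABSOLUTE, 2 RELATIVE, 3 HYBRID, 4 UTILITY, 5 POLICY.

static inline double enc_rel(double r, double v) {
  if (v == 0.0) return 0.0;
  double av = std::fabs(v);
  double out = r / av;
  double corr = -v / av;
  if (corr > 0.0) out += corr;
  return out;
}

static inline double encode(int model, double r, double v, double omega, double upsilon) {
  switch (model) {
  case 2: return enc_rel(r, v);
  case 3: return omega * enc_rel(r, v) + (1.0 - omega) * r;
  case 4: return (std::fabs(std::fabs(r) - 1.0) < 1e-9) ? upsilon * r : r;
  default: return r; // ABSOLUTE and POLICY
  }
}

static inline double choice_p(int model, double q_c, double q_o, double beta) {
  double z;
  if (model == 5) {
    double den = q_c + q_o;
    z = (std::fabs(den) < 1e-12) ? 0.0 : ((q_o - q_c) / den) / beta;
  } else {
    z = (q_o - q_c) / beta;
  }
  if (z > 500.0) z = 500.0;
  if (z < -500.0) z = -500.0;
  return 1.0 / (1.0 + std::exp(z));
}

static inline double floored_log(double p) {
  return std::log(p < 1e-15 ? 1e-15 : p);
}

// Replay a subject's fixed choice/outcome history under one model and
// return the learning- and transfer-phase negative log-likelihoods plus the
// post-learning option values. Option and context indices are 1-based.
// [[Rcpp::export]]
List replay_nll_cpp(int model, double beta, double alpha_f, double alpha_c,
                    double omega, double upsilon,
                    IntegerVector ctx, IntegerVector opt_c, IntegerVector opt_u,
                    NumericVector out_c, NumericVector out_u, LogicalVector shown_u,
                    int n_options, int n_contexts,
                    IntegerVector t_opt_c, IntegerVector t_opt_u) {
  int n = ctx.size();
  std::vector<double> Q(n_options, 0.0), V(n_contexts, 0.0);
  double nll_learn = 0.0, nll_trans = 0.0;
  NumericVector logp_learn(n), logp_trans(t_opt_c.size());

  for (int i = 0; i < n; ++i) {
    int c = opt_c[i] - 1, u = opt_u[i] - 1, s = ctx[i] - 1;
    double qc = Q[c], qu = Q[u];
    double p = choice_p(model, qc, qu, beta);
    logp_learn[i] = floored_log(p);
    nll_learn -= logp_learn[i];

    // state value: first non-zero observed outcome, chosen before unchosen
    if (V[s] == 0.0 && out_c[i] != 0.0) V[s] = out_c[i];
    if (V[s] == 0.0 && shown_u[i] && out_u[i] != 0.0) V[s] = out_u[i];

    double rc = encode(model, out_c[i], V[s], omega, upsilon);
    Q[c] = qc + alpha_f * (rc - qc);
    if (shown_u[i]) {
      double ru = encode(model, out_u[i], V[s], omega, upsilon);
      Q[u] = qu + alpha_c * (ru - qu);
    }
  }

  for (int i = 0; i < t_opt_c.size(); ++i) {
    double p = choice_p(model, Q[t_opt_c[i] - 1], Q[t_opt_u[i] - 1], beta);
    logp_trans[i] = floored_log(p);
    nll_trans -= logp_trans[i];
  }

  return List::create(_["nll_learning"] = nll_learn,
                      _["nll_transfer"] = nll_trans,
                      _["logp_learning"] = logp_learn,
                      _["logp_transfer"] = logp_trans,
                      _["Q"] = NumericVector(Q.begin(), Q.end()),
                      _["V"] = NumericVector(V.begin(), V.end()));
}
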