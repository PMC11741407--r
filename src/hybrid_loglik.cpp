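#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood of the hybrid model-based/model-free agent.
// Missing trials are encoded -1; they contribute 0 and clear the
// perseveration memory. Mirrors the R-level agent_update()/
// stage1_choice_probs() recursions exactly.
// [[Rcpp::export]]
double hybrid_loglik_cpp(IntegerVector s1, IntegerVector s2s,
                         IntegerVector s2c, IntegerVector rew,
                         double alpha1, double alpha2, double beta1,
                         double beta2, double lam, double w,
                         double pi_persev, double p_common) {
  int n = s1.size();
  double q_mf[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev = -1;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (s1[t] < 0 || s2c[t] < 0 || rew[t] < 0) {
      prev = -1;  // incomplete trial: no value update, no sticky bonus next
      continue;
    }
    int a1 = s1[t], st = s2s[t], a2 = s2c[t];

    // stage-1 probabilities
    double best0 = std::max(q2[0][0], q2[0][1]);
    double best1 = std::max(q2[1][0], q2[1][1]);
    double qmb0 = p_common * best0 + (1.0 - p_common) * best1;
    double qmb1 = p_common * best1 + (1.0 - p_common) * best0;
    double v0 = w * qmb0 + (1.0 - w) * q_mf[0];
    double v1 = w * qmb1 + (1.0 - w) * q_mf[1];
    if (prev == 0) v0 += pi_persev;
    if (prev == 1) v1 += pi_persev;
    double u0 = beta1 * v0, u1 = beta1 * v1;
    double m = std::max(u0, u1);
    double lse = m + std::log(std::exp(u0 - m) + std::exp(u1 - m));
    ll += (a1 == 0 ? u0 : u1) - lse;

    // stage-2 probabilities
    double w0 = beta2 * q2[st][0], w1 = beta2 * q2[st][1];
    double m2 = std::max(w0, w1);
    double lse2 = m2 + std::log(std::exp(w0 - m2) + std::exp(w1 - m2));
    ll += (a2 == 0 ? w0 : w1) - lse2;

    // SARSA(lambda) updates
    double delta1 = q2[st][a2] - q_mf[a1];
    q_mf[a1] += alpha1 * delta1;
    double delta2 = (double)rew[t] - q2[st][a2];
    q2[st][a2] += alpha2 * delta2;
    q_mf[a1] += alpha1 * lam * delta2;
    prev = a1;
  }
  return ll;
}
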