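#include <Rcpp.h>
using namespace Rcpp;

// SUSTAIN forward/learning pass over an ordered trial sequence.
//
// Stimuli are 3 binary attributes encoded one-hot per attribute. Clusters
// hold a position (per-attribute distribution over the two values) and
// per-category association weights. Receptive-field activation uses the
// halved city-block distance mu_ij and attention tunings lambda_i with focus
// exponent gamma; cluster competition uses lateral-inhibition exponent beta;
// the choice rule is a softmax with consistency d. Learning recruits a new
// cluster when the winner predicts the wrong category or its activation
// falls below tau_h, and otherwise moves the winner toward the stimulus,
// updates its association weights by a humble-teacher delta rule, and takes
// a receptive-field gradient step on each lambda_i (clamped at 0), all at
// rate eta. State (clusters, lambdas) carries over across the whole
// sequence, so problem-to-problem carryover is automatic when all three
// problems are passed in experienced order.
//
// mode: 0 = replay (learn from feedback; report P(observed response)),
//       1 = simulate (sample responses from the choice rule; uses R's RNG).
// resp: 0 = A, 1 = B, NA_INTEGER = no response (ignored in likelihood).
// [[Rcpp::export(name = ".sustain_core_cpp")]]
List sustain_core_cpp(IntegerMatrix stim_bits, IntegerVector true_cls,
                      IntegerVector resp, double gamma, double beta,
                      double eta, double d, double tau_h, int mode) {
  const int n = stim_bits.nrow();
  const int n_attr = stim_bits.ncol();
  if (true_cls.size() != n || resp.size() != n)
    stop("trial vectors must align with the stimulus matrix");

  // cluster storage: positions[c][i][v], weights[c][k]
  std::vector<std::array<std::array<double, 2>, 3>> pos;
  std::vector<std::array<double, 2>> w;
  std::vector<double> lambda(n_attr, 1.0);

  NumericVector p_a(n), p_resp(n);
  IntegerVector resp_out(n), n_clusters(n);
  LogicalVector recruited(n);
  NumericMatrix lambda_traj(n, n_attr);

  RNGScope rngScope;

  for (int t = 0; t < n; ++t) {
    // one-hot encoding of this stimulus
    std::array<std::array<double, 2>, 3> enc;
    for (int i = 0; i < n_attr; ++i) {
      int bit = stim_bits(t, i);
      enc[i][0] = bit == 0 ? 1.0 : 0.0;
      enc[i][1] = bit == 1 ? 1.0 : 0.0;
    }

    const int nc = (int) pos.size();
    double act_w = 0.0, out_w = 0.0;
    int winner = -1;
    double cA = 0.0, cB = 0.0;

    if (nc > 0) {
      std::vector<double> act(nc);
      double lam_pow_sum = 0.0;
      std::vector<double> lam_pow(n_attr);
      for (int i = 0; i < n_attr; ++i) {
        lam_pow[i] = std::pow(lambda[i], gamma);
        lam_pow_sum += lam_pow[i];
      }
      for (int c = 0; c < nc; ++c) {
        double num = 0.0;
        for (int i = 0; i < n_attr; ++i) {
          double mu = 0.5 * (std::fabs(pos[c][i][0] - enc[i][0]) +
                             std::fabs(pos[c][i][1] - enc[i][1]));
          num += lam_pow[i] * std::exp(-lambda[i] * mu);
        }
        act[c] = lam_pow_sum > 0.0 ? num / lam_pow_sum : 0.0;
      }
      // ties break to the most recently recruited cluster, so a fresh
      // cluster can displace a stale one sitting at the same position
      winner = 0;
      for (int c = 1; c < nc; ++c) if (act[c] >= act[winner]) winner = c;
      double inhib_sum = 0.0;
      for (int c = 0; c < nc; ++c) inhib_sum += std::pow(act[c], beta);
      act_w = act[winner];
      out_w = inhib_sum > 0.0
        ? (std::pow(act_w, beta) / inhib_sum) * act_w : 0.0;
      cA = w[winner][0] * out_w;
      cB = w[winner][1] * out_w;
    }

    // softmax choice rule; no clusters -> chance
    double pa = 0.5;
    if (nc > 0) {
      double ea = std::exp(d * cA), eb = std::exp(d * cB);
      pa = ea / (ea + eb);
    }
    p_a[t] = pa;

    int this_resp;
    if (mode == 1) {
      this_resp = (unif_rand() < pa) ? 0 : 1;
      p_resp[t] = this_resp == 0 ? pa : 1.0 - pa;
    } else {
      this_resp = resp[t];
      p_resp[t] = (this_resp == NA_INTEGER)
        ? NA_REAL : (this_resp == 0 ? pa : 1.0 - pa);
    }
    resp_out[t] = this_resp;

    // supervised learning from the true category
    const int truth = true_cls[t];
    bool recruit = false;
    if (nc == 0) {
      recruit = true;
    } else {
      int predicted = (cA >= cB) ? 0 : 1;  // tie -> A (lowest index)
      recruit = (predicted != truth) || (act_w < tau_h);
    }

    if (recruit) {
      pos.push_back(enc);
      w.push_back({0.0, 0.0});
      winner = (int) pos.size() - 1;
      // the fresh cluster sits on the stimulus: activation 1 by definition
      act_w = 1.0;
      double inhib_sum = 1.0;  // act_w^beta
      for (int c = 0; c < winner; ++c) {
        double num = 0.0;
        double lam_pow_sum = 0.0;
        for (int i = 0; i < n_attr; ++i) {
          double lp = std::pow(lambda[i], gamma);
          lam_pow_sum += lp;
          double mu = 0.5 * (std::fabs(pos[c][i][0] - enc[i][0]) +
                             std::fabs(pos[c][i][1] - enc[i][1]));
          num += lp * std::exp(-lambda[i] * mu);
        }
        double a = lam_pow_sum > 0.0 ? num / lam_pow_sum : 0.0;
        inhib_sum += std::pow(a, beta);
      }
      out_w = act_w / inhib_sum;
      cA = 0.0; cB = 0.0;
    }

    // winner-only updates at rate eta
    // receptive-field gradient on each lambda_i (before moving the winner)
    for (int i = 0; i < n_attr; ++i) {
      double mu = 0.5 * (std::fabs(pos[winner][i][0] - enc[i][0]) +
                         std::fabs(pos[winner][i][1] - enc[i][1]));
      lambda[i] += eta * std::exp(-lambda[i] * mu) * (1.0 - lambda[i] * mu);
      if (lambda[i] < 0.0) lambda[i] = 0.0;
    }
    // move winner toward the stimulus
    for (int i = 0; i < n_attr; ++i)
      for (int v = 0; v < 2; ++v)
        pos[winner][i][v] += eta * (enc[i][v] - pos[winner][i][v]);
    // humble-teacher delta rule on the winner's association weights
    double tA = (truth == 0) ? std::max(cA, 1.0) : std::min(cA, -1.0);
    double tB = (truth == 1) ? std::max(cB, 1.0) : std::min(cB, -1.0);
    w[winner][0] += eta * (tA - cA) * out_w;
    w[winner][1] += eta * (tB - cB) * out_w;

    recruited[t] = recruit;
    n_clusters[t] = (int) pos.size();
    for (int i = 0; i < n_attr; ++i) lambda_traj(t, i) = lambda[i];
  }

  return List::create(
    _["p_a"] = p_a, _["p_resp"] = p_resp, _["response"] = resp_out,
    _["lambda"] = lambda_traj, _["recruited"] = recruited,
    _["n_clusters"] = n_clusters);
}
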