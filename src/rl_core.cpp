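#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the Rescorla-Wagner family over one session.
//
// model: 1 = single learning rate; 2 = valence-specific learning rates
// (alpha_con after reward, alpha_dis after punishment); 3 = as model 2
// plus a counterfactual update of the unchosen stimulus with
// delta_u = (1 - r) - Q_u, using the same valence-selected rate.
//
// chosen/unchosen are 1-based stimulus indices; reward is 0/1.
// All Q values start at 0.5.

static inline double softmax_p(double qc, double qu, double beta) {
  // max-subtraction keeps exp() bounded for beta up to 100
  double m = std::max(qc, qu) * beta;
  double ec = std::exp(qc * beta - m);
  double eu = std::exp(qu * beta - m);
  return ec / (ec + eu);
}

static const double P_FLOOR = 1e-12;

// [[Rcpp::export(name = ".rl_nll_cpp")]]
double rl_nll_cpp(int model, IntegerVector chosen, IntegerVector unchosen,
                  IntegerVector reward, double alpha_con, double alpha_dis,
                  double beta) {
  int n = chosen.size();
  double Q[5] = {0.5, 0.5, 0.5, 0.5, 0.5};
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = chosen[t] - 1, u = unchosen[t] - 1;
    double p = softmax_p(Q[c], Q[u], beta);
    nll -= std::log(std::max(p, P_FLOOR));
    double r = reward[t];
    double a = (model == 1) ? alpha_con : (r > 0.5 ? alpha_con : alpha_dis);
    Q[c] += a * (r - Q[c]);
    if (model == 3) Q[u] += a * ((1.0 - r) - Q[u]);
  }
  return nll;
}

// [[Rcpp::export(name = ".rl_traj_cpp")]]
List rl_traj_cpp(int model, IntegerVector chosen, IntegerVector unchosen,
                 IntegerVector reward, double alpha_con, double alpha_dis,
                 double beta) {
  int n = chosen.size();
  double Q[5] = {0.5, 0.5, 0.5, 0.5, 0.5};
  NumericMatrix Qmat(n, 5);   // values before the trial's update
  NumericVector pc(n), dc(n), du(n);
  for (int t = 0; t < n; ++t) {
    int c = chosen[t] - 1, u = unchosen[t] - 1;
    for (int s = 0; s < 5; ++s) Qmat(t, s) = Q[s];
    pc[t] = softmax_p(Q[c], Q[u], beta);
    double r = reward[t];
    dc[t] = r - Q[c];
    du[t] = (model == 3) ? (1.0 - r) - Q[u] : NA_REAL;
    double a = (model == 1) ? alpha_con : (r > 0.5 ? alpha_con : alpha_dis);
    Q[c] += a * dc[t];
    if (model == 3) Q[u] += a * du[t];
  }
  return List::create(_["Q"] = Qmat, _["p_chosen"] = pc,
                      _["delta_chosen"] = dc, _["delta_unchosen"] = du);
}

// Minimum NLL over a full parameter grid. Exploits that value
// trajectories do not depend on beta: for each learning-rate
// combination the per-trial value difference is computed once and the
// softmax likelihood is then evaluated for every beta.
// For model 1, alpha_dis is ignored (pass any single value).
// [[Rcpp::export(name = ".rl_grid_min_cpp")]]
List rl_grid_min_cpp(int model, IntegerVector chosen, IntegerVector unchosen,
                     IntegerVector reward, NumericVector alpha_con_grid,
                     NumericVector alpha_dis_grid, NumericVector beta_grid) {
  int n = chosen.size();
  int nac = alpha_con_grid.size();
  int nad = (model == 1) ? 1 : alpha_dis_grid.size();
  int nb = beta_grid.size();
  double best = R_PosInf, b_ac = NA_REAL, b_ad = NA_REAL, b_b = NA_REAL;
  std::vector<double> qdiff(n);
  for (int i = 0; i < nac; ++i) {
    double ac = alpha_con_grid[i];
    for (int j = 0; j < nad; ++j) {
      double ad = (model == 1) ? ac : alpha_dis_grid[j];
      double Q[5] = {0.5, 0.5, 0.5, 0.5, 0.5};
      for (int t = 0; t < n; ++t) {
        int c = chosen[t] - 1, u = unchosen[t] - 1;
        qdiff[t] = Q[u] - Q[c];
        double r = reward[t];
        double a = (model == 1) ? ac : (r > 0.5 ? ac : ad);
        Q[c] += a * (r - Q[c]);
        if (model == 3) Q[u] += a * ((1.0 - r) - Q[u]);
      }
      for (int k = 0; k < nb; ++k) {
        double beta = beta_grid[k];
        double nll = 0.0;
        for (int t = 0; t < n; ++t) {
          // -log p = log(1 + exp(beta * (Q_u - Q_c))), stable form
          double x = beta * qdiff[t];
          double l = (x > 35.0) ? x : std::log1p(std::exp(x));
          nll += l;
          if (nll > best) break;  // cannot recover; prune
        }
        if (nll < best) {
          best = nll; b_ac = ac; b_ad = (model == 1) ? NA_REAL : ad;
          b_b = beta;
        }
      }
    }
  }
  return List::create(_["neg_ll"] = best, _["alpha_con"] = b_ac,
                      _["alpha_dis"] = b_ad, _["beta"] = b_b);
}
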