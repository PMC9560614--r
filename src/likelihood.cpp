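#include <Rcpp.h>
using namespace Rcpp;

// Model codes (kept in sync with model_code() on the R side):
// 1 Static, 2 Deval, 3 Choice, 4 ConfSpec, 5 ConfUnspec, 6 Perseveration.
// Parameter vector layout: [alpha_r, beta, extra1, extra2] with
// Deval: extra1 = alpha_d; Choice: extra1 = lambda;
// ConfSpec/ConfUnspec: extra1 = alpha_c, extra2 = gamma;
// Perseveration: extra1 = eta.

static inline double logistic(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static double nll_core(const IntegerVector& block, const IntegerVector& phase,
                       const IntegerVector& left, const IntegerVector& right,
                       const IntegerVector& choice_right,
                       const NumericVector& reward,
                       const NumericVector& confidence,
                       int model, const double* par, int n_cs) {
  const double alpha_r = par[0], beta = par[1];
  const double extra1 = par[2], extra2 = par[3];
  const double floor_p = 1e-12;

  std::vector<double> v(n_cs), cb(n_cs);
  std::vector<int> prev(n_cs * n_cs);
  double cbar = 0.0;
  double nll = 0.0;
  const int n = block.size();

  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != block[t - 1]) {
      std::fill(v.begin(), v.end(), 0.0);
      std::fill(cb.begin(), cb.end(), 0.0);
      std::fill(prev.begin(), prev.end(), -1);
      cbar = 0.0;
    }
    const int l = left[t], r = right[t];
    const int act = choice_right[t] ? r : l;
    const int lo = l < r ? l : r, hi = l < r ? r : l;
    const int pk = lo * n_cs + hi;

    double x = beta * (v[r] - v[l]);
    if (model == 6 && phase[t] == 2 && prev[pk] >= 0) {
      const double cpr = prev[pk] == r ? 1.0 : 0.0;
      const double cpl = prev[pk] == l ? 1.0 : 0.0;
      x = beta * ((v[r] - v[l]) + extra1 * (cpr - cpl));
    }
    const double p_right = logistic(x);
    const double p_obs = choice_right[t] ? p_right : 1.0 - p_right;
    nll -= std::log(p_obs > floor_p ? p_obs : floor_p);

    double dc = 0.0;
    if (model == 4) {
      dc = confidence[t] - cb[act];
    } else if (model == 5) {
      dc = confidence[t] - cbar;
    }

    if (phase[t] == 1 || phase[t] == 3) {
      v[act] += alpha_r * (reward[t] - v[act]);
    } else {
      // no-feedback update targets the model-predicted CS
      const int tgt = p_right >= 0.5 ? r : l;
      switch (model) {
      case 2: v[tgt] *= (1.0 - extra1); break;
      case 3: v[tgt] += extra1; break;
      case 4:
      case 5: v[tgt] += extra2 * dc; break;
      default: break;
      }
    }
    if (model == 4) {
      cb[act] += extra1 * dc;
    } else if (model == 5) {
      cbar += extra1 * dc;
    }
    if (model == 6) {
      prev[pk] = act;
    }
  }
  return nll;
}

// [[Rcpp::export]]
double nll_trials_cpp(IntegerVector block, IntegerVector phase,
                      IntegerVector left, IntegerVector right,
                      IntegerVector choice_right, NumericVector reward,
                      NumericVector confidence, int model,
                      NumericVector par, int n_cs) {
  double p[4] = {0, 0, 0, 0};
  for (int i = 0; i < par.size() && i < 4; ++i) p[i] = par[i];
  return nll_core(block, phase, left, right, choice_right, reward,
                  confidence, model, p, n_cs);
}

// Evaluate the likelihood on a whole parameter grid (rows of `pars`).
// [[Rcpp::export]]
NumericVector nll_batch_cpp(IntegerVector block, IntegerVector phase,
                            IntegerVector left, IntegerVector right,
                            IntegerVector choice_right, NumericVector reward,
                            NumericVector confidence, int model,
                            NumericMatrix pars, int n_cs) {
  const int m = pars.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double p[4] = {0, 0, 0, 0};
    for (int j = 0; j < pars.ncol() && j < 4; ++j) p[j] = pars(i, j);
    out[i] = nll_core(block, phase, left, right, choice_right, reward,
                      confidence, model, p, n_cs);
  }
  return out;
}
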