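// Model scoring and MC3 model-composition sampling for g-prior BMA.
// Marginal likelihoods are log Bayes factors against the null model, so the
// null model anchors every chain at 0 and only differences enter the MH ratio.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---- quadrature -----------------------------------------------------------

static double simpson(const std::function<double(double)>& f, double a,
                      double b, double fa, double fm, double fb, double whole,
                      double eps, int depth) {
  double m = 0.5 * (a + b);
  double lm = 0.5 * (a + m), rm = 0.5 * (m + b);
  double flm = f(lm), frm = f(rm);
  double left = (m - a) / 6.0 * (fa + 4.0 * flm + fm);
  double right = (b - m) / 6.0 * (fm + 4.0 * frm + fb);
  if (depth <= 0 || std::fabs(left + right - whole) < 15.0 * eps)
    return left + right + (left + right - whole) / 15.0;
  return simpson(f, a, m, fa, flm, fm, left, eps * 0.5, depth - 1) +
         simpson(f, m, b, fm, frm, fb, right, eps * 0.5, depth - 1);
}

// log of integral over (0,1) of exp(logf(u)), with max-shift for stability.
// Segment edges accumulate geometrically toward u = 1, where the integrands
// peak (the posterior scale of g grows with n, so u* ~ 1 - O(1/n)).
static double log_integral01(const std::function<double(double)>& logf) {
  const int ngeo = 18;  // edges 1 - 2^{-k}; resolves peaks down to ~4e-6
  std::vector<double> edge;
  edge.push_back(0.0);
  edge.push_back(0.25);
  for (int k = 1; k <= ngeo; ++k) edge.push_back(1.0 - std::ldexp(1.0, -k));
  edge.push_back(1.0);
  double M = NEG_INF;
  for (size_t i = 0; i + 1 < edge.size(); ++i)
    for (int q = 1; q < 4; ++q) {
      double u = edge[i] + 0.25 * q * (edge[i + 1] - edge[i]);
      double v = logf(u);
      if (v > M) M = v;
    }
  if (!std::isfinite(M)) return M;
  auto f = [&](double u) {
    if (u <= 0.0 || u >= 1.0) u = std::min(std::max(u, 1e-12), 1.0 - 1e-12);
    double v = logf(u) - M;
    return v > -745.0 ? std::exp(v) : 0.0;
  };
  double total = 0.0;
  for (size_t s = 0; s + 1 < edge.size(); ++s) {
    double a = edge[s], b = edge[s + 1];
    double fa = f(a), fb = f(b), fm = f(0.5 * (a + b));
    double whole = (b - a) / 6.0 * (fa + 4.0 * fm + fb);
    total += simpson(f, a, b, fa, fm, fb, whole, 1e-10, 30);
  }
  if (total <= 0.0) return NEG_INF;
  return M + std::log(total);
}

// ---- marginal likelihoods -------------------------------------------------

// variant codes: 0 fixed-g, 1 hyper-g, 2 eb-local, 3 jzs, 4 bic, 5 aic
static double log_marg(double r2, int d, int n, int variant, double g,
                       double a) {
  if (d == 0) return 0.0;
  if (r2 < 0.0) r2 = 0.0;
  const double r2cap = 1.0 - 1e-12;
  switch (variant) {
  case 0:
    return 0.5 * (n - 1 - d) * std::log1p(g) -
           0.5 * (n - 1) * std::log1p(g * (1.0 - r2));
  case 1: {
    if (r2 > r2cap) r2 = r2cap;
    double c1 = 0.5 * (d + a) - 2.0, c2 = 0.5 * (n - 1), z = r2;
    auto lf = [&](double u) {
      return c1 * std::log1p(-u) - c2 * std::log1p(-u * z);
    };
    return std::log(0.5 * (a - 2.0)) + log_integral01(lf);
  }
  case 2: {
    if (n - 1 - d <= 0) return NEG_INF;
    if (r2 > r2cap) r2 = r2cap;
    double F = (r2 / d) / ((1.0 - r2) / (n - 1 - d));
    double gh = F - 1.0;
    if (gh <= 0.0) return 0.0;
    return 0.5 * (n - 1 - d) * std::log1p(gh) -
           0.5 * (n - 1) * std::log1p(gh * (1.0 - r2));
  }
  case 3: {
    if (n - 1 - d <= 0) return NEG_INF;
    if (r2 > r2cap) r2 = r2cap;
    double z = r2;
    auto lf = [&](double u) {
      double gg = u / (1.0 - u);
      return 0.5 * std::log(0.5 * n) - std::lgamma(0.5) -
             1.5 * std::log(gg) - 0.5 * n * (1.0 - u) / u +
             0.5 * d * std::log1p(-u) -
             0.5 * (n - 1) * std::log1p(-u * z) - 2.0 * std::log1p(-u);
    };
    return log_integral01(lf);
  }
  case 4: {
    if (r2 > r2cap) r2 = r2cap;
    return -0.5 * (n * std::log1p(-r2) + d * std::log((double)n));
  }
  case 5: {
    if (r2 > r2cap) r2 = r2cap;
    return -0.5 * (n * std::log1p(-r2) + 2.0 * d);
  }
  }
  return NEG_INF;
}

// prior codes: 0 uniform, 1 beta-binomial(1,1), 2 truncated beta-binomial
static double log_model_prior(int d, int p, int n, int prior_kind,
                              int max_size) {
  if (d > n - 2) return NEG_INF;  // mass zero rather than an error
  switch (prior_kind) {
  case 0: return -p * std::log(2.0);
  case 1: return -std::log((double)p + 1.0) - R::lchoose(p, d);
  case 2: {
    int m = std::min(max_size, p);
    if (d > m) return NEG_INF;
    return -std::log((double)m + 1.0) - R::lchoose(p, d);
  }
  }
  return NEG_INF;
}

// R^2 of the OLS fit on the selected columns; ok=false if rank-deficient
static double model_r2(const arma::mat& XtX, const arma::vec& Xty, double tss,
                       const std::vector<int>& gam, int d, bool& ok) {
  ok = true;
  if (d == 0) return 0.0;
  int p = gam.size();
  arma::uvec idx(d);
  int k = 0;
  for (int j = 0; j < p; ++j)
    if (gam[j]) idx[k++] = j;
  arma::mat A = XtX.submat(idx, idx);
  arma::vec b = Xty.elem(idx);
  arma::vec sol;
  ok = arma::solve(sol, A, b,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (!ok) return 0.0;
  double r = arma::dot(sol, b) / tss;
  if (r > 1.0 + 1e-8) { ok = false; return 0.0; }
  return std::min(std::max(r, 0.0), 1.0);
}

// [[Rcpp::export(name = ".score_models_cpp")]]
NumericMatrix score_models_cpp(const IntegerMatrix& gammas,
                               const arma::mat& XtX, const arma::vec& Xty,
                               double tss, int n, int variant, double g,
                               double a) {
  int m = gammas.nrow(), p = gammas.ncol();
  NumericMatrix out(m, 2);  // columns: r2, log_marginal
  std::vector<int> gam(p);
  for (int i = 0; i < m; ++i) {
    int d = 0;
    for (int j = 0; j < p; ++j) {
      gam[j] = gammas(i, j) != 0;
      d += gam[j];
    }
    bool ok;
    double r2 = model_r2(XtX, Xty, tss, gam, d, ok);
    out(i, 0) = ok ? r2 : NA_REAL;
    out(i, 1) = ok ? log_marg(r2, d, n, variant, g, a) : NEG_INF;
  }
  return out;
}

// [[Rcpp::export(name = ".enumerate_cpp")]]
List enumerate_cpp(const arma::mat& XtX, const arma::vec& Xty, double tss,
                   int n, int variant, double g, double a, int prior_kind,
                   int max_size) {
  int p = XtX.n_rows;
  if (p > 30) stop("enumeration limited to p <= 30");
  R_xlen_t nm = (R_xlen_t)1 << p;
  NumericVector lmg(nm), lpr(nm), r2v(nm);
  IntegerVector dv(nm);
  std::vector<int> gam(p);
  for (R_xlen_t idx = 0; idx < nm; ++idx) {
    int d = 0;
    for (int j = 0; j < p; ++j) {
      gam[j] = (idx >> j) & 1;
      d += gam[j];
    }
    dv[idx] = d;
    double lp = log_model_prior(d, p, n, prior_kind, max_size);
    lpr[idx] = lp;
    if (!std::isfinite(lp)) { lmg[idx] = NEG_INF; r2v[idx] = NA_REAL; continue; }
    bool ok;
    double r2 = model_r2(XtX, Xty, tss, gam, d, ok);
    if (!ok) { lmg[idx] = NEG_INF; lpr[idx] = NEG_INF; r2v[idx] = NA_REAL; continue; }
    r2v[idx] = r2;
    lmg[idx] = log_marg(r2, d, n, variant, g, a);
  }
  return List::create(_["log_marginal"] = lmg, _["log_prior"] = lpr,
                      _["r2"] = r2v, _["d"] = dv);
}

struct ModelRec {
  double logmarg, logprior, r2;
  int d, visits, index;
};

// [[Rcpp::export(name = ".mc3_cpp")]]
List mc3_cpp(const arma::mat& XtX, const arma::vec& Xty, double tss, int n,
             int variant, double g, double a, int prior_kind, int max_size,
             int n_iter) {
  int p = XtX.n_rows;
  RNGScope scope;
  std::unordered_map<std::string, ModelRec> table;
  std::vector<std::string> order;  // insertion order of unique models
  std::vector<int> gam(p, 0), prop(p);
  std::string key(p, '0'), pkey(p, '0');
  std::vector<double> incl(p, 0.0);

  auto score = [&](const std::vector<int>& gv, const std::string& kv,
                   int d) -> ModelRec& {
    auto it = table.find(kv);
    if (it != table.end()) return it->second;
    ModelRec rec;
    rec.d = d;
    rec.visits = 0;
    rec.index = (int)order.size();
    rec.logprior = log_model_prior(d, p, n, prior_kind, max_size);
    if (std::isfinite(rec.logprior)) {
      bool ok;
      rec.r2 = model_r2(XtX, Xty, tss, gv, d, ok);
      rec.logmarg = ok ? log_marg(rec.r2, d, n, variant, g, a) : NEG_INF;
      if (!ok) rec.r2 = NA_REAL;
    } else {
      rec.r2 = NA_REAL;
      rec.logmarg = NEG_INF;
    }
    order.push_back(kv);
    return table.emplace(kv, rec).first->second;
  };

  int d = 0;
  ModelRec* cur = &score(gam, key, d);
  double cur_lp = cur->logmarg + cur->logprior;
  if (!std::isfinite(cur_lp)) stop("initial (null) model has zero posterior mass");
  int accepted = 0;

  for (int it = 0; it < n_iter; ++it) {
    prop = gam;
    pkey = key;
    int pd = d;
    bool do_swap = (unif_rand() < 0.5) && d > 0 && d < p;
    if (do_swap) {
      int ri = (int)(unif_rand() * d);
      int rj = (int)(unif_rand() * (p - d));
      int jin = -1, jout = -1, ci = 0, cj = 0;
      for (int j = 0; j < p; ++j) {
        if (gam[j]) { if (ci++ == ri) jin = j; }
        else { if (cj++ == rj) jout = j; }
      }
      prop[jin] = 0; prop[jout] = 1;
      pkey[jin] = '0'; pkey[jout] = '1';
    } else {
      int j = (int)(unif_rand() * p);
      if (j >= p) j = p - 1;
      prop[j] = 1 - prop[j];
      pkey[j] = prop[j] ? '1' : '0';
      pd += prop[j] ? 1 : -1;
    }
    ModelRec& cand = score(prop, pkey, pd);
    double cand_lp = cand.logmarg + cand.logprior;
    double lr = cand_lp - cur_lp;
    if (!do_swap) {
      // add/delete carries full proposal mass at the boundary states
      // (d = 0 or d = p, where the swap is impossible) but only half of it
      // elsewhere; the MH ratio must include that asymmetry.
      double q_fwd = (d > 0 && d < p) ? 0.5 : 1.0;
      double q_rev = (pd > 0 && pd < p) ? 0.5 : 1.0;
      lr += std::log(q_rev) - std::log(q_fwd);
    }
    if (std::isfinite(cand_lp) && (lr >= 0.0 || unif_rand() < std::exp(lr))) {
      gam = prop; key = pkey; d = pd;
      cur = &cand; cur_lp = cand_lp;
      ++accepted;
    }
    cur->visits += 1;
    for (int j = 0; j < p; ++j) incl[j] += gam[j];
  }

  int m = (int)order.size();
  IntegerMatrix models(m, p);
  NumericVector lmg(m), lpr(m), r2v(m);
  IntegerVector dv(m), visits(m);
  for (int i = 0; i < m; ++i) {
    const ModelRec& rec = table[order[i]];
    const std::string& kv = order[i];
    for (int j = 0; j < p; ++j) models(i, j) = kv[j] == '1';
    lmg[i] = rec.logmarg; lpr[i] = rec.logprior; r2v[i] = rec.r2;
    dv[i] = rec.d; visits[i] = rec.visits;
  }
  NumericVector inclp(p);
  for (int j = 0; j < p; ++j) inclp[j] = incl[j] / n_iter;
  return List::create(_["models"] = models, _["log_marginal"] = lmg,
                      _["log_prior"] = lpr, _["r2"] = r2v, _["d"] = dv,
                      _["visits"] = visits, _["inclusion_freq"] = inclp,
                      _["accept_rate"] = (double)accepted / n_iter);
}
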