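// Core numerics for the nominal-response model family:
//  - joint log posterior and analytic gradient on the unconstrained scale
//    (discrimination parameters alpha are sampled as u = log(alpha))
//  - a No-U-Turn sampler (slice variant, dual-averaging step size,
//    diagonal mass matrix estimated during warmup)
//  - the S x N pointwise log-likelihood matrix evaluated at retained draws
//
// Variant codes: 0 nrm_2pl, 1 nrm_1pl, 2 mdnrm_orig, 3 mdnrm_a,
//                4 mdnrm_b, 5 mdnrm_r
// Alpha prior codes: 0 none, 1 gamma(shape 2, rate 2), 2 half-normal(scale 10)
//
// Ability layout theta[j,s,t] -> j + J*(s + C*t)  (column-major, as R's
// array(dim = c(J, C, C))); item arrays [i,s] -> i + I*s.
//
// In every MDNRM variant the easiness term beta_{is} is constant over the
// response index t, so it cancels in the softmax: the likelihood code omits
// it and beta feels only its prior.  The NRM variants index beta by the
// response class, where it does not cancel.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const double LOG_2PI = 1.8378770664093454836;

struct Model {
  int I, J, C, N;
  int variant;  // 0..5
  int aprior;   // 0 none, 1 gamma(2,2), 2 half-normal(10)
  int beta_resp = 0;  // MDNRM easiness indexed by response class (non-canonical)
  std::vector<int> item, rater, truth, resp;
  int n_theta, n_alpha, n_beta, npar;

  void set_dims() {
    if (variant <= 1) {  // NRM family: scalar ability per rater
      n_theta = J;
      n_alpha = (variant == 0) ? I * C : 0;
      n_beta = I * C;
    } else {
      n_theta = J * C * C;
      switch (variant) {
        case 2: n_alpha = 0;     n_beta = I * C; break;  // original
        case 3: n_alpha = I * C; n_beta = C;     break;  // subtype a
        case 4: n_alpha = C;     n_beta = I * C; break;  // subtype b
        default: n_alpha = I * C; n_beta = I * C;        // subtype r
      }
    }
    npar = n_theta + n_alpha + n_beta;
  }

  // log posterior and gradient; q is [theta | u = log(alpha) | beta]
  double logpost(const std::vector<double>& q, std::vector<double>& grad) const {
    const int C_ = C;
    double lp = 0.0;
    std::fill(grad.begin(), grad.end(), 0.0);
    const double* th = q.data();
    const double* uu = q.data() + n_theta;
    const double* be = q.data() + n_theta + n_alpha;
    double* gth = grad.data();
    double* guu = grad.data() + n_theta;
    double* gbe = grad.data() + n_theta + n_alpha;

    // priors: theta, beta ~ Normal(0, 2)
    for (int k = 0; k < n_theta; ++k) {
      lp += -0.5 * LOG_2PI - std::log(2.0) - th[k] * th[k] / 8.0;
      gth[k] += -th[k] / 4.0;
    }
    for (int k = 0; k < n_beta; ++k) {
      lp += -0.5 * LOG_2PI - std::log(2.0) - be[k] * be[k] / 8.0;
      gbe[k] += -be[k] / 4.0;
    }
    // alpha on the log scale: cache exp(u) once per call
    std::vector<double> av(n_alpha);
    for (int k = 0; k < n_alpha; ++k) av[k] = std::exp(uu[k]);
    // alpha prior with log-transform Jacobian folded in
    if (aprior == 1) {
      for (int k = 0; k < n_alpha; ++k) {
        lp += 2.0 * std::log(2.0) + 2.0 * uu[k] - 2.0 * av[k];
        guu[k] += 2.0 - 2.0 * av[k];
      }
    } else if (aprior == 2) {
      for (int k = 0; k < n_alpha; ++k) {
        double a2 = av[k] * av[k];
        lp += 0.5 * std::log(2.0 / M_PI) - std::log(10.0) + uu[k] - a2 / 200.0;
        guu[k] += 1.0 - a2 / 100.0;
      }
    }

    std::vector<double> z(C_), p(C_);
    for (int n = 0; n < N; ++n) {
      const int i = item[n], j = rater[n], s = truth[n], r = resp[n];
      double coef = 1.0;
      int a_idx = -1;
      if (variant >= 2) {
        if (variant == 3 || variant == 5) { a_idx = i + I * s; coef = av[a_idx]; }
        else if (variant == 4)            { a_idx = s;         coef = av[a_idx]; }
        for (int t = 0; t < C_; ++t) {
          z[t] = coef * th[j + J * (s + C_ * t)];
          if (beta_resp) z[t] += (variant == 3) ? be[t] : be[i + I * t];
        }
      } else if (variant == 0) {
        for (int t = 0; t < C_; ++t)
          z[t] = av[i + I * t] * th[j] + be[i + I * t];
      } else {
        for (int t = 0; t < C_; ++t) z[t] = th[j] + be[i + I * t];
      }
      double zmax = z[0];
      for (int t = 1; t < C_; ++t) if (z[t] > zmax) zmax = z[t];
      double sum = 0.0;
      for (int t = 0; t < C_; ++t) { p[t] = std::exp(z[t] - zmax); sum += p[t]; }
      lp += z[r] - zmax - std::log(sum);
      for (int t = 0; t < C_; ++t) p[t] /= sum;

      if (variant >= 2) {
        double acc_u = 0.0;
        for (int t = 0; t < C_; ++t) {
          double e = ((t == r) ? 1.0 : 0.0) - p[t];
          double tht = th[j + J * (s + C_ * t)];
          gth[j + J * (s + C_ * t)] += coef * e;
          acc_u += e * tht;
          if (beta_resp) gbe[(variant == 3) ? t : i + I * t] += e;
        }
        if (a_idx >= 0) guu[a_idx] += coef * acc_u;
      } else if (variant == 0) {
        for (int t = 0; t < C_; ++t) {
          double e = ((t == r) ? 1.0 : 0.0) - p[t];
          double a = av[i + I * t];
          gth[j] += e * a;
          guu[i + I * t] += e * a * th[j];
          gbe[i + I * t] += e;
        }
      } else {
        for (int t = 0; t < C_; ++t) {
          double e = ((t == r) ? 1.0 : 0.0) - p[t];
          gth[j] += e;  // sums to zero; kept for clarity
          gbe[i + I * t] += e;
        }
      }
    }
    return lp;
  }

  // pointwise log-likelihood at one draw
  void loglik_row(const double* q, double* out) const {
    const int C_ = C;
    const double* th = q;
    const double* uu = q + n_theta;
    const double* be = q + n_theta + n_alpha;
    std::vector<double> z(C_);
    for (int n = 0; n < N; ++n) {
      const int i = item[n], j = rater[n], s = truth[n], r = resp[n];
      if (variant >= 2) {
        double coef = 1.0;
        if (variant == 3 || variant == 5) coef = std::exp(uu[i + I * s]);
        else if (variant == 4) coef = std::exp(uu[s]);
        for (int t = 0; t < C_; ++t) {
          z[t] = coef * th[j + J * (s + C_ * t)];
          if (beta_resp) z[t] += (variant == 3) ? be[t] : be[i + I * t];
        }
      } else if (variant == 0) {
        for (int t = 0; t < C_; ++t)
          z[t] = std::exp(uu[i + I * t]) * th[j] + be[i + I * t];
      } else {
        for (int t = 0; t < C_; ++t) z[t] = th[j] + be[i + I * t];
      }
      double zmax = z[0];
      for (int t = 1; t < C_; ++t) if (z[t] > zmax) zmax = z[t];
      double sum = 0.0;
      for (int t = 0; t < C_; ++t) sum += std::exp(z[t] - zmax);
      out[n] = z[r] - zmax - std::log(sum);
    }
  }
};

Model build_model(int I, int J, int C, int variant, int aprior,
                  const IntegerVector& item, const IntegerVector& rater,
                  const IntegerVector& truth, const IntegerVector& resp,
                  int beta_resp = 0) {
  Model m;
  m.I = I; m.J = J; m.C = C; m.N = item.size();
  m.variant = variant; m.aprior = aprior; m.beta_resp = beta_resp;
  m.item.assign(item.begin(), item.end());
  m.rater.assign(rater.begin(), rater.end());
  m.truth.assign(truth.begin(), truth.end());
  m.resp.assign(resp.begin(), resp.end());
  m.set_dims();
  return m;
}

// ---------------------------------------------------------------- NUTS ----

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double normal() { return norm(gen); }
  double uniform() { return unif(gen); }
  double expo() { return -std::log(1.0 - unif(gen)); }
};

struct Sampler {
  const Model& m;
  Rng& rng;
  std::vector<double> minv;  // inverse mass diagonal
  double max_depth_hits = 0, divergences = 0;
  long n_grad = 0;

  Sampler(const Model& model, Rng& r) : m(model), rng(r), minv(model.npar, 1.0) {}

  double joint(const std::vector<double>& p, double lp) const {
    double k = 0.0;
    for (int d = 0; d < m.npar; ++d) k += p[d] * p[d] * minv[d];
    return lp - 0.5 * k;
  }

  void leapfrog(std::vector<double>& q, std::vector<double>& p,
                std::vector<double>& grad, double& lp, double eps) {
    for (int d = 0; d < m.npar; ++d) p[d] += 0.5 * eps * grad[d];
    for (int d = 0; d < m.npar; ++d) q[d] += eps * minv[d] * p[d];
    lp = m.logpost(q, grad);
    ++n_grad;
    for (int d = 0; d < m.npar; ++d) p[d] += 0.5 * eps * grad[d];
  }

  struct Tree {
    std::vector<double> q_minus, p_minus, g_minus;
    std::vector<double> q_plus, p_plus, g_plus;
    std::vector<double> q_prop;
    double lp_prop = 0.0;
    int n_valid = 0;
    bool ok = false, divergent = false;
    double sum_alpha = 0.0;
    int n_alpha = 0;
  };

  bool no_uturn(const std::vector<double>& qm, const std::vector<double>& qp,
                const std::vector<double>& pm, const std::vector<double>& pp) const {
    double dm = 0.0, dp = 0.0;
    for (int d = 0; d < m.npar; ++d) {
      double dq = qp[d] - qm[d];
      dm += dq * minv[d] * pm[d];
      dp += dq * minv[d] * pp[d];
    }
    return dm >= 0.0 && dp >= 0.0;
  }

  Tree build(std::vector<double> q, std::vector<double> p, std::vector<double> g,
             double lp, double log_u, int dir, int depth, double eps, double joint0) {
    Tree t;
    if (depth == 0) {
      leapfrog(q, p, g, lp, dir * eps);
      double j1 = joint(p, lp);
      t.n_valid = (log_u <= j1) ? 1 : 0;
      t.divergent = (log_u - 1000.0 > j1) || !std::isfinite(j1);
      t.ok = !t.divergent;
      t.q_minus = q; t.p_minus = p; t.g_minus = g;
      t.q_plus = q; t.p_plus = p; t.g_plus = g;
      t.q_prop = q; t.lp_prop = lp;
      double a = std::exp(std::min(0.0, j1 - joint0));
      if (!std::isfinite(a)) a = 0.0;
      t.sum_alpha = a; t.n_alpha = 1;
      return t;
    }
    Tree t1 = build(q, p, g, lp, log_u, dir, depth - 1, eps, joint0);
    if (!t1.ok) return t1;
    Tree t2;
    if (dir == -1)
      t2 = build(t1.q_minus, t1.p_minus, t1.g_minus, 0.0, log_u, dir, depth - 1, eps, joint0);
    else
      t2 = build(t1.q_plus, t1.p_plus, t1.g_plus, 0.0, log_u, dir, depth - 1, eps, joint0);
    Tree t3;
    t3.sum_alpha = t1.sum_alpha + t2.sum_alpha;
    t3.n_alpha = t1.n_alpha + t2.n_alpha;
    t3.divergent = t2.divergent;
    if (!t2.ok) { t3.ok = false; return t3; }
    if (dir == -1) {
      t3.q_minus = t2.q_minus; t3.p_minus = t2.p_minus; t3.g_minus = t2.g_minus;
      t3.q_plus = t1.q_plus; t3.p_plus = t1.p_plus; t3.g_plus = t1.g_plus;
    } else {
      t3.q_minus = t1.q_minus; t3.p_minus = t1.p_minus; t3.g_minus = t1.g_minus;
      t3.q_plus = t2.q_plus; t3.p_plus = t2.p_plus; t3.g_plus = t2.g_plus;
    }
    t3.n_valid = t1.n_valid + t2.n_valid;
    if (t2.n_valid > 0 &&
        rng.uniform() < (double)t2.n_valid / std::max(1, t3.n_valid)) {
      t3.q_prop = t2.q_prop; t3.lp_prop = t2.lp_prop;
    } else {
      t3.q_prop = t1.q_prop; t3.lp_prop = t1.lp_prop;
    }
    t3.ok = no_uturn(t3.q_minus, t3.q_plus, t3.p_minus, t3.p_plus);
    return t3;
  }

  // one NUTS transition; returns average acceptance statistic
  double transition(std::vector<double>& q, std::vector<double>& grad, double& lp,
                    double eps, int max_depth, bool count_div) {
    std::vector<double> p(m.npar);
    for (int d = 0; d < m.npar; ++d)
      p[d] = rng.normal() / std::sqrt(minv[d]);
    double joint0 = joint(p, lp);
    double log_u = joint0 - rng.expo();

    std::vector<double> qm = q, qp = q, pm = p, pp = p, gm = grad, gp = grad;
    std::vector<double> q_prop = q;
    double lp_prop = lp;
    int n_valid = 1;
    double sum_alpha = 0.0;
    int n_alpha_acc = 0;
    bool ok = true;
    int depth = 0;
    while (ok && depth < max_depth) {
      int dir = (rng.uniform() < 0.5) ? -1 : 1;
      Tree t;
      if (dir == -1) t = build(qm, pm, gm, 0.0, log_u, dir, depth, eps, joint0);
      else t = build(qp, pp, gp, 0.0, log_u, dir, depth, eps, joint0);
      sum_alpha += t.sum_alpha; n_alpha_acc += t.n_alpha;
      if (t.divergent && count_div) divergences += 1;
      if (!t.ok) break;
      if (dir == -1) { qm = t.q_minus; pm = t.p_minus; gm = t.g_minus; }
      else { qp = t.q_plus; pp = t.p_plus; gp = t.g_plus; }
      if (t.n_valid > 0 &&
          rng.uniform() < std::min(1.0, (double)t.n_valid / n_valid)) {
        q_prop = t.q_prop; lp_prop = t.lp_prop;
      }
      n_valid += t.n_valid;
      ok = no_uturn(qm, qp, pm, pp);
      ++depth;
    }
    if (depth == max_depth) max_depth_hits += 1;
    q = q_prop;
    lp = m.logpost(q, grad);
    ++n_grad;
    return (n_alpha_acc > 0) ? sum_alpha / n_alpha_acc : 0.0;
  }

  double find_epsilon(std::vector<double> q, std::vector<double> grad, double lp) {
    double eps = 1.0;
    std::vector<double> p(m.npar);
    for (int d = 0; d < m.npar; ++d) p[d] = rng.normal() / std::sqrt(minv[d]);
    double j0 = joint(p, lp);
    std::vector<double> q1 = q, p1 = p, g1 = grad;
    double lp1 = lp;
    leapfrog(q1, p1, g1, lp1, eps);
    double j1 = joint(p1, lp1);
    if (!std::isfinite(j1)) {
      while (!std::isfinite(j1) && eps > 1e-10) {
        eps *= 0.5;
        q1 = q; p1 = p; g1 = grad; lp1 = lp;
        leapfrog(q1, p1, g1, lp1, eps);
        j1 = joint(p1, lp1);
      }
      return eps;
    }
    double a = (j1 - j0 > std::log(0.5)) ? 1.0 : -1.0;
    while (a * (j1 - j0) > -a * std::log(2.0) && eps > 1e-10 && eps < 1e7) {
      eps *= std::pow(2.0, a);
      q1 = q; p1 = p; g1 = grad; lp1 = lp;
      leapfrog(q1, p1, g1, lp1, eps);
      j1 = joint(p1, lp1);
      if (!std::isfinite(j1)) { eps *= 0.5; break; }
    }
    return eps;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_logpost_grad(NumericVector q, int I, int J, int C, int variant, int aprior,
                      IntegerVector item, IntegerVector rater,
                      IntegerVector truth, IntegerVector resp, int beta_resp = 0) {
  Model m = build_model(I, J, C, variant, aprior, item, rater, truth, resp, beta_resp);
  if ((int)q.size() != m.npar)
    stop("parameter vector has length %d; variant requires %d", (int)q.size(), m.npar);
  std::vector<double> qq(q.begin(), q.end()), grad(m.npar);
  double lp = m.logpost(qq, grad);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(NumericMatrix draws, int I, int J, int C,
                                int variant, int aprior,
                                IntegerVector item, IntegerVector rater,
                                IntegerVector truth, IntegerVector resp,
                                int beta_resp = 0) {
  Model m = build_model(I, J, C, variant, aprior, item, rater, truth, resp, beta_resp);
  if (draws.ncol() != m.npar)
    stop("draws matrix has %d columns; variant requires %d", draws.ncol(), m.npar);
  const int S = draws.nrow();
  NumericMatrix out(S, m.N);
  std::vector<double> q(m.npar), row(m.N);
  for (int s = 0; s < S; ++s) {
    for (int d = 0; d < m.npar; ++d) q[d] = draws(s, d);
    m.loglik_row(q.data(), row.data());
    for (int n = 0; n < m.N; ++n) out(s, n) = row[n];
  }
  return out;
}

// Run one chain of NUTS.  init: starting point on the unconstrained scale.
// Returns retained draws (n_samples x npar) plus adaptation diagnostics.
// [[Rcpp::export]]
List cpp_nuts_chain(NumericVector init, int I, int J, int C, int variant, int aprior,
                    IntegerVector item, IntegerVector rater,
                    IntegerVector truth, IntegerVector resp,
                    int n_warmup, int n_samples, double seed,
                    double target_accept = 0.8, int max_depth = 10,
                    bool likelihood = true, int beta_resp = 0) {
  Model m = build_model(I, J, C, variant, aprior, item, rater, truth, resp, beta_resp);
  if (!likelihood) m.N = 0;  // prior-predictive mode
  if ((int)init.size() != m.npar)
    stop("init has length %d; variant requires %d", (int)init.size(), m.npar);
  Rng rng((uint64_t)seed);
  Sampler smp(m, rng);

  std::vector<double> q(init.begin(), init.end()), grad(m.npar);
  double lp = m.logpost(q, grad);
  if (!std::isfinite(lp))
    stop("log posterior is not finite at the initial point");

  double eps = smp.find_epsilon(q, grad, lp);
  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps = std::log(eps), log_eps_bar = 0.0;
  double h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_iter = 0;

  // expanding mass-matrix windows between an initial and a terminal
  // step-size-only buffer, doubling in length as warmup proceeds
  const int init_buffer = 75;
  const int term_buffer = std::max(50, (int)(0.1 * n_warmup));
  std::vector<int> win_ends;
  {
    int base = 25;
    if (n_warmup >= init_buffer + term_buffer + base) {
      int cur = init_buffer, size = base;
      const int last = n_warmup - term_buffer;
      while (true) {
        int end = cur + size;
        if (end + 2 * size > last) end = last;
        win_ends.push_back(end);
        if (end >= last) break;
        cur = end;
        size *= 2;
      }
    }
  }
  std::vector<double> w_mean(m.npar, 0.0), w_m2(m.npar, 0.0);
  long w_n = 0;
  size_t win_idx = 0;

  NumericMatrix draws(n_samples, m.npar);
  double accept_sum = 0.0;

  for (int it = 0; it < n_warmup + n_samples; ++it) {
    bool warm = it < n_warmup;
    double a = smp.transition(q, grad, lp, eps, max_depth, !warm);
    if (warm) {
      ++adapt_iter;
      double eta = 1.0 / (adapt_iter + t0);
      h_bar = (1.0 - eta) * h_bar + eta * (target_accept - a);
      log_eps = mu - std::sqrt((double)adapt_iter) / gamma * h_bar;
      double x = std::pow((double)adapt_iter, -kappa);
      log_eps_bar = x * log_eps + (1.0 - x) * log_eps_bar;
      eps = std::exp(log_eps);
      if (win_idx < win_ends.size() && it >= init_buffer) {
        ++w_n;
        for (int d = 0; d < m.npar; ++d) {
          double delta = q[d] - w_mean[d];
          w_mean[d] += delta / w_n;
          w_m2[d] += delta * (q[d] - w_mean[d]);
        }
        if (it + 1 == win_ends[win_idx]) {
          if (w_n >= 10) {
            for (int d = 0; d < m.npar; ++d) {
              double v = w_m2[d] / (w_n - 1);
              // shrink toward unit scale as Stan does for short windows
              smp.minv[d] = (w_n / (w_n + 5.0)) * v + 1e-3 * (5.0 / (w_n + 5.0));
              if (smp.minv[d] <= 0 || !std::isfinite(smp.minv[d])) smp.minv[d] = 1.0;
            }
            eps = smp.find_epsilon(q, grad, lp);
            mu = std::log(10.0 * eps);
            log_eps = std::log(eps);
            log_eps_bar = 0.0; h_bar = 0.0; adapt_iter = 0;
          }
          std::fill(w_mean.begin(), w_mean.end(), 0.0);
          std::fill(w_m2.begin(), w_m2.end(), 0.0);
          w_n = 0;
          ++win_idx;
        }
      }
    } else {
      if (it == n_warmup) eps = std::exp(log_eps_bar);
      accept_sum += a;
      int row = it - n_warmup;
      for (int d = 0; d < m.npar; ++d) draws(row, d) = q[d];
    }
  }

  List out = List::create(
      _["draws"] = draws,
      _["step_size"] = eps,
      _["divergences"] = smp.divergences,
      _["max_depth_hits"] = smp.max_depth_hits,
      _["accept_mean"] = (n_samples > 0) ? accept_sum / n_samples : NA_REAL,
      _["n_grad"] = (double)smp.n_grad,
      _["inv_mass"] = NumericVector(smp.minv.begin(), smp.minv.end()));
  return out;
}
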