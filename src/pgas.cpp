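// Conditional SMC with ancestor sampling (PGAS) and a bootstrap particle
// filter for the bursting autoregressive fluorescence model.
//
// Latent state per step: firing regime q (0/1), spike count s, calcium pair
// (c_t, c_{t-1}) (deterministic given spikes), baseline b (Gaussian random
// walk). Observation: F_t ~ N(c_t + b_t, sigma2).
//
// The sweep uses the optimal proposal: (q,s) from a 2 x (s_max+1) probability
// table with the baseline integrated analytically, then deterministic calcium
// propagation, then the baseline from its Gaussian full conditional. The
// importance weight of each particle is the table normalizer Z of its
// ancestor, computed in log space with max-subtraction.
//
// All randomness comes from R's RNG (reproducible under set.seed()).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  double dt;
  double r0, r1, w01, w10;
  double gamma1, gamma2, A, c0;
  double sigma2, sigma2b;
  int s_max;
  bool single_state;            // non-bursting variant: q fixed at 0
  // precomputed
  double lW[2][2];              // log per-step switching probabilities
  std::vector<double> lpois0, lpois1;  // log Poisson pmf for s = 0..s_max
  double v;                     // sigma2 + sigma2b*dt (proposal variance)
  double log_norm_I;            // -0.5*log(2*pi*v)
  double sb2dt;                 // sigma2b*dt
};

inline double log_or_neginf(double p) {
  return p > 0 ? std::log(p) : R_NegInf;
}

Model make_model(double dt, double r0, double r1, double w01, double w10,
                 double gamma1, double gamma2, double A, double c0,
                 double sigma2, double sigma2b, int s_max, bool single_state) {
  Model m;
  m.dt = dt; m.r0 = r0; m.r1 = r1; m.w01 = w01; m.w10 = w10;
  m.gamma1 = gamma1; m.gamma2 = gamma2; m.A = A; m.c0 = c0;
  m.sigma2 = sigma2; m.sigma2b = sigma2b; m.s_max = s_max;
  m.single_state = single_state;
  if (sigma2 <= 0) stop("sigma2 must be positive");
  if (sigma2b <= 0) stop("sigma2_b must be positive inside the sweep");
  if (w01 * dt >= 1 || w10 * dt >= 1) stop("w*dt must be < 1");
  m.lW[0][0] = log_or_neginf(1 - w01 * dt);
  m.lW[0][1] = log_or_neginf(w01 * dt);
  m.lW[1][0] = log_or_neginf(w10 * dt);
  m.lW[1][1] = log_or_neginf(1 - w10 * dt);
  m.lpois0.resize(s_max + 1);
  m.lpois1.resize(s_max + 1);
  for (int s = 0; s <= s_max; ++s) {
    m.lpois0[s] = R::dpois(s, r0 * dt, 1);
    m.lpois1[s] = R::dpois(s, r1 * dt, 1);
  }
  m.sb2dt = sigma2b * dt;
  m.v = sigma2 + m.sb2dt;
  m.log_norm_I = -0.5 * std::log(2.0 * M_PI * m.v);
  return m;
}

// Draw n sorted uniforms in O(n) via exponential spacings.
void sorted_uniforms(int n, std::vector<double>& u) {
  u.resize(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += R::exp_rand();
    u[i] = acc;
  }
  acc += R::exp_rand();
  for (int i = 0; i < n; ++i) u[i] /= acc;
}

// Multinomial resampling of n_draws indices proportional to exp(logw - max),
// using one merge pass over sorted uniforms. O(N + n_draws).
void multinomial_resample(const std::vector<double>& logw, int n_draws,
                          std::vector<int>& out, std::vector<double>& scratch_u,
                          std::vector<double>& scratch_cw) {
  const int n = (int)logw.size();
  double mx = R_NegInf;
  for (int i = 0; i < n; ++i) if (logw[i] > mx) mx = logw[i];
  if (!std::isfinite(mx)) stop("particle weights degenerate (all zero)");
  scratch_cw.resize(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += std::exp(logw[i] - mx);
    scratch_cw[i] = acc;
  }
  sorted_uniforms(n_draws, scratch_u);
  out.resize(n_draws);
  int j = 0;
  for (int i = 0; i < n_draws; ++i) {
    const double target = scratch_u[i] * acc;
    while (j < n - 1 && scratch_cw[j] < target) ++j;
    out[i] = j;
  }
  // deliberately left in drawn (sorted) order; particles are exchangeable
}

// One categorical draw from unnormalized log scores.
int categorical_from_logs(const std::vector<double>& ls) {
  const int n = (int)ls.size();
  double mx = R_NegInf;
  for (int i = 0; i < n; ++i) if (ls[i] > mx) mx = ls[i];
  if (!std::isfinite(mx)) return -1;
  double acc = 0.0;
  std::vector<double> cw(n);
  for (int i = 0; i < n; ++i) {
    acc += std::exp(ls[i] - mx);
    cw[i] = acc;
  }
  const double target = unif_rand() * acc;
  for (int i = 0; i < n; ++i) if (cw[i] >= target) return i;
  return n - 1;
}

// Optimal-proposal table over (q', s') given the ancestor state, in log
// space. Fills lent (row-major: q' * (s_max+1) + s') and returns the log
// normalizer log Z (including the Gaussian-convolution normalizer).
double proposal_table(const Model& m, int q_prev, double c_prev,
                      double c_prev2, double b_prev, double f,
                      std::vector<double>& lent, double& c_pred) {
  c_pred = m.gamma1 * c_prev + m.gamma2 * c_prev2;
  const int ns = m.s_max + 1;
  const int nq = m.single_state ? 1 : 2;
  lent.assign(2 * ns, R_NegInf);
  double mx = R_NegInf;
  for (int q = 0; q < nq; ++q) {
    const double lw = m.single_state ? 0.0 : m.lW[q_prev][q];
    if (!std::isfinite(lw)) continue;
    const std::vector<double>& lp = (q == 1) ? m.lpois1 : m.lpois0;
    for (int s = 0; s < ns; ++s) {
      const double diff = b_prev - (f - c_pred - m.A * s);
      const double le = lw + lp[s] - 0.5 * diff * diff / m.v;
      lent[q * ns + s] = le;
      if (le > mx) mx = le;
    }
  }
  if (!std::isfinite(mx)) return R_NegInf;
  double acc = 0.0;
  for (int q = 0; q < nq; ++q)
    for (int s = 0; s < ns; ++s) {
      const double le = lent[q * ns + s];
      if (le - mx > -45.0) acc += std::exp(le - mx);
    }
  return mx + std::log(acc) + m.log_norm_I;
}

// Sample (q', s') from a filled log-entry table.
void sample_qs(const Model& m, const std::vector<double>& lent,
               std::vector<double>& cw, int& q_out, int& s_out) {
  const int ns = m.s_max + 1;
  const int nq = m.single_state ? 1 : 2;
  double mx = R_NegInf;
  for (int k = 0; k < nq * ns; ++k) if (lent[k] > mx) mx = lent[k];
  double acc = 0.0;
  cw.resize(nq * ns);
  for (int k = 0; k < nq * ns; ++k) {
    const double d = lent[k] - mx;
    acc += (d > -45.0) ? std::exp(d) : 0.0;
    cw[k] = acc;
  }
  const double target = unif_rand() * acc;
  int k = 0;
  while (k < nq * ns - 1 && cw[k] < target) ++k;
  q_out = k / ns;
  s_out = k % ns;
}

inline double sample_baseline_draw(const Model& m, double b_prev, double c_t,
                                   double f) {
  const double mu = (b_prev * m.sigma2 + (f - c_t) * m.sb2dt) / m.v;
  const double sd = std::sqrt(m.sigma2 * m.sb2dt / m.v);
  return mu + sd * norm_rand();
}

inline double obs_logdens(const Model& m, double f, double c, double b) {
  const double r = f - c - b;
  return -0.5 * r * r / m.sigma2 - 0.5 * std::log(2.0 * M_PI * m.sigma2);
}

}  // namespace

//' @title Internal PGAS sweep (C++)
//' @description One conditional-SMC-with-ancestor-sampling pass. Not part of
//'   the public API; use pgas_sweep().
//' @keywords internal
// [[Rcpp::export]]
List cpp_pgas_sweep(NumericVector F, double dt, IntegerVector q_ref,
                    IntegerVector s_ref, NumericVector b_ref, double r0,
                    double r1, double w01, double w10, double gamma1,
                    double gamma2, double A, double c0, double sigma2,
                    double sigma2b, int n_particles, int s_max,
                    bool single_state, int mutation, bool return_particles,
                    bool ancestor_sampling) {
  const int T = F.size();
  const int N = n_particles;
  if (T < 2) stop("trace too short");
  if (N < 2) stop("need at least 2 particles");
  if ((int)q_ref.size() != T || (int)s_ref.size() != T ||
      (int)b_ref.size() != T)
    stop("reference trajectory length mismatch with trace");
  Model m = make_model(dt, r0, r1, w01, w10, gamma1, gamma2, A, c0, sigma2,
                       sigma2b, s_max, single_state);
  RNGScope scope;

  // reference calcium re-propagated under the current kinetics
  std::vector<double> c_ref(T), c_ref_prev(T);
  c_ref[0] = c0 + A * s_ref[0];
  c_ref_prev[0] = 0.0;
  for (int t = 1; t < T; ++t) {
    c_ref_prev[t] = c_ref[t - 1];
    const double c2 = (t >= 2) ? c_ref[t - 2] : 0.0;
    c_ref[t] = gamma1 * c_ref[t - 1] + gamma2 * c2 + A * s_ref[t];
  }

  // particle storage, [t*N + i]
  std::vector<int> Q((size_t)T * N), S((size_t)T * N), ANC((size_t)T * N, -1);
  std::vector<double> C((size_t)T * N), CP((size_t)T * N), B((size_t)T * N);
  std::vector<double> LW((size_t)T * N);

  // --- initialization (t = 1) ---
  for (int i = 0; i < N; ++i) {
    int q1, s1;
    double b1;
    if (i == N - 1) {
      q1 = q_ref[0]; s1 = s_ref[0]; b1 = b_ref[0];
    } else {
      q1 = single_state ? 0 : (unif_rand() < 0.5 ? 0 : 1);
      const double r = (q1 == 1) ? r1 : r0;
      s1 = (int)R::rpois(r * dt);
      b1 = norm_rand();
    }
    const double c1 = c0 + A * s1;
    Q[i] = q1; S[i] = s1; B[i] = b1; C[i] = c1; CP[i] = 0.0;
    double lw = obs_logdens(m, F[0], c1, b1);
    if (mutation == 1) lw *= 2.0;     // deliberately broken weights (tests)
    else if (mutation == 2) lw = -lw;
    LW[i] = lw;
  }

  std::vector<int> anc;
  std::vector<double> lw_prev(N), su, scw, lent, as_scores(N), qs_cw;
  int n_as_fallback = 0;

  // --- forward sweep ---
  for (int t = 1; t < T; ++t) {
    const size_t off = (size_t)t * N, offp = (size_t)(t - 1) * N;
    for (int i = 0; i < N; ++i) lw_prev[i] = LW[offp + i];

    // multinomial resampling for the first N-1 particles
    multinomial_resample(lw_prev, N - 1, anc, su, scw);

    // Ancestor sampling for the reference slot. Because calcium is a
    // deterministic function of the spike history, reconnecting the
    // reference to a new ancestor changes the calcium entering every later
    // observation; the exact ancestor weight therefore carries, besides the
    // stochastic junction factors (switching probability and baseline
    // increment; the Poisson term is constant across ancestors), the future
    // observation likelihood with calcium re-propagated from the candidate
    // ancestor. The homogeneous AR(2) solution is linear in the ancestor's
    // calcium pair (c1, c2), so that likelihood is a quadratic form whose
    // coefficients are accumulated once per time step:
    //   c_{t+k}^base = a_k c1 + b_k c2,  z_k = spike-driven part,
    //   sum_k (r_k - a_k c1 - b_k c2)^2,  r_k = F - b_ref - z_k.
    {
      double Sra = 0, Srb = 0, Saa = 0, Sab = 0, Sbb = 0;
      // horizon: basis coefficients decay like the dominant root
      const double root_p = 0.5 * (gamma1 +
                                   std::sqrt(gamma1 * gamma1 + 4 * gamma2));
      int Lh = T - t;
      if (root_p > 0 && root_p < 1) {
        const int cap = (int)std::ceil(std::log(1e-12) / std::log(root_p));
        if (cap < Lh) Lh = cap;
      }
      // lag-1 seeds are the coefficients of (c1, c2) in c_{t-1} itself
      double a_k = gamma1, a_k1 = 1.0;   // a_{-1} = 1
      double b_k = gamma2, b_k1 = 0.0;   // b_{-1} = 0
      double z_k = A * s_ref[t], z_k1 = 0.0;
      for (int k = 0; k < Lh; ++k) {
        if (k > 0) {
          const double a_new = gamma1 * a_k + gamma2 * a_k1;
          const double b_new = gamma1 * b_k + gamma2 * b_k1;
          const double z_new = gamma1 * z_k + gamma2 * z_k1 +
                               A * s_ref[t + k];
          a_k1 = a_k; a_k = a_new;
          b_k1 = b_k; b_k = b_new;
          z_k1 = z_k; z_k = z_new;
        }
        const double r_k = F[t + k] - b_ref[t + k] - z_k;
        Sra += r_k * a_k; Srb += r_k * b_k;
        Saa += a_k * a_k; Sab += a_k * b_k; Sbb += b_k * b_k;
      }
      const double half_prec = 0.5 / sigma2;
      for (int i = 0; i < N; ++i) {
        double sc = lw_prev[i];
        if (!single_state) sc += m.lW[Q[offp + i]][q_ref[t]];
        const double db = b_ref[t] - B[offp + i];
        sc += -0.5 * db * db / m.sb2dt;
        const double c1 = C[offp + i], c2 = CP[offp + i];
        sc -= half_prec * (Saa * c1 * c1 + 2 * Sab * c1 * c2 +
                           Sbb * c2 * c2 - 2 * (Sra * c1 + Srb * c2));
        as_scores[i] = sc;
      }
    }
    int J;
    if (!ancestor_sampling) {
      J = N - 1;  // plain particle Gibbs: keep the reference lineage intact
    } else {
      J = categorical_from_logs(as_scores);
    }
    if (J < 0) {  // all ancestor scores underflowed; fall back to weights
      ++n_as_fallback;
      std::vector<int> one;
      multinomial_resample(lw_prev, 1, one, su, scw);
      J = one[0];
    }

    for (int i = 0; i < N; ++i) {
      const int a = (i == N - 1) ? J : anc[i];
      const int q_prev = Q[offp + a];
      const double c_prev = C[offp + a], c_prev2 = CP[offp + a];
      const double b_prev = B[offp + a];
      double c_pred;
      const double logz = proposal_table(m, q_prev, c_prev, c_prev2, b_prev,
                                         F[t], lent, c_pred);
      if (!std::isfinite(logz))
        stop("optimal-proposal table underflowed at time index %d", t + 1);
      int q_new, s_new;
      double b_new, c_new;
      if (i == N - 1) {
        q_new = q_ref[t]; s_new = s_ref[t]; b_new = b_ref[t];
        c_new = c_pred + A * s_new;  // re-propagated through ancestor J
      } else {
        sample_qs(m, lent, qs_cw, q_new, s_new);
        c_new = c_pred + A * s_new;
        b_new = sample_baseline_draw(m, b_prev, c_new, F[t]);
      }
      double lw = logz;
      if (mutation == 1) lw *= 2.0;
      else if (mutation == 2) lw = -lw;
      Q[off + i] = q_new; S[off + i] = s_new; C[off + i] = c_new;
      CP[off + i] = c_prev; B[off + i] = b_new;
      ANC[off + i] = a;
      LW[off + i] = lw;
    }
  }

  // --- final draw and backtracking ---
  for (int i = 0; i < N; ++i) lw_prev[i] = LW[(size_t)(T - 1) * N + i];
  std::vector<int> pick;
  multinomial_resample(lw_prev, 1, pick, su, scw);
  int k = pick[0];

  IntegerVector q_out(T), s_out(T);
  NumericVector c_out(T), b_out(T);
  int idx = k;
  for (int t = T - 1; t >= 0; --t) {
    const size_t off = (size_t)t * N;
    q_out[t] = Q[off + idx];
    s_out[t] = S[off + idx];
    c_out[t] = C[off + idx];
    b_out[t] = B[off + idx];
    if (t > 0) idx = ANC[off + idx];
  }

  List out = List::create(
      _["q"] = q_out, _["s"] = s_out, _["c"] = c_out, _["b"] = b_out,
      _["n_ancestor_fallbacks"] = n_as_fallback);
  if (return_particles) {
    IntegerMatrix Qm(T, N), Sm(T, N), Am(T, N);
    NumericMatrix Cm(T, N), CPm(T, N), Bm(T, N), LWm(T, N);
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < N; ++i) {
        const size_t off = (size_t)t * N + i;
        Qm(t, i) = Q[off]; Sm(t, i) = S[off]; Am(t, i) = ANC[off];
        Cm(t, i) = C[off]; CPm(t, i) = CP[off]; Bm(t, i) = B[off];
        LWm(t, i) = LW[off];
      }
    out["particles"] = List::create(
        _["q"] = Qm, _["s"] = Sm, _["anc"] = Am, _["c"] = Cm,
        _["c_prev"] = CPm, _["b"] = Bm, _["logw"] = LWm);
  }
  return out;
}

//' @title Internal bootstrap particle filter (C++)
//' @description Plain bootstrap filter used to initialize the Gibbs sampler
//'   with a calcium-consistent reference trajectory.
//' @keywords internal
// [[Rcpp::export]]
List cpp_bootstrap_filter(NumericVector F, double dt, double r0, double r1,
                          double w01, double w10, double gamma1, double gamma2,
                          double A, double c0, double sigma2, double sigma2b,
                          int n_particles, bool single_state) {
  const int T = F.size();
  const int N = n_particles;
  Model m = make_model(dt, r0, r1, w01, w10, gamma1, gamma2, A, c0, sigma2,
                       sigma2b, 1, single_state);  // lpois unused here
  RNGScope scope;

  std::vector<int> Q((size_t)T * N), S((size_t)T * N), ANC((size_t)T * N, -1);
  std::vector<double> C((size_t)T * N), CP((size_t)T * N), B((size_t)T * N);
  std::vector<double> logw(N);
  std::vector<int> anc;
  std::vector<double> su, scw;

  const double p01 = w01 * dt, p10 = w10 * dt;
  for (int i = 0; i < N; ++i) {
    const int q1 = single_state ? 0 : (unif_rand() < 0.5 ? 0 : 1);
    const int s1 = (int)R::rpois(((q1 == 1) ? r1 : r0) * dt);
    const double b1 = norm_rand();
    const double c1 = c0 + A * s1;
    Q[i] = q1; S[i] = s1; B[i] = b1; C[i] = c1; CP[i] = 0.0;
    logw[i] = obs_logdens(m, F[0], c1, b1);
  }

  for (int t = 1; t < T; ++t) {
    const size_t off = (size_t)t * N, offp = (size_t)(t - 1) * N;
    multinomial_resample(logw, N, anc, su, scw);
    for (int i = 0; i < N; ++i) {
      const int a = anc[i];
      const int q_prev = Q[offp + a];
      int q_new;
      if (single_state) q_new = 0;
      else if (q_prev == 0) q_new = (unif_rand() < p01) ? 1 : 0;
      else q_new = (unif_rand() < p10) ? 0 : 1;
      const int s_new = (int)R::rpois(((q_new == 1) ? r1 : r0) * dt);
      const double c_new = gamma1 * C[offp + a] + gamma2 * CP[offp + a] +
                           A * s_new;
      const double b_new = B[offp + a] + std::sqrt(m.sb2dt) * norm_rand();
      Q[off + i] = q_new; S[off + i] = s_new; C[off + i] = c_new;
      CP[off + i] = C[offp + a]; B[off + i] = b_new; ANC[off + i] = a;
    }
    double mx = R_NegInf;
    std::vector<double> lw_new(N);
    for (int i = 0; i < N; ++i) {
      lw_new[i] = obs_logdens(m, F[t], C[off + i], B[off + i]);
      if (lw_new[i] > mx) mx = lw_new[i];
    }
    if (!std::isfinite(mx))
      return List::create(_["ok"] = false, _["t_fail"] = t + 1);
    logw = lw_new;
  }

  std::vector<int> pick;
  multinomial_resample(logw, 1, pick, su, scw);
  int idx = pick[0];
  IntegerVector q_out(T), s_out(T);
  NumericVector c_out(T), b_out(T);
  for (int t = T - 1; t >= 0; --t) {
    const size_t off = (size_t)t * N;
    q_out[t] = Q[off + idx];
    s_out[t] = S[off + idx];
    c_out[t] = C[off + idx];
    b_out[t] = B[off + idx];
    if (t > 0) idx = ANC[off + idx];
  }
  return List::create(_["ok"] = true, _["q"] = q_out, _["s"] = s_out,
                      _["c"] = c_out, _["b"] = b_out);
}
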