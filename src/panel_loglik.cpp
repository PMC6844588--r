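// Core numerics for interval-censored multistate panel data:
//  - intensity matrix construction from log-linear parameters
//  - transition probabilities via eigendecomposition of Q (Pade fallback)
//  - log-likelihood and analytic gradient over a cohort of intervals
//  - continuous-time trajectory simulation with age-frozen micro-steps
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Parameter layout: theta = (log_baseline[1..K], beta[k=1..K, c=1..C] row-major).
// Transition k runs trans(k,0) -> trans(k,1) (0-based states); the absorbing
// state has no outgoing transitions by construction of `trans`.

static vec rates_at(const vec& theta, const imat& trans, const rowvec& z) {
  const int K = trans.n_rows, C = z.n_elem;
  vec q(K);
  for (int k = 0; k < K; ++k) {
    double lq = theta[k];
    for (int c = 0; c < C; ++c) lq += theta[K + k * C + c] * z[c];
    // guard against optimizer line-search excursions: 1000/person-year is
    // far beyond any plausible transition rate
    q[k] = std::exp(std::min(lq, std::log(1000.0)));
  }
  return q;
}

// inversion-free scaling-and-squaring Taylor exponential; robust for the
// (possibly defective) intensity matrices where the eigen route is refused
static mat safe_expm(const mat& M) {
  const double nrm = norm(M, "inf");
  int s = 0;
  if (nrm > 0.5 && std::isfinite(nrm)) {
    s = (int) std::ceil(std::log2(nrm / 0.5));
  }
  mat T = M / std::pow(2.0, s);
  mat term = eye(M.n_rows, M.n_cols);
  mat acc = eye(M.n_rows, M.n_cols);
  for (int i = 1; i <= 40; ++i) {
    term = term * T / (double) i;
    acc += term;
    if (norm(term, "inf") < 1e-17) break;
  }
  for (int i = 0; i < s; ++i) acc = acc * acc;
  return acc;
}

static mat q_to_Q(const vec& q, const imat& trans, int S) {
  mat Q(S, S, fill::zeros);
  for (unsigned k = 0; k < trans.n_rows; ++k) {
    Q(trans(k, 0), trans(k, 1)) += q[k];
    Q(trans(k, 0), trans(k, 0)) -= q[k];
  }
  return Q;
}

// P(dt) and, if wanted, T(k, t) = dP(r, target_t)/d log_baseline_k evaluated
// with a unit multiplier (covariate scaling applied by the caller).
// Eigendecomposition route: P = V diag(exp(lam dt)) V^{-1};
// dP = V (G o Phi) V^{-1} with G = V^{-1} dQ V and divided differences Phi.
// Falls back to scaling-and-squaring plus block-matrix Frechet derivatives
// when Q is (near-)defective.
static void interval_derivs(const mat& Q, const vec& q, const imat& trans,
                            double dt, int r, const uvec& targets,
                            bool want_grad, mat& P, mat& T) {
  const int S = Q.n_rows, K = trans.n_rows, nt = targets.n_elem;
  bool ok = false;
  cx_vec lam;
  cx_mat V;
  if (eig_gen(lam, V, Q)) {
    double scale = std::max(1.0, arma::abs(lam).max());
    double gap = datum::inf;
    for (int i = 0; i < S; ++i)
      for (int j = i + 1; j < S; ++j)
        gap = std::min(gap, std::abs(lam[i] - lam[j]));
    if (gap > 1e-6 * scale && rcond(V) > 1e-9) ok = true;
    if (ok) {
      cx_mat Vinv = inv(V);
      cx_vec E = exp(lam * dt);
      P = real(V * diagmat(E) * Vinv);
      if (want_grad) {
        cx_mat Phi(S, S);
        for (int i = 0; i < S; ++i)
          for (int j = 0; j < S; ++j)
            Phi(i, j) = (i == j) ? dt * E[i] : (E[i] - E[j]) / (lam[i] - lam[j]);
        T.set_size(K, nt);
        for (int k = 0; k < K; ++k) {
          const int kf = trans(k, 0), kt = trans(k, 1);
          cx_vec alpha(S);
          for (int i = 0; i < S; ++i) alpha[i] = V(r, i) * Vinv(i, kf);
          cx_vec aPhi = Phi.st() * alpha; // aPhi[j] = sum_i alpha_i Phi_ij
          for (int t = 0; t < nt; ++t) {
            const int s = targets[t];
            cx_double acc(0.0, 0.0);
            for (int j = 0; j < S; ++j)
              acc += aPhi[j] * (V(kt, j) - V(kf, j)) * Vinv(j, s);
            T(k, t) = q[k] * acc.real();
          }
        }
      }
      return;
    }
  }
  // defective / ill-conditioned Q: dense fallback
  P = safe_expm(Q * dt);
  if (want_grad) {
    T.set_size(K, nt);
    for (int k = 0; k < K; ++k) {
      const int kf = trans(k, 0), kt = trans(k, 1);
      mat dQ(S, S, fill::zeros);
      dQ(kf, kt) += q[k];
      dQ(kf, kf) -= q[k];
      mat B(2 * S, 2 * S, fill::zeros);
      B.submat(0, 0, S - 1, S - 1) = Q;
      B.submat(S, S, 2 * S - 1, 2 * S - 1) = Q;
      B.submat(0, S, S - 1, 2 * S - 1) = dQ;
      mat F = safe_expm(B * dt);
      for (int t = 0; t < nt; ++t) T(k, t) = F(r, S + targets[t]);
    }
  }
}

// Interval table `ivl` columns (0-based codes): subject, type (0 = panel
// observation pair, 1 = exact death after last living observation),
// from-state r, to-state s (ignored for deaths). Z holds the covariate row
// used for the interval's frozen Q; Zd the row used for the death intensity
// factor (equal to Z's row for non-death intervals).
// [[Rcpp::export]]
Rcpp::List cohort_loglik_cpp(const arma::vec& theta, const arma::imat& trans,
                             int S, const arma::mat& Z, const arma::mat& Zd,
                             const arma::imat& ivl, const arma::vec& dt,
                             int n_subj, bool want_grad) {
  const int K = trans.n_rows, C = Z.n_cols, n = ivl.n_rows;
  const int npar = K + K * C;
  const int death = S - 1;
  vec ll(n_subj, fill::zeros);
  vec grad(npar, fill::zeros);
  int bad_row = -1, bad_r = -1, bad_s = -1;
  mat P, T;
  uvec living(S - 1);
  for (int j = 0; j < S - 1; ++j) living[j] = j;

  for (int i = 0; i < n; ++i) {
    const int subj = ivl(i, 0), type = ivl(i, 1), r = ivl(i, 2), s = ivl(i, 3);
    const rowvec z = Z.row(i);
    const vec q = rates_at(theta, trans, z);
    const mat Q = q_to_Q(q, trans, S);
    if (type == 0) {
      uvec tg(1); tg[0] = (unsigned) s;
      interval_derivs(Q, q, trans, dt[i], r, tg, want_grad, P, T);
      double p = P(r, s);
      if (!(p > 0.0)) {
        ll[subj] = -datum::inf;
        if (bad_row < 0) { bad_row = i; bad_r = r; bad_s = s; }
        continue;
      }
      ll[subj] += std::log(p);
      if (want_grad) {
        for (int k = 0; k < K; ++k) {
          const double g = T(k, 0) / p;
          grad[k] += g;
          for (int c = 0; c < C; ++c) grad[K + k * C + c] += g * z[c];
        }
      }
    } else {
      // exact death time, unknown state at death:
      // L = sum_{j living} P_{r j}(dt) * q_{j,death}(z_d)
      const rowvec zd = Zd.row(i);
      const vec qd = rates_at(theta, trans, zd);
      interval_derivs(Q, q, trans, dt[i], r, living, want_grad, P, T);
      double L = 0.0;
      vec qjD(S - 1, fill::zeros);
      ivec kD(S - 1); kD.fill(-1);
      for (int k = 0; k < K; ++k)
        if (trans(k, 1) == death) { qjD[trans(k, 0)] = qd[k]; kD[trans(k, 0)] = k; }
      for (int j = 0; j < S - 1; ++j) L += P(r, j) * qjD[j];
      if (!(L > 0.0)) {
        ll[subj] = -datum::inf;
        if (bad_row < 0) { bad_row = i; bad_r = r; bad_s = death; }
        continue;
      }
      ll[subj] += std::log(L);
      if (want_grad) {
        for (int k = 0; k < K; ++k) {
          double dL = 0.0;
          for (int j = 0; j < S - 1; ++j) dL += T(k, j) * qjD[j];
          const double g = dL / L;
          grad[k] += g;
          for (int c = 0; c < C; ++c) grad[K + k * C + c] += g * z[c];
        }
        for (int j = 0; j < S - 1; ++j) {
          if (kD[j] < 0 || qjD[j] <= 0.0) continue;
          const double g = P(r, j) * qjD[j] / L;
          grad[kD[j]] += g;
          for (int c = 0; c < C; ++c) grad[K + kD[j] * C + c] += g * zd[c];
        }
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("ll_subj") = ll, Rcpp::Named("grad") = grad,
      Rcpp::Named("bad_row") = bad_row + 1, Rcpp::Named("bad_from") = bad_r,
      Rcpp::Named("bad_to") = bad_s);
}

// Age-resolved covariate row: fixed covariates plus the age terms.
// age_form: 0 none, 1 log-linear (z = age - center), 2 bands (indicators for
// [b1, b2) and [b2, inf)); age_cols are 0-based design column indices.
static rowvec design_row(const rowvec& zfixed, int age_form,
                         const ivec& age_cols, const vec& age_pars,
                         double age) {
  rowvec z = zfixed;
  if (age_form == 1) {
    z[age_cols[0]] = age - age_pars[0];
  } else if (age_form == 2) {
    z[age_cols[0]] = (age >= age_pars[0] && age < age_pars[1]) ? 1.0 : 0.0;
    z[age_cols[1]] = (age >= age_pars[1]) ? 1.0 : 0.0;
  }
  return z;
}

// One continuous-time trajectory; Q frozen over micro-steps of width `micro`
// to honour age dependence. Returns rows (age, state) starting at entry,
// one row per state change, final row at death or horizon.
// [[Rcpp::export]]
arma::mat sim_path_cpp(const arma::vec& theta, const arma::imat& trans, int S,
                       const arma::rowvec& zfixed, int age_form,
                       const arma::ivec& age_cols, const arma::vec& age_pars,
                       double age0, int state0, double horizon, double micro) {
  const int death = S - 1;
  std::vector<double> ages; std::vector<int> states;
  double age = age0; int st = state0;
  ages.push_back(age); states.push_back(st);
  const double end_age = age0 + horizon;
  while (age < end_age && st != death) {
    const rowvec z = design_row(zfixed, age_form, age_cols, age_pars, age);
    const vec q = rates_at(theta, trans, z);
    double lam = 0.0;
    for (unsigned k = 0; k < trans.n_rows; ++k)
      if (trans(k, 0) == st) lam += q[k];
    const double step_end = std::min(age + micro, end_age);
    if (lam <= 0.0) { age = step_end; continue; }
    const double wait = R::exp_rand() / lam;
    if (age + wait >= step_end) { age = step_end; continue; }
    age += wait;
    double u = unif_rand() * lam, cum = 0.0;
    int nxt = st;
    for (unsigned k = 0; k < trans.n_rows; ++k) {
      if (trans(k, 0) != st) continue;
      cum += q[k];
      if (u <= cum) { nxt = trans(k, 1); break; }
    }
    st = nxt;
    ages.push_back(age); states.push_back(st);
  }
  if (st != death && (ages.empty() || ages.back() < end_age)) {
    ages.push_back(end_age); states.push_back(st);
  }
  mat out(ages.size(), 2);
  for (size_t i = 0; i < ages.size(); ++i) {
    out(i, 0) = ages[i];
    out(i, 1) = states[i];
  }
  return out;
}

// Batch simulation oracle: per-trajectory occupancy time in each state over
// [age0, age0 + horizon], the state occupied at age0 + record_t (death code
// once dead), and the death age (NaN if alive at horizon).
// [[Rcpp::export]]
Rcpp::List sim_batch_cpp(int n, const arma::vec& theta, const arma::imat& trans,
                         int S, const arma::rowvec& zfixed, int age_form,
                         const arma::ivec& age_cols, const arma::vec& age_pars,
                         double age0, int state0, double horizon, double micro,
                         double record_t) {
  const int death = S - 1;
  mat occ(n, S, fill::zeros);
  ivec state_at(n);
  vec death_age(n); death_age.fill(datum::nan);
  const double rec_age = age0 + record_t;
  for (int i = 0; i < n; ++i) {
    mat path = sim_path_cpp(theta, trans, S, zfixed, age_form, age_cols,
                            age_pars, age0, state0, horizon, micro);
    int st_rec = (int) path(path.n_rows - 1, 1);
    for (unsigned e = 0; e + 1 < path.n_rows; ++e) {
      const int st = (int) path(e, 1);
      occ(i, st) += path(e + 1, 0) - path(e, 0);
      if (path(e, 0) <= rec_age && rec_age < path(e + 1, 0)) st_rec = st;
    }
    const int st_end = (int) path(path.n_rows - 1, 1);
    if (st_end == death) {
      death_age[i] = path(path.n_rows - 1, 0);
      if (rec_age >= death_age[i]) st_rec = death;
    }
    state_at[i] = st_rec;
  }
  return Rcpp::List::create(Rcpp::Named("occupancy") = occ,
                            Rcpp::Named("state_at") = state_at,
                            Rcpp::Named("death_age") = death_age);
}
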