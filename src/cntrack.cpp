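#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// One-interval site probabilities.  a = kA*C + kD; lamE through expm1 so the
// expression is well conditioned down to C -> 0; lamF via the identity
// lamF = lamE + exp(-a dt).  C == 0 is the analytic pure-desorption limit.
// ---------------------------------------------------------------------------
static inline void lam_pair(double kA, double kD, double dt, double C,
                            double &lamF, double &lamE) {
  if (C <= 0.0) {
    lamE = 0.0;
    lamF = std::exp(-kD * dt);
    return;
  }
  double a = kA * C + kD;
  double decay = std::exp(-a * dt);
  lamE = kA * C / a * (-std::expm1(-a * dt));
  lamF = lamE + decay;
}

// d lamE / dC, analytic.  For C > 0:
//   kA * [ kD*(1-exp(-a dt))/a^2 + kA*C*dt*exp(-a dt)/a ]
// with the C == 0 limits kA*(1-exp(-kD dt))/kD (kD>0) and kA*dt (kD=0).
static inline double dlamE_dC(double kA, double kD, double dt, double C) {
  if (C <= 0.0) {
    if (kD <= 0.0) return kA * dt;
    return kA * (-std::expm1(-kD * dt)) / kD;
  }
  double a = kA * C + kD;
  double g = -std::expm1(-a * dt);
  return kA * (g * kD / (a * a) + kA * C * dt * std::exp(-a * dt) / a);
}

struct ChooseTab {
  int NT;
  std::vector<double> tab; // (NT+1) x (NT+1)
  explicit ChooseTab(int NT_) : NT(NT_), tab((NT_ + 1) * (NT_ + 1), 0.0) {
    for (int n = 0; n <= NT; ++n) {
      at(n, 0) = 1.0;
      for (int k = 1; k <= n; ++k)
        at(n, k) = (k == n) ? 1.0 : at(n - 1, k - 1) + at(n - 1, k);
    }
  }
  double &at(int n, int k) { return tab[n * (NT + 1) + k]; }
  double cat(int n, int k) const { return tab[n * (NT + 1) + k]; }
};

// Power tables p[i] = lam^i etc., filled up to NT.
static inline void fill_pows(double lam, int NT, double *p, double *q) {
  p[0] = 1.0; q[0] = 1.0;
  double om = 1.0 - lam;
  for (int i = 1; i <= NT; ++i) {
    p[i] = p[i - 1] * lam;
    q[i] = q[i - 1] * om;
  }
}

// Exact convolved-binomial pmf value Pr(count = y | y_prev), given the
// power tables for lamF/lamE of the current particle.
static inline double conv_pmf_val(int y, int yp, int NT, const ChooseTab &ch,
                                  const double *pF, const double *qF,
                                  const double *pE, const double *qE) {
  int ne = NT - yp;
  int mlo = y - ne; if (mlo < 0) mlo = 0;
  int mhi = (y < yp) ? y : yp;
  double s = 0.0;
  for (int m = mlo; m <= mhi; ++m) {
    s += ch.cat(yp, m) * pF[m] * qF[yp - m] *
         ch.cat(ne, y - m) * pE[y - m] * qE[ne - (y - m)];
  }
  return s;
}

// Sum over sensors of log p(y_j | y_prev_j, C) for one concentration value.
static inline double loglik_sensors(double C, const int *y, const int *yp,
                                    int Ns, double kA, double kD, int NT,
                                    double dt, const ChooseTab &ch,
                                    double *pF, double *qF,
                                    double *pE, double *qE) {
  double lamF, lamE;
  lam_pair(kA, kD, dt, C, lamF, lamE);
  fill_pows(lamF, NT, pF, qF);
  fill_pows(lamE, NT, pE, qE);
  // product in linear space with one final log; pmf factors are >= ~1e-6
  // in normal operation, so underflow (guarded) needs an extreme mismatch
  double prod = 1.0;
  for (int j = 0; j < Ns; ++j)
    prod *= conv_pmf_val(y[j], yp[j], NT, ch, pF, qF, pE, qE);
  if (prod > 1e-300) return std::log(prod);
  double ll = 0.0; // near-underflow: accumulate in log space instead
  for (int j = 0; j < Ns; ++j) {
    double p = conv_pmf_val(y[j], yp[j], NT, ch, pF, qF, pE, qE);
    if (p <= 0.0) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_loglik_exact(NumericVector C, IntegerVector y,
                               IntegerVector y_prev, double kA, double kD,
                               int NT, double dt) {
  int M = C.size(), Ns = y.size();
  if (y_prev.size() != Ns) stop("y and y_prev lengths differ");
  if (Ns == 0) return NumericVector(M); // no sensors: flat likelihood
  ChooseTab ch(NT);
  std::vector<double> pF(NT + 1), qF(NT + 1), pE(NT + 1), qE(NT + 1);
  NumericVector out(M);
  for (int i = 0; i < M; ++i)
    out[i] = loglik_sensors(C[i], &y[0], &y_prev[0], Ns, kA, kD, NT, dt,
                            ch, pF.data(), qF.data(), pE.data(), qE.data());
  return out;
}

// ---------------------------------------------------------------------------
// Kinetic Monte Carlo (exact SSA) count sampler: within each interval the
// occupancy jumps with propensities kA*C*(NT-y) (up) and kD*y (down).
// Uses R's RNG (exp_rand / unif_rand), so set.seed() reproduces runs.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_ssa_counts(NumericVector C, int y0, double kA, double kD,
                             int NT, double dt) {
  int K = C.size();
  IntegerVector out(K);
  int y = y0;
  for (int k = 0; k < K; ++k) {
    double t = 0.0, Ck = C[k];
    for (;;) {
      double a_up = kA * Ck * (NT - y);
      double a_dn = kD * y;
      double rate = a_up + a_dn;
      if (rate <= 0.0) break;
      t += exp_rand() / rate;
      if (t > dt) break;
      if (unif_rand() * rate < a_up) ++y; else --y;
    }
    out[k] = y;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Linearized observation at evaluation point Ceval (clipped at 0 upstream):
//   h_j    = NT*lamE + yp_j*exp(-a dt)
//   Cbar_j = NT*dlamE - yp_j*kA*dt*exp(-a dt)
//   r_j    = yp_j*lamF*(1-lamF) + (NT-yp_j)*lamE*(1-lamE)
// ---------------------------------------------------------------------------
static inline void linearize_one(double Ceval, int yp, double kA, double kD,
                                 int NT, double dt,
                                 double &h, double &cbar, double &r) {
  double lamF, lamE;
  lam_pair(kA, kD, dt, Ceval, lamF, lamE);
  double decay = lamF - lamE; // exp(-a dt)
  double dE = dlamE_dC(kA, kD, dt, Ceval);
  h = NT * lamE + yp * decay;
  cbar = NT * dE - yp * kA * dt * decay;
  r = yp * lamF * (1.0 - lamF) + (NT - yp) * lamE * (1.0 - lamE);
}

struct KFUp { double mean, P, ll; bool updated; };

// Modeled per-sensor measurement variances are floored at this value (in
// squared molecule counts).  The moment-matched Gaussian variance vanishes
// at the C = 0 boundary while the observation Jacobian does not, which
// would make the Kalman gain unbounded there; 1e-3 is the exact-model
// variance of an empty sensor about 1 uM from the boundary and an order of
// magnitude below the variance at typical operating occupancies.
#define OBS_VAR_FLOOR 1e-3

// Scalar-state information-form measurement update over Ns sensors with
// diagonal R (algebraically identical to the innovation-form gain), plus
// the Gaussian innovation log-likelihood log N(nu; 0, Cbar P Cbar' + R).
static KFUp kf_update_one(double mp, double Pp, const int *y, const int *yp,
                          int Ns, double kA, double kD, int NT, double dt) {
  double Ceval = mp > 0.0 ? mp : 0.0;
  std::vector<double> h(Ns), c(Ns), r(Ns);
  for (int j = 0; j < Ns; ++j)
    linearize_one(Ceval, yp[j], kA, kD, NT, dt, h[j], c[j], r[j]);
  KFUp out;
  if (Ns == 0) {
    out.mean = mp; out.P = Pp; out.ll = 0.0; out.updated = false;
    return out;
  }
  double Ic = 0.0, Iy = 0.0, qsum = 0.0, logdetR = 0.0;
  for (int j = 0; j < Ns; ++j) {
    double rj = r[j] > OBS_VAR_FLOOR ? r[j] : OBS_VAR_FLOOR;
    double nu = (double)y[j] - h[j];
    Ic += c[j] * c[j] / rj;
    Iy += c[j] * nu / rj;
    qsum += nu * nu / rj;
    logdetR += std::log(rj);
  }
  double d = 1.0 + Pp * Ic;
  double Pk = Pp / d;
  out.mean = mp + Pk * Iy;
  out.P = Pk;
  out.ll = -0.5 * (Ns * std::log(2.0 * M_PI) + logdetR + std::log(d) +
                   (qsum - Pp * Iy * Iy / d));
  out.updated = true;
  return out;
}

// [[Rcpp::export]]
List cpp_kf_run(IntegerMatrix counts, IntegerVector y0, double kA, double kD,
                int NT, double dt, double q, double init_mean,
                double init_var) {
  int K = counts.nrow(), Ns = counts.ncol();
  NumericVector mean(K), var(K), est(K);
  std::vector<int> yp(Ns), yk(Ns);
  for (int j = 0; j < Ns; ++j) yp[j] = y0[j];
  double m = init_mean, P = init_var;
  for (int k = 0; k < K; ++k) {
    P += q; // predict: random walk, A = 1
    for (int j = 0; j < Ns; ++j) yk[j] = counts(k, j);
    KFUp up = kf_update_one(m, P, yk.data(), yp.data(), Ns, kA, kD, NT, dt);
    m = up.mean; P = up.P;
    mean[k] = m; var[k] = P; est[k] = m > 0.0 ? m : 0.0;
    yp = yk;
  }
  return List::create(_["mean"] = mean, _["var"] = var, _["est"] = est);
}

// [[Rcpp::export]]
List cpp_gpb2_run(IntegerMatrix counts, IntegerVector y0, double kA,
                  double kD, int NT, double dt, NumericMatrix Pi,
                  NumericVector qs, double init_mean, double init_var,
                  NumericVector p0) {
  int K = counts.nrow(), Ns = counts.ncol(), H = Pi.nrow();
  NumericVector est(K), var(K), mean_raw(K);
  NumericMatrix rprob(K, H);
  std::vector<double> m(H, init_mean), P(H, init_var), p(p0.begin(), p0.end());
  std::vector<int> yp(Ns), yk(Ns);
  for (int j = 0; j < Ns; ++j) yp[j] = y0[j];
  std::vector<double> bm(H * H), bP(H * H), lw(H * H), a(H * H);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Ns; ++j) yk[j] = counts(k, j);
    double L = R_NegInf;
    for (int g = 0; g < H; ++g) {
      for (int h = 0; h < H; ++h) {
        int b = g * H + h;
        if (p[g] <= 0.0 || Pi(g, h) <= 0.0) {
          lw[b] = R_NegInf; bm[b] = m[g]; bP[b] = P[g] + qs[h];
          continue;
        }
        KFUp up = kf_update_one(m[g], P[g] + qs[h], yk.data(), yp.data(),
                                Ns, kA, kD, NT, dt);
        bm[b] = up.mean; bP[b] = up.P;
        lw[b] = std::log(p[g]) + std::log(Pi(g, h)) + up.ll;
        if (lw[b] > L) L = lw[b];
      }
    }
    long double tot = 0.0;
    if (R_finite(L)) {
      for (int b = 0; b < H * H; ++b) {
        a[b] = R_finite(lw[b]) ? std::exp(lw[b] - L) : 0.0;
        tot += a[b];
      }
    } else { // all branch likelihoods vanished: transition-prior fallback
      for (int g = 0; g < H; ++g)
        for (int h = 0; h < H; ++h) { a[g * H + h] = p[g] * Pi(g, h); tot += a[g * H + h]; }
    }
    for (int b = 0; b < H * H; ++b) a[b] /= (double)tot;
    // merge per current regime
    double xk = 0.0;
    std::vector<double> mh(H), Ph(H), pn(H, 0.0);
    for (int h = 0; h < H; ++h)
      for (int g = 0; g < H; ++g) pn[h] += a[g * H + h];
    for (int h = 0; h < H; ++h) {
      if (pn[h] > 0.0) {
        double mm = 0.0;
        for (int g = 0; g < H; ++g) mm += a[g * H + h] / pn[h] * bm[g * H + h];
        double PP = 0.0;
        for (int g = 0; g < H; ++g) {
          double d = bm[g * H + h] - mm;
          PP += a[g * H + h] / pn[h] * (bP[g * H + h] + d * d);
        }
        mh[h] = mm; Ph[h] = PP;
      } else { // unreachable regime: carry the predicted prior mixture
        double mm = 0.0;
        for (int g = 0; g < H; ++g) mm += p[g] * m[g];
        double PP = 0.0;
        for (int g = 0; g < H; ++g) {
          double d = m[g] - mm;
          PP += p[g] * (P[g] + qs[h] + d * d);
        }
        mh[h] = mm; Ph[h] = PP;
      }
      xk += pn[h] * mh[h];
    }
    double Pk = 0.0;
    for (int h = 0; h < H; ++h) {
      double d = mh[h] - xk;
      Pk += pn[h] * (Ph[h] + d * d);
    }
    for (int h = 0; h < H; ++h) { m[h] = mh[h]; P[h] = Ph[h]; p[h] = pn[h]; rprob(k, h) = pn[h]; }
    mean_raw[k] = xk; var[k] = Pk; est[k] = xk > 0.0 ? xk : 0.0;
    yp = yk;
  }
  return List::create(_["mean"] = mean_raw, _["var"] = var, _["est"] = est,
                      _["regime_probs"] = rprob);
}

// ---------------------------------------------------------------------------
// Particle filters.  All RNG goes through R's stream (rnorm/unif_rand) in a
// fixed call order, so the pure-R reference engines reproduce the C++ paths
// draw-for-draw under the same seed.
// ---------------------------------------------------------------------------

static void systematic_resample(std::vector<double> &x,
                                const std::vector<double> &w, int M) {
  // resample M values from (x, w) in place; one uniform draw
  double u = unif_rand() / M;
  std::vector<double> nx(M);
  long double cum = 0.0;
  int j = -1, n = (int)x.size();
  for (int i = 0; i < M; ++i) {
    double pos = u + (double)i / M;
    while (cum < pos && j + 1 < n) { ++j; cum += w[j]; }
    nx[i] = x[j < 0 ? 0 : j];
  }
  x.swap(nx);
  x.resize(M);
}

// Scalar draws through R::rnorm consume the RNG stream exactly like a
// vectorized rnorm(n, mean, sd) call in R (no draw when sd == 0).
static void draw_initial(std::vector<double> &x, int M, double mean,
                         double sd) {
  for (int i = 0; i < M; ++i) x[i] = R::rnorm(mean, sd);
  for (;;) { // redraw negatives (truncation at 0 by resampling)
    std::vector<int> neg;
    for (int i = 0; i < M; ++i) if (x[i] < 0.0) neg.push_back(i);
    if (neg.empty()) break;
    for (int idx : neg) x[idx] = R::rnorm(mean, sd);
  }
}

// normalize log-weights in place into w; returns total mass before
// normalization (0 if all -inf)
static double norm_weights(const std::vector<double> &lw,
                           std::vector<double> &w) {
  int M = (int)lw.size();
  double mx = R_NegInf;
  for (int i = 0; i < M; ++i) if (lw[i] > mx) mx = lw[i];
  if (!R_finite(mx)) { return 0.0; }
  long double s = 0.0;
  for (int i = 0; i < M; ++i) { w[i] = std::exp(lw[i] - mx); s += w[i]; }
  for (int i = 0; i < M; ++i) w[i] /= (double)s;
  return (double)s;
}

static double ess_of(const std::vector<double> &w) {
  long double s2 = 0.0;
  for (double wi : w) { double p2 = wi * wi; s2 += p2; }
  return (double)(1.0 / s2);
}

// [[Rcpp::export]]
List cpp_pf_run(IntegerMatrix counts, IntegerVector y0, double kA, double kD,
                int NT, double dt, double q, int M, double init_mean,
                double init_var, double ess_frac, IntegerVector snap_steps) {
  int K = counts.nrow(), Ns = counts.ncol();
  ChooseTab ch(NT);
  std::vector<double> pF(NT + 1), qF(NT + 1), pE(NT + 1), qE(NT + 1);
  std::vector<double> x(M), w(M, 1.0 / M), lw(M);
  draw_initial(x, M, init_mean, std::sqrt(init_var));
  NumericVector est(K);
  LogicalVector resampled(K);
  int n_flat = 0;
  double sd = std::sqrt(q);
  std::vector<int> yp(Ns), yk(Ns);
  for (int j = 0; j < Ns; ++j) yp[j] = y0[j];
  List snaps;
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Ns; ++j) yk[j] = counts(k, j);
    for (int i = 0; i < M; ++i) x[i] = std::fabs(x[i] + R::rnorm(0.0, sd));
    for (int i = 0; i < M; ++i)
      lw[i] = std::log(w[i]) +
        loglik_sensors(x[i], yk.data(), yp.data(), Ns, kA, kD, NT, dt,
                       ch, pF.data(), qF.data(), pE.data(), qE.data());
    if (norm_weights(lw, w) == 0.0) { // likelihood underflow
      ++n_flat;
      std::fill(w.begin(), w.end(), 1.0 / M);
    }
    if (ess_of(w) < ess_frac * M) {
      systematic_resample(x, w, M);
      std::fill(w.begin(), w.end(), 1.0 / M);
      resampled[k] = true;
      long double s = 0.0;
      for (int i = 0; i < M; ++i) s += x[i];
      est[k] = (double)(s / M);
    } else {
      long double s = 0.0;
      for (int i = 0; i < M; ++i) s += w[i] * x[i];
      est[k] = (double)s;
    }
    for (int s_ = 0; s_ < snap_steps.size(); ++s_) {
      if (snap_steps[s_] == k + 1) {
        snaps.push_back(List::create(_["step"] = k + 1,
                                     _["values"] = NumericVector(x.begin(), x.end()),
                                     _["weights"] = NumericVector(w.begin(), w.end())));
      }
    }
    yp = yk;
  }
  return List::create(_["est"] = est, _["resampled"] = resampled,
                      _["n_flat"] = n_flat, _["snapshots"] = snaps);
}

// [[Rcpp::export]]
List cpp_pfmcmc_run(IntegerMatrix counts, IntegerVector y0, double kA,
                    double kD, int NT, double dt, NumericMatrix Pi,
                    NumericVector qs, int M, double init_mean,
                    double init_var, NumericVector p0, double ess_frac) {
  int K = counts.nrow(), Ns = counts.ncol(), H = Pi.nrow();
  ChooseTab ch(NT);
  std::vector<double> pF(NT + 1), qF(NT + 1), pE(NT + 1), qE(NT + 1);
  std::vector<std::vector<double>> X(H), W(H);
  std::vector<double> p(p0.begin(), p0.end());
  for (int h = 0; h < H; ++h) {
    X[h].assign(M, init_mean);
    W[h].assign(M, 1.0 / M);
    if (p[h] > 0.0) draw_initial(X[h], M, init_mean, std::sqrt(init_var));
  }
  NumericVector est(K);
  LogicalVector any_resample(K);
  NumericMatrix rprob(K, H);
  int n_fallback = 0;
  std::vector<int> yp(Ns), yk(Ns);
  for (int j = 0; j < Ns; ++j) yp[j] = y0[j];
  int B = H * H;
  std::vector<std::vector<double>> bx(B), bv(B);
  std::vector<double> logm(B), A(B), bmean(B);
  std::vector<bool> active(B);
  std::vector<double> lwv(M);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < Ns; ++j) yk[j] = counts(k, j);
    double L = R_NegInf;
    for (int g = 0; g < H; ++g) {
      for (int h = 0; h < H; ++h) {
        int b = g * H + h;
        active[b] = (p[g] > 0.0 && Pi(g, h) > 0.0);
        logm[b] = R_NegInf;
        if (!active[b]) continue;
        bx[b].resize(M); bv[b].resize(M);
        double sdh = std::sqrt(qs[h]);
        for (int i = 0; i < M; ++i)
          bx[b][i] = std::fabs(X[g][i] + R::rnorm(0.0, sdh));
        for (int i = 0; i < M; ++i)
          lwv[i] = std::log(W[g][i]) +
            loglik_sensors(bx[b][i], yk.data(), yp.data(), Ns, kA, kD, NT,
                           dt, ch, pF.data(), qF.data(), pE.data(), qE.data());
        double mass = norm_weights(lwv, bv[b]);
        if (mass > 0.0) {
          double mx = R_NegInf;
          for (int i = 0; i < M; ++i) if (lwv[i] > mx) mx = lwv[i];
          logm[b] = std::log(p[g]) + std::log(Pi(g, h)) + mx + std::log(mass);
        } else {
          bv[b] = W[g]; // transition-prior fallback for this branch
        }
        if (logm[b] > L) L = logm[b];
      }
    }
    long double tot = 0.0;
    if (R_finite(L)) {
      for (int b = 0; b < B; ++b) {
        A[b] = (active[b] && R_finite(logm[b])) ? std::exp(logm[b] - L) : 0.0;
        tot += A[b];
      }
    } else { // every branch underflowed: weight by the transition prior
      ++n_fallback;
      for (int g = 0; g < H; ++g)
        for (int h = 0; h < H; ++h) {
          int b = g * H + h;
          A[b] = active[b] ? p[g] * Pi(g, h) : 0.0;
          tot += A[b];
        }
    }
    for (int b = 0; b < B; ++b) A[b] /= (double)tot;
    double xk = 0.0;
    for (int b = 0; b < B; ++b) {
      if (!active[b] || A[b] <= 0.0) { bmean[b] = 0.0; continue; }
      long double s = 0.0;
      for (int i = 0; i < M; ++i) s += bv[b][i] * bx[b][i];
      bmean[b] = (double)s;
      xk += A[b] * bmean[b];
    }
    est[k] = xk;
    // collapse the H^2 branches to one population per current regime
    std::vector<double> pn(H, 0.0);
    for (int h = 0; h < H; ++h)
      for (int g = 0; g < H; ++g) pn[h] += A[g * H + h];
    for (int h = 0; h < H; ++h) {
      rprob(k, h) = pn[h];
      if (pn[h] <= 0.0) continue; // unreachable: keep previous population
      int gdom = -1, ncontrib = 0;
      double fmax = 0.0;
      for (int g = 0; g < H; ++g) {
        double f = A[g * H + h] / pn[h];
        if (f > 0.0) ++ncontrib;
        if (f > fmax) { fmax = f; gdom = g; }
      }
      if (ncontrib == 1 || fmax > 1.0 - 1e-12) {
        int b = gdom * H + h;
        std::vector<double> nx = bx[b], nv = bv[b];
        if (ess_of(nv) < ess_frac * M) {
          systematic_resample(nx, nv, M);
          std::fill(nv.begin(), nv.end(), 1.0 / M);
          any_resample[k] = true;
        }
        X[h] = nx; W[h] = nv;
      } else {
        std::vector<double> cx, cw;
        cx.reserve(ncontrib * M); cw.reserve(ncontrib * M);
        for (int g = 0; g < H; ++g) {
          int b = g * H + h;
          double f = A[b] / pn[h];
          if (f <= 0.0) continue;
          for (int i = 0; i < M; ++i) { cx.push_back(bx[b][i]); cw.push_back(f * bv[b][i]); }
        }
        systematic_resample(cx, cw, M);
        X[h] = cx;
        W[h].assign(M, 1.0 / M);
        any_resample[k] = true;
      }
    }
    p = pn;
    yp = yk;
  }
  return List::create(_["est"] = est, _["regime_probs"] = rprob,
                      _["resampled"] = any_resample,
                      _["n_fallback"] = n_fallback);
}
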