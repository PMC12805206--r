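// Adaptive Metropolis-within-Gibbs sampler for the two-group ordinal MRF
// pseudoposterior.
//
// The pseudolikelihood is evaluated on deduplicated response patterns with
// multiplicities, which is exact and keeps per-update cost proportional to
// the number of distinct patterns rather than the number of respondents.
// Per-group "rest scores" R[u, i] = sum_j sigma_g(i, j) * x_u(j) are cached
// and updated incrementally when an interaction parameter changes, and the
// per-variable log-pseudolikelihood contributions are cached so each
// Metropolis proposal only evaluates the affected variables.
//
// All randomness comes from R's RNG (unif_rand / norm_rand), so runs are
// reproducible via set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int MAX_CATS = 64;  // categories per variable (m + 1)

// log pseudolikelihood contribution of variable i in one group.
// mu points at thresholds for categories 1..m (baseline 0 fixed at zero).
// If shift_j >= 0, the rest score of variable i is evaluated as if
// sigma(i, shift_j) had changed by shift_coef (proposal evaluation without
// touching the cache).
static double logpl_var(const IntegerMatrix& U, const IntegerVector& w,
                        const std::vector<double>& R, int i,
                        const double* mu, int m,
                        int shift_j, double shift_coef) {
  const int n = U.nrow();
  if (n == 0) return 0.0;
  double total = 0.0;
  const double* Rcol = R.data() + (size_t)i * n;
  const int* Ui = &U(0, i);
  const int* Uj = (shift_j >= 0) ? &U(0, shift_j) : nullptr;
  // fast path: denominator 1 + sum_c exp(mu_c) * exp(r)^c with one exp and
  // one log per row, safe when the largest exponent stays well below
  // overflow; otherwise a max-subtracted fallback
  double emu[MAX_CATS], mumax = 0.0;
  for (int c = 0; c < m; ++c) {
    emu[c] = std::exp(mu[c]);
    if (std::fabs(mu[c]) > mumax) mumax = std::fabs(mu[c]);
  }
  double tmp[MAX_CATS + 1];
  for (int u = 0; u < n; ++u) {
    double r = Rcol[u];
    if (Uj) r += shift_coef * Uj[u];
    const int x = Ui[u];
    if (m * std::fabs(r) + mumax < 600.0) {
      const double er = std::exp(r);
      double pw = 1.0, s = 1.0;
      for (int c = 0; c < m; ++c) {
        pw *= er;
        s += emu[c] * pw;
      }
      const double num = (x == 0) ? 0.0 : mu[x - 1] + x * r;
      total += w[u] * (num - std::log(s));
    } else {
      double mx = 0.0;
      tmp[0] = 0.0;
      double cr = 0.0;
      for (int c = 1; c <= m; ++c) {
        cr += r;
        double v = mu[c - 1] + cr;
        tmp[c] = v;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int c = 0; c <= m; ++c) s += std::exp(tmp[c] - mx);
      total += w[u] * (tmp[x] - mx - std::log(s));
    }
  }
  return total;
}

static inline double log_thr_prior(double mu, double a, double b) {
  double log1pe = (mu > 0 ? mu : 0.0) + std::log1p(std::exp(-std::fabs(mu)));
  return a * mu - (a + b) * log1pe;  // - log B(a,b) constant omitted (MH ratio)
}

static inline double log_cauchy_d(double x, double s) {
  double z = x / s;
  return -std::log(M_PI * s) - std::log1p(z * z);
}

static inline double log_dnorm(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) -
         0.5 * (x / sd) * (x / sd);
}

struct Move {
  int type;  // 0 thrA scalar, 1 thrB (block in collapse, scalar in free),
             // 2 sigma scalar, 3 sigdiff scalar, 4 thr flip, 5 sig flip
  int i;
  int j;     // partner variable (types 2,3,5) or category index (types 0,
             // and 1 in free mode); -1 otherwise
};

// [[Rcpp::export]]
List cpp_run_sampler(IntegerMatrix U1, IntegerVector w1,
                     IntegerMatrix U2, IntegerVector w2,
                     IntegerVector ncat1, IntegerVector ncat2,
                     int threshold_mode,  // 0 collapse, 1 free
                     bool selection,
                     double thr_a, double thr_b, double sigma_scale,
                     double thr_diff_scale, double sig_diff_scale,
                     int thr_ind_type, double thr_ind_p1, double thr_ind_p2,
                     int sig_ind_type, double sig_ind_p1, double sig_ind_p2,
                     int n_main, int n_burn1, int n_burn2,
                     double target_accept, double decay,
                     double sd_min, double sd_max,
                     bool upd_thr, bool upd_sigma,
                     bool upd_thr_diff, bool upd_sig_diff,
                     NumericMatrix init_thrA, NumericMatrix init_thrB,
                     NumericMatrix init_sigma, NumericMatrix init_sigdiff,
                     IntegerVector init_thr_ind, IntegerVector init_sig_ind) {
  const int p = ncat1.size();
  const bool collapse = (threshold_mode == 0);
  const int m1max = max(ncat1) - 1, m2max = max(ncat2) - 1;
  const int maxm = std::max(m1max, m2max);
  if (maxm + 1 > MAX_CATS) stop("too many categories per variable");
  const int npairs = p * (p - 1) / 2;
  std::vector<int> mi1(p), mi2(p);
  for (int i = 0; i < p; ++i) { mi1[i] = ncat1[i] - 1; mi2[i] = ncat2[i] - 1; }

  // parameter state (copies of initials)
  NumericMatrix thrA = clone(init_thrA);   // collapse: overall; free: group 1
  NumericMatrix thrB = clone(init_thrB);   // collapse: diffs;  free: group 2
  NumericMatrix sigma = clone(init_sigma);
  NumericMatrix sigdiff = clone(init_sigdiff);
  std::vector<int> thr_ind(p), sig_ind(npairs);
  for (int i = 0; i < p; ++i) thr_ind[i] = init_thr_ind[i];
  for (int k = 0; k < npairs; ++k) sig_ind[k] = init_sig_ind[k];

  // pair index
  std::vector<std::vector<int> > pidx(p, std::vector<int>(p, -1));
  {
    int k = 0;
    for (int i = 0; i < p - 1; ++i)
      for (int j = i + 1; j < p; ++j) { pidx[i][j] = pidx[j][i] = k; ++k; }
  }

  const int n1 = U1.nrow(), n2 = U2.nrow();

  // group-level rest scores under group-specific sigmas
  std::vector<double> R1((size_t)n1 * p, 0.0), R2((size_t)n2 * p, 0.0);
  auto sig_g = [&](int g, int i, int j) {
    double d = sigdiff(i, j);
    return sigma(i, j) + (g == 1 ? -0.5 : 0.5) * d;
  };
  for (int i = 0; i < p; ++i) {
    for (int u = 0; u < n1; ++u) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) if (j != i) s += sig_g(1, i, j) * U1(u, j);
      R1[(size_t)i * n1 + u] = s;
    }
    for (int u = 0; u < n2; ++u) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) if (j != i) s += sig_g(2, i, j) * U2(u, j);
      R2[(size_t)i * n2 + u] = s;
    }
  }

  // effective group thresholds for variable i into buf (categories 1..m)
  auto mu_group = [&](int g, int i, double* buf) {
    if (collapse) {
      for (int c = 0; c < mi1[i]; ++c)
        buf[c] = thrA(i, c) + (g == 1 ? -0.5 : 0.5) * thrB(i, c);
    } else {
      if (g == 1) for (int c = 0; c < mi1[i]; ++c) buf[c] = thrA(i, c);
      else        for (int c = 0; c < mi2[i]; ++c) buf[c] = thrB(i, c);
    }
  };

  // cached per-variable log-pseudolikelihood contributions
  std::vector<double> cur1(p), cur2(p);
  double mubuf[MAX_CATS], mubuf2[MAX_CATS];
  for (int i = 0; i < p; ++i) {
    mu_group(1, i, mubuf);
    cur1[i] = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
    mu_group(2, i, mubuf);
    cur2[i] = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
  }

  // proposal sds and acceptance counters
  NumericMatrix sd_thrA(p, maxm), sd_thrB(p, std::max(maxm, 1));
  NumericVector sd_thrB_block(p, 1.0);  // collapse-mode block proposal sd
  NumericVector sd_sigma(npairs, 1.0), sd_sigdiff(npairs, 1.0);
  std::fill(sd_thrA.begin(), sd_thrA.end(), 1.0);
  std::fill(sd_thrB.begin(), sd_thrB.end(), 1.0);
  NumericVector acc(6, 0.0), att(6, 0.0);  // per move type, main phase only

  auto adapt = [&](double& sd, bool accepted, int t) {
    double step = std::pow((double)t, -decay);
    double ls = std::log(sd) + step * ((accepted ? 1.0 : 0.0) - target_accept);
    sd = std::exp(ls);
    if (sd < sd_min) sd = sd_min;
    if (sd > sd_max) sd = sd_max;
  };

  auto prior_odds_flip = [&](int type_code, double a1, double a2,
                             int k_other, int K) {
    if (type_code == 0) return a1 / (1.0 - a1);            // Bernoulli(pi)
    return (a1 + k_other) / (a2 + (K - 1) - k_other);      // beta-Bernoulli
  };

  // build the move list (content fixed; order reshuffled every iteration)
  std::vector<Move> moves;
  if (upd_thr) {
    for (int i = 0; i < p; ++i)
      for (int c = 0; c < mi1[i]; ++c) moves.push_back({0, i, c});
    if (!collapse)
      for (int i = 0; i < p; ++i)
        for (int c = 0; c < mi2[i]; ++c) moves.push_back({1, i, c});
  }
  if (collapse && upd_thr_diff) {
    for (int i = 0; i < p; ++i) {
      moves.push_back({1, i, -1});                       // RW block
      if (selection) moves.push_back({4, i, -1});        // indicator flip
    }
  }
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j) {
      if (upd_sigma) moves.push_back({2, i, j});
      if (upd_sig_diff) {
        moves.push_back({3, i, j});
        if (selection) moves.push_back({5, i, j});
      }
    }
  }
  const int n_moves = (int)moves.size();
  std::vector<int> order(n_moves);
  for (int k = 0; k < n_moves; ++k) order[k] = k;

  // output storage (main phase)
  NumericMatrix out_thrA(n_main, p * maxm), out_thrB(n_main, p * maxm);
  NumericMatrix out_sigma(n_main, npairs), out_sigdiff(n_main, npairs);
  IntegerMatrix out_thr_ind(n_main, p), out_sig_ind(n_main, npairs);

  const int n_burn = n_burn1 + n_burn2;
  const int n_total = n_burn + n_main;

  for (int iter = 1; iter <= n_total; ++iter) {
    const bool in_burn = iter <= n_burn;
    const bool inds_active = selection && iter > n_burn1;
    // Fisher-Yates reshuffle of the sweep order
    for (int k = n_moves - 1; k > 0; --k) {
      int r = (int)std::floor(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(order[k], order[r]);
    }

    for (int s = 0; s < n_moves; ++s) {
      const Move& mv = moves[order[s]];
      const int ty = mv.type, i = mv.i;
      bool accepted = false;

      if (ty == 0 || (ty == 1 && !collapse)) {
        // scalar threshold update (overall, or a group's own in free mode)
        const int c = mv.j;
        NumericMatrix& M = (ty == 0) ? thrA : thrB;
        double& sd = (ty == 0) ? sd_thrA(i, c) : sd_thrB(i, c);
        const double old = M(i, c);
        const double prop = old + sd * norm_rand();
        double lr = log_thr_prior(prop, thr_a, thr_b) -
                    log_thr_prior(old, thr_a, thr_b);
        double n1new = cur1[i], n2new = cur2[i];
        M(i, c) = prop;
        if (ty == 0 && collapse) {  // overall threshold touches both groups
          mu_group(1, i, mubuf);
          n1new = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
          mu_group(2, i, mubuf);
          n2new = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
          lr += (n1new - cur1[i]) + (n2new - cur2[i]);
        } else if (ty == 0) {       // free mode, group 1 only
          mu_group(1, i, mubuf);
          n1new = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
          lr += n1new - cur1[i];
        } else {                    // free mode, group 2 only
          mu_group(2, i, mubuf);
          n2new = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
          lr += n2new - cur2[i];
        }
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          accepted = true;
          cur1[i] = n1new; cur2[i] = n2new;
        } else {
          M(i, c) = old;
        }
        if (in_burn) adapt(sd, accepted, iter);

      } else if (ty == 1) {
        // collapse mode: joint RW on the threshold-difference vector
        if (selection && thr_ind[i] == 0) continue;
        const int m = mi1[i];
        double old[MAX_CATS];
        double& sd = sd_thrB_block[i];
        double lr = 0.0;
        for (int c = 0; c < m; ++c) {
          old[c] = thrB(i, c);
          double prop = old[c] + sd * norm_rand();
          lr += log_cauchy_d(prop, thr_diff_scale) -
                log_cauchy_d(old[c], thr_diff_scale);
          thrB(i, c) = prop;
        }
        mu_group(1, i, mubuf);
        double n1new = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
        mu_group(2, i, mubuf);
        double n2new = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
        lr += (n1new - cur1[i]) + (n2new - cur2[i]);
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          accepted = true;
          cur1[i] = n1new; cur2[i] = n2new;
        } else {
          for (int c = 0; c < m; ++c) thrB(i, c) = old[c];
        }
        if (in_burn) adapt(sd, accepted, iter);

      } else if (ty == 2 || ty == 3) {
        // scalar RW on an interaction (overall or difference)
        const int j = mv.j, k = pidx[i][j];
        if (ty == 3 && selection && sig_ind[k] == 0) continue;
        NumericMatrix& M = (ty == 2) ? sigma : sigdiff;
        double& sd = (ty == 2) ? sd_sigma[k] : sd_sigdiff[k];
        const double old = M(i, j);
        const double prop = old + sd * norm_rand();
        const double d = prop - old;
        const double d1 = (ty == 2) ? d : -0.5 * d;   // shift in group 1 sigma
        const double d2 = (ty == 2) ? d : 0.5 * d;
        double lr = (ty == 2)
          ? log_cauchy_d(prop, sigma_scale) - log_cauchy_d(old, sigma_scale)
          : log_cauchy_d(prop, sig_diff_scale) - log_cauchy_d(old, sig_diff_scale);
        mu_group(1, i, mubuf);
        double n1i = logpl_var(U1, w1, R1, i, mubuf, mi1[i], j, d1);
        mu_group(1, j, mubuf);
        double n1j = logpl_var(U1, w1, R1, j, mubuf, mi1[j], i, d1);
        mu_group(2, i, mubuf);
        double n2i = logpl_var(U2, w2, R2, i, mubuf, mi2[i], j, d2);
        mu_group(2, j, mubuf);
        double n2j = logpl_var(U2, w2, R2, j, mubuf, mi2[j], i, d2);
        lr += (n1i - cur1[i]) + (n1j - cur1[j]) +
              (n2i - cur2[i]) + (n2j - cur2[j]);
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          accepted = true;
          M(i, j) = M(j, i) = prop;
          for (int u = 0; u < n1; ++u) {
            R1[(size_t)i * n1 + u] += d1 * U1(u, j);
            R1[(size_t)j * n1 + u] += d1 * U1(u, i);
          }
          for (int u = 0; u < n2; ++u) {
            R2[(size_t)i * n2 + u] += d2 * U2(u, j);
            R2[(size_t)j * n2 + u] += d2 * U2(u, i);
          }
          cur1[i] = n1i; cur1[j] = n1j; cur2[i] = n2i; cur2[j] = n2j;
        }
        if (in_burn) adapt(sd, accepted, iter);

      } else if (ty == 4) {
        // pairwise flip of a threshold-difference indicator + its vector
        if (!inds_active) continue;
        const int m = mi1[i];
        int k_other = 0;
        for (int q = 0; q < p; ++q) if (q != i) k_other += thr_ind[q];
        const double podds = prior_odds_flip(thr_ind_type, thr_ind_p1,
                                             thr_ind_p2, k_other, p);
        const double sd = sd_thrB_block[i];
        double old[MAX_CATS];
        for (int c = 0; c < m; ++c) old[c] = thrB(i, c);
        double lr;
        if (thr_ind[i] == 0) {
          // propose inclusion: draw the vector from the tuned proposal
          double lprop = 0.0, lslab = 0.0;
          for (int c = 0; c < m; ++c) {
            double v = sd * norm_rand();
            thrB(i, c) = v;
            lprop += log_dnorm(v, sd);
            lslab += log_cauchy_d(v, thr_diff_scale);
          }
          mu_group(1, i, mubuf);
          double n1new = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
          mu_group(2, i, mubuf);
          double n2new = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
          lr = (n1new - cur1[i]) + (n2new - cur2[i]) +
               lslab - lprop + std::log(podds);
          if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
            accepted = true;
            thr_ind[i] = 1; cur1[i] = n1new; cur2[i] = n2new;
          } else {
            for (int c = 0; c < m; ++c) thrB(i, c) = old[c];
          }
        } else {
          // propose exclusion: set the vector to exact zero
          double lprop = 0.0, lslab = 0.0;
          for (int c = 0; c < m; ++c) {
            lprop += log_dnorm(old[c], sd);
            lslab += log_cauchy_d(old[c], thr_diff_scale);
            thrB(i, c) = 0.0;
          }
          mu_group(1, i, mubuf);
          double n1new = logpl_var(U1, w1, R1, i, mubuf, mi1[i], -1, 0.0);
          mu_group(2, i, mubuf);
          double n2new = logpl_var(U2, w2, R2, i, mubuf, mi2[i], -1, 0.0);
          lr = (n1new - cur1[i]) + (n2new - cur2[i]) +
               lprop - lslab - std::log(podds);
          if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
            accepted = true;
            thr_ind[i] = 0; cur1[i] = n1new; cur2[i] = n2new;
          } else {
            for (int c = 0; c < m; ++c) thrB(i, c) = old[c];
          }
        }

      } else {
        // pairwise flip of an interaction-difference indicator + parameter
        if (!inds_active) continue;
        const int j = mv.j, k = pidx[i][j];
        int k_other = 0;
        for (int q = 0; q < npairs; ++q) if (q != k) k_other += sig_ind[q];
        const double podds = prior_odds_flip(sig_ind_type, sig_ind_p1,
                                             sig_ind_p2, k_other, npairs);
        const double sd = sd_sigdiff[k];
        const double old = sigdiff(i, j);
        double prop, lr;
        if (sig_ind[k] == 0) prop = sd * norm_rand();
        else prop = 0.0;
        const double d = prop - old;
        const double d1 = -0.5 * d, d2 = 0.5 * d;
        mu_group(1, i, mubuf);
        double n1i = logpl_var(U1, w1, R1, i, mubuf, mi1[i], j, d1);
        mu_group(1, j, mubuf);
        double n1j = logpl_var(U1, w1, R1, j, mubuf, mi1[j], i, d1);
        mu_group(2, i, mubuf);
        double n2i = logpl_var(U2, w2, R2, i, mubuf, mi2[i], j, d2);
        mu_group(2, j, mubuf);
        double n2j = logpl_var(U2, w2, R2, j, mubuf, mi2[j], i, d2);
        lr = (n1i - cur1[i]) + (n1j - cur1[j]) +
             (n2i - cur2[i]) + (n2j - cur2[j]);
        if (sig_ind[k] == 0) {
          lr += log_cauchy_d(prop, sig_diff_scale) - log_dnorm(prop, sd) +
                std::log(podds);
        } else {
          lr += log_dnorm(old, sd) - log_cauchy_d(old, sig_diff_scale) -
                std::log(podds);
        }
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          accepted = true;
          sigdiff(i, j) = sigdiff(j, i) = prop;
          sig_ind[k] = 1 - sig_ind[k];
          for (int u = 0; u < n1; ++u) {
            R1[(size_t)i * n1 + u] += d1 * U1(u, j);
            R1[(size_t)j * n1 + u] += d1 * U1(u, i);
          }
          for (int u = 0; u < n2; ++u) {
            R2[(size_t)i * n2 + u] += d2 * U2(u, j);
            R2[(size_t)j * n2 + u] += d2 * U2(u, i);
          }
          cur1[i] = n1i; cur1[j] = n1j; cur2[i] = n2i; cur2[j] = n2j;
        }
      }

      if (!in_burn) { att[ty] += 1.0; if (accepted) acc[ty] += 1.0; }
    }

    if (!in_burn) {
      const int t = iter - n_burn - 1;
      for (int i = 0; i < p; ++i) {
        for (int c = 0; c < maxm; ++c) {
          out_thrA(t, i + p * c) = (c < mi1[i]) ? thrA(i, c) : NA_REAL;
          int mB = collapse ? mi1[i] : mi2[i];
          out_thrB(t, i + p * c) = (c < mB) ? thrB(i, c) : NA_REAL;
        }
        out_thr_ind(t, i) = collapse ? thr_ind[i] : NA_INTEGER;
      }
      for (int i = 0, k = 0; i < p - 1; ++i) {
        for (int j = i + 1; j < p; ++j, ++k) {
          out_sigma(t, k) = sigma(i, j);
          out_sigdiff(t, k) = sigdiff(i, j);
          out_sig_ind(t, k) = sig_ind[k];
        }
      }
    }
  }

  NumericVector acc_rate(6);
  for (int ty = 0; ty < 6; ++ty)
    acc_rate[ty] = att[ty] > 0 ? acc[ty] / att[ty] : NA_REAL;

  return List::create(
    _["thrA"] = out_thrA, _["thrB"] = out_thrB,
    _["sigma"] = out_sigma, _["sigdiff"] = out_sigdiff,
    _["thr_ind"] = out_thr_ind, _["sig_ind"] = out_sig_ind,
    _["acceptance_rates"] = acc_rate,
    _["final_sd"] = List::create(
      _["thrA"] = sd_thrA, _["thrB"] = sd_thrB,
      _["thrB_block"] = sd_thrB_block,
      _["sigma"] = sd_sigma, _["sigdiff"] = sd_sigdiff));
}
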