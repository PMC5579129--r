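// Season engine: fish-school turnover, intermittent agent search, local
// sensing, lambda-weighted information sharing, sequential harvest
// settlement, and TAC/IFQ season closure on a periodic 2-D domain.
//
// All randomness goes through R's RNG (unif_rand/exp_rand), so a single
// set.seed() in R makes a whole season bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrapL(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;  // guard against floating round-up
  return x;
}

// minimal-image signed component difference, input in (-L, L)
static inline double mimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double tdist2(double ax, double ay, double bx, double by, double L) {
  double dx = mimg(bx - ax, L);
  double dy = mimg(by - ay, L);
  return dx * dx + dy * dy;
}

// Fisher-Yates permutation of 0..n-1 using R's RNG
static void rperm(std::vector<int> &idx) {
  const int n = (int)idx.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// spawned-school size under the depletion rule
static inline double spawn_fish(bool depletion, double F_n, double P, double cum) {
  if (!depletion) return F_n;
  double frac = (P - cum) / P;
  if (frac < 0) frac = 0;
  return F_n * frac;
}

// Modes
enum { SEARCHING = 0, TRAVELING = 1, HARVESTING = 2, RETIRED = 3 };

// [[Rcpp::export]]
List cpp_run_season(List cfg) {
  const double L       = as<double>(cfg["L"]);
  const int n_schools  = as<int>(cfg["n_schools"]);
  const double F_s     = as<double>(cfg["F_s"]);
  const double F_n     = as<double>(cfg["F_n"]);
  const double tau_l   = as<double>(cfg["tau_l"]);
  const double dt      = as<double>(cfg["dt"]);
  const int N          = as<int>(cfg["n_agents"]);
  const double v       = as<double>(cfg["v"]);
  const double r_sense = as<double>(cfg["r_sense"]);
  const double C_q     = as<double>(cfg["C_q"]);
  const double turn_rate = as<double>(cfg["turn_rate"]);
  const double lam     = as<double>(cfg["lam"]);
  const int mgmt       = as<int>(cfg["mgmt"]);   // 0 = TAC, 1 = IFQ
  const double T       = as<double>(cfg["T"]);
  const double t_max   = as<double>(cfg["t_max"]);
  const bool depletion = as<bool>(cfg["depletion"]);
  const double P       = depletion ? as<double>(cfg["P"]) : R_PosInf;

  const double p_death = 1.0 - std::exp(-dt / tau_l);
  const double p_turn  = 1.0 - std::exp(-turn_rate * dt);
  const double detect2 = (r_sense + F_s) * (r_sense + F_s);
  const double Fs2     = F_s * F_s;
  const double step_len = v * dt;
  const double T_i     = T / N;
  const double eps     = 1e-9;

  // schools
  std::vector<double> sx(n_schools), sy(n_schools), sfish(n_schools);
  double cum = 0.0;
  for (int s = 0; s < n_schools; ++s) {
    sx[s] = unif_rand() * L;
    sy[s] = unif_rand() * L;
    sfish[s] = spawn_fish(depletion, F_n, P, cum);
  }

  // agents
  std::vector<double> ax(N), ay(N), hx(N), hy(N), catch_tot(N, 0.0);
  std::vector<int> mode(N, SEARCHING), tgt(N, -1);
  std::vector<double> tx(N, 0.0), ty(N, 0.0);
  std::vector<double> retire_t(N, NA_REAL);
  for (int i = 0; i < N; ++i) {
    ax[i] = unif_rand() * L;
    ay[i] = unif_rand() * L;
    double th = unif_rand() * 2.0 * M_PI;
    hx[i] = std::cos(th);
    hy[i] = std::sin(th);
  }

  std::vector<double> catch_steps;   // row-per-step, N per row
  std::vector<int> active_steps;
  std::vector<double> stock_trace;
  catch_steps.reserve(4096 * N);
  active_steps.reserve(4096 * N);
  stock_trace.reserve(4096);

  std::vector<int> sensed(N, -1);
  std::vector<int> order(N);
  double t = 0.0;
  int terminated = 0;  // 1 = quota closure, 2 = t_max cap
  const int max_steps = (int)std::ceil(t_max / dt + 1e-9);

  for (int step = 0; step < max_steps; ++step) {
    // activity mask: active = not retired at start of step
    for (int i = 0; i < N; ++i)
      active_steps.push_back(mode[i] == RETIRED ? 0 : 1);

    // (1) school turnover: empties and Poisson deaths are replaced
    for (int s = 0; s < n_schools; ++s) {
      bool dead = (sfish[s] <= 0.0) || (unif_rand() < p_death);
      if (dead) {
        sx[s] = unif_rand() * L;
        sy[s] = unif_rand() * L;
        sfish[s] = spawn_fish(depletion, F_n, P, cum);
        for (int i = 0; i < N; ++i) {
          if (tgt[i] == s && mode[i] != RETIRED) {
            mode[i] = SEARCHING;
            tgt[i] = -1;
          }
        }
      }
    }

    // (2) sensing: nearest school with edge within the sensory zone
    for (int i = 0; i < N; ++i) {
      sensed[i] = -1;
      if (mode[i] == RETIRED || mode[i] == HARVESTING) continue;
      double best = detect2;
      for (int s = 0; s < n_schools; ++s) {
        if (sfish[s] <= 0.0) continue;
        double d2 = tdist2(ax[i], ay[i], sx[s], sy[s], L);
        if (d2 <= best) {
          best = d2;
          sensed[i] = s;
        }
      }
    }

    // (3) information: each harvester broadcasts its school location to
    // each searching/traveling agent with probability lam per step;
    // local sensing beats the inbox; nearest source wins ties by sender id
    if (lam > 0.0) {
      for (int h = 0; h < N; ++h) {
        if (mode[h] != HARVESTING) continue;
        int s = tgt[h];
        for (int j = 0; j < N; ++j) {
          if (j == h) continue;
          if (mode[j] != SEARCHING && mode[j] != TRAVELING) continue;
          if (sensed[j] >= 0) continue;
          if (unif_rand() < lam) {
            double d2 = tdist2(ax[j], ay[j], sx[s], sy[s], L);
            if (mode[j] == SEARCHING || tgt[j] < 0) {
              mode[j] = TRAVELING;
              tgt[j] = s; tx[j] = sx[s]; ty[j] = sy[s];
            } else {
              // already traveling: switch only to a strictly nearer source
              double cur2 = tdist2(ax[j], ay[j], tx[j], ty[j], L);
              if (d2 < cur2) {
                tgt[j] = s; tx[j] = sx[s]; ty[j] = sy[s];
              }
            }
          }
        }
      }
    }
    // travelers whose targeted school vanished or emptied resume searching
    for (int i = 0; i < N; ++i) {
      if (mode[i] == TRAVELING && (tgt[i] < 0 || sfish[tgt[i]] <= 0.0)) {
        mode[i] = SEARCHING;
        tgt[i] = -1;
      }
    }

    // (4) movement
    for (int i = 0; i < N; ++i) {
      if (mode[i] == RETIRED || mode[i] == HARVESTING) continue;
      double gx, gy;
      bool directed = false;
      if (sensed[i] >= 0) {           // approach sensed school center
        gx = sx[sensed[i]]; gy = sy[sensed[i]];
        directed = true;
      } else if (mode[i] == TRAVELING) {
        gx = tx[i]; gy = ty[i];
        directed = true;
      } else {
        gx = gy = 0.0;
      }
      if (directed) {
        double dx = mimg(gx - ax[i], L), dy = mimg(gy - ay[i], L);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= step_len) {
          ax[i] = wrapL(gx, L);
          ay[i] = wrapL(gy, L);
        } else {
          ax[i] = wrapL(ax[i] + step_len * dx / d, L);
          ay[i] = wrapL(ay[i] + step_len * dy / d, L);
        }
        if (sensed[i] >= 0) {
          double d2 = tdist2(ax[i], ay[i], sx[sensed[i]], sy[sensed[i]], L);
          if (d2 <= Fs2) {            // inside the school: start harvesting
            mode[i] = HARVESTING;
            tgt[i] = sensed[i];
          } else if (mode[i] == TRAVELING) {
            // sensing overrides the remembered location
            tgt[i] = sensed[i]; tx[i] = sx[sensed[i]]; ty[i] = sy[sensed[i]];
          }
        } else if (mode[i] == TRAVELING) {
          // arrived at the shared location but found nothing
          double d2 = tdist2(ax[i], ay[i], tx[i], ty[i], L);
          if (d2 <= 1e-18) {
            mode[i] = SEARCHING;
            tgt[i] = -1;
          }
        }
      } else {
        if (turn_rate > 0.0 && unif_rand() < p_turn) {
          double th = unif_rand() * 2.0 * M_PI;
          hx[i] = std::cos(th);
          hy[i] = std::sin(th);
        }
        ax[i] = wrapL(ax[i] + step_len * hx[i], L);
        ay[i] = wrapL(ay[i] + step_len * hy[i], L);
      }
    }

    // (5) harvest settlement in randomized agent order, capped by stock
    std::vector<double> inc(N, 0.0);
    for (int i = 0; i < N; ++i) order[i] = i;
    rperm(order);
    for (int k = 0; k < N; ++k) {
      int i = order[k];
      if (mode[i] != HARVESTING) continue;
      int s = tgt[i];
      double take = C_q * dt;
      if (take > sfish[s]) take = sfish[s];
      sfish[s] -= take;
      inc[i] = take;
      catch_tot[i] += take;
      cum += take;
      if (sfish[s] <= 0.0) {
        sfish[s] = 0.0;
        mode[i] = SEARCHING;
        tgt[i] = -1;
      }
    }
    for (int i = 0; i < N; ++i) catch_steps.push_back(inc[i]);
    stock_trace.push_back(cum);
    t += dt;

    // (6) management
    if (mgmt == 1) {
      bool all_ret = true;
      for (int i = 0; i < N; ++i) {
        if (mode[i] != RETIRED) {
          if (catch_tot[i] >= T_i - eps) {
            mode[i] = RETIRED;
            tgt[i] = -1;
            retire_t[i] = t;
          } else {
            all_ret = false;
          }
        }
      }
      if (all_ret) { terminated = 1; break; }
    } else {
      if (cum >= T - eps) { terminated = 1; break; }
    }
    if (t >= t_max - 1e-12) { terminated = 2; break; }
  }
  if (terminated == 0) terminated = 2;

  const int n_steps = (int)stock_trace.size();
  NumericMatrix catch_mat(n_steps, N);
  LogicalMatrix active_mat(n_steps, N);
  for (int r = 0; r < n_steps; ++r)
    for (int i = 0; i < N; ++i) {
      catch_mat(r, i) = catch_steps[(size_t)r * N + i];
      active_mat(r, i) = active_steps[(size_t)r * N + i] == 1;
    }

  return List::create(
    _["catch"] = catch_mat,
    _["active"] = active_mat,
    _["retire_time"] = NumericVector(retire_t.begin(), retire_t.end()),
    _["catch_total"] = NumericVector(catch_tot.begin(), catch_tot.end()),
    _["cumulative_harvest"] = cum,
    _["stock_trace"] = NumericVector(stock_trace.begin(), stock_trace.end()),
    _["duration"] = t,
    _["n_steps"] = n_steps,
    _["terminated_by"] = terminated == 1 ? "quota" : "t_max");
}

// Time until a lone intermittent searcher first senses a school, with
// school turnover active; one value per independent trial.
// [[Rcpp::export]]
NumericVector cpp_first_encounter(List cfg, double turn_rate, int n_trials,
                                  double max_time) {
  const double L       = as<double>(cfg["L"]);
  const int n_schools  = as<int>(cfg["n_schools"]);
  const double F_s     = as<double>(cfg["F_s"]);
  const double tau_l   = as<double>(cfg["tau_l"]);
  const double dt      = as<double>(cfg["dt"]);
  const double v       = as<double>(cfg["v"]);
  const double r_sense = as<double>(cfg["r_sense"]);

  const double p_death = std::isfinite(tau_l) ? 1.0 - std::exp(-dt / tau_l) : 0.0;
  const double p_turn  = 1.0 - std::exp(-turn_rate * dt);
  const double detect2 = (r_sense + F_s) * (r_sense + F_s);
  const double step_len = v * dt;

  NumericVector out(n_trials);
  std::vector<double> sx(n_schools), sy(n_schools);

  for (int trial = 0; trial < n_trials; ++trial) {
    for (int s = 0; s < n_schools; ++s) {
      sx[s] = unif_rand() * L;
      sy[s] = unif_rand() * L;
    }
    double x = unif_rand() * L, y = unif_rand() * L;
    double th = unif_rand() * 2.0 * M_PI;
    double hx = std::cos(th), hy = std::sin(th);
    double t = 0.0;
    bool found = false;
    for (int s = 0; s < n_schools && !found; ++s)
      found = tdist2(x, y, sx[s], sy[s], L) <= detect2;
    while (!found && t < max_time) {
      for (int s = 0; s < n_schools; ++s) {
        if (p_death > 0.0 && unif_rand() < p_death) {
          sx[s] = unif_rand() * L;
          sy[s] = unif_rand() * L;
        }
      }
      if (turn_rate > 0.0 && unif_rand() < p_turn) {
        th = unif_rand() * 2.0 * M_PI;
        hx = std::cos(th);
        hy = std::sin(th);
      }
      x = wrapL(x + step_len * hx, L);
      y = wrapL(y + step_len * hy, L);
      t += dt;
      for (int s = 0; s < n_schools && !found; ++s)
        found = tdist2(x, y, sx[s], sy[s], L) <= detect2;
    }
    out[trial] = t;
  }
  return out;
}
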