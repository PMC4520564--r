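#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid rate modifier; callers guarantee lp strictly inside (0, 1).
static inline double kfac(double lp, double center, double slope, double kmax) {
  return kmax / (1.0 + std::exp((center - lp) * slope));
}

static inline double rexp_rate(double rate) {
  // R's exponential generator has mean 1; scale by 1/rate.
  return R::exp_rand() / rate;
}

// Event-driven engine for a sequence of movement attempts with persistent,
// optionally adaptive, leadership tendencies.
//
// Each attempt: every agent draws an initiation time at rate k(L_i)/tau_o;
// the earliest wins and departs. Then, repeatedly, every non-departed agent
// draws a follow time at rate 1/tau_r (its own k, current departed count r,
// initiator included) and the initiator draws a cancel time at rate C_r; the
// earliest event is applied and all pending clocks are redrawn with the
// updated r (memorylessness makes redrawing equivalent to advancing).
// The attempt ends when everyone has departed (success) or the cancel clock
// fires first (failure). In adaptive mode the initiator's LT is then
// reinforced: L <- clip(L(1-lambda) + lambda*reward).
//
// Ties in event times are broken towards the lowest agent index (the cancel
// event carries the initiator's index) so runs are reproducible.
//
// [[Rcpp::export]]
List run_attempts_cpp(int n, int n_attempts, NumericVector lt0, List model,
                      List adapt, bool record_events) {
  const double tau_o = model["tau_o"], alpha_f = model["alpha_f"],
               beta_f = model["beta_f"], alpha_c = model["alpha_c"],
               gamma_c = model["gamma_c"], epsilon_c = model["epsilon_c"],
               slope = model["sigmoid_slope"], center = model["sigmoid_center"],
               kmax = model["k_max"];
  const double lambda = adapt["lambda_rate"], lt_min = adapt["lt_min"],
               lt_max = adapt["lt_max"], rw_s = adapt["reward_success"],
               rw_f = adapt["reward_failure"];
  const bool adaptive = adapt["adaptive"];

  std::vector<double> lt(lt0.begin(), lt0.end());
  std::vector<double> k_init(n), k_resp(n); // k(L) and k(1 - L) per agent
  for (int i = 0; i < n; ++i) {
    k_init[i] = kfac(lt[i], center, slope, kmax);
    k_resp[i] = kfac(1.0 - lt[i], center, slope, kmax);
  }

  IntegerVector initiator(n_attempts);
  LogicalVector success(n_attempts);
  IntegerVector final_departed(n_attempts);
  std::vector<int> chg_attempt, chg_agent;
  std::vector<double> chg_value;
  std::vector<int> ev_attempt, ev_kind, ev_agent; // kind: 0 init, 1 follow, 2 cancel
  std::vector<double> ev_time;

  std::vector<int> departed(n);

  for (int a = 0; a < n_attempts; ++a) {
    // Initiation competition: earliest clock wins, others are discarded.
    int init_id = 0;
    double t_min = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double t = rexp_rate(k_init[i] / tau_o);
      if (t < t_min) {
        t_min = t;
        init_id = i;
      }
    }
    std::fill(departed.begin(), departed.end(), 0);
    departed[init_id] = 1;
    int r = 1;
    double now = t_min;
    bool ok = true;
    if (record_events) {
      ev_attempt.push_back(a + 1);
      ev_kind.push_back(0);
      ev_agent.push_back(init_id + 1);
      ev_time.push_back(now);
    }

    while (r < n) {
      const double base_tau = alpha_f + beta_f * (double)(n - r) / (double)r;
      const double c_rate =
          k_resp[init_id] * alpha_c / (1.0 + std::pow(r / gamma_c, epsilon_c));
      double t_best = rexp_rate(c_rate);
      int who = init_id;
      int kind = 2;
      for (int j = 0; j < n; ++j) {
        if (departed[j]) continue;
        double t = rexp_rate(k_resp[j] / base_tau);
        if (t < t_best || (t == t_best && j < who)) {
          t_best = t;
          who = j;
          kind = 1;
        }
      }
      now += t_best;
      if (kind == 2) {
        ok = false;
        if (record_events) {
          ev_attempt.push_back(a + 1);
          ev_kind.push_back(2);
          ev_agent.push_back(init_id + 1);
          ev_time.push_back(now);
        }
        break;
      }
      departed[who] = 1;
      ++r;
      if (record_events) {
        ev_attempt.push_back(a + 1);
        ev_kind.push_back(1);
        ev_agent.push_back(who + 1);
        ev_time.push_back(now);
      }
    }

    initiator[a] = init_id + 1;
    success[a] = ok;
    final_departed[a] = r;

    if (adaptive) {
      const double reward = ok ? rw_s : rw_f;
      double v = lt[init_id] * (1.0 - lambda) + lambda * reward;
      v = std::min(std::max(v, lt_min), lt_max);
      if (v != lt[init_id]) {
        lt[init_id] = v;
        k_init[init_id] = kfac(v, center, slope, kmax);
        k_resp[init_id] = kfac(1.0 - v, center, slope, kmax);
        chg_attempt.push_back(a + 1);
        chg_agent.push_back(init_id + 1);
        chg_value.push_back(v);
      }
    }
  }

  List out = List::create(
      _["initiator_id"] = initiator, _["success"] = success,
      _["final_departed"] = final_departed,
      _["change_attempt"] = wrap(chg_attempt),
      _["change_agent"] = wrap(chg_agent),
      _["change_value"] = wrap(chg_value), _["final_lt"] = wrap(lt));
  if (record_events) {
    out["event_attempt"] = wrap(ev_attempt);
    out["event_kind"] = wrap(ev_kind);
    out["event_agent"] = wrap(ev_agent);
    out["event_time"] = wrap(ev_time);
  }
  return out;
}
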