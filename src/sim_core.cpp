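#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step simulation of the single-compartment detection configuration:
// n_aff synapse circuits drive a conveyor-clamped postsynaptic node, so each
// synapse's current is its conductance times a constant driving factor. The
// gate of each synapse charges linearly (DAC pulse) and discharges linearly;
// the conductance is exponential in the gate, so across one step it evolves
// by a multiplicative factor (tabulated per efficacy; partial pulse overlaps
// fall back to a direct exponential). Adaptive rectangular STDP updates the
// 4-bit efficacies from the exact event times.

// Fraction of the phase interval [p, p + dp) inside the duty window of each
// oscillator cycle (integral of the indicator frac(x) < duty).
static inline double on_fraction(double p, double dp, double duty) {
  if (dp <= 0.0) return 0.0;
  double a = std::floor(p) * duty + std::min(p - std::floor(p), duty);
  double q = p + dp;
  double b = std::floor(q) * duty + std::min(q - std::floor(q), duty);
  return (b - a) / dp;
}

// [[Rcpp::export]]
List sim_detect_cpp(IntegerVector ev_aff, NumericVector ev_time,
                    int n_aff, double duration, double dt,
                    double charge_rate, double discharge_rate,
                    double gate_floor, double gate_max, double pulse_width,
                    double g_unit, double ut_eff, double drive,
                    bool oscillatory, double f_unit, double v_f, double duty,
                    double c_mem, double g_leak, double v_rest,
                    double v_thresh, double v_reset, double t_refr,
                    bool learn, double t_pre,
                    NumericVector sched_t, NumericVector sched_v,
                    IntegerVector w0, int w_min, int w_max,
                    double snapshot_every) {
  const int n_ev = ev_aff.size();
  const long n_steps = (long)std::llround(duration / dt);
  const int n_knot = sched_t.size();
  // piecewise-linear non-decreasing t_post schedule
  auto t_post_at = [&](double tt) {
    if (tt <= sched_t[0]) return sched_v[0];
    for (int k = 1; k < n_knot; ++k) {
      if (tt <= sched_t[k]) {
        double f = (tt - sched_t[k - 1]) / (sched_t[k] - sched_t[k - 1]);
        return sched_v[k - 1] + f * (sched_v[k] - sched_v[k - 1]);
      }
    }
    return sched_v[n_knot - 1];
  };

  std::vector<double> gate(n_aff, 0.0), g(n_aff, 0.0);
  std::vector<double> fv(n_aff, 0.0), phase(n_aff, 0.0);
  std::vector<double> pulse_start(n_aff, -1.0), pulse_until(n_aff, -1.0);
  std::vector<double> last_pre(n_aff, -1e18);
  std::vector<int> w(n_aff);
  for (int i = 0; i < n_aff; ++i) w[i] = w0[i % w0.size()];

  // per-efficacy multiplicative conductance/frequency factors for a full
  // step of charging (net rate c*w - d) and one for pure discharge
  std::vector<double> gfac(w_max + 1), ffac(w_max + 1);
  for (int k = 0; k <= w_max; ++k) {
    double net = (charge_rate * k - discharge_rate) * dt;
    gfac[k] = std::exp(net / ut_eff);
    ffac[k] = std::exp(net / v_f);
  }
  const double gdec = std::exp(-discharge_rate * dt / ut_eff);
  const double fdec = std::exp(-discharge_rate * dt / v_f);
  const double g_at_max = g_unit * std::exp(gate_max / ut_eff);
  const double f_at_max = f_unit * std::exp(gate_max / v_f);

  double v_m = v_rest, refr_until = -1.0, last_post = -1e18;
  std::vector<double> post_times;
  post_times.reserve(1 << 16);

  const long snap_stride =
      snapshot_every > 0 ? (long)std::llround(snapshot_every / dt) : 0;
  std::vector<double> snap_times;
  std::vector<int> snap_w;
  std::vector<double> snap_tpost;

  int ev = 0;
  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const double t1 = t + dt;

    // input events in this step: depression check, pre memory, pulse timing
    while (ev < n_ev && ev_time[ev] < t1) {
      const int a = ev_aff[ev];
      const double te = ev_time[ev];
      if (learn) {
        double tp = t_post_at(te);
        if (te > last_post && te - last_post < tp && w[a] > w_min) w[a]--;
      }
      last_pre[a] = te;
      if (te >= pulse_until[a]) pulse_start[a] = te;
      pulse_until[a] = std::max(pulse_until[a], te + pulse_width);
      ++ev;
    }

    // synapse gates and total drive
    double i_total = 0.0;
    for (int i = 0; i < n_aff; ++i) {
      double overlap = 0.0;
      if (pulse_until[i] > t) {
        double lo = std::max(t, pulse_start[i]);
        double hi = std::min(t1, pulse_until[i]);
        if (hi > lo) overlap = hi - lo;
      }
      if (gate[i] <= 0.0 && overlap <= 0.0) continue;

      double net = charge_rate * w[i] * overlap - discharge_rate * dt;
      double gnew = gate[i] + net;
      if (gnew <= 0.0) {
        gate[i] = 0.0; g[i] = 0.0; fv[i] = 0.0;
        continue;
      }
      if (gnew >= gate_max) {          // rail-bounded gate node
        gnew = gate_max;
        g[i] = g_at_max;
        if (oscillatory) fv[i] = f_at_max;
      } else if (gate[i] >= gate_max) { // leaving the rail: recompute
        g[i] = g_unit * std::exp(gnew / ut_eff);
        if (oscillatory) fv[i] = f_unit * std::exp(gnew / v_f);
      } else if (gate[i] <= 0.0) {     // freshly activated
        g[i] = g_unit * std::exp(gnew / ut_eff);
        if (oscillatory) fv[i] = f_unit * std::exp(gnew / v_f);
      } else if (overlap <= 0.0) {     // pure discharge
        g[i] *= gdec;
        if (oscillatory) fv[i] *= fdec;
      } else if (overlap >= dt) {      // full-step charging
        g[i] *= gfac[w[i]];
        if (oscillatory) fv[i] *= ffac[w[i]];
      } else {                         // partial overlap: direct exponential
        g[i] *= std::exp(net / ut_eff);
        if (oscillatory) fv[i] *= std::exp(net / v_f);
      }
      gate[i] = gnew;

      if (oscillatory) {
        if (gnew > gate_floor) {
          double dp = fv[i] * dt;
          i_total += g[i] * on_fraction(phase[i], dp, duty) / duty;
          phase[i] += dp;
        }
        // oscillator off below the floor: no packets, no current
      } else {
        i_total += g[i];
      }
    }
    i_total *= drive;

    // leaky integrate-and-fire soma
    if (t < refr_until) {
      v_m = v_reset;
    } else {
      double dv = 1000.0 * dt *
          (g_leak * (v_rest - v_m) + i_total) / c_mem;
      double v_new = v_m + dv;
      if (v_new >= v_thresh && dv > 0.0) {
        double ts = t + (v_thresh - v_m) / dv * dt;
        post_times.push_back(ts);
        v_m = v_reset;
        refr_until = ts + t_refr;
        if (learn) {
          for (int i = 0; i < n_aff; ++i) {
            if (last_pre[i] <= ts && ts - last_pre[i] < t_pre &&
                w[i] < w_max) w[i]++;
          }
        }
        last_post = ts;
      } else {
        v_m = v_new;
      }
    }

    if (snap_stride > 0 && (s + 1) % snap_stride == 0) {
      snap_times.push_back(t1);
      snap_tpost.push_back(t_post_at(t1));
      for (int i = 0; i < n_aff; ++i) snap_w.push_back(w[i]);
    }
  }

  return List::create(
      _["post_spike_times"] = wrap(post_times),
      _["final_w"] = wrap(w),
      _["snapshot_times"] = wrap(snap_times),
      _["snapshot_w"] = wrap(snap_w),
      _["snapshot_t_post"] = wrap(snap_tpost));
}

// Slew-limited reflected random-walk rate profiles (uniform increments,
// triangle fold into [lo, hi]); uses R's RNG so generation is seed-exact.
// [[Rcpp::export]]
NumericMatrix rate_walk_cpp(int n_steps, int n_aff, double lo, double hi,
                            double step_max) {
  NumericMatrix out(n_steps + 1, n_aff);
  const double span = hi - lo;
  for (int a = 0; a < n_aff; ++a) {
    double x = R::runif(lo, hi);
    out(0, a) = x;
    for (int s = 1; s <= n_steps; ++s) {
      x += R::runif(-step_max, step_max);
      double p = (x - lo) / (2.0 * span);
      double y = (p - std::floor(p)) * 2.0 * span;
      out(s, a) = lo + span - std::fabs(y - span);
    }
  }
  return out;
}
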