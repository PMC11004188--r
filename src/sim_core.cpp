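#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Intermittent-pulse state machine shared by the closed-loop simulator and
// the bounded-walk generator. Mirrors intermittent_command() in R exactly.
struct ICState {
  bool active = false;
  double t_trigger = 0.0;
  double sgn = 0.0;
};

static inline double ic_velocity(double xm, double t, ICState &st,
                                 double threshold, double vmax,
                                 double c, double t0) {
  if (st.active) {
    double tc = st.t_trigger + t0;
    if (t <= tc + 4.0 * c) {
      double u = (t - tc) / c;
      return -st.sgn * vmax * std::exp(-0.5 * u * u);
    }
    st.active = false;
  }
  if (std::fabs(xm) > threshold) {
    st.active = true;
    st.t_trigger = t;
    st.sgn = (xm > 0.0) ? 1.0 : -1.0;
    double tc = t + t0;
    double u = (t - tc) / c;
    return -st.sgn * vmax * std::exp(-0.5 * u * u);
  }
  return 0.0;
}

// Fixed-step closed-loop simulation of one trial.
//
// Plant advanced by exact zero-order-hold discretization (Ad, Bd precomputed
// in R via the matrix exponential). Feedback measurements are read from a
// history buffer delay_steps samples back (zero-filled at start).
//
// arch: 1 = leaky-integrator disturbance (model i), 2 = free-integrator loop
// (model ii), 3 = noisy forward-path velocity command (model iii).
// noise_w / noise_f are per-step velocity / torque noise samples (already
// scaled by 1/sqrt(dt) in R).
// [[Rcpp::export]]
NumericVector sim_loop_cpp(NumericMatrix Ad, NumericVector Bd,
                           int n_steps, double dt, int delay_steps,
                           int arch, double kc, double kv,
                           double cancel_stiffness, double v_ref,
                           double leak_alpha,
                           NumericVector noise_w, NumericVector noise_f,
                           bool has_ic, double ic_threshold, double ic_vmax,
                           double ic_c, double ic_t0,
                           int decim) {
  const double a11 = Ad(0, 0), a12 = Ad(0, 1), a21 = Ad(1, 0), a22 = Ad(1, 1);
  const double b1 = Bd[0], b2 = Bd[1];

  std::vector<double> xhist(n_steps + 1, 0.0);
  std::vector<double> vhist;
  if (arch == 2) vhist.assign(n_steps + 1, 0.0);

  double x = 0.0, v = 0.0, xr = 0.0, nfilt = 0.0;
  ICState ic;

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double xm_del = (k >= delay_steps) ? xhist[k - delay_steps] : 0.0;

    double v_ic = 0.0;
    if (has_ic)
      v_ic = ic_velocity(xm_del, t, ic, ic_threshold, ic_vmax, ic_c, ic_t0);

    double torque;
    if (arch == 3) {
      xr += (v_ref + v_ic + noise_w[k]) * dt;
      torque = kc * (xr - xm_del) + noise_f[k];
    } else if (arch == 1) {
      xr += v_ref * dt;
      nfilt += leak_alpha * (noise_f[k] - nfilt);
      torque = kc * (xr - xm_del) + nfilt;
    } else { // arch == 2
      double vm_del = (k >= delay_steps) ? vhist[k - delay_steps] : 0.0;
      torque = kv * (v_ref - vm_del) - cancel_stiffness * x + noise_f[k];
    }

    double xn = a11 * x + a12 * v + b1 * torque;
    double vn = a21 * x + a22 * v + b2 * torque;
    x = xn;
    v = vn;
    xhist[k + 1] = x;
    if (arch == 2) vhist[k + 1] = v;
  }

  int n_out = n_steps / decim + 1;
  NumericVector out(n_out);
  for (int j = 0; j < n_out; ++j) out[j] = xhist[(std::size_t)j * decim];
  return out;
}

// Bounded random walk: Wiener increments plus the intermittent corrective
// velocity acting directly on the walker's position.
// increments are N(0, sigma^2 dt) samples generated in R.
// [[Rcpp::export]]
NumericVector bounded_walk_cpp(NumericVector increments, double dt,
                               double threshold, double vmax,
                               double c, double t0) {
  int n = increments.size();
  NumericVector out(n + 1);
  double x = 0.0;
  ICState ic;
  for (int k = 0; k < n; ++k) {
    double t = k * dt;
    double v_ic = ic_velocity(x, t, ic, threshold, vmax, c, t0);
    x += increments[k] + v_ic * dt;
    out[k + 1] = x;
  }
  return out;
}
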