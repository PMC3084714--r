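#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Four-pool receptor recycling kinetics:
// s = (R, LR_act, LR_des, R_int), rates = (k_f, k_r, k_des, k_i, k_up).
static inline void pool_rhs(const double *s, double L, const double *k,
                            double *ds) {
  const double bind = k[0] * L * s[0];
  ds[0] = -bind + k[1] * s[1] + k[4] * s[3];
  ds[1] = bind - (k[1] + k[2]) * s[1];
  ds[2] = k[2] * s[1] - k[3] * s[2];
  ds[3] = k[3] * s[2] - k[4] * s[3];
}

// One fixed-step RK4 update at constant ligand concentration.
// Clamps negative overshoot below tol, aborts beyond it.
static inline void rk4_step(double *s, double L, const double *k, double h,
                            double tol) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  pool_rhs(s, L, k, k1);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
  pool_rhs(tmp, L, k, k2);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
  pool_rhs(tmp, L, k, k3);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + h * k3[i];
  pool_rhs(tmp, L, k, k4);
  for (int i = 0; i < 4; ++i) {
    s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (s[i] < 0.0) {
      if (s[i] < -tol)
        stop("RK4 step produced a negative receptor pool (%g): reduce dt",
             s[i]);
      s[i] = 0.0;
    }
  }
}

// [[Rcpp::export]]
NumericVector integrate_pool_cpp(NumericVector state, double L,
                                 NumericVector rates, double Ru,
                                 double dt, double duration) {
  double s[4] = {state[0], state[1], state[2], state[3]};
  double k[5] = {rates[0], rates[1], rates[2], rates[3], rates[4]};
  const double tol = 1e-9 * Ru;
  const int n_steps = (int)std::ceil(duration / dt - 1e-9);
  double t = 0.0, max_err = 0.0;
  for (int i = 0; i < n_steps; ++i) {
    double h = std::min(dt, duration - t);
    rk4_step(s, L, k, h, tol);
    double err = std::fabs(s[0] + s[1] + s[2] + s[3] - Ru);
    if (err > max_err) max_err = err;
    t += h;
  }
  NumericVector out = NumericVector::create(s[0], s[1], s[2], s[3]);
  out.attr("max_conservation_error") = max_err;
  return out;
}

static inline double wrap_2pi(double a) {
  const double twopi = 2.0 * M_PI;
  a -= twopi * std::floor(a / twopi);
  if (a >= twopi) a -= twopi;
  return a;
}

// Signed smallest angular difference target - heading for angles already in
// [0, 2*pi), mapped to (-pi, pi].
static inline double ang_diff(double target, double heading) {
  double d = target - heading;
  if (d > M_PI) d -= 2.0 * M_PI;
  if (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

// Total concentration of one ligand (index lig, 1-based in column 6)
// summed over its fields. Field rows: cx, cy, Lmax, L0, A, n, ligand_index.
static inline double conc_at(const NumericMatrix &fields, int lig,
                             double x, double y) {
  double out = 0.0;
  for (int f = 0; f < fields.nrow(); ++f) {
    if ((int)fields(f, 6) != lig) continue;
    const double dx = x - fields(f, 0), dy = y - fields(f, 1);
    const double rho = std::sqrt(dx * dx + dy * dy);
    const double A = fields(f, 4);
    if (rho <= A)
      out += fields(f, 3) +
             (fields(f, 2) - fields(f, 3)) * std::pow(1.0 - rho / A,
                                                      fields(f, 5));
    else
      out += fields(f, 3);
  }
  return out;
}

// Agent-based migration of one cell: threshold-gated directed/random
// stepping with orientation-proportional persistence time and turning rate,
// receptor kinetics integrated by RK4 at every sub-step.
//
// fields: one row per gradient source (see conc_at);
// params: one row per ligand (k_f, k_r, k_des, k_i, k_up, R_u);
// dirs:   n_units x 2 unit direction matrix;
// states0: 4 x (n_units * n_ligands) starting receptor pools
//          (unit fastest, ligand outer).
// Random draws come from R's RNG: one uniform for the initial heading,
// then one per sub-threshold (random-mode) step.
// [[Rcpp::export]]
List simulate_track_cpp(double x0, double y0,
                        NumericMatrix fields, NumericMatrix params,
                        NumericMatrix dirs, double unit_radius,
                        NumericMatrix states0,
                        double speed, double threshold, double tau_opt,
                        double tau_min, double v_sat, double substep_dt,
                        double ode_dt, double total_time) {
  const int n_units = dirs.nrow();
  const int n_lig = params.nrow();
  const int n_sub_total = (int)std::lround(total_time / substep_dt);
  const int n_ode = (int)std::lround(substep_dt * 60.0 / ode_dt);
  const double ode_h = substep_dt * 60.0 / n_ode;

  // working receptor states: [4][unit][ligand]
  std::vector<double> S(states0.begin(), states0.end());
  auto pool = [&](int unit, int lig) -> double * {
    return &S[4 * (unit + n_units * lig)];
  };

  NumericMatrix samples(n_sub_total + 1, 6);
  double max_err = 0.0;
  double x = x0, y = y0;
  double heading = 2.0 * M_PI * unif_rand();

  auto net_orientation = [&](double *vx, double *vy) {
    *vx = 0.0; *vy = 0.0;
    for (int lig = 0; lig < n_lig; ++lig)
      for (int u = 0; u < n_units; ++u) {
        const double lr = pool(u, lig)[1];
        *vx += lr * dirs(u, 0);
        *vy += lr * dirs(u, 1);
      }
    *vx *= 4.0 / n_units;
    *vy *= 4.0 / n_units;
  };

  double vx, vy;
  net_orientation(&vx, &vy);
  double mag = std::sqrt(vx * vx + vy * vy);
  samples(0, 0) = 0.0; samples(0, 1) = x; samples(0, 2) = y;
  samples(0, 3) = heading; samples(0, 4) = mag; samples(0, 5) = 0.0;

  int sub = 0;
  while (sub < n_sub_total) {
    net_orientation(&vx, &vy);
    mag = std::sqrt(vx * vx + vy * vy);
    const bool directed = mag >= threshold;
    double target;
    if (directed) {
      target = std::atan2(vy, vx);
    } else {
      target = 2.0 * M_PI * unif_rand();
      heading = wrap_2pi(target);  // random mode reorients instantaneously
    }
    const double tau =
        std::min(tau_opt, std::max(tau_min, tau_opt * mag / v_sat));
    int n_sub_step = (int)std::lround(tau / substep_dt);
    if (n_sub_step < 1) n_sub_step = 1;
    if (n_sub_step > n_sub_total - sub) n_sub_step = n_sub_total - sub;
    const double omega = (M_PI / tau_opt) * (mag / v_sat);  // rad / min

    for (int ss = 0; ss < n_sub_step; ++ss) {
      if (directed) {
        const double d = ang_diff(target, heading);
        const double turn = std::min(omega * substep_dt, std::fabs(d));
        heading = wrap_2pi(heading + (d >= 0.0 ? turn : -turn));
      }
      x += speed * substep_dt * std::cos(heading);
      y += speed * substep_dt * std::sin(heading);
      for (int lig = 0; lig < n_lig; ++lig) {
        const double kk[5] = {params(lig, 0), params(lig, 1), params(lig, 2),
                              params(lig, 3), params(lig, 4)};
        const double Ru = params(lig, 5);
        const double tol = 1e-9 * Ru;
        for (int u = 0; u < n_units; ++u) {
          const double ux = x + unit_radius * dirs(u, 0);
          const double uy = y + unit_radius * dirs(u, 1);
          const double L = conc_at(fields, lig + 1, ux, uy);
          double *s = pool(u, lig);
          for (int i = 0; i < n_ode; ++i) rk4_step(s, L, kk, ode_h, tol);
          const double err = std::fabs(s[0] + s[1] + s[2] + s[3] - Ru);
          if (err > max_err) max_err = err;
        }
      }
      ++sub;
      samples(sub, 0) = sub * substep_dt;
      samples(sub, 1) = x; samples(sub, 2) = y;
      samples(sub, 3) = heading; samples(sub, 4) = mag;
      samples(sub, 5) = directed ? 1.0 : 0.0;
    }
  }

  NumericVector states_out(S.begin(), S.end());
  states_out.attr("dim") = IntegerVector::create(4, n_units, n_lig);
  return List::create(_["samples"] = samples,
                      _["states"] = states_out,
                      _["max_conservation_error"] = max_err);
}
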