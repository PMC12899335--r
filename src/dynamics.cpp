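// Stochastic flight-dynamics stepping kernels.
//
// The per-step state updates for the bird kinematic model (bank-angle /
// turn-rate coupling, Euler-Maruyama noise), the point-mass PID quadrotor,
// and the Ornstein-Uhlenbeck wind gust live here; full-trajectory loops call
// the same step routines so the exported single-step functions and the
// simulator share one implementation.  All randomness goes through R's RNG,
// so set.seed() on the R side makes every trajectory reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const double GRAV = 9.81;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline void scale3(double* a, double c) {
  a[0] *= c; a[1] *= c; a[2] *= c;
}
static inline bool normalize3(double* a) {
  double n = norm3(a);
  if (n < 1e-300) return false;
  scale3(a, 1.0 / n);
  return true;
}
// component of v perpendicular to unit vector u, written to out
static inline void perp3(const double* v, const double* u, double* out) {
  double d = dot3(v, u);
  out[0] = v[0] - d * u[0];
  out[1] = v[1] - d * u[1];
  out[2] = v[2] - d * u[2];
}

// Rodrigues rotation of v about unit axis k by angle theta
static void rodrigues(const double* v, const double* k, double theta,
                      double* out) {
  double c = std::cos(theta), s = std::sin(theta);
  double kxv[3];
  cross3(k, v, kxv);
  double kd = dot3(k, v) * (1.0 - c);
  for (int i = 0; i < 3; ++i) out[i] = v[i] * c + kxv[i] * s + k[i] * kd;
}

// [[Rcpp::export]]
NumericVector cpp_rodrigues(NumericVector v, NumericVector axis,
                            double angle) {
  double k[3] = {axis[0], axis[1], axis[2]};
  double n = norm3(k);
  if (n < 1e-12) stop("rotation axis must be non-zero");
  if (std::abs(n - 1.0) > 1e-9) stop("rotation axis must be a unit vector");
  scale3(k, 1.0 / n);
  double in[3] = {v[0], v[1], v[2]}, out[3];
  rodrigues(in, k, angle, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// ---------------------------------------------------------------------------
// Environment: OU gust + wind field
// ---------------------------------------------------------------------------

// Exact conditional-Gaussian OU update: the stationary per-axis standard
// deviation equals sigma for any dt.
static void ou_step(double* gust, double tau, double sigma, double dt) {
  double a = std::exp(-dt / tau);
  double b = sigma * std::sqrt(1.0 - a * a);
  for (int i = 0; i < 3; ++i) gust[i] = gust[i] * a + b * R::norm_rand();
}

// [[Rcpp::export]]
NumericVector cpp_step_gust(NumericVector gust, double tau, double sigma,
                            double dt) {
  double g[3] = {gust[0], gust[1], gust[2]};
  ou_step(g, tau, sigma, dt);
  return NumericVector::create(g[0], g[1], g[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_gust(NumericVector gust0, double tau, double sigma,
                                double dt, int n_steps) {
  NumericMatrix out(n_steps, 3);
  double g[3] = {gust0[0], gust0[1], gust0[2]};
  for (int t = 0; t < n_steps; ++t) {
    ou_step(g, tau, sigma, dt);
    out(t, 0) = g[0]; out(t, 1) = g[1]; out(t, 2) = g[2];
  }
  return out;
}

struct WindField {
  double w_base[3];
  double tau, sigma;
  double tc[2];
  double tstrength, tradius;
};

static WindField wind_from_list(List wind) {
  WindField w;
  NumericVector wb = wind["w_base"], tc = wind["thermal_center"];
  w.w_base[0] = wb[0]; w.w_base[1] = wb[1]; w.w_base[2] = wb[2];
  w.tau = as<double>(wind["tau_gust"]);
  w.sigma = as<double>(wind["sigma_gust"]);
  w.tc[0] = tc[0]; w.tc[1] = tc[1];
  w.tstrength = as<double>(wind["thermal_strength"]);
  w.tradius = as<double>(wind["thermal_radius"]);
  return w;
}

static void wind_at(const WindField& w, const double* gust, const double* x,
                    double* out) {
  double dx = x[0] - w.tc[0], dy = x[1] - w.tc[1];
  double d2 = dx * dx + dy * dy;
  double therm = w.tstrength * std::exp(-d2 / (2.0 * w.tradius * w.tradius));
  out[0] = w.w_base[0] + gust[0];
  out[1] = w.w_base[1] + gust[1];
  out[2] = w.w_base[2] + gust[2] + therm;
}

// [[Rcpp::export]]
NumericVector cpp_wind_at(List wind, NumericVector gust, NumericVector x) {
  WindField w = wind_from_list(wind);
  double g[3] = {gust[0], gust[1], gust[2]};
  double xx[3] = {x[0], x[1], x[2]}, out[3];
  wind_at(w, g, xx, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// ---------------------------------------------------------------------------
// Bird kinematic stochastic model
// ---------------------------------------------------------------------------

struct Species {
  double k_s, s_star, beta_tw, sigma_s, k_phi, k_g, k_h, k_w, k_a;
  double phi_max, sigma_phi, sigma_a, sigma_u, s_min, s_max, avoid_cutoff;
};

static Species species_from_list(List sp) {
  Species s;
  s.k_s = as<double>(sp["k_s"]);
  s.s_star = as<double>(sp["s_star"]);
  s.beta_tw = as<double>(sp["beta_tw"]);
  s.sigma_s = as<double>(sp["sigma_s"]);
  s.k_phi = as<double>(sp["k_phi"]);
  s.k_g = as<double>(sp["k_g"]);
  s.k_h = as<double>(sp["k_h"]);
  s.k_w = as<double>(sp["k_w"]);
  s.k_a = as<double>(sp["k_a"]);
  s.phi_max = as<double>(sp["phi_max"]);
  s.sigma_phi = as<double>(sp["sigma_phi"]);
  s.sigma_a = as<double>(sp["sigma_a"]);
  s.sigma_u = as<double>(sp["sigma_u"]);
  s.s_min = as<double>(sp["s_min"]);
  s.s_max = as<double>(sp["s_max"]);
  s.avoid_cutoff = as<double>(sp["avoid_cutoff"]);
  return s;
}

struct Scene {
  double goal[3];
  double h_pref;
  NumericMatrix obstacles; // n x 3 (possibly 0 rows)
};

static Scene scene_from_list(List env) {
  Scene sc;
  NumericVector g = env["goal"];
  sc.goal[0] = g[0]; sc.goal[1] = g[1]; sc.goal[2] = g[2];
  sc.h_pref = as<double>(env["h_pref"]);
  sc.obstacles = as<NumericMatrix>(env["obstacles"]);
  return sc;
}

// inverse-square repulsion away from obstacles within a cutoff radius;
// an agent sitting exactly on an obstacle skips that term
static void avoidance_accel(const double* x, const NumericMatrix& obs,
                            double gain, double cutoff, double* out) {
  out[0] = out[1] = out[2] = 0.0;
  for (int i = 0; i < obs.nrow(); ++i) {
    double d[3] = {x[0] - obs(i, 0), x[1] - obs(i, 1), x[2] - obs(i, 2)};
    double dist = norm3(d);
    if (dist < 1e-9 || dist > cutoff) continue;
    double c = gain / (dist * dist * dist);
    out[0] += c * d[0]; out[1] += c * d[1]; out[2] += c * d[2];
  }
}

// behavioral acceleration command: goal attraction, altitude hold, cross-wind
// compensation, obstacle repulsion and lateral Gaussian noise (all lateral
// terms projected perpendicular to the heading u)
static void bird_accel(const double* x, const double* u, double s,
                       const Species& sp, const Scene& sc, const double* w,
                       bool draw_noise, double* out) {
  double tmp[3], p[3];
  out[0] = out[1] = out[2] = 0.0;
  // goal attraction
  tmp[0] = sc.goal[0] - x[0]; tmp[1] = sc.goal[1] - x[1];
  tmp[2] = sc.goal[2] - x[2];
  if (normalize3(tmp)) {
    perp3(tmp, u, p);
    out[0] += sp.k_g * s * p[0];
    out[1] += sp.k_g * s * p[1];
    out[2] += sp.k_g * s * p[2];
  }
  // altitude hold
  out[2] += sp.k_h * (sc.h_pref - x[2]);
  // cross-wind compensation (horizontal wind only)
  tmp[0] = w[0]; tmp[1] = w[1]; tmp[2] = 0.0;
  perp3(tmp, u, p);
  out[0] -= sp.k_w * p[0]; out[1] -= sp.k_w * p[1]; out[2] -= sp.k_w * p[2];
  // obstacle repulsion
  avoidance_accel(x, sc.obstacles, sp.k_a, sp.avoid_cutoff, tmp);
  out[0] += tmp[0]; out[1] += tmp[1]; out[2] += tmp[2];
  // lateral random acceleration
  if (draw_noise) {
    double eta[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
    perp3(eta, u, p);
    out[0] += sp.sigma_a * p[0];
    out[1] += sp.sigma_a * p[1];
    out[2] += sp.sigma_a * p[2];
  }
}

// [[Rcpp::export]]
NumericVector cpp_bird_accel(NumericVector x, NumericVector u, double s,
                             List sp, List env, List wind,
                             NumericVector gust, bool draw_noise) {
  Species spp = species_from_list(sp);
  Scene sc = scene_from_list(env);
  WindField wf = wind_from_list(wind);
  double xx[3] = {x[0], x[1], x[2]}, uu[3] = {u[0], u[1], u[2]};
  double g[3] = {gust[0], gust[1], gust[2]}, w[3], out[3];
  wind_at(wf, g, xx, w);
  bird_accel(xx, uu, s, spp, sc, w, draw_noise, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// leftward horizontal unit vector relative to heading u (positive-bank side)
static bool lat_dir(const double* u, double* n_lat) {
  double ez[3] = {0.0, 0.0, 1.0};
  cross3(ez, u, n_lat);
  return normalize3(n_lat);
}

// desired bank angle: atan of horizontal lateral command over g, signed by
// turn direction, saturated at the species maximum
static double desired_bank(const double* a_cmd, const double* u,
                           double phi_max) {
  double n_lat[3];
  if (!lat_dir(u, n_lat)) return 0.0; // heading vertical: no defined side
  double a_h[3] = {a_cmd[0], a_cmd[1], 0.0};
  double u_h[3] = {u[0], u[1], 0.0};
  double a_lat[3];
  if (normalize3(u_h)) {
    perp3(a_h, u_h, a_lat);
  } else {
    a_lat[0] = a_h[0]; a_lat[1] = a_h[1]; a_lat[2] = 0.0;
  }
  double mag = norm3(a_lat);
  if (mag < 1e-300) return 0.0;
  double phi = std::min(std::atan(mag / GRAV), phi_max);
  double sgn = dot3(a_lat, n_lat) >= 0.0 ? 1.0 : -1.0;
  return sgn * phi;
}

// [[Rcpp::export]]
double cpp_desired_bank(NumericVector a_cmd, NumericVector u,
                        double phi_max) {
  double a[3] = {a_cmd[0], a_cmd[1], a_cmd[2]};
  double uu[3] = {u[0], u[1], u[2]};
  return desired_bank(a, uu, phi_max);
}

struct BirdState {
  double x[3], u[3], s, phi;
};

// one Euler-Maruyama step of the bird model; gust is held fixed (the caller
// advances it).  Draws 8 normal deviates in a fixed order regardless of
// which noise amplitudes are zero, so seeded streams stay aligned.
static void bird_step(BirdState& b, const Species& sp, const Scene& sc,
                      const WindField& wf, const double* gust, double dt) {
  double w[3];
  wind_at(wf, gust, b.x, w);

  double a_cmd[3];
  bird_accel(b.x, b.u, b.s, sp, sc, w, true, a_cmd); // 3 draws

  // bank angle relaxation toward the commanded bank, plus roll noise
  double phi_star = desired_bank(a_cmd, b.u, sp.phi_max);
  double xi_phi = R::norm_rand(); // 1 draw
  b.phi += sp.k_phi * (phi_star - b.phi) * dt +
           sp.sigma_phi * std::sqrt(dt) * xi_phi;
  if (b.phi > sp.phi_max) b.phi = sp.phi_max;
  if (b.phi < -sp.phi_max) b.phi = -sp.phi_max;

  // realized perpendicular acceleration: banked-turn lateral component plus
  // the vertical command, capped at the lift limit g*tan(phi_max)
  double n_lat[3];
  double a_L[3] = {0.0, 0.0, 0.0};
  if (lat_dir(b.u, n_lat)) {
    double lat = GRAV * std::tan(b.phi);
    a_L[0] = lat * n_lat[0]; a_L[1] = lat * n_lat[1]; a_L[2] = lat * n_lat[2];
  }
  a_L[2] += a_cmd[2];
  double cap = GRAV * std::tan(sp.phi_max);
  double amag = norm3(a_L);
  if (amag > cap) scale3(a_L, cap / amag);

  // rotate heading by omega = (u x a_L)/s
  double omega[3];
  cross3(b.u, a_L, omega);
  scale3(omega, 1.0 / b.s);
  double om = norm3(omega);
  if (om > 1e-12) {
    double axis[3] = {omega[0] / om, omega[1] / om, omega[2] / om};
    double unew[3];
    rodrigues(b.u, axis, om * dt, unew);
    b.u[0] = unew[0]; b.u[1] = unew[1]; b.u[2] = unew[2];
  }

  // orthogonal heading noise, then renormalize
  double eta[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()}; // 3 draws
  double p[3];
  perp3(eta, b.u, p);
  double su = sp.sigma_u * std::sqrt(dt);
  b.u[0] += su * p[0]; b.u[1] += su * p[1]; b.u[2] += su * p[2];
  normalize3(b.u);

  // airspeed relaxation with tailwind coupling
  double xi_s = R::norm_rand(); // 1 draw
  b.s += sp.k_s * (sp.s_star + sp.beta_tw * dot3(b.u, w) - b.s) * dt +
         sp.sigma_s * std::sqrt(dt) * xi_s;
  if (b.s < sp.s_min) b.s = sp.s_min;
  if (b.s > sp.s_max) b.s = sp.s_max;

  // advance position with airspeed plus wind
  b.x[0] += (b.s * b.u[0] + w[0]) * dt;
  b.x[1] += (b.s * b.u[1] + w[1]) * dt;
  b.x[2] += (b.s * b.u[2] + w[2]) * dt;
}

// [[Rcpp::export]]
List cpp_bird_step(List bird, List sp, List env, List wind,
                   NumericVector gust, double dt) {
  Species spp = species_from_list(sp);
  Scene sc = scene_from_list(env);
  WindField wf = wind_from_list(wind);
  BirdState b;
  NumericVector x = bird["x"], u = bird["u"];
  for (int i = 0; i < 3; ++i) { b.x[i] = x[i]; b.u[i] = u[i]; }
  b.s = as<double>(bird["s"]);
  b.phi = as<double>(bird["phi"]);
  double g[3] = {gust[0], gust[1], gust[2]};
  bird_step(b, spp, sc, wf, g, dt);
  return List::create(
      _["x"] = NumericVector::create(b.x[0], b.x[1], b.x[2]),
      _["u"] = NumericVector::create(b.u[0], b.u[1], b.u[2]),
      _["s"] = b.s, _["phi"] = b.phi);
}

// [[Rcpp::export]]
List cpp_simulate_bird(List bird, List sp, List env, List wind,
                       NumericVector gust0, int n_steps, double dt) {
  Species spp = species_from_list(sp);
  Scene sc = scene_from_list(env);
  WindField wf = wind_from_list(wind);
  BirdState b;
  NumericVector x = bird["x"], u = bird["u"];
  for (int i = 0; i < 3; ++i) { b.x[i] = x[i]; b.u[i] = u[i]; }
  b.s = as<double>(bird["s"]);
  b.phi = as<double>(bird["phi"]);
  double g[3] = {gust0[0], gust0[1], gust0[2]};

  NumericMatrix pos(n_steps + 1, 3);
  NumericVector speed(n_steps + 1), phi(n_steps + 1);
  pos(0, 0) = b.x[0]; pos(0, 1) = b.x[1]; pos(0, 2) = b.x[2];
  speed[0] = b.s; phi[0] = b.phi;
  for (int t = 1; t <= n_steps; ++t) {
    ou_step(g, wf.tau, wf.sigma, dt);
    bird_step(b, spp, sc, wf, g, dt);
    pos(t, 0) = b.x[0]; pos(t, 1) = b.x[1]; pos(t, 2) = b.x[2];
    speed[t] = b.s; phi[t] = b.phi;
  }
  return List::create(_["positions"] = pos, _["speed"] = speed,
                      _["phi"] = phi,
                      _["gust"] = NumericVector::create(g[0], g[1], g[2]),
                      _["u"] = NumericVector::create(b.u[0], b.u[1], b.u[2]));
}

// ---------------------------------------------------------------------------
// Point-mass PID quadrotor
// ---------------------------------------------------------------------------

struct DroneParams {
  double m, kp, kd, ki, a_h_max, a_v_max, tilt_max, tilt_rate_max, thrust_max;
  double k_a, sigma_ctrl, yaw_rate_max, sigma_yaw, h_star, avoid_cutoff;
};

static DroneParams drone_params_from_list(List dp) {
  DroneParams d;
  d.m = as<double>(dp["mass"]);
  d.kp = as<double>(dp["kp"]);
  d.kd = as<double>(dp["kd"]);
  d.ki = as<double>(dp["ki"]);
  d.a_h_max = as<double>(dp["a_h_max"]);
  d.a_v_max = as<double>(dp["a_v_max"]);
  d.tilt_max = as<double>(dp["tilt_max"]);
  d.tilt_rate_max = as<double>(dp["tilt_rate_max"]);
  d.thrust_max = as<double>(dp["thrust_max"]);
  d.k_a = as<double>(dp["k_a_drone"]);
  d.sigma_ctrl = as<double>(dp["sigma_ctrl"]);
  d.yaw_rate_max = as<double>(dp["yaw_rate_max"]);
  d.sigma_yaw = as<double>(dp["sigma_yaw"]);
  d.h_star = as<double>(dp["h_star"]);
  d.avoid_cutoff = as<double>(dp["avoid_cutoff"]);
  return d;
}

struct DroneState {
  double x[3], v[3], t_hat[3], psi;
  double e_int[3];
  double tilt, thrust; // diagnostics from the last step
};

static double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// rotate unit vector `from` toward unit vector `to` by at most max_angle
static void rotate_toward(double* from, const double* to, double max_angle) {
  double c = clampd(dot3(from, to), -1.0, 1.0);
  double ang = std::acos(c);
  if (ang < 1e-12) return;
  double axis[3];
  cross3(from, to, axis);
  if (!normalize3(axis)) return; // antiparallel: leave unchanged
  double theta = std::min(ang, max_angle);
  double out[3];
  rodrigues(from, axis, theta, out);
  from[0] = out[0]; from[1] = out[1]; from[2] = out[2];
  normalize3(from);
}

static void drone_step(DroneState& d, const DroneParams& dp, const Scene& sc,
                       const WindField& wf, const double* gust, double dt) {
  double w[3];
  wind_at(wf, gust, d.x, w);

  // PID position error; the altitude target replaces the goal's z
  double e[3] = {sc.goal[0] - d.x[0], sc.goal[1] - d.x[1],
                 dp.h_star - d.x[2]};
  for (int i = 0; i < 3; ++i) d.e_int[i] += e[i] * dt;

  double a_des[3];
  for (int i = 0; i < 3; ++i)
    a_des[i] = dp.kp * e[i] - dp.kd * d.v[i] + dp.ki * d.e_int[i] -
               dp.kd * w[i];
  double av[3];
  avoidance_accel(d.x, sc.obstacles, dp.k_a, dp.avoid_cutoff, av);
  for (int i = 0; i < 3; ++i) a_des[i] += av[i];
  for (int i = 0; i < 3; ++i) a_des[i] += dp.sigma_ctrl * R::norm_rand(); // 3

  // separate horizontal / vertical saturation
  double hmag = std::sqrt(a_des[0] * a_des[0] + a_des[1] * a_des[1]);
  if (hmag > dp.a_h_max) {
    a_des[0] *= dp.a_h_max / hmag;
    a_des[1] *= dp.a_h_max / hmag;
  }
  a_des[2] = clampd(a_des[2], -dp.a_v_max, dp.a_v_max);

  // desired thrust direction; rate-limited tilt toward it, capped tilt
  double t_des[3] = {a_des[0], a_des[1], a_des[2] + GRAV};
  if (!normalize3(t_des)) { t_des[0] = 0; t_des[1] = 0; t_des[2] = 1; }
  rotate_toward(d.t_hat, t_des, dp.tilt_rate_max * dt);
  double ez[3] = {0.0, 0.0, 1.0};
  double tilt = std::acos(clampd(d.t_hat[2], -1.0, 1.0));
  if (tilt > dp.tilt_max) {
    rotate_toward(d.t_hat, ez, tilt - dp.tilt_max);
    tilt = dp.tilt_max;
  }

  // thrust: desired force projected on the actual thrust axis, saturated
  double f_des[3] = {a_des[0], a_des[1], a_des[2] + GRAV};
  double T = clampd(dp.m * dot3(f_des, d.t_hat), 0.0, dp.thrust_max);

  for (int i = 0; i < 3; ++i)
    d.v[i] += ((T / dp.m) * d.t_hat[i] - GRAV * ez[i]) * dt;
  for (int i = 0; i < 3; ++i) d.x[i] += d.v[i] * dt;
  if (d.x[2] < 0.0) { d.x[2] = 0.0; if (d.v[2] < 0.0) d.v[2] = 0.0; }

  // yaw tracks the velocity heading (goal heading when hovering)
  double vh = std::sqrt(d.v[0] * d.v[0] + d.v[1] * d.v[1]);
  double target;
  if (vh > 0.5) target = std::atan2(d.v[1], d.v[0]);
  else target = std::atan2(sc.goal[1] - d.x[1], sc.goal[0] - d.x[0]);
  double dpsi = target - d.psi;
  while (dpsi > M_PI) dpsi -= 2.0 * M_PI;
  while (dpsi < -M_PI) dpsi += 2.0 * M_PI;
  d.psi += clampd(dpsi, -dp.yaw_rate_max * dt, dp.yaw_rate_max * dt) +
           dp.sigma_yaw * std::sqrt(dt) * R::norm_rand(); // 1 draw

  d.tilt = tilt;
  d.thrust = T;
}

static DroneState drone_from_list(List drone) {
  DroneState d;
  NumericVector x = drone["x"], v = drone["v"], th = drone["t_hat"],
                ei = drone["e_int"];
  for (int i = 0; i < 3; ++i) {
    d.x[i] = x[i]; d.v[i] = v[i]; d.t_hat[i] = th[i]; d.e_int[i] = ei[i];
  }
  d.psi = as<double>(drone["psi"]);
  d.tilt = 0.0; d.thrust = 0.0;
  return d;
}

static List drone_to_list(const DroneState& d) {
  return List::create(
      _["x"] = NumericVector::create(d.x[0], d.x[1], d.x[2]),
      _["v"] = NumericVector::create(d.v[0], d.v[1], d.v[2]),
      _["t_hat"] = NumericVector::create(d.t_hat[0], d.t_hat[1], d.t_hat[2]),
      _["psi"] = d.psi,
      _["e_int"] = NumericVector::create(d.e_int[0], d.e_int[1], d.e_int[2]),
      _["tilt"] = d.tilt, _["thrust"] = d.thrust);
}

// [[Rcpp::export]]
List cpp_drone_step(List drone, List dp, List env, List wind,
                    NumericVector gust, double dt) {
  DroneParams dpp = drone_params_from_list(dp);
  Scene sc = scene_from_list(env);
  WindField wf = wind_from_list(wind);
  DroneState d = drone_from_list(drone);
  double g[3] = {gust[0], gust[1], gust[2]};
  drone_step(d, dpp, sc, wf, g, dt);
  return drone_to_list(d);
}

// [[Rcpp::export]]
List cpp_simulate_drone(List drone, List dp, List env, List wind,
                        NumericVector gust0, int n_steps, double dt) {
  DroneParams dpp = drone_params_from_list(dp);
  Scene sc = scene_from_list(env);
  WindField wf = wind_from_list(wind);
  DroneState d = drone_from_list(drone);
  double g[3] = {gust0[0], gust0[1], gust0[2]};

  NumericMatrix pos(n_steps + 1, 3);
  NumericVector tilt(n_steps + 1), thrust(n_steps + 1);
  pos(0, 0) = d.x[0]; pos(0, 1) = d.x[1]; pos(0, 2) = d.x[2];
  tilt[0] = std::acos(clampd(d.t_hat[2], -1.0, 1.0));
  thrust[0] = NA_REAL;
  for (int t = 1; t <= n_steps; ++t) {
    ou_step(g, wf.tau, wf.sigma, dt);
    drone_step(d, dpp, sc, wf, g, dt);
    pos(t, 0) = d.x[0]; pos(t, 1) = d.x[1]; pos(t, 2) = d.x[2];
    tilt[t] = d.tilt; thrust[t] = d.thrust;
  }
  return List::create(_["positions"] = pos, _["tilt"] = tilt,
                      _["thrust"] = thrust, _["state"] = drone_to_list(d),
                      _["gust"] = NumericVector::create(g[0], g[1], g[2]));
}
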