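#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Agent-based core of the arena simulator. One call integrates a full
// trial at fixed time step dt, updating mosquitofish (correlated random
// walk + cohesion/alignment + robot avoidance), tadpoles (slower
// correlated random walk with short perception range and optional
// coupling to recent fish turning activity), and the robotic predator
// (patrol trajectory + three-tier attack state machine).
//
// Uses R's RNG, so results are reproducible under set.seed().

static inline double wrap_angle(double a) {
  while (a >= M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_fish, int n_tad, bool robot_present,
              int n_frames, double dt, double r_use,
              NumericVector x0, NumericVector y0, NumericVector h0,
              IntegerVector attack_frames, NumericMatrix patrol,
              List par) {
  const double v_fish = par["v_fish"], v_tad = par["v_tad"];
  const double sig_fish = par["sig_fish"], sig_tad = par["sig_tad"];
  const double k_coh = par["k_coh"], k_align = par["k_align"];
  const double k_rep = par["k_rep"], rep_radius = par["rep_radius"];
  const double k_wall = par["k_wall"], wall_margin = par["wall_margin"];
  const double turn_max = par["turn_max"], k_flee = par["k_flee"];
  const double r_percep_fish = par["r_percep_fish"];
  const double r_percep_tad = par["r_percep_tad"];
  const double fear = par["fear_gain"], g_tf = par["g_tf"], g_ft = par["g_ft"];
  const double tau_act = par["tau_act"], s_act = par["s_act"];
  const double act_impulse = par["act_impulse"];
  const int window = par["window"];
  const double accel = par["accel"], vmax = par["vmax"];
  const double standoff = par["standoff"], hold_s = par["hold_s"];
  const double pursue_cap = par["pursue_cap"];
  const double patrol_speed = par["patrol_speed"];
  const double contact_r = par["contact_r"], inspect_r = par["inspect_r"];
  const double speed_jitter = par["speed_jitter"];
  const double vmax_fish = par["vmax_fish"], vmax_tad = par["vmax_tad"];

  const int n_anim = n_fish + n_tad;
  const int n_agents = n_anim + (robot_present ? 1 : 0);
  const int i_rob = n_anim;  // robot column index when present

  NumericMatrix X(n_frames, n_agents), Y(n_frames, n_agents),
      H(n_frames, n_agents);
  NumericVector rob_speed(n_frames);

  std::vector<double> px(x0.begin(), x0.end());
  std::vector<double> py(y0.begin(), y0.end());
  std::vector<double> ph(h0.begin(), h0.end());
  // escape-burst energy per fish: bursts are anaerobic, so sustained
  // fleeing fades and recovers when the predator is away
  std::vector<double> flee_en(std::max(n_fish, 1), 1.0);

  // activity (agitation) OU processes, one per species
  double a_f = 0.0, a_t = 0.0;
  const double ou_sd = s_act * std::sqrt(2.0 * dt / tau_act);

  // ring buffers of per-frame mean |heading change| per species
  std::vector<double> buf_f(window, 0.0), buf_t(window, 0.0);
  double sum_f = 0.0, sum_t = 0.0;
  // start the ring buffer so that drive refreshes align with the windows of
  // the measured (displacement-based) turning signal, which lags heading
  // changes by two frames
  int buf_pos = std::min(2, window - 1);
  // slow reference level (EMA) of the windowed turning magnitude
  double ema_f = sig_fish * std::sqrt(dt) * 0.8;
  double ema_t = sig_tad * std::sqrt(dt) * 0.8;
  const double ema_alpha = dt / 30.0;
  double hold_zf = 0.0, hold_zt = 0.0;  // drives held per tick window

  // robot controller state
  int rob_state = 0;  // 0 idle, 1 pursue, 2 hold, 3 return
  int rob_tier = -1, rob_target = -1;
  double rob_v = 0.0, hold_left = 0.0, pursue_elapsed = 0.0;
  double home_x = 0.0, home_y = 0.0, home_h = 0.0;
  double patrol_pos = 0.0;  // fractional index into the patrol table
  const int n_patrol = patrol.nrow();
  int next_attack = 0;
  const int n_attacks = attack_frames.size();

  std::vector<double> log_trig, log_dist, log_complete;
  std::vector<int> log_target, log_tier;

  RNGScope scope;

  for (int k = 0; k < n_frames; k++) {
    // record current state
    for (int i = 0; i < n_anim; i++) {
      X(k, i) = px[i]; Y(k, i) = py[i]; H(k, i) = ph[i];
    }
    if (robot_present) {
      X(k, i_rob) = px[i_rob]; Y(k, i_rob) = py[i_rob]; H(k, i_rob) = ph[i_rob];
      rob_speed[k] = rob_v;
    }
    if (k == n_frames - 1) break;

    // ---- robot ----
    bool attack_started = false;
    if (robot_present) {
      if (next_attack < n_attacks && k >= attack_frames[next_attack]) {
        if (rob_state == 0 && n_fish > 0) {
          // target: the fish closest to its nearest tadpole
          int best = 0; double best_d = R_PosInf;
          for (int i = 0; i < n_fish; i++) {
            double dmin = R_PosInf;
            if (n_tad > 0) {
              for (int j = n_fish; j < n_anim; j++) {
                double dx = px[i] - px[j], dy = py[i] - py[j];
                double d = dx * dx + dy * dy;
                if (d < dmin) dmin = d;
              }
            } else {
              double dx = px[i] - px[i_rob], dy = py[i] - py[i_rob];
              dmin = dx * dx + dy * dy;
            }
            if (dmin < best_d) { best_d = dmin; best = i; }
          }
          rob_target = best;
          double dx = px[rob_target] - px[i_rob];
          double dy = py[rob_target] - py[i_rob];
          double d0 = std::sqrt(dx * dx + dy * dy);
          rob_tier = d0 < contact_r ? 0 : (d0 <= inspect_r ? 1 : 2);
          home_x = px[i_rob]; home_y = py[i_rob]; home_h = ph[i_rob];
          log_trig.push_back(k * dt);
          log_target.push_back(rob_target);
          log_dist.push_back(d0);
          log_tier.push_back(rob_tier);
          log_complete.push_back(NA_REAL);
          if (d0 > 0) ph[i_rob] = std::atan2(dy, dx);  // face the fish
          if (rob_tier == 0) {  // contact: brake in place, then hold
            rob_state = 4;
          } else {  // approach starts from the current (patrol) speed
            rob_state = 1; pursue_elapsed = 0.0;
          }
          attack_started = true;
        }
        next_attack++;  // consume (skip if robot was busy)
      }

      if (rob_state == 0) {  // idle: follow the patrol loop, ramping up
        rob_v = std::min(patrol_speed, rob_v + accel * dt);
        patrol_pos += rob_v / patrol_speed;
        int idx = ((long)patrol_pos) % n_patrol;
        px[i_rob] = patrol(idx, 0);
        py[i_rob] = patrol(idx, 1);
        ph[i_rob] = patrol(idx, 2);
      } else if (rob_state == 1) {  // pursue current target position
        pursue_elapsed += dt;
        double gx = px[rob_target], gy = py[rob_target];
        double dx = gx - px[i_rob], dy = gy - py[i_rob];
        double dist = std::sqrt(dx * dx + dy * dy);
        double remaining = dist - standoff;
        if (remaining <= 1.0 || pursue_elapsed >= pursue_cap) {
          // within the approach band of the (moving) fish, or pursuit
          // timed out: brake to rest at 20 cm/s^2, then hold
          rob_state = 4;
        } else {
          ph[i_rob] = std::atan2(dy, dx);
          bool brake = (rob_v * rob_v / (2.0 * accel) + rob_v * dt) >= remaining;
          double v_next = brake ? std::max(0.0, rob_v - accel * dt)
                                : std::min(vmax, rob_v + accel * dt);
          if (v_next <= 0.0) v_next = std::min(vmax, accel * dt);
          double step = std::min(v_next * dt, remaining);
          px[i_rob] += step * dx / dist;
          py[i_rob] += step * dy / dist;
          rob_v = v_next;
          if (remaining - step <= 1e-9) rob_state = 4;
        }
      } else if (rob_state == 4) {  // terminal brake at the standoff
        rob_v = std::max(0.0, rob_v - accel * dt);
        px[i_rob] += rob_v * dt * std::cos(ph[i_rob]);
        py[i_rob] += rob_v * dt * std::sin(ph[i_rob]);
        if (rob_v <= 1e-9) { rob_v = 0.0; rob_state = 2; hold_left = hold_s; }
      } else if (rob_state == 2) {  // hold
        rob_v = 0.0;
        hold_left -= dt;
        if (hold_left <= 1e-9) rob_state = 3;
      } else if (rob_state == 5) {  // settle at home: ramp the command down
        rob_v = std::max(0.0, rob_v - accel * dt);
        if (rob_v <= 1e-9) {
          rob_v = 0.0; ph[i_rob] = home_h; rob_state = 0;
          log_complete.back() = (k + 1) * dt;
        }
      } else {  // return to pre-attack pose
        {
          double dx = home_x - px[i_rob], dy = home_y - py[i_rob];
          double dist = std::sqrt(dx * dx + dy * dy);
          if (dist <= 1e-9) {
            px[i_rob] = home_x; py[i_rob] = home_y;
            rob_state = 5;
          } else {
            ph[i_rob] = std::atan2(dy, dx);
            bool brake = (rob_v * rob_v / (2.0 * accel) + rob_v * dt) >= dist;
            double v_next = brake ? std::max(0.0, rob_v - accel * dt)
                                  : std::min(vmax, rob_v + accel * dt);
            if (v_next <= 0.0) v_next = std::min(vmax, accel * dt);
            double step = std::min(v_next * dt, dist);
            px[i_rob] += step * dx / dist;
            py[i_rob] += step * dy / dist;
            rob_v = v_next;
            if (dist - step <= 1e-9) {
              px[i_rob] = home_x; py[i_rob] = home_y;
              rob_state = 5;
            }
          }
        }
      }
      // the robot arm keeps the predator inside the arena
      double rr = std::sqrt(px[i_rob] * px[i_rob] + py[i_rob] * py[i_rob]);
      if (rr > r_use) { px[i_rob] *= r_use / rr; py[i_rob] *= r_use / rr; }
    }

    // ---- species activity processes ----
    a_f += -a_f * dt / tau_act + ou_sd * norm_rand();
    a_t += -a_t * dt / tau_act + ou_sd * norm_rand();
    if (attack_started) a_f += fear * act_impulse;

    // coupling drives: relative turning magnitude of the other species in
    // the last completed tick window (held constant within a window, so the
    // response lags the drive by exactly one tick)
    double mult_f = 1.0 + a_f + g_ft * hold_zt;
    double mult_t = 1.0 + a_t + g_tf * hold_zf;
    if (mult_f < 0.15) mult_f = 0.15; if (mult_f > 6.0) mult_f = 6.0;
    if (mult_t < 0.15) mult_t = 0.15; if (mult_t > 6.0) mult_t = 6.0;

    double frame_turn_f = 0.0, frame_turn_t = 0.0;

    // fish centroid (for cohesion)
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n_fish; i++) { cx += px[i]; cy += py[i]; }

    // ---- mosquitofish ----
    for (int i = 0; i < n_fish; i++) {
      double h = ph[i];
      double turn = 0.0;
      if (n_fish > 1) {
        double ox = (cx - px[i]) / (n_fish - 1) - px[i];
        double oy = (cy - py[i]) / (n_fish - 1) - py[i];
        if (ox != 0.0 || oy != 0.0)
          turn += k_coh * wrap_angle(std::atan2(oy, ox) - h);
        double sc = 0.0, ss = 0.0;
        double near_d = R_PosInf; int near_j = -1;
        for (int j = 0; j < n_fish; j++) {
          if (j == i) continue;
          sc += std::cos(ph[j]); ss += std::sin(ph[j]);
          double dx = px[i] - px[j], dy = py[i] - py[j];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < near_d) { near_d = d; near_j = j; }
        }
        turn += k_align * wrap_angle(std::atan2(ss, sc) - h);
        if (near_j >= 0 && near_d < rep_radius && near_d > 0) {
          double away = std::atan2(py[i] - py[near_j], px[i] - px[near_j]);
          turn += k_rep * (1.0 - near_d / rep_radius) * wrap_angle(away - h);
        }
      }
      double r = std::sqrt(px[i] * px[i] + py[i] * py[i]);
      if (r > r_use - wall_margin && r > 0) {
        double w = (r - (r_use - wall_margin)) / wall_margin;
        double to_c = std::atan2(-py[i], -px[i]);
        turn += k_wall * w * wrap_angle(to_c - h);
      }
      double v = v_fish * (1.0 + 0.3 * a_f);
      if (robot_present) {
        double dx = px[i] - px[i_rob], dy = py[i] - py[i_rob];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < r_percep_fish && d > 0) {
          double away = std::atan2(dy, dx);
          double w = 1.0 - d / r_percep_fish;
          turn += fear * k_flee * w * wrap_angle(away - h);
          v += 0.6 * fear * w * v_fish * flee_en[i];  // escape burst
          flee_en[i] = std::max(0.0, flee_en[i] - w * dt / 1.5);
        } else {
          flee_en[i] = std::min(1.0, flee_en[i] + dt / 6.0);
        }
      } else {
        flee_en[i] = std::min(1.0, flee_en[i] + dt / 6.0);
      }
      double tcap = turn_max * dt;
      if (turn > tcap) turn = tcap; if (turn < -tcap) turn = -tcap;
      double noise = mult_f * sig_fish * std::sqrt(dt) * norm_rand();
      double h_new = wrap_angle(h + turn + noise);
      frame_turn_f += std::fabs(wrap_angle(h_new - h));
      v += speed_jitter * norm_rand();
      if (v < 0.2) v = 0.2; if (v > vmax_fish) v = vmax_fish;
      double nx = px[i] + v * dt * std::cos(h_new);
      double ny = py[i] + v * dt * std::sin(h_new);
      double rn = std::sqrt(nx * nx + ny * ny);
      if (rn > r_use) {  // reflective wall
        double ux = nx / rn, uy = ny / rn;
        double dx = std::cos(h_new), dy = std::sin(h_new);
        double dot = dx * ux + dy * uy;
        double rx = dx - 2.0 * dot * ux, ry = dy - 2.0 * dot * uy;
        h_new = std::atan2(ry, rx);
        nx = px[i] + v * dt * rx;
        ny = py[i] + v * dt * ry;
        if (std::sqrt(nx * nx + ny * ny) > r_use) { nx = px[i]; ny = py[i]; }
      }
      px[i] = nx; py[i] = ny; ph[i] = h_new;
    }

    // ---- tadpoles ----
    for (int i = n_fish; i < n_anim; i++) {
      double h = ph[i];
      double turn = 0.0;
      // collision avoidance among tadpoles
      double near_d = R_PosInf; int near_j = -1;
      for (int j = n_fish; j < n_anim; j++) {
        if (j == i) continue;
        double dx = px[i] - px[j], dy = py[i] - py[j];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < near_d) { near_d = d; near_j = j; }
      }
      if (near_j >= 0 && near_d < rep_radius && near_d > 0) {
        double away = std::atan2(py[i] - py[near_j], px[i] - px[near_j]);
        turn += k_rep * (1.0 - near_d / rep_radius) * wrap_angle(away - h);
      }
      double r = std::sqrt(px[i] * px[i] + py[i] * py[i]);
      if (r > r_use - wall_margin && r > 0) {
        double w = (r - (r_use - wall_margin)) / wall_margin;
        double to_c = std::atan2(-py[i], -px[i]);
        turn += k_wall * w * wrap_angle(to_c - h);
      }
      double v = v_tad * (1.0 + 0.3 * a_t);
      if (robot_present) {  // tadpoles only notice the robot very close by
        double dx = px[i] - px[i_rob], dy = py[i] - py[i_rob];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < r_percep_tad && d > 0) {
          double away = std::atan2(dy, dx);
          double w = 1.0 - d / r_percep_tad;
          turn += k_flee * w * wrap_angle(away - h);
          v += w * v_tad;
        }
      }
      double tcap = turn_max * dt;
      if (turn > tcap) turn = tcap; if (turn < -tcap) turn = -tcap;
      double noise = mult_t * sig_tad * std::sqrt(dt) * norm_rand();
      double h_new = wrap_angle(h + turn + noise);
      frame_turn_t += std::fabs(wrap_angle(h_new - h));
      v += 0.3 * speed_jitter * norm_rand();
      if (v < 0.05) v = 0.05; if (v > vmax_tad) v = vmax_tad;
      double nx = px[i] + v * dt * std::cos(h_new);
      double ny = py[i] + v * dt * std::sin(h_new);
      double rn = std::sqrt(nx * nx + ny * ny);
      if (rn > r_use) {
        double ux = nx / rn, uy = ny / rn;
        double dx = std::cos(h_new), dy = std::sin(h_new);
        double dot = dx * ux + dy * uy;
        double rx = dx - 2.0 * dot * ux, ry = dy - 2.0 * dot * uy;
        h_new = std::atan2(ry, rx);
        nx = px[i] + v * dt * rx;
        ny = py[i] + v * dt * ry;
        if (std::sqrt(nx * nx + ny * ny) > r_use) { nx = px[i]; ny = py[i]; }
      }
      px[i] = nx; py[i] = ny; ph[i] = h_new;
    }

    // body exclusion: animals cannot interpenetrate; push overlapping
    // pairs apart symmetrically along their connecting axis
    const double d_min = 1.0;
    for (int i = 0; i < n_anim; i++) {
      for (int j = i + 1; j < n_anim; j++) {
        double dx = px[j] - px[i], dy = py[j] - py[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < d_min) {
          double ux, uy;
          if (d > 1e-9) { ux = dx / d; uy = dy / d; }
          else { ux = std::cos(ph[i]); uy = std::sin(ph[i]); }
          double push = 0.5 * (d_min - d);
          px[i] -= push * ux; py[i] -= push * uy;
          px[j] += push * ux; py[j] += push * uy;
          for (int a : {i, j}) {
            double ra = std::sqrt(px[a] * px[a] + py[a] * py[a]);
            if (ra > r_use) { px[a] *= r_use / ra; py[a] *= r_use / ra; }
          }
        }
      }
    }

    // the robot is a solid body: animals cannot sit under it
    if (robot_present) {
      const double d_rob = 2.4;
      for (int i = 0; i < n_anim; i++) {
        // the attacked fish is approached to the 1-cm standoff: it is not
        // displaced by the robot while the attack is in progress
        if (i == rob_target && (rob_state == 1 || rob_state == 2)) continue;
        double dx = px[i] - px[i_rob], dy = py[i] - py[i_rob];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < d_rob) {
          double ux, uy;
          if (d > 1e-9) { ux = dx / d; uy = dy / d; }
          else { ux = 1.0; uy = 0.0; }
          px[i] = px[i_rob] + d_rob * ux;
          py[i] = py[i_rob] + d_rob * uy;
          double ra = std::sqrt(px[i] * px[i] + py[i] * py[i]);
          if (ra > r_use) { px[i] *= r_use / ra; py[i] *= r_use / ra; }
        }
      }
    }

    // update windowed turning magnitudes and their slow references
    double mf = n_fish > 0 ? frame_turn_f / n_fish : 0.0;
    double mt = n_tad > 0 ? frame_turn_t / n_tad : 0.0;
    sum_f += mf - buf_f[buf_pos]; buf_f[buf_pos] = mf;
    sum_t += mt - buf_t[buf_pos]; buf_t[buf_pos] = mt;
    buf_pos = (buf_pos + 1) % window;
    ema_f += ema_alpha * (sum_f / window - ema_f);
    ema_t += ema_alpha * (sum_t / window - ema_t);
    if (buf_pos == 0) {  // a tick window just completed: refresh the drives
      hold_zf = sum_f / window / (ema_f + 1e-12) - 1.0;
      hold_zt = sum_t / window / (ema_t + 1e-12) - 1.0;
      if (hold_zf > 2.0) hold_zf = 2.0; if (hold_zf < -2.0) hold_zf = -2.0;
      if (hold_zt > 2.0) hold_zt = 2.0; if (hold_zt < -2.0) hold_zt = -2.0;
    }
  }

  return List::create(
      _["x"] = X, _["y"] = Y, _["heading"] = H,
      _["robot_speed"] = rob_speed,
      _["attack_t"] = wrap(log_trig),
      _["attack_target"] = wrap(log_target),
      _["attack_dist"] = wrap(log_dist),
      _["attack_tier"] = wrap(log_tier),
      _["attack_complete"] = wrap(log_complete));
}
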