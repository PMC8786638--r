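#' Behavioural parameters of the simulated animals
#'
#' Defaults describe young-adult mosquitofish (~2 cm body length, cruising
#' around 5 cm/s, schooling via cohesion and alignment) and slower motorbike
#' frog tadpoles (~6 cm, cruising around 1.5 cm/s, weakly social, able to
#' perceive the predator only in close proximity). Heading noise follows a
#' correlated random walk; a shared per-species agitation process
#' (Ornstein-Uhlenbeck) modulates turning activity and speed, and carries
#' the directed between-species coupling and the response to attacks.
#'
#' @param v_fish,v_tad Mean cruising speeds, cm/s.
#' @param vmax_fish,vmax_tad Speed caps, cm/s.
#' @param sig_fish,sig_tad Baseline heading-noise intensity, rad/sqrt(s).
#' @param k_coh,k_align,k_rep Weights of cohesion, alignment and
#'   close-range repulsion among fish (dimensionless).
#' @param rep_radius Fish-fish repulsion radius, cm.
#' @param k_wall Wall-avoidance turning weight; `wall_margin` its range, cm.
#' @param turn_max Cap on deterministic turning, rad/s.
#' @param k_flee Predator-avoidance turning weight.
#' @param r_percep_fish,r_percep_tad Distance at which fish / tadpoles
#'   perceive the robot, cm.
#' @param tau_act Agitation autocorrelation time, s.
#' @param s_act Stationary standard deviation of the agitation process.
#' @param act_impulse Agitation jump at each attack trigger (scaled by the
#'   fear gain).
#' @param speed_jitter Per-step speed noise SD, cm/s.
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(v_fish = 5, v_tad = 2.5, vmax_fish = 15, vmax_tad = 6,
                       sig_fish = 1.2, sig_tad = 0.8,
                       k_coh = 0.4, k_align = 0.3, k_rep = 1,
                       rep_radius = 2.5, k_wall = 1.5, wall_margin = 3,
                       turn_max = 6, k_flee = 2,
                       r_percep_fish = 10, r_percep_tad = 3,
                       tau_act = 3, s_act = 0.6, act_impulse = 2,
                       speed_jitter = 0.5) {
  structure(as.list(environment()), class = "sim_params")
}

# closed patrol loop: a smoothed Lissajous curve inside the patrol radius,
# resampled to constant arc-length steps of patrol_speed/fps; columns
# (x, y, heading)
make_patrol <- function(params = robot_params(), fps = 20) {
  r <- 0.9 * params$patrol_radius
  t <- seq(0, 2 * pi, length.out = 4001L)[-4001L]
  x <- r * sin(2 * t)
  y <- r * sin(3 * t + pi / 4)
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  step <- params$patrol_speed / fps
  n <- max(8L, floor(total / step))
  s_new <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  xs <- stats::approx(s, c(x, x[1]), xout = s_new)$y
  ys <- stats::approx(s, c(y, y[1]), xout = s_new)$y
  dx <- diff(c(xs, xs[1]))
  dy <- diff(c(ys, ys[1]))
  cbind(x = xs, y = ys, heading = atan2(dy, dx))
}

#' Simulate one trial in the arena
#'
#' Generates ground-truth trajectories for a mixed group of mosquitofish
#' and tadpoles over one trial, optionally with the interactive robotic
#' predator (robot-exposed treatment). The robot patrols a stored closed
#' curve and executes scheduled attacks, each targeting the mosquitofish
#' currently closest to its nearest tadpole. Directed behavioural coupling
#' between species is controlled by [coupling_spec()]. The same seed and
#' configuration always reproduce the identical recording.
#'
#' @param geometry An [arena_geometry()].
#' @param coupling A [coupling_spec()].
#' @param treatment `"non_exposed"` (no robot) or `"robot_exposed"`.
#' @param duration Trial duration, s.
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @param n_fish,n_tad Group sizes (defaults 6 and 6).
#' @param params A [sim_params()].
#' @param robot A [robot_params()].
#' @param attack_rate Nominal attack rate, attacks per minute.
#' @param standardize_attacks Optional exact number of attacks per trial.
#' @return An object of class `trial_recording`: frame-indexed position and
#'   heading matrices (one column per agent), an agent table, the attack
#'   log, and full provenance (seed, configuration).
#' @examples
#' rec <- simulate_trial(duration = 10, seed = 1)
#' rec
#' @export
simulate_trial <- function(geometry = arena_geometry(),
                           coupling = coupling_spec(),
                           treatment = c("robot_exposed", "non_exposed"),
                           duration = 3600, fps = 20, seed = 1L,
                           n_fish = 6L, n_tad = 6L,
                           params = sim_params(), robot = robot_params(),
                           attack_rate = 1, standardize_attacks = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(geometry, "arena_geometry"),
            inherits(coupling, "coupling_spec"),
            duration >= 0, n_fish >= 0, n_tad >= 0)
  if (fps <= 0 || abs(fps * duration - round(fps * duration)) > 1e-9) {
    stop("inconsistent fps/duration: fps * duration must be a whole frame count",
         call. = FALSE)
  }
  n_frames <- as.integer(round(fps * duration))
  if (n_frames < 1L) {
    stop("duration too short: no frames to simulate", call. = FALSE)
  }
  dt <- 1 / fps
  robot_present <- treatment == "robot_exposed"

  set.seed(as.integer(seed))
  d_max <- attack_max_duration(geometry, robot)
  triggers <- numeric(0)
  if (robot_present && duration > 0) {
    triggers <- schedule_attacks(duration, attack_rate, standardize_attacks,
                                 seed = sample.int(.Machine$integer.max, 1L),
                                 max_attack_duration = d_max)
  }

  r_use <- geometry$radius - 0.5
  n_anim <- n_fish + n_tad
  # initial placement: fish schooled around a random point, tadpoles spread
  centre <- stats::runif(2, -0.4, 0.4) * r_use
  fx <- centre[1] + stats::runif(n_fish, -4, 4)
  fy <- centre[2] + stats::runif(n_fish, -4, 4)
  tx <- stats::runif(n_tad, -0.7, 0.7) * r_use
  ty <- stats::runif(n_tad, -0.7, 0.7) * r_use
  x0 <- c(fx, tx); y0 <- c(fy, ty)
  rad <- sqrt(x0^2 + y0^2)
  scale <- pmin(1, (r_use - 1) / pmax(rad, 1e-9))
  x0 <- x0 * scale; y0 <- y0 * scale
  h0 <- stats::runif(n_anim, -pi, pi)

  patrol <- make_patrol(robot, fps)
  if (robot_present) {
    x0 <- c(x0, patrol[1, 1]); y0 <- c(y0, patrol[1, 2])
    h0 <- c(h0, patrol[1, 3])
  }

  par <- c(unclass(params),
           list(fear_gain = coupling$fish_fear_gain,
                g_tf = coupling$tadpole_from_fish_gain,
                g_ft = coupling$fish_from_tadpole_gain,
                window = max(1L, as.integer(round(fps / 2))),
                accel = robot$accel, vmax = robot$vmax,
                standoff = robot$standoff, hold_s = robot$hold_s,
                pursue_cap = robot$pursue_cap,
                patrol_speed = robot$patrol_speed,
                contact_r = 1, inspect_r = 10))

  res <- .sim_core(as.integer(n_fish), as.integer(n_tad), robot_present,
                   n_frames, dt, r_use, x0, y0, h0,
                   as.integer(round(triggers * fps)), patrol, par)

  species <- c(rep("mosquitofish", n_fish), rep("tadpole", n_tad),
               if (robot_present) "robot")
  ids <- c(sprintf("fish_%02d", seq_len(n_fish)),
           sprintf("tad_%02d", seq_len(n_tad)),
           if (robot_present) "robot_01")
  agents <- data.frame(agent_id = ids, species = species,
                       stringsAsFactors = FALSE)
  colnames(res$x) <- colnames(res$y) <- colnames(res$heading) <- ids

  attacks <- data.frame(
    t_trigger_s = res$attack_t,
    target_id = if (length(res$attack_target)) ids[res$attack_target + 1L]
                else character(0),
    initial_distance_cm = res$attack_dist,
    tier = c("contact", "inspection", "pursuit")[res$attack_tier + 1L],
    t_complete_s = res$attack_complete,
    stringsAsFactors = FALSE
  )

  structure(
    list(fps = fps, duration = duration, n_frames = n_frames,
         agents = agents, x = res$x, y = res$y, heading = res$heading,
         robot_speed = if (robot_present) res$robot_speed else NULL,
         attacks = attacks, treatment = treatment, seed = as.integer(seed),
         coupling = coupling, geometry = geometry,
         scheduled_triggers = triggers),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("trial_recording: %.0f s at %g fps (%d frames), %s\n",
              x$duration, x$fps, x$n_frames, x$treatment))
  ns <- table(x$agents$species)
  cat("  agents:", paste(sprintf("%d %s", ns, names(ns)), collapse = ", "), "\n")
  if (nrow(x$attacks)) {
    cat(sprintf("  attacks: %d (%s)\n", nrow(x$attacks),
                paste(sprintf("%d %s", table(x$attacks$tier),
                              names(table(x$attacks$tier))), collapse = ", ")))
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
plot.trial_recording <- function(x, which = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  r <- x$geometry$radius
  plot(r * cos(th), r * sin(th), type = "l", asp = 1, xlab = "x (cm)",
       ylab = "y (cm)", main = sprintf("trial (%s)", x$treatment), ...)
  lines(x$geometry$central_radius * cos(th),
        x$geometry$central_radius * sin(th), lty = 3, col = "grey")
  cols <- c(mosquitofish = "#1f77b4", tadpole = "#2ca02c", robot = "#d62728")
  idx <- if (is.null(which)) seq_len(nrow(x$agents)) else which
  for (i in idx) {
    lines(x$x[, i], x$y[, i], col = cols[[x$agents$species[i]]], lwd = 0.5)
  }
  invisible(x)
}

# positions of one species as (frames x n) matrices; shared by metrics and
# signal builders for both trial recordings and track sets
species_positions <- function(obj, species) {
  sel <- obj$agents$species == species
  if (!any(sel)) {
    stop("no agents of species '", species, "' present", call. = FALSE)
  }
  list(x = obj$x[, sel, drop = FALSE], y = obj$y[, sel, drop = FALSE])
}
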