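#' Robotic predator kinematic parameters
#'
#' The robot accelerates at 20 cm/s^2 up to a maximum speed of 20 cm/s,
#' stops 1 cm away from the targeted fish, holds for 1 s, then returns to
#' its pre-attack position and heading. A pursuit cap bounds how long the
#' robot will chase a fleeing target before giving up and holding in place.
#'
#' @param accel Acceleration magnitude, cm/s^2.
#' @param vmax Maximum speed, cm/s.
#' @param standoff Stopping distance from the target, cm.
#' @param hold_s Hold duration at the end of an approach, s.
#' @param pursue_cap Maximum pursuit duration, s.
#' @param patrol_speed Cruising speed along the patrol trajectory, cm/s.
#' @param patrol_radius Radius of the patrol curve, cm.
#' @return A list of class `robot_params`.
#' @export
robot_params <- function(accel = 20, vmax = 20, standoff = 1, hold_s = 1,
                         pursue_cap = 6, patrol_speed = 8,
                         patrol_radius = 15) {
  stopifnot(accel > 0, vmax > 0, standoff >= 0, hold_s >= 0, pursue_cap > 0,
            patrol_speed > 0, patrol_radius > 0)
  structure(list(accel = accel, vmax = vmax, standoff = standoff,
                 hold_s = hold_s, pursue_cap = pursue_cap,
                 patrol_speed = patrol_speed, patrol_radius = patrol_radius),
            class = "robot_params")
}

# time to cover distance d from rest to rest with a trapezoidal speed
# profile (accelerate at a, cruise at vmax, decelerate at a)
travel_time <- function(d, accel = 20, vmax = 20) {
  d_ramp <- vmax^2 / accel  # accel + decel distance when vmax is reached
  ifelse(d <= d_ramp, 2 * sqrt(d / accel), d / vmax + vmax / accel)
}

#' Worst-case duration of a single attack
#'
#' Upper bound on the time between an attack trigger and its completion:
#' the pursuit cap, plus the hold, plus the return leg across the full
#' arena diameter. The attack scheduler uses this bound to keep attacks
#' non-overlapping.
#'
#' @param geometry An [arena_geometry()].
#' @param params A [robot_params()].
#' @return Duration in seconds.
#' @export
attack_max_duration <- function(geometry = arena_geometry(),
                                params = robot_params()) {
  params$pursue_cap + params$hold_s +
    travel_time(geometry$diameter - params$standoff, params$accel, params$vmax)
}

#' Classify an attack tier from the robot-target distance
#'
#' Attacks come in three tiers keyed to the initial distance between robot
#' and targeted fish: contact (< 1 cm; the robot only turns toward the fish
#' and holds), inspection (1-10 cm; short approach), and pursuit (> 10 cm;
#' full acceleration to maximum speed).
#'
#' @param distance Robot-to-target distance in cm.
#' @param contact_radius,inspection_radius Tier thresholds in cm.
#' @return Character: `"contact"`, `"inspection"` or `"pursuit"`.
#' @export
attack_tier <- function(distance, contact_radius = 1, inspection_radius = 10) {
  stopifnot(all(distance >= 0))
  ifelse(distance < contact_radius, "contact",
         ifelse(distance <= inspection_radius, "inspection", "pursuit"))
}

#' Schedule attack trigger times for a trial
#'
#' Generates strictly increasing attack trigger times at approximately
#' `rate` attacks per minute. Consecutive triggers are separated by at least
#' the worst-case attack duration, so attacks never overlap, and every
#' scheduled attack can complete before the trial ends. Without
#' standardisation, each inter-trigger gap is the nominal period plus the
#' attack-time budget jitter, so an hour-long trial at one attack per minute
#' always yields fewer than 60 attacks. With `standardize_to`, exactly that
#' many triggers are drawn, one per equal-width bin.
#'
#' @param duration Trial duration in seconds.
#' @param rate Nominal attack rate in attacks per minute.
#' @param standardize_to Optional exact number of attacks.
#' @param seed Integer seed.
#' @param max_attack_duration Worst-case per-attack duration in seconds
#'   (see [attack_max_duration()]).
#' @return Numeric vector of trigger times in `[0, duration)`.
#' @export
schedule_attacks <- function(duration, rate = 1, standardize_to = NULL,
                             seed = 1L,
                             max_attack_duration = attack_max_duration()) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= 0,
            is.numeric(rate), rate > 0, max_attack_duration > 0)
  set.seed(as.integer(seed))
  period <- 60 / rate
  d_max <- max_attack_duration

  if (!is.null(standardize_to)) {
    n <- as.integer(standardize_to)
    if (n > floor(duration / 60 * rate)) {
      stop(sprintf(
        "standardize_to = %d infeasible: at most %d attacks fit a %.0f-s trial at %.2f per min",
        n, floor(duration / 60 * rate), duration, rate), call. = FALSE)
    }
    width <- (duration - d_max) / n
    if (width < d_max) {
      stop("standardize_to infeasible: bins narrower than the maximum attack duration",
           call. = FALSE)
    }
    u <- stats::runif(n, 0, width - d_max)
    return((seq_len(n) - 1) * width + u)
  }

  out <- numeric(0)
  t <- stats::runif(1, 0, period)
  gap_base <- max(period, d_max)
  while (t + d_max <= duration) {
    out <- c(out, t)
    t <- t + gap_base + stats::runif(1, 1, 5)
  }
  out
}

#' Begin an attack: snapshot the robot's state and classify the tier
#'
#' @param robot Robot state: a list with `position` (2-vector, cm),
#'   `heading` (rad) and `speed` (cm/s).
#' @param target_position Target fish position (2-vector, cm).
#' @return A controller phase object to feed to [attack_controller_step()].
#' @export
attack_begin <- function(robot, target_position) {
  d <- sqrt(sum((target_position - robot$position)^2))
  list(stage = "orient", tier = attack_tier(d), initial_distance = d,
       hold_left = NA_real_, pursue_elapsed = 0,
       home_position = robot$position, home_heading = robot$heading)
}

#' One control step of the robotic predator's attack state machine
#'
#' Advances the robot by one time step through the phases
#' idle-patrol / orient / pursue / hold / return. In the contact tier
#' (< 1 cm) the robot turns toward the fish without translating, holds 1 s,
#' and restores its heading. In the inspection and pursuit tiers it
#' accelerates at up to 20 cm/s^2 (capped at 20 cm/s), stops at the 1-cm
#' standoff from the current target position, holds 1 s, then returns to its
#' pre-attack position and heading with the same speed profile. Heading
#' changes are instantaneous.
#'
#' @param robot Robot state: list with `position`, `heading`, `speed`.
#' @param target_position Current position of the targeted fish (cm).
#' @param phase Controller phase from [attack_begin()] or a previous step;
#'   a phase with `stage = "idle"` leaves the robot untouched.
#' @param dt Time step in seconds (> 0).
#' @param geometry An [arena_geometry()]; the target must lie inside it.
#' @param params A [robot_params()].
#' @return List with elements `robot` (updated state) and `phase`.
#' @export
attack_controller_step <- function(robot, target_position, phase, dt,
                                   geometry = arena_geometry(),
                                   params = robot_params()) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar", call. = FALSE)
  }
  if (sqrt(sum(target_position^2)) > geometry$radius + 1e-9) {
    stop("target position outside arena", call. = FALSE)
  }
  stopifnot(phase$stage %in% c("idle", "orient", "pursue", "hold", "return"))

  move_towards <- function(robot, goal, stop_at) {
    vec <- goal - robot$position
    dist <- sqrt(sum(vec^2))
    remaining <- dist - stop_at
    if (remaining <= 1e-9) {
      robot$speed <- max(0, robot$speed - params$accel * dt)
      return(list(robot = robot, arrived = TRUE))
    }
    robot$heading <- atan2(vec[2], vec[1])
    v <- robot$speed
    # brake when the stopping distance at the next speed reaches the goal
    brake <- (v^2 / (2 * params$accel) + v * dt) >= remaining
    v_next <- if (brake) max(0, v - params$accel * dt)
              else min(params$vmax, v + params$accel * dt)
    if (v_next <= 0) v_next <- min(params$vmax, params$accel * dt)
    step <- min(v_next * dt, remaining)
    robot$position <- robot$position + step * vec / dist
    robot$speed <- v_next
    arrived <- (remaining - step) <= 1e-9
    list(robot = robot, arrived = arrived)
  }

  repeat {
    if (phase$stage == "idle") {
      robot$speed <- max(0, robot$speed - params$accel * dt)
      return(list(robot = robot, phase = phase))
    }
    if (phase$stage == "orient") {
      d <- sqrt(sum((target_position - robot$position)^2))
      if (d > 0) robot$heading <- atan2(target_position[2] - robot$position[2],
                                        target_position[1] - robot$position[1])
      robot$speed <- 0
      if (phase$tier == "contact") {
        phase$stage <- "hold"
        phase$hold_left <- params$hold_s
        return(list(robot = robot, phase = phase))
      }
      phase$stage <- "pursue"
      next
    }
    if (phase$stage == "pursue") {
      phase$pursue_elapsed <- phase$pursue_elapsed + dt
      mv <- move_towards(robot, target_position, params$standoff)
      robot <- mv$robot
      if (mv$arrived || phase$pursue_elapsed >= params$pursue_cap) {
        phase$stage <- "hold"
        phase$hold_left <- params$hold_s
      }
      return(list(robot = robot, phase = phase))
    }
    if (phase$stage == "hold") {
      # residual approach speed decays at the acceleration limit
      robot$speed <- max(0, robot$speed - params$accel * dt)
      phase$hold_left <- phase$hold_left - dt
      if (phase$hold_left <= 1e-9) phase$stage <- "return"
      return(list(robot = robot, phase = phase))
    }
    # return
    if (phase$tier == "contact") {
      robot$heading <- phase$home_heading
      robot$speed <- 0
      phase$stage <- "idle"
      return(list(robot = robot, phase = phase))
    }
    mv <- move_towards(robot, phase$home_position, 0)
    robot <- mv$robot
    if (mv$arrived) {
      robot$position <- phase$home_position
      robot$heading <- phase$home_heading
      phase$stage <- "idle"
    }
    return(list(robot = robot, phase = phase))
  }
}
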