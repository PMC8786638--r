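#' Constant-velocity Kalman filter for track smoothing and gap filling
#'
#' Each track carries a four-dimensional state (x, y, vx, vy) evolving
#' under a constant-velocity motion model with white-acceleration process
#' noise. With an observation the filter performs the standard
#' predict-update cycle; when the detection is missed, the prediction alone
#' extrapolates the track (and the appended sample is flagged as
#' predicted).
#'
#' @param position Initial position (2-vector).
#' @param velocity Initial velocity estimate (2-vector).
#' @param pos_var,vel_var Initial variances for position and velocity; a
#'   large `vel_var` encodes an uninformative initial velocity.
#' @return A `kalman_state` list with `x` (state) and `P` (covariance).
#' @export
kalman_init <- function(position, velocity = c(0, 0), pos_var = 1,
                        vel_var = 100) {
  stopifnot(length(position) == 2L, all(is.finite(position)))
  list(x = c(position, velocity),
       P = diag(c(pos_var, pos_var, vel_var, vel_var)))
}

#' @rdname kalman_init
#' @param state A `kalman_state` from [kalman_init()] or a previous step.
#' @param observation Observed position (2-vector), or `NULL` for a missed
#'   detection.
#' @param dt Time step in seconds.
#' @param process_noise White-acceleration spectral density q; the process
#'   covariance is the standard piecewise-constant acceleration form.
#' @param measurement_noise Measurement variance r (same for x and y).
#' @return `kalman_step` returns the updated state with an added
#'   `predicted_position` element (the prior used for gating) and
#'   `observed` flag.
#' @export
kalman_step <- function(state, observation = NULL, dt,
                        process_noise = 2, measurement_noise = 0.01) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(observation) && any(!is.finite(observation))) {
    stop("non-finite observation", call. = FALSE)
  }
  f <- diag(4)
  f[1, 3] <- f[2, 4] <- dt
  q <- process_noise
  q11 <- q * dt^3 / 3; q13 <- q * dt^2 / 2; q33 <- q * dt
  qm <- matrix(0, 4, 4)
  qm[1, 1] <- qm[2, 2] <- q11
  qm[1, 3] <- qm[3, 1] <- qm[2, 4] <- qm[4, 2] <- q13
  qm[3, 3] <- qm[4, 4] <- q33

  x_pred <- f %*% state$x
  p_pred <- f %*% state$P %*% t(f) + qm

  if (is.null(observation)) {
    return(list(x = drop(x_pred), P = p_pred,
                predicted_position = drop(x_pred)[1:2], observed = FALSE))
  }
  hmat <- matrix(0, 2, 4); hmat[1, 1] <- hmat[2, 2] <- 1
  s <- hmat %*% p_pred %*% t(hmat) + diag(measurement_noise, 2)
  k <- p_pred %*% t(hmat) %*% solve(s)
  innov <- observation - drop(hmat %*% x_pred)
  x_new <- drop(x_pred + k %*% innov)
  p_new <- (diag(4) - k %*% hmat) %*% p_pred
  list(x = x_new, P = p_new,
       predicted_position = drop(x_pred)[1:2], observed = TRUE)
}
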