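#' Build a group-level signal at half-second resolution
#'
#' Two group signals underlie the information-flow analysis, both sampled
#' on a regular grid of `dt`-spaced ticks (default 0.5 s):
#' `turning_magnitude` is the average over group members of the unsigned
#' turning rate (rad/s), averaged within each tick window (a rate is
#' averaged); `central_count` is the number of the species' individuals
#' inside the central region (radius < 15 cm) at each tick instant (a state
#' is sampled). A 60-min trial at 0.5-s ticks gives 7,200 signal points.
#'
#' @param obj A `trial_recording` or `track_set`.
#' @param variable `"turning_magnitude"` or `"central_count"`.
#' @param species Species whose group signal to build.
#' @param dt Tick spacing in seconds; the frame rate must be at least
#'   `1/dt` and a whole number of frames must fit each tick.
#' @param motion_floor Displacement floor (cm/step) below which a step's
#'   turning contribution is zero.
#' @return An object of class `group_signal` with fields `values`,
#'   `variable`, `species`, `dt`.
#' @export
group_signal <- function(obj,
                         variable = c("turning_magnitude", "central_count"),
                         species = "mosquitofish", dt = 0.5,
                         motion_floor = 0.1) {
  variable <- match.arg(variable)
  fps <- obj$fps
  if (fps < 1 / dt) stop("sampling rate below 1/dt", call. = FALSE)
  step <- fps * dt
  if (abs(step - round(step)) > 1e-9) {
    stop("dt must be a whole number of frames", call. = FALSE)
  }
  step <- as.integer(round(step))
  p <- species_positions(obj, species)
  n_frames <- nrow(p$x)
  n_win <- n_frames %/% step
  if (n_win < 1L) stop("recording shorter than one tick", call. = FALSE)

  if (variable == "turning_magnitude") {
    ang <- turning_angles(p$x, p$y, motion_floor)
    ang[is.na(ang)] <- 0  # at rest: no turning
    g <- rep(0, n_frames)
    if (nrow(ang)) g[3:n_frames] <- rowMeans(ang) * fps
    idx <- rep(seq_len(n_win), each = step)
    values <- as.numeric(tapply(g[seq_len(n_win * step)], idx, mean))
  } else {
    r <- sqrt(p$x^2 + p$y^2)
    ticks <- seq_len(n_win) * step
    values <- rowSums(r[ticks, , drop = FALSE] <
                        obj$geometry$central_radius)
  }
  structure(list(values = values, variable = variable, species = species,
                 dt = dt), class = "group_signal")
}

#' @export
print.group_signal <- function(x, ...) {
  cat(sprintf("group_signal: %s of %s, %d points at dt = %g s\n",
              x$variable, x$species, length(x$values), x$dt))
  invisible(x)
}

#' Symbolize a signal into a binary increase/no-increase sequence
#'
#' Each consecutive pair of signal values is encoded as `"+"` if the signal
#' increased and `"-"` if it stayed equal or decreased; the symbolic series
#' is one element shorter than the signal.
#'
#' @param signal A `group_signal` or a numeric vector.
#' @return Character vector over `{"+", "-"}` of class `symbolic_series`.
#' @examples
#' symbolize(c(1.0, 1.2, 1.2, 0.9))
#' @export
symbolize <- function(signal) {
  values <- if (inherits(signal, "group_signal")) signal$values else signal
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite signal values", call. = FALSE)
  n <- length(values)
  structure(ifelse(values[-1] > values[-n], "+", "-"),
            class = "symbolic_series")
}

# symbolic input -> integer 0/1 ( "+" = 1 )
as_binary_symbols <- function(s) {
  if (inherits(s, "symbolic_series") || is.character(s)) {
    if (!all(s %in% c("+", "-"))) stop("symbols must be '+' or '-'",
                                       call. = FALSE)
    return(as.integer(s == "+"))
  }
  if (is.logical(s)) return(as.integer(s))
  if (is.numeric(s)) {
    if (!all(s %in% c(0, 1))) stop("numeric symbols must be 0/1",
                                   call. = FALSE)
    return(as.integer(s))
  }
  stop("unsupported symbol encoding", call. = FALSE)
}
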