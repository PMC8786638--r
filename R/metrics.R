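#' Group cohesion: average furthest neighbour distance (AFND)
#'
#' For each frame, each individual's distance to its furthest group-mate is
#' averaged over individuals; the trial value is the mean over frames.
#' AFND measures group dispersion: it never falls below the average
#' inter-individual distance.
#'
#' @param x,y Numeric matrices (frames x individuals) of positions in cm
#'   for one species.
#' @return AFND in cm.
#' @export
afnd <- function(x, y) {
  check_group(x, y)
  mean(vapply(seq_len(nrow(x)), function(k) {
    d <- as.matrix(stats::dist(cbind(x[k, ], y[k, ])))
    mean(apply(d, 1, max))
  }, numeric(1)))
}

#' Group cohesion: average inter-individual distance (AIID)
#'
#' Mean over all unordered pairs of individuals of their distance, per
#' frame, then averaged over frames.
#'
#' @inheritParams afnd
#' @return AIID in cm.
#' @export
aiid <- function(x, y) {
  check_group(x, y)
  mean(vapply(seq_len(nrow(x)), function(k) {
    mean(stats::dist(cbind(x[k, ], y[k, ])))
  }, numeric(1)))
}

check_group <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (ncol(x) < 2L) {
    stop("group metric undefined for fewer than 2 individuals",
         call. = FALSE)
  }
  if (nrow(x) < 1L) stop("no frames", call. = FALSE)
  invisible(TRUE)
}

#' Distance swam over a trial
#'
#' Sum of successive Euclidean displacements per individual, averaged over
#' the individuals of the species.
#'
#' @inheritParams afnd
#' @return Mean path length in cm.
#' @export
distance_swam <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            nrow(x) >= 2L)
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  mean(colSums(steps))
}

#' Average turning rate
#'
#' Per time step, the unsigned angle between successive displacement
#' vectors divided by the step duration; steps in which either displacement
#' is below the motion floor are skipped (heading is undefined at rest).
#' The value is the mean over retained steps per individual, then the mean
#' over individuals.
#'
#' @inheritParams afnd
#' @param dt Time step in seconds.
#' @param motion_floor Minimum displacement (cm) per step for the turning
#'   angle to be defined.
#' @return Turning rate in rad/s.
#' @export
turning_rate <- function(x, y, dt, motion_floor = 0.1) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            nrow(x) >= 3L, dt > 0)
  ang <- turning_angles(x, y, motion_floor)
  per_ind <- colMeans(ang, na.rm = TRUE) / dt
  if (all(!is.finite(per_ind))) {
    stop("turning rate undefined: all steps below the motion floor",
         call. = FALSE)
  }
  mean(per_ind[is.finite(per_ind)])
}

# unsigned turning angles between successive displacement vectors;
# (frames-2) x individuals, NA where motion floor not met
turning_angles <- function(x, y, motion_floor = 0.1) {
  dx <- diff(x); dy <- diff(y)
  len <- sqrt(dx^2 + dy^2)
  n <- nrow(dx)
  a1x <- dx[-n, , drop = FALSE]; a1y <- dy[-n, , drop = FALSE]
  a2x <- dx[-1, , drop = FALSE]; a2y <- dy[-1, , drop = FALSE]
  dotp <- a1x * a2x + a1y * a2y
  crs <- a1x * a2y - a1y * a2x
  ang <- abs(atan2(crs, dotp))
  ang[len[-n, , drop = FALSE] < motion_floor |
        len[-1, , drop = FALSE] < motion_floor] <- NA_real_
  ang
}

#' Time spent in each concentric region of the arena
#'
#' Assigns every sample to its concentric ring (half-open 3-cm rings; the
#' outermost ring includes the wall), and condenses rings into the central
#' (0-15 cm) and external (15-21 cm) regions. Times are sample counts over
#' fps, summed over the species' individuals and divided by the group size,
#' so that `central_s + external_s` equals the trial duration.
#'
#' @inheritParams afnd
#' @param geometry An [arena_geometry()].
#' @param fps Frames per second.
#' @return List with `central_s`, `external_s` and `per_ring_s`
#'   (vector of length `n_rings`).
#' @export
region_occupancy <- function(x, y, geometry = arena_geometry(), fps = 20) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)), fps > 0)
  r <- sqrt(x^2 + y^2)
  ring <- ring_index(r, geometry)
  counts <- tabulate(ring + 1L, nbins = geometry$n_rings)
  n_ind <- ncol(x)
  per_ring <- counts / fps / n_ind
  central_rings <- seq_len(ceiling(geometry$central_radius /
                                     geometry$ring_width))
  list(central_s = sum(per_ring[central_rings]),
       external_s = sum(per_ring[-central_rings]),
       per_ring_s = per_ring)
}

#' Fulton's condition factor
#'
#' Body-condition index `K = weight / length^3 * 10^4` (g mm^-3 10^4), a
#' standard proxy for energy reserves in fish.
#'
#' @param weight Body weight in g (>= 0).
#' @param length Standard length in mm (> 0).
#' @return K, in g mm^-3 10^4. Vectorised.
#' @examples
#' fulton_k(0.15, 21.32)
#' @export
fulton_k <- function(weight, length) {
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  if (any(weight < 0)) stop("weight must be non-negative", call. = FALSE)
  weight / length^3 * 1e4
}

#' Per-trial, per-species behaviour summary
#'
#' Computes the full metric vector (AFND, AIID, distance swam, turning
#' rate, central/external/per-ring occupancy) for each animal species in a
#' trial recording or track set. Predicted (gap-filled) tracker samples are
#' included, as in the original real-time system.
#'
#' @param obj A `trial_recording` or `track_set`.
#' @param trial_id Identifier copied into the output.
#' @param species Species to summarise (default: the animal species
#'   present).
#' @return A data.frame with one row per species.
#' @export
behavior_summary <- function(obj, trial_id = "trial",
                             species = intersect(c("mosquitofish", "tadpole"),
                                                 obj$agents$species)) {
  fps <- obj$fps
  rows <- lapply(species, function(sp) {
    p <- species_positions(obj, sp)
    occ <- region_occupancy(p$x, p$y, obj$geometry, fps)
    data.frame(trial_id = trial_id, species = sp,
               afnd_cm = afnd(p$x, p$y), aiid_cm = aiid(p$x, p$y),
               distance_swam_cm = distance_swam(p$x, p$y),
               turning_rate_rad_s = turning_rate(p$x, p$y, dt = 1 / fps),
               central_time_s = occ$central_s,
               external_time_s = occ$external_s,
               t(stats::setNames(occ$per_ring_s,
                                 paste0("ring", seq_along(occ$per_ring_s) - 1,
                                        "_time_s"))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
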