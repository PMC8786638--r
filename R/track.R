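#' Tracker configuration
#'
#' Defaults match the default [render_config()]: species are separated by
#' blob area and intensity bands that are pairwise disjoint, the
#' robot by its distinct intensity band (which is also how its image is
#' prevented from interfering with animal tracking). The assignment gate is
#' a generous upper bound on per-frame displacement at 20 fps.
#'
#' @param group_sizes Named integer vector: expected number of tracks per
#'   species (closed population; tracks are seeded once).
#' @param thresholds Gray-level thresholds; `NULL` fits them from the first
#'   three frames with [fit_thresholds()].
#' @param area_bounds Per-species blob area ranges (px^2) used by [detect()].
#' @param criteria Per-species classification intervals, see
#'   [classify_species()].
#' @param typical_area Typical single-animal blob area per species (px^2);
#'   detections well above this are treated as merged blobs.
#' @param gate_cm Assignment gate in cm per frame.
#' @param coalesce_cm Radius within which an undetected individual's
#'   prediction is considered merged into a neighbouring blob.
#' @param process_noise,measurement_noise Kalman parameters, cm units.
#' @param cm_per_pixel Image scale.
#' @param geometry An [arena_geometry()].
#' @return List of class `track_config`.
#' @export
track_config <- function(group_sizes = c(mosquitofish = 6L, tadpole = 6L,
                                         robot = 1L),
                         thresholds = NULL,
                         area_bounds = list(mosquitofish = c(25, 260),
                                            tadpole = c(121, 560),
                                            robot = c(401, 900)),
                         criteria = list(
                           mosquitofish = list(area = c(25, 260),
                                               intensity = c(140, 200)),
                           tadpole = list(area = c(121, 560),
                                          intensity = c(80, 135)),
                           robot = list(area = c(401, 900),
                                        intensity = c(205, 255))),
                         typical_area = c(mosquitofish = 60, tadpole = 240,
                                          robot = 520),
                         gate_cm = 5, coalesce_cm = 1.2,
                         process_noise = 2, measurement_noise = 0.01,
                         cm_per_pixel = 0.1,
                         geometry = arena_geometry()) {
  structure(as.list(environment()), class = "track_config")
}

#' Track all individuals through a frame stack
#'
#' Runs the full tracking chain per frame: multiple-threshold blob
#' detection, species classification by body characteristics, optimal
#' assignment of detections to the predicted track positions (per species),
#' and a constant-velocity Kalman update. Individuals missing from a frame
#' are carried by the Kalman prediction and flagged `predicted`. Pixel
#' coordinates are converted to arena-centred cm (y up) at the boundary.
#'
#' @param stack A `frame_stack` from [render_frames()], a list of grayscale
#'   matrices (0-255), or a directory of PNG/TIFF frames.
#' @param config A [track_config()].
#' @param fps Frames per second (taken from the stack when available).
#' @return An object of class `track_set`: position matrices `x`, `y`
#'   (frames x tracks, cm), logical `observed` matrix, an `agents` table
#'   with track ids and species, plus scale and geometry metadata.
#' @export
track_trial <- function(stack, config = track_config(), fps = 20) {
  if (is.character(stack)) stack <- read_frames(stack)
  if (inherits(stack, "frame_stack")) {
    fps <- stack$fps
    frames <- stack$frames
  } else {
    frames <- stack
  }
  stopifnot(inherits(config, "track_config"))
  n_frames <- length(frames)
  if (n_frames == 0L) {
    return(structure(list(
      x = matrix(numeric(0), 0, 0), y = matrix(numeric(0), 0, 0),
      observed = matrix(logical(0), 0, 0),
      agents = data.frame(agent_id = character(0), species = character(0)),
      fps = fps, cm_per_pixel = config$cm_per_pixel,
      geometry = config$geometry), class = "track_set"))
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frame size changes mid-stack", call. = FALSE)
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  s <- config$cm_per_pixel
  thr <- config$thresholds
  if (is.null(thr)) {
    thr <- fit_thresholds(frames[seq_len(min(3L, n_frames))])
    if (!length(thr)) stop("threshold fitting failed: uniform frames?",
                           call. = FALSE)
  }
  gate_px <- config$gate_cm / s
  species_names <- names(config$group_sizes)
  dt <- 1 / fps
  typical <- config$typical_area
  # merged blobs (area well above a single animal) carry a centroid offset;
  # blend with the track's own prediction to keep identities apart
  blend_pos <- function(obs, pred, area, sp) {
    if (area > 1.6 * typical[[sp]]) (obs + pred) / 2 else obs
  }

  tracks <- list()  # each: species, filter, x[], y[], obs[]
  new_track <- function(sp, x_px, y_px, frame) {
    xs <- rep(x_px, n_frames); ys <- rep(y_px, n_frames)
    ob <- rep(FALSE, n_frames)
    ob[frame] <- TRUE
    list(species = sp, filter = kalman_init(c(x_px, y_px)),
         x = xs, y = ys, obs = ob)
  }

  for (k in seq_len(n_frames)) {
    det <- detect(frames[[k]], thr, config$area_bounds)
    det <- classify_species(det, config$criteria)
    for (sp in species_names) {
      dsp <- det[det$species == sp, , drop = FALSE]
      t_idx <- which(vapply(tracks, function(t) t$species == sp, logical(1)))
      if (length(t_idx)) {
        # predict all live tracks of this species
        preds <- matrix(NA_real_, length(t_idx), 2)
        filt_pred <- vector("list", length(t_idx))
        for (m in seq_along(t_idx)) {
          st <- kalman_step(tracks[[t_idx[m]]]$filter, NULL, dt,
                            config$process_noise, config$measurement_noise)
          preds[m, ] <- st$predicted_position
          filt_pred[[m]] <- st
        }
        am <- assign_detections(preds, cbind(dsp$x_px, dsp$y_px),
                                gate = gate_px)
        matched_det <- integer(0)
        if (nrow(am$matches)) {
          for (r in seq_len(nrow(am$matches))) {
            m <- am$matches[r, "track"]; d <- am$matches[r, "detection"]
            ti <- t_idx[m]
            obs <- blend_pos(c(dsp$x_px[d], dsp$y_px[d]), preds[m, ],
                             dsp$area[d], sp)
            tracks[[ti]]$filter <- kalman_step(tracks[[ti]]$filter, obs, dt,
                                               config$process_noise,
                                               config$measurement_noise)
            tracks[[ti]]$x[k] <- obs[1]; tracks[[ti]]$y[k] <- obs[2]
            tracks[[ti]]$obs[k] <- TRUE
          }
          matched_det <- am$matches[, "detection"]
        }
        # closed population: an unmatched detection alongside an unmatched
        # track means the track lost its animal (e.g. filter divergence
        # after a misassociation); recover by re-seeding the track there
        um_t <- am$unmatched_tracks
        um_d <- am$unmatched_detections
        while (length(um_t) && length(um_d)) {
          dmat <- outer(seq_along(um_t), seq_along(um_d),
                        function(a, b) sqrt((preds[um_t[a], 1] -
                                               dsp$x_px[um_d[b]])^2 +
                                              (preds[um_t[a], 2] -
                                                 dsp$y_px[um_d[b]])^2))
          pick <- arrayInd(which.min(dmat), dim(dmat))
          ti <- t_idx[um_t[pick[1]]]
          d <- um_d[pick[2]]
          tracks[[ti]]$filter <- kalman_init(c(dsp$x_px[d], dsp$y_px[d]))
          tracks[[ti]]$x[k] <- dsp$x_px[d]; tracks[[ti]]$y[k] <- dsp$y_px[d]
          tracks[[ti]]$obs[k] <- TRUE
          am$unmatched_tracks <- setdiff(am$unmatched_tracks, um_t[pick[1]])
          um_t <- um_t[-pick[1]]
          um_d <- um_d[-pick[2]]
        }
        for (m in am$unmatched_tracks) {
          ti <- t_idx[m]
          pp <- filt_pred[[m]]$predicted_position
          # occlusion: if the prediction lies on a same-species blob (two
          # animals merged into one component), ride that blob's centroid
          # rather than extrapolating blindly; identity is not resolved
          snapped <- FALSE
          dall <- det[det$species == sp, , drop = FALSE]
          if (nrow(dall)) {
            dd <- sqrt((dall$x_px - pp[1])^2 + (dall$y_px - pp[2])^2)
            j <- which.min(dd)
            if (dd[j] <= config$coalesce_cm / s) {
              obs <- (c(dall$x_px[j], dall$y_px[j]) + pp) / 2
              tracks[[ti]]$filter <- kalman_step(tracks[[ti]]$filter, obs,
                                                 dt, config$process_noise,
                                                 config$measurement_noise)
              tracks[[ti]]$x[k] <- obs[1]; tracks[[ti]]$y[k] <- obs[2]
              tracks[[ti]]$obs[k] <- FALSE
              snapped <- TRUE
            }
          }
          if (!snapped) {
            tracks[[ti]]$filter <- filt_pred[[m]][c("x", "P")]
            tracks[[ti]]$x[k] <- pp[1]
            tracks[[ti]]$y[k] <- pp[2]
            tracks[[ti]]$obs[k] <- FALSE
          }
        }
        dsp <- dsp[setdiff(seq_len(nrow(dsp)), matched_det), , drop = FALSE]
      }
      # seed tracks for this species up to its group size
      free <- config$group_sizes[[sp]] - length(t_idx)
      if (free > 0L && nrow(dsp)) {
        for (d in seq_len(min(free, nrow(dsp)))) {
          tracks[[length(tracks) + 1L]] <-
            new_track(sp, dsp$x_px[d], dsp$y_px[d], k)
        }
      }
    }
  }

  if (!length(tracks)) {
    return(structure(list(
      x = matrix(numeric(0), n_frames, 0), y = matrix(numeric(0), n_frames, 0),
      observed = matrix(logical(0), n_frames, 0),
      agents = data.frame(agent_id = character(0), species = character(0)),
      fps = fps, cm_per_pixel = s, geometry = config$geometry),
      class = "track_set"))
  }
  sp <- vapply(tracks, `[[`, character(1), "species")
  ord <- order(match(sp, species_names))
  tracks <- tracks[ord]; sp <- sp[ord]
  x_cm <- vapply(tracks, function(t) (t$x - cx) * s, numeric(n_frames))
  y_cm <- vapply(tracks, function(t) (cy - t$y) * s, numeric(n_frames))
  x_cm <- matrix(x_cm, nrow = n_frames)
  y_cm <- matrix(y_cm, nrow = n_frames)
  obs <- matrix(vapply(tracks, `[[`, logical(n_frames), "obs"),
                nrow = n_frames)
  ids <- stats::ave(sp, sp, FUN = function(v) sprintf("%s_%02d", v,
                                                      seq_along(v)))
  colnames(x_cm) <- colnames(y_cm) <- colnames(obs) <- ids
  structure(
    list(x = x_cm, y = y_cm, observed = obs,
         agents = data.frame(agent_id = ids, species = sp,
                             stringsAsFactors = FALSE),
         fps = fps, cm_per_pixel = s, geometry = config$geometry),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d frames at %g fps, %d tracks\n",
              nrow(x$x), x$fps, ncol(x$x)))
  if (nrow(x$agents)) {
    ns <- table(x$agents$species)
    cat("  species:", paste(sprintf("%d %s", ns, names(ns)),
                            collapse = ", "), "\n")
    if (length(x$observed)) {
      cat(sprintf("  observed samples: %.1f%%\n", 100 * mean(x$observed)))
    }
  }
  invisible(x)
}

#' @export
plot.track_set <- function(x, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  r <- x$geometry$radius
  plot(r * cos(th), r * sin(th), type = "l", asp = 1,
       xlab = "x (cm)", ylab = "y (cm)", main = "tracks", ...)
  cols <- c(mosquitofish = "#1f77b4", tadpole = "#2ca02c", robot = "#d62728",
            unknown = "grey")
  for (i in seq_len(ncol(x$x))) {
    lines(x$x[, i], x$y[, i], col = cols[[x$agents$species[i]]], lwd = 0.5)
  }
  invisible(x)
}
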