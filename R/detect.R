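#' Fit detection thresholds from initial frames
#'
#' Mirrors the tracker's initialisation on the first frames of a recording:
#' the pooled pixel histogram is smoothed and the valleys between the
#' background mode and the blob intensity modes are taken as the ordered
#' threshold levels of the multiple-thresholding strategy.
#'
#' @param frames A list of grayscale matrices (0-255), typically the first
#'   three frames of a stack.
#' @param bw Density bandwidth in gray levels.
#' @param min_mass Minimum pixel mass (fraction) a mode must carry for the
#'   valley above it to be retained; suppresses noise wiggles.
#' @return Increasing numeric vector of threshold gray levels.
#' @export
fit_thresholds <- function(frames, bw = 4, min_mass = 2e-5) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  px <- unlist(lapply(frames, as.numeric), use.names = FALSE)
  d <- stats::density(px, bw = bw, n = 512, from = 0, to = 255)
  y <- d$y
  n <- length(y)
  valley <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  if (!length(valley)) return(numeric(0))
  # keep valleys that separate modes with non-trivial mass on both sides
  keep <- vapply(valley, function(v) {
    lo <- sum(y[1:v]); hi <- sum(y[v:n])
    min(lo, hi) / sum(y) > min_mass
  }, logical(1))
  sort(d$x[valley[keep]])
}

#' Detect blobs in a grayscale frame by multiple thresholding
#'
#' Thresholds the frame at each gray level, labels connected components
#' (via `EBImage::bwlabel`), and merges components across levels by
#' centroid proximity, keeping for each blob the component found at the
#' highest threshold at which it still appears (this separates touching
#' animals of different brightness). Components whose area falls outside
#' every supplied per-species range are discarded as noise.
#'
#' @param frame Numeric matrix, gray levels 0-255 (rows = y pixels).
#' @param thresholds Increasing vector of threshold gray levels.
#' @param area_bounds List of `c(min, max)` area ranges in px^2, one per
#'   species (names are informational).
#' @param merge_radius Centroid distance in px under which components from
#'   different threshold levels are considered the same blob.
#' @return A data.frame with columns `x_px`, `y_px`, `area`,
#'   `mean_intensity` (one row per detection).
#' @export
detect <- function(frame, thresholds, area_bounds, merge_radius = 5) {
  if (!is.matrix(frame) || length(frame) == 0L) {
    stop("frame must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!length(thresholds)) stop("at least one threshold required", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 255)) {
    stop("thresholds outside the 0-255 gray range", call. = FALSE)
  }
  stopifnot(is.list(area_bounds), length(area_bounds) >= 1L)

  comps_at <- function(thr) {
    mask <- frame > thr
    if (!any(mask)) return(NULL)
    lab <- EBImage::bwlabel(mask)
    labv <- as.integer(lab)
    nz <- labv > 0L
    if (!any(nz)) return(NULL)
    idx <- which(nz)
    lv <- labv[nz]
    rows <- (idx - 1L) %% nrow(frame) + 1L
    cols <- (idx - 1L) %/% nrow(frame) + 1L
    area <- tabulate(lv)
    data.frame(
      x_px = rowsum(as.numeric(cols), lv)[, 1] / area,
      y_px = rowsum(as.numeric(rows), lv)[, 1] / area,
      area = area,
      mean_intensity = rowsum(frame[idx], lv)[, 1] / area
    )
  }

  kept <- NULL
  for (thr in sort(thresholds, decreasing = TRUE)) {
    cc <- comps_at(thr)
    if (is.null(cc)) next
    if (is.null(kept)) {
      kept <- cc
    } else {
      d2 <- outer(cc$x_px, kept$x_px, `-`)^2 + outer(cc$y_px, kept$y_px, `-`)^2
      new <- apply(d2, 1L, min) > merge_radius^2
      if (any(new)) kept <- rbind(kept, cc[new, , drop = FALSE])
    }
  }
  if (is.null(kept)) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area = numeric(0), mean_intensity = numeric(0)))
  }
  lo <- vapply(area_bounds, `[`, numeric(1), 1L)
  hi <- vapply(area_bounds, `[`, numeric(1), 2L)
  ok <- vapply(kept$area, function(a) any(a >= lo & a <= hi), logical(1))
  res <- kept[ok, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify detections into species by body characteristics
#'
#' Labels each detection with the unique species whose area and intensity
#' intervals both contain it; detections matching no species are labelled
#' `"unknown"`. Criteria must be pairwise disjoint on at least one feature,
#' so a full match is unique; if a detection nevertheless matches several
#' species, the optional motion context (typical per-species speeds)
#' breaks the tie.
#'
#' @param detections A data.frame from [detect()].
#' @param criteria Named list (one entry per species) of lists with `area`
#'   and `intensity` elements, each `c(min, max)`.
#' @param motion_context Optional list with `speed_px` (per-detection
#'   observed displacement, px/frame) and `species_speed_px` (named typical
#'   speeds per species).
#' @return `detections` with an added `species` character column.
#' @export
classify_species <- function(detections, criteria, motion_context = NULL) {
  stopifnot(is.list(criteria), length(criteria) >= 1L)
  sp <- names(criteria)
  if (length(sp) > 1L) {
    for (i in seq_along(sp)[-length(sp)]) for (j in (i + 1):length(sp)) {
      a <- criteria[[i]]; b <- criteria[[j]]
      overlap <- function(u, v) u[1] <= v[2] && v[1] <= u[2]
      if (overlap(a$area, b$area) && overlap(a$intensity, b$intensity)) {
        stop(sprintf("criteria for '%s' and '%s' overlap on all features",
                     sp[i], sp[j]), call. = FALSE)
      }
    }
  }
  n <- nrow(detections)
  label <- rep("unknown", n)
  if (n) {
    in_iv <- function(v, iv) v >= iv[1] & v <= iv[2]
    area_ok <- vapply(sp, function(s) in_iv(detections$area,
                                            criteria[[s]]$area), logical(n))
    int_ok <- vapply(sp, function(s) in_iv(detections$mean_intensity,
                                           criteria[[s]]$intensity),
                     logical(n))
    area_ok <- matrix(area_ok, nrow = n, dimnames = list(NULL, sp))
    int_ok <- matrix(int_ok, nrow = n, dimnames = list(NULL, sp))
    for (i in seq_len(n)) {
      full <- sp[area_ok[i, ] & int_ok[i, ]]
      if (length(full) == 1L) {
        label[i] <- full
      } else if (length(full) == 0L && !is.null(motion_context)) {
        # features disagree: fall back on the movement pattern among the
        # species matched by at least one feature
        part <- sp[area_ok[i, ] | int_ok[i, ]]
        if (length(part)) {
          dev <- abs(motion_context$species_speed_px[part] -
                       motion_context$speed_px[i])
          label[i] <- part[which.min(dev)]
        }
      } else if (length(full) > 1L && !is.null(motion_context)) {
        dev <- abs(motion_context$species_speed_px[full] -
                     motion_context$speed_px[i])
        label[i] <- full[which.min(dev)]
      }
    }
  }
  detections$species <- label
  detections
}
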