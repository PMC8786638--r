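#' Render a simulated trial into grayscale frames
#'
#' Rasterises each frame of a [simulate_trial()] recording: every agent not
#' dropped by the miss process is drawn as a filled disc whose area and mean
#' gray level are set per species by the [render_config()], on a dark
#' background with additive Gaussian pixel noise. Gray levels are on a
#' 0-255 scale. Ground truth (which agent produced which blob centre, in
#' pixels) is retained for testing the tracker.
#'
#' @param recording A `trial_recording`.
#' @param rc A [render_config()].
#' @param seed Integer seed for pixel noise and the miss process.
#' @param frames Optional integer vector of frame indices to render
#'   (default: all).
#' @return An object of class `frame_stack`: a list with `frames` (list of
#'   numeric matrices, rows = y pixels), `truth` (data.frame: frame,
#'   agent_id, species, x_px, y_px, drawn), and the scale metadata.
#' @export
render_frames <- function(recording, rc = render_config(), seed = 1L,
                          frames = NULL) {
  stopifnot(inherits(recording, "trial_recording"),
            inherits(rc, "render_config"))
  if (is.null(frames)) frames <- seq_len(recording$n_frames)
  w <- rc$image_size[1]; h <- rc$image_size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  if (recording$geometry$diameter / rc$cm_per_pixel > min(w, h)) {
    stop("image too small: arena does not fit at this scale", call. = FALSE)
  }
  radii <- sqrt(rc$species_blob_area / pi)
  if (any(2 * radii < 1)) {
    stop("blob diameter below 1 px after scaling", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_agents <- nrow(recording$agents)
  sp <- recording$agents$species

  out <- vector("list", length(frames))
  truth <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    k <- frames[fi]
    img <- matrix(rc$background, nrow = h, ncol = w)
    drawn <- if (n_agents)
      stats::runif(n_agents) >= rc$miss_rate else logical(0)
    xs <- ys <- rep(NA_real_, n_agents)
    for (a in seq_len(n_agents)) {
      x_px <- cx + recording$x[k, a] / rc$cm_per_pixel
      y_px <- cy - recording$y[k, a] / rc$cm_per_pixel
      xs[a] <- x_px; ys[a] <- y_px
      if (!drawn[a]) next
      r <- radii[[sp[a]]]
      cols <- max(1L, floor(x_px - r)):min(w, ceiling(x_px + r))
      rows <- max(1L, floor(y_px - r)):min(h, ceiling(y_px + r))
      dd <- outer((rows - y_px)^2, (cols - x_px)^2, `+`)
      inside <- dd <= r^2
      block <- img[rows, cols, drop = FALSE]
      block[inside] <- rc$species_intensity[[sp[a]]]
      img[rows, cols] <- block
    }
    if (rc$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(w * h, 0, rc$noise_sd), nrow = h)
    }
    out[[fi]] <- pmin(pmax(img, 0), 255)
    truth[[fi]] <- data.frame(frame = rep(k, n_agents),
                              agent_id = recording$agents$agent_id,
                              species = sp, x_px = xs, y_px = ys,
                              drawn = drawn, stringsAsFactors = FALSE)
  }
  structure(
    list(frames = out, frame_index = frames,
         truth = do.call(rbind, truth),
         cm_per_pixel = rc$cm_per_pixel, image_size = rc$image_size,
         fps = recording$fps, geometry = recording$geometry,
         render_config = rc),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames of %dx%d px (%.3f cm/px)\n",
              length(x$frames), x$image_size[1], x$image_size[2],
              x$cm_per_pixel))
  invisible(x)
}

#' Write or read a frame stack as PNG/TIFF files
#'
#' Frames are written as one image file per frame (`frame_000001.png` ...)
#' in `dir`. Gray levels 0-255 are stored as [0, 1] image intensities.
#'
#' @param stack A `frame_stack` (or a plain list of matrices for
#'   `write_frames`).
#' @param dir Directory for the image files.
#' @param format `"png"` or `"tiff"`.
#' @return `write_frames` returns the file paths invisibly; `read_frames`
#'   returns a list of numeric matrices on the 0-255 gray scale.
#' @export
write_frames <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    img <- frames[[i]] / 255
    paths[i] <- file.path(dir, sprintf("frame_%06d.%s", i, format))
    if (format == "png") png::writePNG(img, paths[i])
    else tiff::writeTIFF(img, paths[i])
  }
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (!length(paths)) stop("no PNG/TIFF frames found in ", dir, call. = FALSE)
  lapply(paths, function(p) {
    img <- if (grepl("\\.png$", p)) png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # documented grayscale conversion
    img * 255
  })
}
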