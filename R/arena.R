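#' Arena geometry
#'
#' Describes the circular experimental arena: a 42-cm diameter tank whose
#' floor is partitioned into seven concentric rings, each 3 cm wide, and
#' condensed for space-use analyses into a central region (0-15 cm radius,
#' rings 0-4) and an external region (15-21 cm radius, rings 5-6).
#'
#' @param diameter Arena diameter in cm.
#' @param ring_width Width of each concentric ring in cm.
#' @param n_rings Number of concentric rings; `n_rings * ring_width` must
#'   equal `diameter / 2`.
#' @param central_radius Radius in cm separating the central from the
#'   external region; must lie strictly inside the arena.
#' @param water_depth Water depth in cm (metadata only, not used in any
#'   computation).
#' @return An object of class `arena_geometry`.
#' @examples
#' geom <- arena_geometry()
#' geom$radius
#' @export
arena_geometry <- function(diameter = 42, ring_width = 3, n_rings = 7,
                           central_radius = 15, water_depth = 10) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0,
            is.numeric(ring_width), ring_width > 0,
            is.numeric(n_rings), n_rings >= 1)
  if (abs(n_rings * ring_width - diameter / 2) > 1e-9) {
    stop("n_rings * ring_width must equal diameter / 2", call. = FALSE)
  }
  if (!(central_radius > 0 && central_radius < diameter / 2)) {
    stop("central_radius must lie in (0, diameter/2)", call. = FALSE)
  }
  structure(
    list(diameter = diameter, radius = diameter / 2, ring_width = ring_width,
         n_rings = as.integer(n_rings), central_radius = central_radius,
         water_depth = water_depth),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("Circular arena: diameter %.1f cm, %d rings of %.1f cm,\n",
              x$diameter, x$n_rings, x$ring_width))
  cat(sprintf("  central region 0-%.0f cm, external %.0f-%.0f cm\n",
              x$central_radius, x$central_radius, x$radius))
  invisible(x)
}

#' Directed behavioural coupling between species
#'
#' Gains that define the ground-truth directed interactions the simulator
#' embeds and that the transfer-entropy stage is expected to recover.
#' `fish_fear_gain` scales the mosquitofish response to the robotic predator
#' (repulsion, agitation after attacks, increased cohesion);
#' `tadpole_from_fish_gain` scales how strongly tadpole turning activity
#' follows recent mosquitofish turning activity; `fish_from_tadpole_gain`
#' is the reverse direction. A spec of the form (a, 0) with a > 0 encodes
#' unidirectional fish-to-tadpole coupling; the default (1, 0.5, 0) is the
#' robot-exposed ground truth in which tadpole turning follows mosquitofish
#' turning but not vice versa. Use all-zero gains for independent species.
#'
#' @param fish_fear_gain,tadpole_from_fish_gain,fish_from_tadpole_gain
#'   Non-negative dimensionless gains.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(fish_fear_gain = 1,
                          tadpole_from_fish_gain = 0.5,
                          fish_from_tadpole_gain = 0) {
  g <- c(fish_fear_gain, tadpole_from_fish_gain, fish_from_tadpole_gain)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("coupling gains must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(fish_fear_gain = fish_fear_gain,
         tadpole_from_fish_gain = tadpole_from_fish_gain,
         fish_from_tadpole_gain = fish_from_tadpole_gain),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("coupling: fear %.2f, fish->tadpole %.2f, tadpole->fish %.2f\n",
              x$fish_fear_gain, x$tadpole_from_fish_gain,
              x$fish_from_tadpole_gain))
  invisible(x)
}

#' Rendering configuration for synthetic video frames
#'
#' Controls how a simulated trial is rasterised into grayscale frames.
#' Species are separable by blob area and mean gray level, the cues the
#' tracker's body-characteristic filtering relies on. Gray levels are on a
#' 0-255 scale; the background is dark and animals are bright.
#'
#' @param image_size Integer vector (width, height) in pixels, or a scalar
#'   for a square image.
#' @param cm_per_pixel Scale mapping arena cm to pixels.
#' @param species_blob_area Named numeric vector of blob areas in px^2 for
#'   `mosquitofish`, `tadpole` and `robot`; must be pairwise distinct.
#' @param species_intensity Named numeric vector of mean blob gray levels
#'   (0-255) per species.
#' @param background Background gray level.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   gray levels.
#' @param miss_rate Probability that an agent is omitted from a frame
#'   (simulating detection failure); in [0, 1).
#' @return An object of class `render_config`.
#' @export
render_config <- function(image_size = c(480L, 480L),
                          cm_per_pixel = 0.1,
                          species_blob_area = c(mosquitofish = 60,
                                                tadpole = 240, robot = 520),
                          species_intensity = c(mosquitofish = 170,
                                                tadpole = 110, robot = 235),
                          background = 20,
                          noise_sd = 4,
                          miss_rate = 0) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  stopifnot(all(image_size > 0), cm_per_pixel > 0, noise_sd >= 0)
  if (!(miss_rate >= 0 && miss_rate < 1)) {
    stop("miss_rate must be in [0, 1)", call. = FALSE)
  }
  sp <- c("mosquitofish", "tadpole", "robot")
  if (!all(sp %in% names(species_blob_area)) ||
      !all(sp %in% names(species_intensity))) {
    stop("species_blob_area and species_intensity must name all of: ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(species_blob_area[sp])) {
    stop("species blob areas must be pairwise distinct", call. = FALSE)
  }
  structure(
    list(image_size = image_size, cm_per_pixel = cm_per_pixel,
         species_blob_area = species_blob_area[sp],
         species_intensity = species_intensity[sp],
         background = background, noise_sd = noise_sd,
         miss_rate = miss_rate),
    class = "render_config"
  )
}

# ring index for radius r: half-open rings [3k, 3k+3); the outermost ring
# includes the wall itself. Vectorised; errors on r beyond the wall.
ring_index <- function(r, geometry = arena_geometry()) {
  if (any(r > geometry$radius + 1e-9)) {
    stop("position outside arena: radius exceeds ", geometry$radius, " cm",
         call. = FALSE)
  }
  k <- pmin(floor(r / geometry$ring_width), geometry$n_rings - 1L)
  as.integer(k)
}
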