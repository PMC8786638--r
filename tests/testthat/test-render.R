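make_static_recording <- function(pos, species, fps = 20, n_frames = 3) {
  ids <- sprintf("%s_%02d", substr(species, 1, 4), seq_along(species))
  x <- matrix(rep(pos[, 1], each = n_frames), nrow = n_frames)
  y <- matrix(rep(pos[, 2], each = n_frames), nrow = n_frames)
  colnames(x) <- colnames(y) <- ids
  structure(
    list(fps = fps, duration = n_frames / fps, n_frames = n_frames,
         agents = data.frame(agent_id = ids, species = species,
                             stringsAsFactors = FALSE),
         x = x, y = y, heading = x * 0,
         attacks = data.frame(), treatment = "non_exposed", seed = 0L,
         coupling = coupling_spec(0, 0, 0), geometry = arena_geometry()),
    class = "trial_recording")
}

test_that("zero agents render as noise-only frames", {
  rec <- make_static_recording(matrix(numeric(0), 0, 2), character(0))
  st <- render_frames(rec, render_config(noise_sd = 3), seed = 1)
  f <- st$frames[[1]]
  expect_equal(dim(f), c(480, 480))
  expect_equal(mean(f), 20, tolerance = 0.1)   # background plus zero-mean noise
  expect_lt(sd(f), 4)
})

test_that("13 well-separated agents give 13 blobs with accurate centroids", {
  th <- seq(0, 2 * pi, length.out = 14)[1:13]
  pos <- cbind(14 * cos(th), 14 * sin(th))
  species <- c(rep("mosquitofish", 6), rep("tadpole", 6), "robot")
  rec <- make_static_recording(pos, species)
  st <- render_frames(rec, render_config(noise_sd = 0), seed = 1)
  f <- st$frames[[1]]
  # independent centroid measurement: label connected bright pixels
  lab <- EBImage::bwlabel(f > 50)
  expect_equal(max(lab), 13)
  labv <- as.integer(lab); idx <- which(labv > 0)
  rows <- (idx - 1) %% 480 + 1; cols <- (idx - 1) %/% 480 + 1
  cx <- tapply(cols, labv[idx], mean); cy <- tapply(rows, labv[idx], mean)
  truth <- st$truth[st$truth$frame == 1, ]
  for (a in seq_len(13)) {
    d <- sqrt((cx - truth$x_px[a])^2 + (cy - truth$y_px[a])^2)
    expect_lt(min(d), 1)  # within 1 px of the projected position
  }
})

test_that("miss process drops agents at the configured rate", {
  th <- seq(0, 2 * pi, length.out = 14)[1:13]
  pos <- cbind(14 * cos(th), 14 * sin(th))
  species <- c(rep("mosquitofish", 6), rep("tadpole", 6), "robot")
  rec <- make_static_recording(pos, species, n_frames = 60)
  st <- render_frames(rec, render_config(miss_rate = 0.3), seed = 2)
  expect_equal(mean(st$truth$drawn), 0.7, tolerance = 0.05)
})

test_that("degenerate render configurations error", {
  rec <- make_static_recording(cbind(0, 0), "mosquitofish")
  expect_error(render_frames(rec, render_config(image_size = 100L)), "small")
  expect_error(render_config(miss_rate = 1), "miss_rate")
  expect_error(
    render_frames(rec, render_config(
      species_blob_area = c(mosquitofish = 0.5, tadpole = 240, robot = 520))),
    "1 px")
})

test_that("PNG round trip preserves frames to 8-bit precision", {
  rec <- make_static_recording(cbind(c(0, 5), c(0, 5)),
                               c("mosquitofish", "tadpole"))
  st <- render_frames(rec, render_config(noise_sd = 2), seed = 3)
  dir <- file.path(tempdir(), "frames_png")
  write_frames(st, dir)
  back <- read_frames(dir)
  expect_length(back, 3)
  expect_lt(max(abs(back[[1]] - st$frames[[1]])), 0.51)
})
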