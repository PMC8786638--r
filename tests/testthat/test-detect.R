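blob_frame <- function(blobs, size = 200, background = 20, noise_sd = 0,
                       seed = 1) {
  set.seed(seed)
  img <- matrix(background, size, size)
  for (b in blobs) {
    r <- sqrt(b$area / pi)
    cols <- max(1, floor(b$x - r)):min(size, ceiling(b$x + r))
    rows <- max(1, floor(b$y - r)):min(size, ceiling(b$y + r))
    dd <- outer((rows - b$y)^2, (cols - b$x)^2, `+`)
    block <- img[rows, cols]
    block[dd <= r^2] <- b$intensity
    img[rows, cols] <- block
  }
  img + matrix(rnorm(size^2, 0, noise_sd), size)
}

bounds <- list(mosquitofish = c(25, 260), tadpole = c(121, 560),
               robot = c(401, 900))

test_that("a blank noise-only frame yields no detections", {
  img <- blob_frame(list(), noise_sd = 3)
  d <- detect(img, thresholds = c(60, 140, 200), area_bounds = bounds)
  expect_equal(nrow(d), 0)
})

test_that("separated blobs are each detected once with area and intensity", {
  img <- blob_frame(list(list(x = 50, y = 60, area = 60, intensity = 170),
                         list(x = 120, y = 40, area = 240, intensity = 110),
                         list(x = 150, y = 150, area = 520, intensity = 235)),
                    noise_sd = 2)
  d <- detect(img, c(60, 140, 200), bounds)
  expect_equal(nrow(d), 3)
  d <- d[order(d$area), ]
  expect_equal(d$area, c(60, 240, 520), tolerance = 0.15)
  expect_equal(d$mean_intensity, c(170, 110, 235), tolerance = 0.05)
  expect_equal(d$x_px, c(50, 120, 150), tolerance = 0.02)
})

test_that("a sub-minimum speck is filtered out", {
  img <- blob_frame(list(list(x = 30, y = 30, area = 2, intensity = 200),
                         list(x = 120, y = 120, area = 60, intensity = 170)))
  d <- detect(img, c(60, 140), bounds)
  expect_equal(nrow(d), 1)
  expect_equal(d$x_px, 120, tolerance = 0.05)
})

test_that("detect validates its inputs", {
  expect_error(detect(matrix(numeric(0), 0, 0), 50, bounds), "empty")
  img <- blob_frame(list())
  expect_error(detect(img, numeric(0), bounds), "threshold")
  expect_error(detect(img, c(50, 300), bounds), "range")
})

test_that("threshold fitting finds valleys between intensity modes", {
  frames <- lapply(1:3, function(s)
    blob_frame(list(list(x = 50, y = 60, area = 300, intensity = 170),
                    list(x = 120, y = 40, area = 400, intensity = 110),
                    list(x = 150, y = 150, area = 520, intensity = 235)),
               noise_sd = 3, seed = s))
  thr <- fit_thresholds(frames)
  expect_gte(length(thr), 3)
  expect_true(any(thr > 20 & thr < 110))
  expect_true(any(thr > 110 & thr < 170))
  expect_true(any(thr > 170 & thr < 235))
})

criteria <- list(
  mosquitofish = list(area = c(25, 260), intensity = c(140, 200)),
  tadpole = list(area = c(121, 560), intensity = c(80, 135)),
  robot = list(area = c(401, 900), intensity = c(205, 255)))

test_that("species classification follows the body-characteristic intervals", {
  d <- data.frame(x_px = c(1, 2, 3, 4), y_px = c(1, 2, 3, 4),
                  area = c(60, 240, 520, 1000),
                  mean_intensity = c(170, 110, 235, 170))
  out <- classify_species(d, criteria)
  expect_equal(out$species,
               c("mosquitofish", "tadpole", "robot", "unknown"))
})

test_that("overlapping criteria on every feature are rejected", {
  bad <- criteria
  bad$tadpole$intensity <- c(140, 200)
  bad$tadpole$area <- c(25, 260)
  d <- data.frame(x_px = 1, y_px = 1, area = 60, mean_intensity = 170)
  expect_error(classify_species(d, bad), "overlap")
})

test_that("motion context resolves detections with conflicting features", {
  amb <- list(slow = list(area = c(10, 100), intensity = c(100, 150)),
              fast = list(area = c(101, 300), intensity = c(151, 250)))
  # area says slow, intensity says fast: features tie, motion decides
  d <- data.frame(x_px = 1, y_px = 1, area = 60, mean_intensity = 200)
  out <- classify_species(d, amb,
                          motion_context = list(
                            speed_px = 9,
                            species_speed_px = c(slow = 1, fast = 10)))
  expect_equal(out$species, "fast")
  expect_equal(classify_species(d, amb)$species, "unknown")
})
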