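rep_frames <- function(pts, n = 4) {
  list(x = matrix(rep(pts[, 1], each = n), nrow = n),
       y = matrix(rep(pts[, 2], each = n), nrow = n))
}

test_that("AFND and AIID match closed forms on fixed configurations", {
  # equilateral triangle with side d: both metrics equal d
  d <- 3.7
  tri <- rbind(c(0, 0), c(d, 0), c(d / 2, d * sqrt(3) / 2))
  p <- rep_frames(tri)
  expect_equal(afnd(p$x, p$y), d)
  expect_equal(aiid(p$x, p$y), d)
  # collinear points at 0, 1, 2: furthest distances (2,1,2), pairs (1,2,1)
  col <- rep_frames(cbind(c(0, 1, 2), 0))
  expect_equal(afnd(col$x, col$y), 5 / 3)
  expect_equal(aiid(col$x, col$y), 4 / 3)
})

test_that("group metrics need at least two individuals", {
  p <- rep_frames(cbind(1, 1))
  expect_error(afnd(p$x, p$y), "fewer than 2")
  expect_error(aiid(p$x, p$y), "fewer than 2")
})

test_that("AIID never exceeds AFND", {
  set.seed(1)
  for (r in 1:20) {
    pts <- matrix(runif(12, -20, 20), ncol = 2)
    p <- rep_frames(pts)
    expect_lte(aiid(p$x, p$y), afnd(p$x, p$y))
  }
})

test_that("distance swam is additive and matches a circle's circumference", {
  x <- matrix(c(0, 0, 0), ncol = 1); y <- matrix(c(0, 0, 0), ncol = 1)
  expect_equal(distance_swam(x, y), 0)
  # straight 10 cm in steps
  x <- matrix(seq(0, 10, by = 0.5), ncol = 1)
  expect_equal(distance_swam(x, 0 * x), 10)
  # full revolution at fine steps: 2*pi*r within 1%
  th <- seq(0, 2 * pi, length.out = 1001)
  r <- 7
  expect_equal(distance_swam(matrix(r * cos(th), ncol = 1),
                             matrix(r * sin(th), ncol = 1)),
               2 * pi * r, tolerance = 0.01)
})

test_that("turning rate is 0 on lines, omega on circles, known on zigzags", {
  x <- matrix(seq(0, 10, by = 0.5), ncol = 1)
  expect_equal(turning_rate(x, 0 * x, dt = 0.05), 0)
  # uniform circular motion at angular speed omega
  omega <- 1.3; fps <- 20
  tt <- seq(0, 10, by = 1 / fps)
  x <- matrix(8 * cos(omega * tt), ncol = 1)
  y <- matrix(8 * sin(omega * tt), ncol = 1)
  expect_equal(turning_rate(x, y, dt = 1 / fps), omega, tolerance = 0.01)
  # alternating +-90 degree zigzag: (pi/2) per 0.05 s step
  n <- 40
  dirs <- rep(c(1, 0), n)[1:n]  # east, north, east, north...
  steps <- cbind(ifelse(dirs == 1, 0.5, 0), ifelse(dirs == 1, 0, 0.5))
  pos <- apply(steps, 2, cumsum)
  expect_equal(turning_rate(matrix(pos[, 1], ncol = 1),
                            matrix(pos[, 2], ncol = 1), dt = 0.05),
               (pi / 2) / 0.05)
})

test_that("turning rate skips sub-floor steps and errors when all are still", {
  x <- matrix(c(0, 0.01, 0.02, 0.03), ncol = 1)
  expect_error(turning_rate(x, 0 * x, dt = 0.05), "motion floor")
})

test_that("region occupancy partitions the trial duration", {
  geom <- arena_geometry()
  # stationary at centre for 600 s
  n <- 600 * 20
  occ <- region_occupancy(matrix(0, n, 1), matrix(0, n, 1), geom, fps = 20)
  expect_equal(occ$central_s, 600)
  expect_equal(occ$external_s, 0)
  # stationary at r = 16 cm: external only
  occ2 <- region_occupancy(matrix(16, 100, 1), matrix(0, 100, 1), geom, 20)
  expect_equal(occ2$central_s, 0)
  expect_equal(occ2$external_s, 5)
  # half-open ring convention at the 15-cm boundary
  occ3 <- region_occupancy(matrix(15, 10, 1), matrix(0, 10, 1), geom, 20)
  expect_equal(occ3$external_s, 0.5)
  # any track: central + external = duration; rings sum likewise
  set.seed(3)
  th <- runif(200, 0, 2 * pi); r <- sqrt(runif(200)) * 21
  occ4 <- region_occupancy(matrix(r * cos(th), ncol = 1),
                           matrix(r * sin(th), ncol = 1), geom, 20)
  expect_equal(occ4$central_s + occ4$external_s, 10)
  expect_equal(sum(occ4$per_ring_s), 10)
  expect_error(region_occupancy(matrix(22, 1, 1), matrix(0, 1, 1), geom, 20),
               "outside")
})

test_that("ring assignment is exhaustive and exclusive over [0, 21]", {
  r <- seq(0, 21, by = 0.01)
  k <- roboprey:::ring_index(r)
  expect_true(all(k >= 0 & k <= 6))
  expect_equal(k[r < 3], rep(0L, sum(r < 3)))
  expect_equal(unique(k[r >= 18]), 6L)
  expect_equal(k[abs(r - 15) < 1e-9], 5L)
})

test_that("Fulton's condition factor matches its definition", {
  expect_equal(fulton_k(1, 10), 10)
  expect_equal(fulton_k(0, 33), 0)
  expect_equal(fulton_k(0.15, 21.32), 0.15 / 21.32^3 * 1e4)
  expect_error(fulton_k(1, 0), "length")
  expect_error(fulton_k(-1, 10), "weight")
})

test_that("metrics are invariant under rigid motions and scale correctly", {
  set.seed(9)
  x <- matrix(cumsum(rnorm(40, 0, 0.8)), ncol = 2)
  y <- matrix(cumsum(rnorm(40, 0, 0.8)), ncol = 2)
  base <- c(afnd(x, y), aiid(x, y), distance_swam(x, y),
            turning_rate(x, y, dt = 0.05, motion_floor = 0))
  for (r in 1:5) {
    th <- runif(1, 0, 2 * pi); shift <- runif(2, -5, 5)
    xr <- cos(th) * x - sin(th) * y + shift[1]
    yr <- sin(th) * x + cos(th) * y + shift[2]
    got <- c(afnd(xr, yr), aiid(xr, yr), distance_swam(xr, yr),
             turning_rate(xr, yr, dt = 0.05, motion_floor = 0))
    expect_equal(got, base, tolerance = 1e-10)
  }
  s <- 2.5
  expect_equal(afnd(s * x, s * y), s * base[1])
  expect_equal(aiid(s * x, s * y), s * base[2])
  expect_equal(distance_swam(s * x, s * y), s * base[3])
  expect_equal(turning_rate(s * x, s * y, dt = 0.05, motion_floor = 0),
               base[4])
})

test_that("behavior_summary assembles a consistent per-species table", {
  rec <- simulate_trial(duration = 10, seed = 14)
  bs <- behavior_summary(rec, trial_id = "t1")
  expect_equal(nrow(bs), 2)
  expect_true(all(bs$afnd_cm >= bs$aiid_cm))
  expect_equal(bs$central_time_s + bs$external_time_s, c(10, 10))
  ring_cols <- grep("^ring", names(bs))
  expect_equal(unname(rowSums(bs[, ring_cols])), c(10, 10))
})
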