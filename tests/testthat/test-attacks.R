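test_that("attack schedule respects rate, spacing and completion bounds", {
  d_max <- attack_max_duration()
  tr <- schedule_attacks(3600, 1, seed = 1)
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr >= 0 & tr < 3600))
  expect_true(all(tr + d_max <= 3600))
  expect_true(all(diff(tr) >= d_max))
  expect_lt(length(tr), 60)
  # several seeds: always fewer than 60 completed attacks per hour
  counts <- vapply(1:25, function(s) length(schedule_attacks(3600, 1, seed = s)),
                   integer(1))
  expect_true(all(counts < 60))
  expect_true(all(counts > 45))  # still approximately one per minute
  expect_identical(schedule_attacks(3600, 1, seed = 9),
                   schedule_attacks(3600, 1, seed = 9))
})

test_that("zero-duration schedule is empty", {
  expect_length(schedule_attacks(0, 1, seed = 1), 0)
})

test_that("standardized schedule yields exactly the requested count", {
  tr <- schedule_attacks(3600, 1, standardize_to = 55, seed = 7)
  expect_length(tr, 55)
  expect_true(all(diff(tr) >= attack_max_duration() - 1e-9))
  expect_true(all(tr + attack_max_duration() <= 3600))
  tr56 <- schedule_attacks(3600, 1, standardize_to = 56, seed = 2)
  expect_length(tr56, 56)
  expect_error(schedule_attacks(3600, 1, standardize_to = 61, seed = 1),
               "infeasible")
  expect_error(schedule_attacks(120, 1, standardize_to = 2, seed = 1,
                                max_attack_duration = 100),
               "infeasible")
})

test_that("attack tiers follow the 1 cm / 10 cm thresholds", {
  expect_equal(attack_tier(0.5), "contact")
  expect_equal(attack_tier(0), "contact")
  expect_equal(attack_tier(1), "inspection")
  expect_equal(attack_tier(10), "inspection")
  expect_equal(attack_tier(10.01), "pursuit")
})

run_attack <- function(start_dist, dt = 0.05, max_steps = 2000) {
  robot <- list(position = c(-12, 0), heading = 0, speed = 0)
  target <- c(start_dist - 12, 0)
  phase <- attack_begin(robot, target)
  speeds <- numeric(0)
  trace <- list()
  for (i in seq_len(max_steps)) {
    st <- attack_controller_step(robot, target, phase, dt)
    robot <- st$robot; phase <- st$phase
    speeds <- c(speeds, robot$speed)
    trace[[i]] <- robot$position
    if (phase$stage == "idle") break
  }
  list(robot = robot, phase = phase, speeds = speeds,
       pos = do.call(rbind, trace))
}

test_that("contact tier turns toward the fish, holds 1 s, no translation", {
  robot <- list(position = c(0, 0), heading = 1.2, speed = 0)
  phase <- attack_begin(robot, c(0.5, 0))
  expect_equal(phase$tier, "contact")
  st <- attack_controller_step(robot, c(0.5, 0), phase, dt = 0.05)
  expect_equal(st$robot$heading, 0)           # turned toward the fish
  expect_equal(st$robot$position, c(0, 0))    # no translation
  expect_equal(st$phase$stage, "hold")
  expect_equal(st$phase$hold_left, 1)
  full <- run_attack(0.5)
  expect_true(all(full$pos[, 1] == -12))      # never translates
  expect_equal(full$robot$heading, 0)         # heading restored... to initial
})

test_that("degenerate zero-distance attack is contact with unchanged heading", {
  robot <- list(position = c(2, 3), heading = 0.7, speed = 0)
  phase <- attack_begin(robot, c(2, 3))
  expect_equal(phase$tier, "contact")
  st <- attack_controller_step(robot, c(2, 3), phase, dt = 0.05)
  expect_equal(st$robot$heading, 0.7)
  expect_equal(st$robot$position, c(2, 3))
})

test_that("pursuit reaches exactly 20 cm/s, obeys bounds, stops at standoff", {
  full <- run_attack(25)   # robot at (-12, 0), fish 25 cm ahead
  expect_equal(max(full$speeds), 20)
  accels <- abs(diff(c(0, full$speeds))) / 0.05
  expect_true(all(accels <= 20 + 1e-9))
  expect_true(all(full$speeds <= 20 + 1e-12))
  # speed rises at 20 cm/s^2 for the first second (covering ~10 cm)
  expect_equal(full$speeds[1:20], seq(1, 20, by = 1))
  expect_equal(full$pos[20, 1] - (-12), 10.5, tolerance = 1e-9)
  # stop point ~1 cm short of the target, then return home
  apex <- max(full$pos[, 1])
  expect_equal(apex, 25 - 12 - 1, tolerance = 1e-6)
  expect_equal(full$robot$position, c(-12, 0))
  expect_equal(full$robot$heading, 0)
  expect_equal(full$phase$stage, "idle")
})

test_that("inspection tier approaches without reaching maximum speed", {
  full <- run_attack(8)
  expect_lt(max(full$speeds), 20)
  expect_equal(max(full$pos[, 1]), 8 - 12 - 1, tolerance = 1e-6)
})

test_that("controller rejects invalid inputs", {
  robot <- list(position = c(0, 0), heading = 0, speed = 0)
  phase <- attack_begin(robot, c(5, 0))
  expect_error(attack_controller_step(robot, c(5, 0), phase, dt = 0),
               "dt")
  expect_error(attack_controller_step(robot, c(50, 0), phase, dt = 0.05),
               "outside")
})
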