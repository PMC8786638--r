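test_that("frame count equals fps times duration and agents stay in-arena", {
  rec <- simulate_trial(duration = 30, fps = 20, seed = 4)
  expect_equal(rec$n_frames, 600)
  expect_equal(nrow(rec$x), 600)
  r <- sqrt(rec$x^2 + rec$y^2)
  expect_true(all(r <= rec$geometry$radius))
  expect_true(all(rec$heading >= -pi & rec$heading < pi))
  expect_error(simulate_trial(duration = 10.025, fps = 20, seed = 1),
               "fps")
})

test_that("robot present iff robot_exposed; attacks only then", {
  rec_r <- simulate_trial(duration = 30, seed = 5)
  rec_n <- simulate_trial(duration = 30, treatment = "non_exposed", seed = 5)
  expect_true("robot" %in% rec_r$agents$species)
  expect_false("robot" %in% rec_n$agents$species)
  expect_equal(nrow(rec_n$attacks), 0)
  expect_equal(ncol(rec_r$x), 13)
  expect_equal(ncol(rec_n$x), 12)
  expect_equal(sum(rec_r$agents$species == "mosquitofish"), 6)
  expect_equal(sum(rec_r$agents$species == "tadpole"), 6)
})

test_that("same seed and config give a bit-identical recording", {
  a <- simulate_trial(duration = 20, seed = 11)
  b <- simulate_trial(duration = 20, seed = 11)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$heading, b$heading)
  expect_identical(a$attacks, b$attacks)
  c <- simulate_trial(duration = 20, seed = 12)
  expect_false(identical(a$x, c$x))
})

test_that("attack log is standardizable and tiers match initial distances", {
  rec <- simulate_trial(duration = 1800, seed = 8, standardize_attacks = 25)
  att <- rec$attacks
  expect_equal(nrow(att), 25)
  expect_true(all(att$t_complete_s > att$t_trigger_s, na.rm = TRUE))
  expect_identical(att$tier, unname(attack_tier(att$initial_distance_cm)))
  expect_true(all(att$target_id %in%
                    rec$agents$agent_id[rec$agents$species == "mosquitofish"]))
  # at most one attack in progress at any time
  expect_true(all(att$t_trigger_s[-1] >= att$t_complete_s[-nrow(att)]))
})

test_that("robot command speed and acceleration stay within the platform limits", {
  rec <- simulate_trial(duration = 600, seed = 13)
  expect_lte(max(rec$robot_speed), 20)
  expect_lte(max(abs(diff(rec$robot_speed))) * rec$fps, 20 + 1e-9)
})

test_that("targeting picks the mosquitofish closest to its nearest tadpole", {
  rec <- simulate_trial(duration = 600, seed = 21)
  att <- rec$attacks
  fish_ids <- rec$agents$agent_id[rec$agents$species == "mosquitofish"]
  tad_idx <- which(rec$agents$species == "tadpole")
  for (r in seq_len(nrow(att))) {
    k <- round(att$t_trigger_s[r] * rec$fps) + 1L
    d2tad <- vapply(fish_ids, function(id) {
      i <- which(rec$agents$agent_id == id)
      min(sqrt((rec$x[k, i] - rec$x[k, tad_idx])^2 +
                 (rec$y[k, i] - rec$y[k, tad_idx])^2))
    }, numeric(1))
    expect_equal(att$target_id[r], names(which.min(d2tad)))
  }
})
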