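static_obj <- function(x, y, species = "mosquitofish", fps = 20) {
  n <- ncol(x)
  ids <- sprintf("a%02d", seq_len(n))
  colnames(x) <- colnames(y) <- ids
  structure(list(fps = fps, x = x, y = y,
                 agents = data.frame(agent_id = ids,
                                     species = rep(species, n),
                                     stringsAsFactors = FALSE),
                 geometry = arena_geometry()),
            class = "track_set")
}

test_that("stationary individuals give an all-zero turning signal", {
  obj <- static_obj(matrix(2, 200, 3), matrix(1, 200, 3))
  sig <- group_signal(obj, "turning_magnitude", "mosquitofish")
  expect_equal(length(sig$values), 20)
  expect_true(all(sig$values == 0))
})

test_that("six individuals at the centre give a constant central count of 6", {
  obj <- static_obj(matrix(0, 100, 6), matrix(0, 100, 6))
  sig <- group_signal(obj, "central_count", "mosquitofish")
  expect_true(all(sig$values == 6))
  # at 16 cm they are all external
  obj2 <- static_obj(matrix(16, 100, 6), matrix(0, 100, 6))
  expect_true(all(group_signal(obj2, "central_count",
                               "mosquitofish")$values == 0))
})

test_that("an hour-long trial yields 7200 ticks and 7199 symbols", {
  rec <- simulate_trial(duration = 3600, seed = 2)
  for (v in c("turning_magnitude", "central_count")) {
    sig <- group_signal(rec, v, "tadpole")
    expect_length(sig$values, 7200)
    sym <- symbolize(sig)
    expect_length(sym, 7199)
    expect_gt(length(sym), 7000)
  }
})

test_that("missing species and too-coarse sampling are rejected", {
  obj <- static_obj(matrix(0, 100, 2), matrix(0, 100, 2))
  expect_error(group_signal(obj, "turning_magnitude", "tadpole"), "species")
  obj_slow <- static_obj(matrix(0, 10, 2), matrix(0, 10, 2), fps = 1)
  expect_error(group_signal(obj_slow, "central_count", "mosquitofish"),
               "sampling")
})

test_that("symbolization encodes increases as + and ties/decreases as -", {
  expect_equal(unclass(symbolize(c(1.0, 1.2, 1.2, 0.9))), c("+", "-", "-"))
  expect_true(all(symbolize(rep(2, 10)) == "-"))
  expect_true(all(symbolize(1:50) == "+"))
  expect_length(symbolize(1:50), 49)
  expect_error(symbolize(c(1, NA, 2)), "finite")
  expect_error(symbolize(1), "at least 2")
})
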