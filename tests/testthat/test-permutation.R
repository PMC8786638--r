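fake_trials <- function(n_trials, n, coupled = FALSE, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    m <- sample(0:1, n, replace = TRUE)
    tt <- if (coupled) c(sample(0:1, 1), m[-n]) else sample(0:1, n, TRUE)
    list(source = ifelse(m == 1, "+", "-"),
         target = ifelse(tt == 1, "+", "-"))
  })
}

test_that("permutation test is deterministic given seed and inputs", {
  trials <- fake_trials(6, 300, coupled = TRUE, seed = 3)
  a <- permutation_test(trials, n_perm = 400, seed = 17)
  b <- permutation_test(trials, n_perm = 400, seed = 17)
  expect_identical(a$null_distribution, b$null_distribution)
  expect_identical(a$significant, b$significant)
  c <- permutation_test(trials, n_perm = 400, seed = 18)
  expect_false(identical(a$null_distribution, c$null_distribution))
})

test_that("a single trial cannot be permuted across trials", {
  expect_error(permutation_test(fake_trials(1, 100), n_perm = 10, seed = 1),
               "at least 2 trials")
})

test_that("null draws always re-pair with a different trial's source", {
  for (n_trials in c(2, 5, 9)) {
    d <- roboprey:::draw_donors(n_trials, 500, seed = 4)
    expect_true(all(d >= 1 & d <= n_trials))
    own <- matrix(rep(seq_len(n_trials), each = 500), nrow = 500)
    expect_true(all(d != own))   # the observed pairing never appears
  }
})

test_that("strong lagged copying is detected; independent series are not", {
  coupled <- permutation_test(fake_trials(8, 500, coupled = TRUE, seed = 6),
                              n_perm = 500, seed = 7,
                              direction = "mosquitofish->tadpole")
  expect_true(coupled$significant)
  expect_gt(coupled$observed_mean, 0.9)
  indep <- permutation_test(fake_trials(8, 500, coupled = FALSE, seed = 8),
                            n_perm = 500, seed = 9)
  expect_false(indep$significant)
})

test_that("the observed statistic is the mean per-trial transfer entropy", {
  trials <- fake_trials(5, 200, coupled = TRUE, seed = 10)
  res <- permutation_test(trials, n_perm = 50, seed = 11)
  per_trial <- vapply(trials, function(tr)
    transfer_entropy(tr$source, tr$target), numeric(1))
  expect_equal(res$te_per_trial, per_trial)
  expect_equal(res$observed_mean, mean(per_trial))
  expect_equal(res$n_permutations, 50L)
  expect_length(res$null_distribution, 50)
})

test_that("te_analysis reports both directions for both variables", {
  recs <- lapply(1:3, function(i)
    simulate_trial(duration = 60, seed = 300 + i))
  rep <- te_analysis(recs, n_perm = 100, seed = 1)
  expect_equal(nrow(rep), 4)
  expect_setequal(unique(rep$variable),
                  c("turning_magnitude", "central_count"))
  expect_setequal(unique(rep$direction),
                  c("mosquitofish->tadpole", "tadpole->mosquitofish"))
  expect_true(all(rep$observed_mean_bits >= 0))
  expect_true(all(rep$null_q95_bits >= 0))
})
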