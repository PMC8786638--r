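# Independent oracles and shared fixtures for the test suite.

# Brute-force transfer entropy: explicit plug-in probabilities for each of
# the eight (T_{t+1}, T_t, M_t) outcomes, written independently of the
# package's tabulation-based estimator.
te_oracle <- function(source, target) {
  to01 <- function(s) if (is.character(s)) as.integer(s == "+") else as.integer(s)
  m <- to01(source); tt <- to01(target)
  n <- length(tt)
  t1 <- tt[-1]; t0 <- tt[-n]; m0 <- m[-n]
  total <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    n_joint <- sum(t1 == a & t0 == b & m0 == cc)
    if (n_joint == 0) next
    p_joint <- n_joint / (n - 1)
    p_full <- n_joint / sum(t0 == b & m0 == cc)
    p_hist <- sum(t1 == a & t0 == b) / sum(t0 == b)
    total <- total + p_joint * log2(p_full / p_hist)
  }
  total
}

# all permutations of 1..n (for the exhaustive assignment oracle)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# exhaustive minimum-cost one-to-one matching over all permutations
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    tot <- sum(cost[cbind(seq_len(n), perms[r, ])])
    if (tot < best) best <- tot
  }
  best
}

# swap-tolerant round-trip error: per frame, per species, optimally match
# tracked to true positions and collect distances
roundtrip_errors <- function(rec, ts) {
  errs <- c()
  for (sp in unique(ts$agents$species)) {
    ti <- which(ts$agents$species == sp)
    ai <- which(rec$agents$species == sp)
    for (k in seq_len(nrow(ts$x))) {
      am <- assign_detections(cbind(ts$x[k, ti], ts$y[k, ti]),
                              cbind(rec$x[k, ai], rec$y[k, ai]))
      errs <- c(errs,
                sqrt((ts$x[k, ti[am$matches[, 1]]] -
                        rec$x[k, ai[am$matches[, 2]]])^2 +
                       (ts$y[k, ti[am$matches[, 1]]] -
                          rec$y[k, ai[am$matches[, 2]]])^2))
    }
  }
  errs
}

# symbolic trial pairs from zero-coupling / coupled simulations
sim_te_trials <- function(n_trials, dur, coupling, treatment, seed0,
                          variable = "turning_magnitude", stride = 1L) {
  lapply(seq_len(n_trials), function(i) {
    rec <- simulate_trial(coupling = coupling, treatment = treatment,
                          duration = dur,
                          seed = (seed0 + stride * i) %% .Machine$integer.max)
    list(source = symbolize(group_signal(rec, variable, "mosquitofish")),
         target = symbolize(group_signal(rec, variable, "tadpole")))
  })
}
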