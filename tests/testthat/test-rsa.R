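# noiseless population where condition i drives unit i only, identically in
# both formats
orthogonal_session <- function(reps = 2, scale_obs = 1, seed = 1) {
  d <- make_design("main", reps_per_condition = reps, seed = seed)
  cond <- paste(d$trials$hand, d$trials$action, d$trials$direction)
  lev <- sort(unique(cond))
  nu <- length(lev)
  arr <- array(0, c(nu, nrow(d$trials), 30))
  for (i in seq_len(nu)) {
    hit <- cond == lev[i]
    amp <- ifelse(d$trials$block == "observation", scale_obs, 1)
    for (b in 11:20) arr[i, , b] <- 20 * amp * as.numeric(hit)
  }
  list(rates = rates_from_array(arr, trial_ids = d$trials$trial_id),
       trials = d$trials)
}

test_that("orthogonal shared codes give near-identity cross-format RSA", {
  s <- orthogonal_session()
  res <- split_half_rsa(s$rates, s$trials, grouping = "all",
                        comparison = "cross", n_splits = 5, seed = 1)
  expect_equal(dim(res$matrix), c(12, 12))
  expect_true(all(diag(res$matrix) > 0.99))
  expect_true(all(res$matrix[row(res$matrix) != col(res$matrix)] < 0))
  expect_gt(res$structure_stat, 0.9)
})

test_that("noiseless data gives identical matrices for 1 and many splits", {
  s <- orthogonal_session()
  m1 <- split_half_rsa(s$rates, s$trials, grouping = "all",
                       comparison = "cross", n_splits = 1, seed = 3)
  m2 <- split_half_rsa(s$rates, s$trials, grouping = "all",
                       comparison = "cross", n_splits = 100, seed = 4)
  expect_equal(m1$matrix, m2$matrix, tolerance = 1e-12)
})

test_that("idiosyncratic remapping has no cross-format structure", {
  sess <- quick_session(c(idiosyncratic = 20), reps = 6, seed = 7,
                        effect = 30)
  r <- bin_rates(sess$spikes, sess$trials)
  res <- split_half_rsa(r, sess$trials, grouping = "action",
                        comparison = "cross", n_splits = 50, seed = 8)
  expect_lt(abs(res$structure_stat), 0.25)
  # the permutation test should reject only at the nominal rate: any one
  # realization can carry accidental cross-format alignment, so test over
  # several independent populations
  keep <- 0
  for (s2 in 1:10) {
    sess2 <- quick_session(c(idiosyncratic = 20), reps = 4, seed = 100 + s2,
                           effect = 30)
    r2 <- bin_rates(sess2$spikes, sess2$trials)
    pt <- rsa_permutation_test(r2, sess2$trials, grouping = "action",
                               comparison = "cross", n_splits = 8,
                               n_perm = 39, seed = s2)
    keep <- keep + (pt$p > 0.05)
  }
  expect_gte(keep, 8)
})

test_that("planted shared-action structure reaches the minimum p", {
  sess <- quick_session(c(shared_action3 = 15), reps = 6, seed = 10,
                        effect = 40, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  pt <- rsa_permutation_test(r, sess$trials, grouping = "action",
                             comparison = "cross", n_splits = 20,
                             n_perm = 99, seed = 11)
  expect_equal(pt$p, 1 / 100)
  expect_gt(pt$observed, 0.5)
})

test_that("within-format matrices are symmetric; statistic is invariant to
           unit order and rate scaling", {
  sess <- quick_session(c(shared_action3 = 8, unselective = 4), reps = 4,
                        seed = 12, effect = 25, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  res <- split_half_rsa(r, sess$trials, grouping = "action",
                        comparison = "intention", n_splits = 20, seed = 13)
  expect_equal(res$matrix, t(res$matrix))

  # uniform scaling of all rates: Pearson invariance, same seed
  r2 <- r; r2$rates <- r$rates * 3.7
  res2 <- split_half_rsa(r2, sess$trials, grouping = "action",
                         comparison = "intention", n_splits = 20,
                         seed = 13)
  expect_equal(res$matrix, res2$matrix, tolerance = 1e-12)

  # unit permutation invariance (same split seed, features permuted)
  perm_units <- rev(r$unit_ids)
  res3 <- split_half_rsa(r, sess$trials, units = perm_units,
                         grouping = "action", comparison = "intention",
                         n_splits = 20, seed = 13)
  expect_equal(res$structure_stat, res3$structure_stat, tolerance = 1e-10)
})

test_that("cross-format structure grows with observation gain", {
  stats <- sapply(c(0, 1), function(g) {
    sess <- quick_session(c(shared_action3 = 12), reps = 6, seed = 20,
                          effect = 30, gain = g)
    r <- bin_rates(sess$spikes, sess$trials)
    split_half_rsa(r, sess$trials, grouping = "action",
                   comparison = "cross", n_splits = 30,
                   seed = 21)$structure_stat
  })
  expect_gt(stats[2], stats[1] + 0.2)
})

test_that("window robustness: stationary codes correlate across windows,
           late codes do not", {
  s <- orthogonal_session()          # active 1-2 s only
  wr <- window_robustness(s$rates, s$trials, grouping = "action",
                          comparison = "cross",
                          windows = list(c(0, 1), c(1, 2), c(1.5, 2.5)),
                          n_splits = 5, seed = 30)
  # identical window to the reference -> r = 1 exactly (same seed)
  expect_equal(wr$r[wr$window == "[1,2)"], 1, tolerance = 1e-12)
  # code absent in [0,1): degenerate or uncorrelated
  r01 <- wr$r[wr$window == "[0,1)"]
  expect_true(is.na(r01) || r01 < 0.5)
})

test_that("all-units control tracks the relevant-unit matrix when signal
           dominates", {
  sess <- quick_session(c(shared_action3 = 10, unselective = 5), reps = 4,
                        seed = 31, effect = 40, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  rel <- sess$ground_truth$unit_id[
    sess$ground_truth$archetype == "shared_action3"]
  ctl <- all_units_control(r, sess$trials, relevant_units = rel,
                           grouping = "action", comparison = "cross",
                           n_splits = 20, seed = 32)
  expect_gt(ctl$r, 0.8)
})

test_that("conditions with too few trials are rejected", {
  s <- orthogonal_session(reps = 2)
  tr <- s$trials[-1, ]
  expect_error(split_half_rsa(s$rates, tr, grouping = "all",
                              comparison = "cross", n_splits = 2),
               ">=2 trials")
})
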