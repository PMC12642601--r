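test_that("the discriminant boundary matches the closed-form Fisher
           solution on a 2-D Gaussian toy", {
  set.seed(1)
  n <- 200
  mu1 <- c(1, 0); mu2 <- c(-1, 0.5)
  S <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  L <- chol(S)
  X <- rbind(matrix(rnorm(n * 2), n) %*% L + rep(mu1, each = n),
             matrix(rnorm(n * 2), n) %*% L + rep(mu2, each = n))
  y <- rep(c("a", "b"), each = n)
  model <- crossformat:::lda_train(X, y)
  # closed form: w = S_pooled^-1 (m1 - m2), threshold at the midpoint
  m1 <- colMeans(X[y == "a", ]); m2 <- colMeans(X[y == "b", ])
  Sp <- (crossprod(sweep(X[y == "a", ], 2, m1)) +
         crossprod(sweep(X[y == "b", ], 2, m2))) / (2 * n - 2)
  w <- solve(Sp, m1 - m2)
  grid <- as.matrix(expand.grid(x = seq(-3, 3, 0.25),
                                y = seq(-3, 3, 0.25)))
  pred <- crossformat:::lda_predict(model, grid)
  fisher <- ifelse(grid %*% w - sum(w * (m1 + m2)) / 2 > 0, "a", "b")
  expect_equal(pred, as.vector(fisher))
})

test_that("our LDA agrees with MASS::lda on well-conditioned data", {
  set.seed(2)
  X <- matrix(rnorm(300 * 4), 300)
  y <- rep(c("a", "b", "c"), each = 100)
  X[y == "a", 1] <- X[y == "a", 1] + 2
  X[y == "c", 2] <- X[y == "c", 2] - 2
  model <- crossformat:::lda_train(X, y)
  Xte <- matrix(rnorm(90 * 4), 90)
  ours <- crossformat:::lda_predict(model, Xte)
  ref <- as.character(predict(MASS::lda(X, grouping = y), Xte)$class)
  expect_gt(mean(ours == ref), 0.97)
})

test_that("identical class distributions decode at chance with a flat
           confusion matrix", {
  sess <- quick_session(c(unselective = 15), reps = 10, seed = 3)
  r <- bin_rates(sess$spikes, sess$trials)
  d <- decode_timecourse(r, sess$trials, label = "hand",
                         blocks = "intention", seed = 4)
  expect_true(all(d$accuracy$accuracy > 0.25 & d$accuracy$accuracy < 0.75))
  expect_equal(mean(d$accuracy$accuracy), 0.5, tolerance = 0.08)
  expect_equal(rowSums(d$confusion), c(left = 1, right = 1))
})

test_that("well-separated planted classes exceed 95% in the response
           window", {
  sess <- quick_session(c(shared_action3 = 18), reps = 10, seed = 5,
                        effect = 40, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  d <- decode_timecourse(r, sess$trials, label = "action",
                         blocks = "intention", seed = 6)
  resp <- d$accuracy$accuracy[d$accuracy$window_center_s > 1 &
                              d$accuracy$window_center_s < 2]
  expect_gt(max(resp), 0.95)
  expect_equal(d$chance, 1 / 3)
})

test_that("cross-time diagonal equals the time-resolved decoder exactly", {
  sess <- quick_session(c(shared_hand = 8, unselective = 4), reps = 6,
                        seed = 7, effect = 25, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  d <- decode_timecourse(r, sess$trials, label = "hand",
                         blocks = "intention", folds = 5, seed = 8)
  m <- cross_time_decode(r, sess$trials, label = "hand",
                         blocks = "intention", folds = 5, seed = 8)
  expect_equal(diag(m$accuracy), d$accuracy$accuracy, tolerance = 1e-12)
})

test_that("a time-stable code generalizes broadly across time", {
  # class means constant over the whole trial: train anywhere, test
  # anywhere
  d <- make_design("main", reps_per_condition = 10, seed = 9)
  sub <- d$trials[d$trials$block == "intention", ]
  mu <- matrix(8 * as.numeric(sub$hand == "right"), 1)
  mu <- rbind(mu, 8 * as.numeric(sub$action == "lift"),
              8 * as.numeric(sub$direction == "right"))
  r <- gaussian_rates(mu, sd = 2, bins_active = 1:30, seed = 10)
  r$trial_ids <- sub$trial_id
  dimnames(r$rates)[[2]] <- sub$trial_id
  m <- cross_time_decode(r, sub, label = "hand", folds = 5, seed = 11)
  expect_gt(min(m$accuracy), max(diag(m$accuracy)) - 0.05)
})

test_that("a code that flips sign mid-trial generalizes below chance
           across the flip", {
  d <- make_design("main", reps_per_condition = 10, seed = 12)
  sub <- d$trials[d$trials$block == "intention", ]
  sig <- 8 * (2 * as.numeric(sub$hand == "right") - 1)
  arr <- array(0, c(2, nrow(sub), 30))
  for (b in 1:15) arr[1, , b] <- sig + rnorm(nrow(sub))
  for (b in 16:30) arr[1, , b] <- -sig + rnorm(nrow(sub))
  arr[2, , ] <- rnorm(nrow(sub) * 30)
  r <- rates_from_array(arr, trial_ids = sub$trial_id)
  m <- cross_time_decode(r, sub, label = "hand", folds = 5, seed = 13)
  early <- m$train_centers_s < 1.5
  cross_blocks <- m$accuracy[early, !early]
  expect_lt(mean(cross_blocks), 0.25)   # well below chance 0.5
  expect_gt(mean(diag(m$accuracy)), 0.9)
})

test_that("cross-format decoding flags shared codes in both directions and
           stays silent for single-format codes", {
  shared <- quick_session(c(shared_action3 = 15), reps = 8, seed = 14,
                          effect = 40, gain = 1)
  r <- bin_rates(shared$spikes, shared$trials)
  m_io <- cross_format_decode(r, shared$trials, label = "action",
                              direction = "int_to_obs", n_perm = 200,
                              seed = 15)
  m_oi <- cross_format_decode(r, shared$trials, label = "action",
                              direction = "obs_to_int", n_perm = 200,
                              seed = 16)
  expect_gt(sum(m_io$sig_mask), 0)
  expect_gt(sum(m_oi$sig_mask), 0)
  # significant cells concentrate at matched response times (1-2 s)
  resp <- m_io$train_centers_s > 1 & m_io$train_centers_s < 2
  expect_gt(sum(m_io$sig_mask[resp, resp]),
            0.5 * sum(m_io$sig_mask))

  single <- quick_session(c(single_intention = 15), reps = 8, seed = 17,
                          effect = 40)
  r2 <- bin_rates(single$spikes, single$trials)
  m2 <- cross_format_decode(r2, single$trials, label = "action",
                            direction = "int_to_obs", n_perm = 200,
                            seed = 18)
  expect_equal(sum(m2$sig_mask), 0)
})

test_that("permutation inference never touches the trained models", {
  sess <- quick_session(c(shared_hand = 10), reps = 6, seed = 19,
                        effect = 30, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  a <- cross_format_decode(r, sess$trials, label = "hand",
                           n_perm = 50, seed = 20)
  b <- cross_format_decode(r, sess$trials, label = "hand",
                           n_perm = 50, seed = 999)
  expect_identical(a$accuracy, b$accuracy)   # only p-values may differ
})

test_that("decoding accuracy is invariant to per-unit affine rescaling on
           separable data", {
  sess <- quick_session(c(shared_action3 = 10), reps = 8, seed = 21,
                        effect = 40, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  d1 <- decode_timecourse(r, sess$trials, label = "action",
                          blocks = "intention", folds = 5, seed = 22)
  r2 <- r
  sc <- seq(0.5, 3, length.out = length(r$unit_ids))
  r2$rates <- r$rates * sc           # recycled over the unit dimension
  d2 <- decode_timecourse(r2, sess$trials, label = "action",
                          blocks = "intention", folds = 5, seed = 22)
  expect_equal(d1$peak$accuracy, d2$peak$accuracy, tolerance = 0.05)
})

test_that("sessionwise decoding reports per-session peaks", {
  d <- make_design("main", reps_per_condition = 5, n_sessions = 2,
                   seed = 23)
  sim <- simulate_spikes(d$design, d$trials,
                         archetype_population(c(shared_hand = 8),
                                              effect_size = 30,
                                              observation_gain = 1),
                         seed = 24)
  r <- bin_rates(sim$spikes, d$trials)
  tab <- sessionwise_decode(r, d$trials, labels = "hand", folds = 5,
                            seed = 25)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$peak_accuracy > 0.8))
})

test_that("degenerate label sets error cleanly", {
  sess <- quick_session(c(unselective = 3), reps = 2, seed = 26)
  tr <- sess$trials[sess$trials$hand == "left", ]
  r <- bin_rates(sess$spikes, sess$trials)
  expect_error(decode_timecourse(r, tr, label = "hand"), "two classes")
})
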