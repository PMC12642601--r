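# binned rates over [-0.5, 3) built from per-condition latent timecourses:
# rate[unit, trial, bin] = sum_k loading[unit, k] * latent[k, bin, cond]
latent_session <- function(loadings, latents_int, latents_obs = latents_int,
                           reps = 4, noise_sd = 0, seed = 1) {
  d <- make_design("main", reps_per_condition = reps, seed = seed)
  nu <- nrow(loadings); nb <- dim(latents_int)[2]
  arr <- array(0, c(nu, nrow(d$trials), nb))
  set.seed(seed + 1)
  acts <- c("lift", "slide", "rotate")
  for (ti in seq_len(nrow(d$trials))) {
    ci <- match(d$trials$action[ti], acts)
    L <- if (d$trials$block[ti] == "intention") latents_int else latents_obs
    arr[, ti, ] <- loadings %*% L[, , ci] +
      matrix(rnorm(nu * nb, 0, noise_sd), nu)
  }
  list(rates = rates_from_array(arr, trial_ids = d$trials$trial_id,
                                window_start = -0.5),
       trials = d$trials)
}

two_latents <- function(nb = 35) {
  t <- seq_len(nb)
  L <- array(0, c(2, nb, 3))
  for (ci in 1:3) {
    L[1, , ci] <- sin(2 * pi * t / nb + ci)
    L[2, , ci] <- cos(2 * pi * t / nb * 2 + ci / 2)
  }
  L
}

test_that("a rank-2 population is fully captured by three components", {
  loadings <- matrix(rnorm(10 * 2), 10)
  s <- latent_session(loadings, two_latents())
  tr <- pca_trajectories(s$rates, s$trials, grouping = "action")
  expect_equal(tr$variance_explained$combined, 1, tolerance = 1e-9)
  expect_equal(nrow(tr$trajectories), 2 * 3 * 30)  # formats x cond x bins
})

test_that("identical planted trajectories across formats coincide
           pointwise", {
  loadings <- matrix(rnorm(8 * 2), 8)
  s <- latent_session(loadings, two_latents())
  tr <- pca_trajectories(s$rates, s$trials, grouping = "action")
  for (cl in unique(tr$trajectories$condition)) {
    a <- tr$trajectories[tr$trajectories$format == "intention" &
                         tr$trajectories$condition == cl, c("PC1", "PC2",
                                                            "PC3")]
    b <- tr$trajectories[tr$trajectories$format == "observation" &
                         tr$trajectories$condition == cl, c("PC1", "PC2",
                                                            "PC3")]
    expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-8)
  }
})

test_that("format-specific subspaces lose captured variance for one
           format", {
  set.seed(5)
  # intention lives on units 1-6, observation on orthogonal units 7-12
  load_int <- rbind(matrix(rnorm(6 * 2, sd = 3), 6), matrix(0, 6, 2))
  load_obs <- rbind(matrix(0, 6, 2), matrix(rnorm(6 * 2, sd = 1), 6))
  L <- two_latents()
  d <- make_design("main", reps_per_condition = 4, seed = 6)
  arr <- array(0, c(12, nrow(d$trials), 35))
  acts <- c("lift", "slide", "rotate")
  for (ti in seq_len(nrow(d$trials))) {
    ci <- match(d$trials$action[ti], acts)
    ld <- if (d$trials$block[ti] == "intention") load_int else load_obs
    arr[, ti, ] <- ld %*% L[, , ci]
  }
  r <- rates_from_array(arr, trial_ids = d$trials$trial_id,
                        window_start = -0.5)
  tr <- pca_trajectories(r, d$trials, grouping = "action")
  # the shared space is dominated by the higher-variance intention patterns
  expect_gt(tr$variance_explained$intention,
            tr$variance_explained$observation)
})

test_that("procrustes distance is exactly zero for identity and for
           similarity transforms", {
  set.seed(7)
  a <- matrix(rnorm(30 * 3), 30)
  expect_equal(procrustes_distance(a, a)$d, 0, tolerance = 1e-14)
  # random rotation, scaling, offset
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  b <- 2.5 * a %*% Q + rep(c(3, -1, 0.5), each = 30)
  expect_lt(procrustes_distance(a, b)$d, 1e-10)
  expect_lt(procrustes_distance(b, a)$d, 1e-10)
})

test_that("procrustes distance agrees with vegan and is symmetric", {
  set.seed(8)
  a <- matrix(rnorm(20 * 3), 20)
  b <- matrix(rnorm(20 * 3), 20)
  d_ab <- procrustes_distance(a, b)$d
  d_ba <- procrustes_distance(b, a)$d
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
  ref <- vegan::procrustes(a, b, symmetric = TRUE)$ss
  expect_equal(d_ab, ref, tolerance = 1e-8)
})

test_that("unrelated trajectories are distant (Monte-Carlo oracle)", {
  # reference quantiles computed with an independent implementation
  # (scipy.spatial.procrustes, 1000 pairs): random walks have 5th
  # percentile ~0.29 and median ~0.55; white-noise trajectories
  # concentrate near 1 (5th percentile ~0.86)
  set.seed(9)
  d_walk <- replicate(400, {
    a <- apply(matrix(rnorm(30 * 3), 30), 2, cumsum)
    b <- apply(matrix(rnorm(30 * 3), 30), 2, cumsum)
    procrustes_distance(a, b)$d
  })
  expect_gt(quantile(d_walk, 0.05), 0.2)
  expect_lt(abs(median(d_walk) - 0.55), 0.1)
  d_noise <- replicate(400, {
    procrustes_distance(matrix(rnorm(90), 30), matrix(rnorm(90), 30))$d
  })
  expect_gt(quantile(d_noise, 0.05), 0.5)
  expect_gt(median(d_noise), 0.85)
})

test_that("degenerate trajectories are rejected", {
  a <- matrix(rnorm(30), 10, 3)
  const <- matrix(1, 10, 3)
  expect_error(procrustes_distance(a, const), "all-constant")
  expect_error(procrustes_distance(a, a[1:5, ]), "equal dims")
})

test_that("shared planted geometry yields smaller distances than
           format-specific geometry", {
  set.seed(10)
  loadings <- matrix(rnorm(10 * 2), 10)
  shared <- latent_session(loadings, two_latents(), noise_sd = 0.05,
                           seed = 11)
  tr_s <- pca_trajectories(shared$rates, shared$trials,
                           grouping = "action")
  d_shared <- mean(procrustes_report(tr_s)$d)

  L2 <- two_latents()
  L2_obs <- L2[, , c(2, 3, 1)]      # remapped latent assignment
  L2_obs[1, , ] <- -L2_obs[1, , ]
  specific <- latent_session(loadings, L2, L2_obs, noise_sd = 0.05,
                             seed = 12)
  tr_f <- pca_trajectories(specific$rates, specific$trials,
                           grouping = "action")
  d_specific <- mean(procrustes_report(tr_f)$d)
  expect_lt(d_shared, d_specific)
  expect_lt(d_shared, 0.1)
})

test_that("all_units_geometry_control runs the unfiltered pipeline", {
  loadings <- matrix(rnorm(8 * 2), 8)
  s <- latent_session(loadings, two_latents(), noise_sd = 0.02, seed = 13)
  rep <- all_units_geometry_control(s$rates, s$trials)
  expect_s3_class(rep, "procrustes_report")
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$d >= 0 & rep$d <= 1))
})

test_that("UMAP embeddings separate planted clusters, are deterministic,
           and summarize groups with ellipses", {
  sess <- quick_session(c(shared_hand = 12), reps = 8, seed = 14,
                        effect = 60, gain = 1)
  r <- bin_rates(sess$spikes, sess$trials)
  e1 <- embed_trials(r, sess$trials, grouping = "hand", seed = 15)
  e2 <- embed_trials(r, sess$trials, grouping = "hand", seed = 15)
  expect_equal(e1$points, e2$points, tolerance = 1e-12)

  # two hand clusters: centroid separation exceeds the ellipse extents
  ell <- e1$ellipses |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(cx = mean(.data$cx), cy = mean(.data$cy),
                     r = max(.data$major_len))
  sep <- sqrt(diff(ell$cx)^2 + diff(ell$cy)^2)
  expect_gt(sep, sum(ell$r))
  # ellipse axes are orthogonal
  dot <- e1$ellipses$major_x * e1$ellipses$minor_x +
         e1$ellipses$major_y * e1$ellipses$minor_y
  expect_true(all(abs(dot) < 1e-8))

  expect_error(embed_trials(r, sess$trials[1:10, ], seed = 1),
               "neighbours")
})
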