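#' Shared-space PCA trajectories
#'
#' Condition-averaged population timecourses for both formats are stacked
#' into a `(conditions x time) x units` matrix, PCA is computed on the
#' combined stack, and every condition/format trajectory is projected into
#' the same top-3 component space. Variance explained by the top three
#' components is reported three ways: for the combined stack, and for each
#' format's rows after projection into the shared space.
#'
#' @param rates a [bin_rates()] result covering the trajectory window
#'   (build with `bin_rates(..., window = c(-0.5, 3))` to include the
#'   pre-stimulus epoch).
#' @param trials trial tibble.
#' @param units unit ids (>= 3) — normally the task-relevant subset.
#' @param grouping `"action"`, `"hand"` or `"direction"`.
#' @param window trajectory window, default `c(-0.5, 2.5)`.
#' @return object of class `trajectory_set`: `trajectories` tibble
#'   (condition, format, time_s, PC1..PC3), `variance_explained` (named
#'   list: combined, intention, observation), `rotation`, `center`.
#' @export
pca_trajectories <- function(rates, trials, units = NULL,
                             grouping = "action", window = c(-0.5, 2.5)) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (is.null(units)) units <- rates$unit_ids
  if (length(units) < 3) stop("need >=3 units to span three components")
  if (!all(c("intention", "observation") %in% trials$block))
    stop("both formats must be present")
  rsub <- subset_rates(rates, unit_ids = units,
                       trial_ids = trials$trial_id)
  bw <- rsub$bin_width_s / 2
  keep <- rsub$bin_centers_s - bw >= window[1] - 1e-9 &
          rsub$bin_centers_s + bw <= window[2] + 1e-9
  tt <- rsub$bin_centers_s[keep]
  lev <- sort(unique(trials[[grouping]]))
  blocks <- c("intention", "observation")
  mats <- list()
  for (f in blocks) for (l in lev) {
    ti <- which(trials$block == f & trials[[grouping]] == l)
    mats[[paste(f, l, sep = ".")]] <-
      t(rowMeans(aperm(rsub$rates[, ti, keep, drop = FALSE],
                       c(1, 3, 2)), dims = 2))   # time x units
  }
  X <- do.call(rbind, mats)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  rot <- sv$v[, 1:3, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- sv$d^2
  var_combined <- sum(ev[1:3]) / sum(ev)
  per_format_var <- function(f) {
    rows <- grepl(paste0("^", f, "\\."), rep(names(mats),
                                             each = length(tt)))
    Xf <- Xc[rows, , drop = FALSE]
    Xf <- sweep(Xf, 2, colMeans(Xf))
    sum(colSums((Xf %*% rot)^2)) / sum(Xf^2)
  }
  traj <- purrr::imap_dfr(mats, function(M, nm) {
    pr <- sweep(M, 2, center) %*% rot
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble::tibble(format = parts[1], condition = parts[2], time_s = tt,
                   PC1 = pr[, 1], PC2 = pr[, 2], PC3 = pr[, 3])
  })
  structure(list(trajectories = traj,
                 variance_explained = list(
                   combined = var_combined,
                   intention = per_format_var("intention"),
                   observation = per_format_var("observation")),
                 rotation = rot, center = center, grouping = grouping),
            class = "trajectory_set")
}

#' Procrustes distance between two trajectories
#'
#' Standardized (symmetric) Procrustes: both matrices are centred and
#' scaled to unit Frobenius norm, then the orthogonal transform (rotation,
#' optionally reflection) and isotropic scaling minimizing the residual
#' Frobenius norm are applied. The distance is the minimized residual sum
#' of squares, `d = 1 - (sum of singular values)^2`, in `[0, 1]`; 0 iff the
#' trajectories are identical up to the allowed transform.
#'
#' @param a,b numeric matrices (time x dims) with equal dimensions.
#' @param allow_reflection allow the orthogonal part to include reflections
#'   (classical Procrustes); set `FALSE` to restrict to proper rotations.
#' @return list of class `procrustes_fit`: `d`, `rotation`, `scale`,
#'   `translation` (applied to the standardized `b`), `b_aligned` (b mapped
#'   onto a, in a's standardized frame).
#' @export
procrustes_distance <- function(a, b, allow_reflection = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("trajectories must have equal dims")
  std <- function(m) {
    mc <- sweep(m, 2, colMeans(m))
    nrm <- sqrt(sum(mc^2))
    if (nrm == 0) stop("all-constant trajectory: scaling undefined")
    list(m = mc / nrm, center = colMeans(m), norm = nrm)
  }
  sa <- std(a); sb <- std(b)
  M <- crossprod(sa$m, sb$m)
  sv <- svd(M)
  R <- sv$v %*% t(sv$u)
  d_sv <- sv$d
  if (!allow_reflection && det(R) < 0) {
    # flip the smallest singular direction to stay in SO(n)
    j <- which.min(sv$d)
    v <- sv$v; v[, j] <- -v[, j]
    R <- v %*% t(sv$u)
    d_sv[j] <- -d_sv[j]
  }
  s <- sum(d_sv)
  d <- 1 - s^2
  structure(list(d = max(d, 0), rotation = R, scale = s,
                 translation = sa$center,
                 b_aligned = s * sb$m %*% R),
            class = "procrustes_fit")
}

#' Per-condition Procrustes alignment report
#'
#' For each condition of a [pca_trajectories()] result, aligns the
#' observation trajectory onto the intention trajectory and reports the
#' normalized Procrustes distance.
#'
#' @param trajset a `trajectory_set`.
#' @param allow_reflection see [procrustes_distance()].
#' @return tibble of class `procrustes_report`: (condition, d) with the
#'   fits in a list-column.
#' @export
procrustes_report <- function(trajset, allow_reflection = TRUE) {
  stopifnot(inherits(trajset, "trajectory_set"))
  tr <- trajset$trajectories
  out <- purrr::map_dfr(sort(unique(tr$condition)), function(cl) {
    a <- as.matrix(tr[tr$format == "intention" & tr$condition == cl,
                      c("PC1", "PC2", "PC3")])
    b <- as.matrix(tr[tr$format == "observation" & tr$condition == cl,
                      c("PC1", "PC2", "PC3")])
    fit <- procrustes_distance(a, b, allow_reflection)
    tibble::tibble(condition = cl, d = fit$d, fit = list(fit))
  })
  class(out) <- c("procrustes_report", class(out))
  out
}

#' All-units geometry control
#'
#' Repeats the PCA + Procrustes pipeline with the unit filter removed.
#'
#' @inheritParams pca_trajectories
#' @return a `procrustes_report`.
#' @export
all_units_geometry_control <- function(rates, trials, grouping = "action",
                                       window = c(-0.5, 2.5)) {
  procrustes_report(pca_trajectories(rates, trials, units = NULL,
                                     grouping = grouping, window = window))
}

#' UMAP embedding of single trials with condition ellipses
#'
#' Embeds trial-level population activity (mean net rate in a 1-2 s window,
#' both formats concatenated) into two dimensions with UMAP (cosine metric,
#' 15 neighbours, minimum distance 0.1), and summarizes each
#' condition-by-format group with its centroid and covariance-eigen
#' ellipse.
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble.
#' @param units unit ids; default all.
#' @param grouping factor column for the ellipses, default `"action"`.
#' @param window averaging window.
#' @param n_neighbors,min_dist,metric UMAP hyper-parameters.
#' @param seed integer seed (fixed seed gives reproducible coordinates).
#' @return object of class `embedding_report`: `points` tibble (trial_id,
#'   block, condition, x, y), `ellipses` tibble (block, condition,
#'   centroid, axes).
#' @export
embed_trials <- function(rates, trials, units = NULL, grouping = "action",
                         window = c(1, 2), n_neighbors = 15,
                         min_dist = 0.1, metric = "cosine", seed = 1) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (nrow(trials) < n_neighbors + 1)
    stop("need more trials than UMAP neighbours (", n_neighbors, ")")
  rsub <- subset_rates(rates, unit_ids = units,
                       trial_ids = trials$trial_id)
  X <- t(window_mean_rates(rsub, window))    # trials x units
  local_rng(seed)
  emb <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                    metric = metric, n_threads = 1, n_sgd_threads = 0)
  pts <- tibble::tibble(trial_id = trials$trial_id, block = trials$block,
                        condition = trials[[grouping]],
                        x = emb[, 1], y = emb[, 2])
  ell <- pts |>
    dplyr::group_by(.data$block, .data$condition) |>
    dplyr::group_modify(function(g, key) {
      ctr <- c(mean(g$x), mean(g$y))
      S <- stats::cov(cbind(g$x, g$y))
      e <- eigen(S, symmetric = TRUE)
      tibble::tibble(cx = ctr[1], cy = ctr[2],
                     major_len = sqrt(pmax(e$values[1], 0)),
                     minor_len = sqrt(pmax(e$values[2], 0)),
                     major_x = e$vectors[1, 1], major_y = e$vectors[2, 1],
                     minor_x = e$vectors[1, 2], minor_y = e$vectors[2, 2])
    }) |>
    dplyr::ungroup()
  structure(list(points = pts, ellipses = ell, grouping = grouping),
            class = "embedding_report")
}
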