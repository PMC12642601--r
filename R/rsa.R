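#' Split-half representational similarity analysis
#'
#' For each of `n_splits` random splits, trials are halved within each
#' condition (and format); condition-averaged feature vectors — time bins in
#' the analysis window concatenated with units — are computed per half, and
#' Pearson correlations between all pairs of condition vectors form a
#' condition-by-condition similarity matrix. Within-format matrices
#' correlate the two half-averages of the same format (split-half
#' reliability geometry); the cross-format matrix correlates half-averages
#' of different formats, so noise levels match. Matrices are averaged over
#' splits. The structure statistic is `mean(diagonal) - mean(off-diagonal)`.
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble.
#' @param units unit ids to include (default: all; normally the
#'   task-relevant subset from [task_relevant_units()]).
#' @param grouping `"all"` (full conditions), `"action"`, `"hand"` or
#'   `"direction"` (marginal regrouping).
#' @param comparison `"intention"`, `"observation"` or `"cross"`.
#' @param n_splits number of random splits.
#' @param window analysis window in seconds, default `c(1, 2)`.
#' @param seed integer seed.
#' @return object of class `rsa_result`: list with `matrix` (condition x
#'   condition), `structure_stat`, `comparison`, `grouping`, `n_splits`,
#'   `window`.
#' @export
split_half_rsa <- function(rates, trials, units = NULL,
                           grouping = c("all", "action", "hand",
                                        "direction"),
                           comparison = c("cross", "intention",
                                          "observation"),
                           n_splits = 500, window = c(1, 2), seed = 1) {
  grouping <- match.arg(grouping)
  comparison <- match.arg(comparison)
  prep <- rsa_prepare(rates, trials, units, grouping, window)
  local_rng(seed)
  acc <- 0
  for (s in seq_len(n_splits))
    acc <- acc + rsa_one_split(prep, comparison)
  M <- acc / n_splits
  # the half assignment is arbitrary for within-format comparisons, so the
  # expected matrix is symmetric; enforce it
  if (comparison != "cross") M <- (M + t(M)) / 2
  dimnames(M) <- list(prep$levels, prep$levels)
  structure(list(matrix = M,
                 structure_stat = mean(diag(M)) -
                   mean(M[row(M) != col(M)]),
                 comparison = comparison, grouping = grouping,
                 n_splits = n_splits, window = window),
            class = "rsa_result")
}

# shared preprocessing: feature matrix + per-format condition indices
rsa_prepare <- function(rates, trials, units, grouping, window,
                        labels = NULL) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (is.null(units)) units <- rates$unit_ids
  rsub <- subset_rates(rates, unit_ids = units)
  bw <- rsub$bin_width_s / 2
  keep <- rsub$bin_centers_s - bw >= window[1] - 1e-9 &
          rsub$bin_centers_s + bw <= window[2] + 1e-9
  A <- rsub$rates[, match(trials$trial_id, rsub$trial_ids), keep,
                  drop = FALSE]
  # feature matrix: trials x (bins x units)
  F <- t(matrix(aperm(A, c(1, 3, 2)), nrow = dim(A)[1] * dim(A)[3]))
  if (is.null(labels)) {
    labels <- if (grouping == "all")
      condition_label(trials, NULL, intersect(c("hand", "action",
                                                "direction"),
                                              names(trials)))
    else trials[[grouping]]
  }
  fmt <- trials$block
  counts <- table(fmt, labels)
  if (any(counts < 2))
    stop("every condition needs >=2 trials per format for split-half RSA")
  cond12 <- condition_label(trials, NULL,
                            intersect(c("hand", "action", "direction",
                                        "conflict"), names(trials)))
  # grouping label carried by each full condition (constant within one)
  cmap <- tapply(labels, cond12, function(v) v[1])
  list(F = F, labels = labels, fmt = fmt,
       levels = sort(unique(labels)), formats = unique(fmt),
       cond12 = cond12, cond_levels = names(cmap),
       cond_group = as.vector(cmap))
}

# one split: returns the condition x condition correlation matrix
rsa_one_split <- function(prep, comparison) {
  lev <- prep$levels
  k <- length(lev)
  halves <- list()
  for (f in prep$formats) {
    A <- matrix(NA_real_, k, ncol(prep$F))
    B <- matrix(NA_real_, k, ncol(prep$F))
    for (i in seq_len(k)) {
      idx <- which(prep$fmt == f & prep$labels == lev[i])
      idx <- idx[sample.int(length(idx))]
      na <- ceiling(length(idx) / 2)      # extra trial goes to side A
      A[i, ] <- colMeans(prep$F[idx[seq_len(na)], , drop = FALSE])
      B[i, ] <- colMeans(prep$F[idx[(na + 1):length(idx)], ,
                                drop = FALSE])
    }
    halves[[f]] <- list(A = A, B = B)
  }
  # constant feature vectors (e.g. a window with no activity) yield NaN
  # correlations with a warning; the NaN is the honest answer here
  if (comparison == "cross") {
    suppressWarnings(stats::cor(t(halves[["intention"]]$A),
                                t(halves[["observation"]]$B)))
  } else {
    suppressWarnings(stats::cor(t(halves[[comparison]]$A),
                                t(halves[[comparison]]$B)))
  }
}

#' Permutation test for RSA structure
#'
#' Null distributions are generated by shuffling condition labels
#' independently within each format before trial splitting, repeating the
#' full split-half procedure, and collecting the structure statistic.
#'
#' Two shuffle schemes are available. `"condition"` (default) relabels
#' whole conditions within each format — trials of one condition keep a
#' common (new) label — which preserves each format's internal geometry
#' and tests exactly the across-format correspondence; it is calibrated
#' both for unstructured populations and for populations with real but
#' format-independent structure (idiosyncratic codes). `"trial"` shuffles
#' labels at the trial level, destroying within-format structure too; it
#' is the appropriate null for within-format reliability but is
#' anticonservative for the cross-format question when within-format
#' structure exists.
#'
#' @inheritParams split_half_rsa
#' @param n_perm number of label shuffles.
#' @param null `"condition"` or `"trial"`, see above.
#' @return list with `p`, `observed`, `null_stats`, and the observed
#'   `rsa_result`.
#' @export
rsa_permutation_test <- function(rates, trials, units = NULL,
                                 grouping = "action", comparison = "cross",
                                 n_splits = 100, n_perm = 200,
                                 window = c(1, 2), seed = 1,
                                 null = c("condition", "trial")) {
  null <- match.arg(null)
  obs <- split_half_rsa(rates, trials, units, grouping, comparison,
                        n_splits, window, seed)
  prep <- rsa_prepare(rates, trials, units, grouping, window)
  local_rng(seed + 1L)
  null_stats <- vapply(seq_len(n_perm), function(j) {
    lab <- prep$labels
    for (f in prep$formats) {
      idx <- which(prep$fmt == f)
      if (null == "trial") {
        lab[idx] <- lab[idx][sample.int(length(idx))]
      } else {
        pi <- sample.int(length(prep$cond_levels))
        new_group <- prep$cond_group[pi]
        lab[idx] <- new_group[match(prep$cond12[idx], prep$cond_levels)]
      }
    }
    pp <- prep; pp$labels <- lab
    acc <- 0
    for (s in seq_len(n_splits)) acc <- acc + rsa_one_split(pp, comparison)
    M <- acc / n_splits
    mean(diag(M)) - mean(M[row(M) != col(M)])
  }, numeric(1))
  list(p = (1 + sum(null_stats >= obs$structure_stat)) / (n_perm + 1),
       observed = obs$structure_stat, null_stats = null_stats,
       result = obs)
}

#' Time-window robustness of RSA structure
#'
#' Recomputes the RSA matrix in alternative windows and reports the Pearson
#' correlation of each matrix's lower triangle (diagonal excluded) with the
#' reference-window matrix.
#'
#' @inheritParams split_half_rsa
#' @param windows list of alternative windows.
#' @param reference_window the main-analysis window.
#' @return tibble (window, r) plus list-column `matrix`.
#' @export
window_robustness <- function(rates, trials, units = NULL,
                              grouping = "action", comparison = "cross",
                              windows = list(c(0, 1), c(0.5, 1),
                                             c(1.5, 2.5), c(2, 3)),
                              reference_window = c(1, 2),
                              n_splits = 100, seed = 1) {
  ref <- split_half_rsa(rates, trials, units, grouping, comparison,
                        n_splits, reference_window, seed)
  lt <- function(M) M[lower.tri(M)]
  purrr::map_dfr(windows, function(w) {
    m <- split_half_rsa(rates, trials, units, grouping, comparison,
                        n_splits, w, seed)
    a <- lt(m$matrix); b <- lt(ref$matrix)
    degenerate <- !all(is.finite(a)) || !all(is.finite(b)) ||
      stats::sd(a) == 0 || stats::sd(b) == 0
    r <- if (degenerate) NA_real_ else stats::cor(a, b)
    tibble::tibble(window = paste0("[", w[1], ",", w[2], ")"), r = r,
                   matrix = list(m$matrix))
  })
}

#' All-units RSA control
#'
#' Correlation (lower triangle plus diagonal) between the RSA matrix
#' computed on all units and the matrix from the task-relevant subset.
#'
#' @inheritParams split_half_rsa
#' @param relevant_units the task-relevant unit ids.
#' @return list with `r`, `matrix_all`, `matrix_relevant`.
#' @export
all_units_control <- function(rates, trials, relevant_units,
                              grouping = "action", comparison = "cross",
                              n_splits = 100, window = c(1, 2), seed = 1) {
  m_rel <- split_half_rsa(rates, trials, relevant_units, grouping,
                          comparison, n_splits, window, seed)
  m_all <- split_half_rsa(rates, trials, NULL, grouping, comparison,
                          n_splits, window, seed)
  ltd <- function(M) M[lower.tri(M, diag = TRUE)]
  list(r = stats::cor(ltd(m_all$matrix), ltd(m_rel$matrix)),
       matrix_all = m_all$matrix, matrix_relevant = m_rel$matrix)
}
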