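# ---- linear discriminant classifier -------------------------------------
#
# Gaussian LDA with pooled within-class covariance and equal priors. The
# covariance is inverted with a pseudo-inverse so rank-deficient inputs
# (features >> trials, or noiseless constructions) degrade gracefully
# instead of erroring; the upstream PCA step usually keeps it full-rank.

lda_train <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("LDA needs at least two classes")
  mu <- t(matrix(vapply(classes, function(k)
    colMeans(X[y == k, , drop = FALSE]), numeric(ncol(X))),
    nrow = ncol(X)))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(K)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    Xi <- sweep(Xi, 2, mu[i, ])
    Sw <- Sw + crossprod(Xi)
  }
  df <- max(nrow(X) - K, 1)
  W <- pinv(Sw / df)
  # linear discriminant: score_k(x) = x W mu_k' - mu_k W mu_k' / 2
  A <- W %*% t(mu)                        # p x K
  b <- -0.5 * colSums(t(mu) * A)          # K
  list(classes = classes, A = A, b = b)
}

lda_predict <- function(model, X) {
  S <- as.matrix(X) %*% model$A + rep(model$b, each = nrow(X))
  model$classes[max.col(S, ties.method = "first")]
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# ---- window preparation --------------------------------------------------

# average adjacent 100 ms bins into non-overlapping windows
window_rates <- function(rates, window_width_s) {
  per <- as.integer(round(window_width_s / rates$bin_width_s))
  nb <- length(rates$bin_centers_s)
  n_win <- nb %/% per
  dims <- dim(rates$rates)
  W <- array(0, dim = c(dims[1], dims[2], n_win))
  centers <- numeric(n_win)
  for (w in seq_len(n_win)) {
    bins <- ((w - 1) * per + 1):(w * per)
    W[, , w] <- rowMeans(rates$rates[, , bins, drop = FALSE], dims = 2)
    centers[w] <- mean(rates$bin_centers_s[bins])
  }
  list(W = W, centers = centers)
}

# trial labels for a decoding problem
decode_labels <- function(trials, label) {
  if (length(label) == 1 && label %in% names(trials))
    return(as.character(trials[[label]]))
  if (identical(label, "condition12"))
    return(paste(trials$hand, trials$action, trials$direction, sep = "."))
  if (is.character(label) && all(label %in% names(trials)))
    return(do.call(paste, c(unname(as.list(trials[, label])), sep = ".")))
  stop("unknown label definition")
}

# PCA fitted on training data stacked across all windows; returns projector
fit_reduction <- function(Wtrain, var_keep = 0.95, max_pc = 50,
                          fixed_pc = NULL) {
  # Wtrain: units x trials x windows -> (trials*windows) x units
  M <- t(matrix(Wtrain, nrow = dim(Wtrain)[1]))
  center <- colMeans(M)
  M <- sweep(M, 2, center)
  sv <- svd(M, nu = 0)
  ev <- sv$d^2
  rank <- sum(sv$d > 1e-10 * max(sv$d, 0))
  k <- if (!is.null(fixed_pc)) min(fixed_pc, rank, ncol(M))
  else {
    cum <- cumsum(ev) / sum(ev)
    min(which(cum >= var_keep)[1], max_pc, rank)
  }
  k <- max(k, 1)
  list(center = center, rotation = sv$v[, seq_len(k), drop = FALSE], k = k)
}

project_window <- function(red, Wslice) {
  # Wslice: units x trials -> trials x k
  sweep(t(Wslice), 2, red$center) %*% red$rotation
}

# ---- within-format / cross-time engine ----------------------------------

decode_engine <- function(rates, trials, label, blocks = NULL,
                          window_width_s = 0.2, folds = 10,
                          var_keep = 0.95, max_pc = 50, cross_time = FALSE,
                          seed = 1) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (!is.null(blocks)) trials <- trials[trials$block %in% blocks, ]
  y <- decode_labels(trials, label)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes to decode")
  if (min(table(y)) < folds) {
    message("reducing folds from ", folds, " to ", min(table(y)))
    folds <- max(2, min(table(y)))
  }
  wr <- window_rates(subset_rates(rates, trial_ids = trials$trial_id),
                     window_width_s)
  W <- wr$W    # already in `trials` order via subset_rates

  n_win <- dim(W)[3]
  fold <- stratified_folds(y, folds, seed)

  acc <- if (cross_time) array(0, c(n_win, n_win, folds))
         else matrix(0, n_win, folds)
  K <- length(classes)
  conf <- array(0L, c(n_win, K, K),
                dimnames = list(NULL, classes, classes))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    red <- fit_reduction(W[, tr, , drop = FALSE], var_keep, max_pc)
    Ptr <- lapply(seq_len(n_win), function(w)
      project_window(red, W[, tr, w]))
    Pte <- lapply(seq_len(n_win), function(w)
      project_window(red, W[, te, w]))
    for (w in seq_len(n_win)) {
      model <- lda_train(Ptr[[w]], y[tr])
      if (cross_time) {
        for (v in seq_len(n_win)) {
          pred <- lda_predict(model, Pte[[v]])
          acc[w, v, f] <- mean(pred == y[te])
          if (v == w)
            conf[w, , ] <- conf[w, , ] +
              table(factor(y[te], classes), factor(pred, classes))
        }
      } else {
        pred <- lda_predict(model, Pte[[w]])
        acc[w, f] <- mean(pred == y[te])
        conf[w, , ] <- conf[w, , ] +
          table(factor(y[te], classes), factor(pred, classes))
      }
    }
  }
  list(acc = acc, conf = conf, centers = wr$centers, classes = classes,
       folds = folds, y = y, fold = fold)
}

#' Time-resolved within-format decoding
#'
#' Linear discriminant decoding of a task variable from population net
#' firing rates in non-overlapping 200 ms windows (adjacent 100 ms bins
#' averaged), with stratified 10-fold cross-validation. Within each fold,
#' PCA is fitted on the training data stacked across all windows (components
#' capturing 95% of variance, at most 50) and both sets are projected before
#' classification. Chance level is `1 / n_classes`.
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble.
#' @param label a factor column name (`"action"`, `"hand"`, `"direction"`),
#'   several (joint labels), or `"condition12"` for the full design.
#' @param blocks block subset to decode within (e.g. `"intention"`).
#' @param window_width_s decoding window width (0.2 s for spikes, 0.5 s for
#'   high-gamma).
#' @param folds cross-validation folds.
#' @param var_keep,max_pc PCA variance criterion and component cap.
#' @param seed integer seed (fold assignment).
#' @return object of class `decoding_result`: `accuracy` tibble
#'   (window_center_s, accuracy, se), `fold_accuracy` matrix, `peak`
#'   (window index and accuracy), `confusion` (row-normalized, at the peak
#'   window), `chance`.
#' @export
decode_timecourse <- function(rates, trials, label = "action",
                              blocks = NULL, window_width_s = 0.2,
                              folds = 10, var_keep = 0.95, max_pc = 50,
                              seed = 1) {
  eng <- decode_engine(rates, trials, label, blocks, window_width_s,
                       folds, var_keep, max_pc, cross_time = FALSE,
                       seed = seed)
  mean_acc <- rowMeans(eng$acc)
  se <- apply(eng$acc, 1, stats::sd) / sqrt(eng$folds)
  peak <- which.max(mean_acc)
  conf <- eng$conf[peak, , ]
  conf_n <- conf / pmax(rowSums(conf), 1)
  structure(list(
    accuracy = tibble::tibble(window_center_s = eng$centers,
                              accuracy = mean_acc, se = se),
    fold_accuracy = eng$acc,
    peak = list(window = peak, window_center_s = eng$centers[peak],
                accuracy = mean_acc[peak]),
    confusion = conf_n,
    classes = eng$classes,
    chance = 1 / length(eng$classes)),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>", length(x$classes), "classes (chance",
      round(x$chance, 3), "); peak", round(x$peak$accuracy, 3), "at",
      x$peak$window_center_s, "s\n")
  invisible(x)
}

#' Cross-time generalization decoding
#'
#' Trains a classifier at each time window and tests it on every window,
#' yielding a train-by-test accuracy matrix whose diagonal reproduces
#' [decode_timecourse()] exactly (same folds and seed). Sustained
#' off-diagonal accuracy indicates a temporally stable code.
#'
#' @inheritParams decode_timecourse
#' @return object of class `generalization_map`: `accuracy` matrix
#'   (train x test), `train_centers_s`, `test_centers_s`, `chance`; no
#'   significance mask (within-format maps are descriptive).
#' @export
cross_time_decode <- function(rates, trials, label = "action",
                              blocks = NULL, window_width_s = 0.2,
                              folds = 10, var_keep = 0.95, max_pc = 50,
                              seed = 1) {
  eng <- decode_engine(rates, trials, label, blocks, window_width_s,
                       folds, var_keep, max_pc, cross_time = TRUE,
                       seed = seed)
  structure(list(accuracy = apply(eng$acc, c(1, 2), mean),
                 train_centers_s = eng$centers,
                 test_centers_s = eng$centers,
                 chance = 1 / length(eng$classes),
                 sig_mask = NULL, p = NULL,
                 direction = "within-format cross-time"),
            class = "generalization_map")
}

#' @export
print.generalization_map <- function(x, ...) {
  cat("<generalization_map>", x$direction, ":",
      nrow(x$accuracy), "x", ncol(x$accuracy), "windows; max",
      round(max(x$accuracy), 3), "\n")
  invisible(x)
}

#' Cross-format generalization decoding
#'
#' Trains on all trials of one format and tests on the other. PCA is fitted
#' on the full training-format data across all time bins (top `max_pc` = 50
#' components retained); an LDA classifier trained on each training time bin
#' is evaluated on every test time bin. Per-cell significance comes from
#' shuffling test-set labels (`n_perm` iterations, map-wide per iteration)
#' with Bonferroni correction over all train-by-test cells.
#'
#' @inheritParams decode_timecourse
#' @param direction `"int_to_obs"` or `"obs_to_int"`.
#' @param n_perm label permutations.
#' @param bin_width_s decoding resolution (per 100 ms bin, no window
#'   averaging).
#' @param alpha family-wise level.
#' @param correction `"maxstat"` (default; max-statistic permutation
#'   correction, exact family-wise control under the map-wide shuffle
#'   null) or `"bonferroni"` (literal Bonferroni on the proportion
#'   estimator; anticonservative at ~900 cells).
#' @return `generalization_map` with `p` (matrix) and `sig_mask`.
#' @export
cross_format_decode <- function(rates, trials, label = "action",
                                direction = c("int_to_obs", "obs_to_int"),
                                bin_width_s = 0.1, max_pc = 50,
                                n_perm = 1000, alpha = 0.05,
                                correction = c("maxstat", "bonferroni"),
                                seed = 1) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  fmts <- if (direction == "int_to_obs") c("intention", "observation")
          else c("observation", "intention")
  if (!all(fmts %in% trials$block)) stop("both formats must be present")
  tr_t <- trials[trials$block == fmts[1], ]
  te_t <- trials[trials$block == fmts[2], ]
  y_tr <- decode_labels(tr_t, label)
  y_te <- decode_labels(te_t, label)
  wr <- window_rates(rates, bin_width_s)
  Wtr <- wr$W[, match(tr_t$trial_id, rates$trial_ids), , drop = FALSE]
  Wte <- wr$W[, match(te_t$trial_id, rates$trial_ids), , drop = FALSE]
  n_win <- dim(Wtr)[3]

  red <- fit_reduction(Wtr, fixed_pc = max_pc)
  Ptr <- lapply(seq_len(n_win), function(w) project_window(red, Wtr[, , w]))
  Pte <- lapply(seq_len(n_win), function(w) project_window(red, Wte[, , w]))

  nte <- length(y_te)
  pred <- array(NA_character_, c(n_win, n_win, nte))
  for (w in seq_len(n_win)) {
    model <- lda_train(Ptr[[w]], y_tr)
    for (v in seq_len(n_win))
      pred[w, v, ] <- lda_predict(model, Pte[[v]])
  }
  obs_acc <- apply(pred, c(1, 2), function(p) mean(p == y_te))

  # permutations: trained models and predictions are fixed; only test
  # labels are shuffled (map-wide per iteration)
  local_rng(seed)
  Pm <- matrix(pred, n_win * n_win, nte)
  exceed <- matrix(0L, n_win, n_win)
  obs_v <- as.vector(obs_acc)
  max_perm <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    yp <- y_te[sample.int(nte)]
    perm_acc <- rowMeans(Pm == rep(yp, each = n_win * n_win))
    exceed <- exceed + (perm_acc >= obs_v - 1e-12)
    max_perm[j] <- max(perm_acc)
  }
  p <- (1 + exceed) / (n_perm + 1)
  sig <- switch(
    correction,
    # max-statistic correction: exact family-wise control under the
    # map-wide shuffle null
    maxstat = {
      p_fwe <- (1 + vapply(obs_v, function(a)
        sum(max_perm >= a - 1e-12), numeric(1))) / (n_perm + 1)
      matrix(p_fwe < alpha, n_win, n_win)
    },
    # literal Bonferroni on the proportion estimator (anticonservative at
    # this cell count; retained for comparability)
    bonferroni = (exceed / n_perm) < alpha / (n_win * n_win))
  structure(list(accuracy = obs_acc, p = p, sig_mask = sig,
                 train_centers_s = wr$centers, test_centers_s = wr$centers,
                 chance = 1 / length(unique(y_tr)),
                 direction = direction),
            class = "generalization_map")
}

#' Dissociation-task decoding
#'
#' Relabels dissociation-task trials by the requested source and decodes:
#' `"instructed"` — the cued action x hand (4 classes); `"video"` — the
#' observed action x hand derived from the conflict type (4 classes);
#' `"trialtype16"` — all 16 action x hand x conflict types; `"conflict"` —
#' the 4 conflict types.
#'
#' @inheritParams decode_timecourse
#' @param source label source, see above.
#' @param incongruent_only drop fully congruent trials first (visual-motor
#'   congruency control).
#' @return a `decoding_result`.
#' @export
dissociation_decode <- function(rates, trials,
                                source = c("instructed", "video",
                                           "trialtype16", "conflict"),
                                blocks = NULL, incongruent_only = FALSE,
                                window_width_s = 0.2, folds = 10,
                                seed = 1, ...) {
  source <- match.arg(source)
  if (!"conflict" %in% names(trials))
    stop("dissociation decoding needs a dissociation-variant trial table")
  tr <- trials
  if (incongruent_only) tr <- tr[tr$conflict != "congruent", ]
  tr <- add_dissociation_labels(tr)
  label <- switch(source,
                  instructed = c("action", "hand"),
                  video = c("video_action", "video_hand"),
                  trialtype16 = c("action", "hand", "conflict"),
                  conflict = "conflict")
  decode_timecourse(rates, tr, label = label, blocks = blocks,
                    window_width_s = window_width_s, folds = folds,
                    seed = seed, ...)
}

add_dissociation_labels <- function(trials) {
  v <- derive_video_labels(trials)
  trials$video_action <- v$video_action
  trials$video_hand <- v$video_hand
  trials
}

#' Session-wise decoding stability
#'
#' Runs [decode_timecourse()] separately within each session and reports
#' the peak accuracy per session and variable.
#'
#' @inheritParams decode_timecourse
#' @param labels variables to decode.
#' @return tibble (session_id, label, peak_accuracy, peak_window_s).
#' @export
sessionwise_decode <- function(rates, trials,
                               labels = c("action", "hand", "direction"),
                               blocks = "intention", folds = 10, seed = 1,
                               ...) {
  purrr::map_dfr(unique(trials$session_id), function(s) {
    tr <- trials[trials$session_id == s, ]
    purrr::map_dfr(labels, function(lb) {
      d <- decode_timecourse(rates, tr, label = lb, blocks = blocks,
                             folds = folds, seed = seed, ...)
      tibble::tibble(session_id = s, label = lb,
                     peak_accuracy = d$peak$accuracy,
                     peak_window_s = d$peak$window_center_s)
    })
  })
}
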