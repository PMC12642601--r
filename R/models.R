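#' The cross-format linear-model family
#'
#' Returns the ten-model family used to classify units by which combination
#' of task factors — shared across formats or format-specific — best
#' predicts their responses:
#'
#' 1. `null` — constant only (*unselective*).
#' 2. `invariant` — action + hand + direction, identical weights across
#'    formats.
#' 3. `action3`, 4. `hand`, 5. `direction` — shared tuning to one factor.
#' 6. `action6` — "action" redefined as the six action x direction
#'    combinations, shared.
#' 7. `mixed` — all main effects and interactions, shared.
#' 8. `idiosyncratic` — full factorial with separate coefficients per
#'    format.
#' 9. `single_intention`, 10. `single_observation` — factor terms for one
#'    format only (intercepts for both).
#'
#' Every non-null model carries a format intercept so format-wise offsets
#' never masquerade as tuning. Dummy coding, first level as reference.
#'
#' @param trials trial tibble with columns `action`, `hand`, `direction`,
#'   `block` (format).
#' @return named list: each element has `X` (design matrix) and `n_params`.
#' @export
model_design_matrices <- function(trials) {
  tr <- data.frame(action = factor(trials$action),
                   hand = factor(trials$hand),
                   direction = factor(trials$direction),
                   format = factor(trials$block))
  tr$action6 <- factor(paste(tr$action, tr$direction, sep = "."))
  is_int <- as.numeric(tr$format != "observation")
  is_obs <- 1 - is_int
  mm <- function(fml) stats::model.matrix(fml, data = tr)
  main_cols <- mm(~ action + hand + direction)[, -1, drop = FALSE]
  specs <- list(
    null = mm(~ 1),
    invariant = mm(~ format + action + hand + direction),
    action3 = mm(~ format + action),
    hand = mm(~ format + hand),
    direction = mm(~ format + direction),
    action6 = mm(~ format + action6),
    mixed = mm(~ format + action * hand * direction),
    idiosyncratic = mm(~ format + format:(action * hand * direction)),
    single_intention = cbind(mm(~ format), is_int * main_cols),
    single_observation = cbind(mm(~ format), is_obs * main_cols))
  purrr::map(specs, function(X) {
    qrX <- qr(X)
    list(X = X, n_params = qrX$rank)
  })
}

#' Condition-mean responses in the model window
#'
#' Mean net firing rate over the analysis window (default 1-2 s after trial
#' onset) for each of the 12 conditions in each format: 24 values per unit.
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble.
#' @param window analysis window, default `c(1, 2)`.
#' @return tibble (unit_id, action, hand, direction, format, mean_rate),
#'   24 rows per unit, ordered by declared condition order then format.
#' @export
condition_means <- function(rates, trials, window = c(1, 2)) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  wm <- window_mean_rates(rates, window)   # unit x trial
  cells <- trials |>
    dplyr::distinct(.data$action, .data$hand, .data$direction, .data$block)
  grid <- tidyr::expand_grid(
    format = unique(trials$block),
    action = unique(trials$action),
    hand = unique(trials$hand),
    direction = unique(trials$direction))
  missing <- dplyr::anti_join(
    grid, dplyr::rename(cells, format = "block"),
    by = c("format", "action", "hand", "direction"))
  if (nrow(missing))
    stop("missing condition cell(s): ",
         paste(utils::head(do.call(paste, c(missing, sep = "/")), 3),
               collapse = ", "))
  lab <- paste(trials$action, trials$hand, trials$direction, trials$block,
               sep = ".")
  g <- factor(lab)
  means <- t(rowsum(t(wm[, match(trials$trial_id, rates$trial_ids),
                         drop = FALSE]),
                    g) / as.vector(table(g)))
  key <- do.call(rbind, strsplit(levels(g), ".", fixed = TRUE))
  out <- tibble::tibble(
    unit_id = rep(rates$unit_ids, times = nlevels(g)),
    action = rep(key[, 1], each = length(rates$unit_ids)),
    hand = rep(key[, 2], each = length(rates$unit_ids)),
    direction = rep(key[, 3], each = length(rates$unit_ids)),
    format = rep(key[, 4], each = length(rates$unit_ids)),
    mean_rate = as.vector(means))
  dplyr::arrange(out, .data$unit_id, .data$format, .data$action,
                 .data$hand, .data$direction)
}

# stratified fold assignment over condition x format cells; remainder
# trials are spread over a random fold rotation so fold sizes stay
# balanced across cells
stratified_folds <- function(cell_labels, folds, seed) {
  local_rng(seed)
  fold <- integer(length(cell_labels))
  for (cl in unique(cell_labels)) {
    idx <- which(cell_labels == cl)
    idx <- idx[sample.int(length(idx))]
    rot <- sample.int(folds)
    fold[idx] <- rot[(seq_along(idx) - 1L) %% folds + 1L]
  }
  fold
}

#' Fit the model family with stratified cross-validation
#'
#' Per unit and model: five-fold cross-validation stratified over the 24
#' condition-by-format cells; ordinary least squares on training trials'
#' window-mean responses; held-out R^2 pooled over folds,
#' `1 - SS_res / SS_tot`, with `SS_tot` taken about the training-fold mean.
#' Negative pooled R^2 is reported as-is.
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble (both formats present).
#' @param window model window, default `c(1, 2)` s.
#' @param folds number of folds (reduced with a message if a cell has fewer
#'   trials).
#' @param seed integer seed for the fold assignment.
#' @param fold optional explicit fold assignment (integer vector, one entry
#'   per included trial in `trials` order), e.g. `seq_len(n)` for
#'   leave-one-out; overrides `folds`/`seed`.
#' @return object of class `model_cv_fit`: list with `scores` (tibble
#'   unit_id, model, cv_r2, n_params), plus the internals needed by
#'   [permutation_gate()] (`fold`, `y` matrix, `models`).
#' @export
fit_models_cv <- function(rates, trials, window = c(1, 2), folds = 5,
                          seed = 1, fold = NULL) {
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  wm <- window_mean_rates(rates, window)
  Y <- t(wm[, match(trials$trial_id, rates$trial_ids), drop = FALSE])
  colnames(Y) <- rates$unit_ids
  if (is.null(fold)) {
    cell <- paste(trials$action, trials$hand, trials$direction,
                  trials$block)
    min_cell <- min(table(cell))
    if (min_cell < folds) {
      message("reducing folds from ", folds, " to ", min_cell,
              " (smallest condition cell)")
      folds <- max(2, min_cell)
    }
    fold <- stratified_folds(cell, folds, seed)
  } else {
    stopifnot(length(fold) == nrow(trials))
    folds <- length(unique(fold))
  }
  models <- model_design_matrices(trials)

  ss_res <- matrix(0, length(models), ncol(Y),
                   dimnames = list(names(models), colnames(Y)))
  ss_tot <- matrix(0, length(models), ncol(Y),
                   dimnames = list(names(models), colnames(Y)))
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- fold == k
    ytr_mean <- colMeans(Y[tr, , drop = FALSE])
    for (mi in seq_along(models)) {
      X <- models[[mi]]$X
      qtr <- qr(X[tr, , drop = FALSE])
      coef <- qr.coef(qtr, Y[tr, , drop = FALSE])
      coef[is.na(coef)] <- 0
      pred <- X[te, , drop = FALSE] %*% coef
      ss_res[mi, ] <- ss_res[mi, ] +
        colSums((Y[te, , drop = FALSE] - pred)^2)
      ss_tot[mi, ] <- ss_tot[mi, ] +
        colSums(sweep(Y[te, , drop = FALSE], 2, ytr_mean)^2)
    }
  }
  r2 <- 1 - ss_res / ss_tot
  scores <- tibble::tibble(
    unit_id = rep(colnames(Y), each = length(models)),
    model = rep(names(models), times = ncol(Y)),
    cv_r2 = as.vector(r2),
    n_params = rep(purrr::map_int(models, "n_params"), times = ncol(Y)))
  structure(list(scores = scores, fold = fold, y = Y, models = models,
                 trials = trials, folds = folds, window = window),
            class = "model_cv_fit")
}

# pooled cv R^2 for one model and a matrix of response columns
cv_r2_matrix <- function(X, Ymat, fold, folds) {
  ss_res <- numeric(ncol(Ymat)); ss_tot <- numeric(ncol(Ymat))
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- fold == k
    qtr <- qr(X[tr, , drop = FALSE])
    coef <- qr.coef(qtr, Ymat[tr, , drop = FALSE])
    coef[is.na(coef)] <- 0
    pred <- X[te, , drop = FALSE] %*% coef
    ss_res <- ss_res + colSums((Ymat[te, , drop = FALSE] - pred)^2)
    mu <- colMeans(Ymat[tr, , drop = FALSE])
    ss_tot <- ss_tot + colSums(sweep(Ymat[te, , drop = FALSE], 2, mu)^2)
  }
  1 - ss_res / ss_tot
}

#' Permutation gate for the winning model
#'
#' Shuffles each unit's responses across trials (design matrix fixed) and
#' recomputes the winning model's pooled cross-validated R^2, yielding a
#' one-tailed p-value `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param fit a [fit_models_cv()] result.
#' @param best tibble (unit_id, model) of winning models; default the
#'   highest `cv_r2` per unit with ties broken toward fewer parameters.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return tibble (unit_id, best_model, cv_r2, perm_p).
#' @export
permutation_gate <- function(fit, best = NULL, n_perm = 1000, seed = 1) {
  stopifnot(inherits(fit, "model_cv_fit"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(best)) best <- best_models(fit)
  local_rng(seed)
  nt <- nrow(fit$y)
  perm_idx <- replicate(n_perm, sample.int(nt))
  out <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
    uid <- best$unit_id[i]
    y <- fit$y[, uid]
    Yp <- matrix(y[perm_idx], nt, n_perm)
    X <- fit$models[[best$best_model[i]]]$X
    null_r2 <- cv_r2_matrix(X, Yp, fit$fold, fit$folds)
    obs <- best$cv_r2[i]
    tibble::tibble(unit_id = uid, best_model = best$best_model[i],
                   cv_r2 = obs,
                   perm_p = (1 + sum(null_r2 >= obs)) / (n_perm + 1))
  })
  out
}

# winner per unit; ties toward fewer parameters
best_models <- function(fit) {
  fit$scores |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::arrange(dplyr::desc(.data$cv_r2), .data$n_params,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", best_model = "model", "cv_r2")
}

#' Classify a population of units
#'
#' Applies the three-gate rule: a unit keeps its winning-model label iff
#' (1) cross-validated R^2 > `r2_min`, (2) the permutation p-value survives
#' Benjamini-Hochberg FDR at `q` across units, and (3) the winner is not the
#' null model. Units failing any gate are labelled `unselective`.
#'
#' @param fit a [fit_models_cv()] result.
#' @param n_perm permutations for the gate.
#' @param q FDR level.
#' @param r2_min minimum cross-validated R^2.
#' @param seed integer seed.
#' @return tibble of class `unit_classification`: (unit_id, best_model,
#'   cv_r2, perm_p, fdr_significant, label).
#' @export
classify_population <- function(fit, n_perm = 1000, q = 0.05,
                                r2_min = 0.01, seed = 1) {
  gates <- permutation_gate(fit, n_perm = n_perm, seed = seed)
  gates$fdr_significant <- stats::p.adjust(gates$perm_p, "BH") < q
  keep <- !is.na(gates$cv_r2) & gates$cv_r2 > r2_min &
    gates$fdr_significant & gates$best_model != "null"
  gates$label <- ifelse(keep, gates$best_model, "unselective")
  class(gates) <- c("unit_classification", class(gates))
  gates
}

#' Task-relevant unit subset
#'
#' Units that are neither unselective nor best fit by a single-format model
#' — the subset entering RSA and geometry analyses.
#'
#' @param classification a [classify_population()] result.
#' @return character vector of unit ids.
#' @export
task_relevant_units <- function(classification) {
  drop <- c("unselective", "single_intention", "single_observation")
  classification$unit_id[!classification$label %in% drop]
}
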