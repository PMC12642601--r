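#' Baseline-comparison responsiveness and latency
#'
#' For every unit, condition and block (format), net firing rates are
#' averaged in overlapping 200 ms windows (100 ms step, starting at stimulus
#' onset) and compared to zero across trials with a t-test — because rates
#' are baseline-subtracted per trial, this is exactly the paired t-test of
#' window activity against the per-trial baseline mean. Significance uses a
#' Bonferroni-corrected threshold (alpha / number of windows); a unit is
#' responsive to a condition iff it shows at least three consecutive
#' significant windows, and its latency is the centre of the first window of
#' the earliest such run.
#'
#' @param rates a [bin_rates()] result (100 ms bins over `[0, 3)`).
#' @param trials trial tibble.
#' @param grouping character vector of factor columns defining a condition;
#'   default all design factors present in `trials`.
#' @param blocks blocks (formats) to analyse; default all in `trials`.
#' @param alpha nominal level before Bonferroni correction.
#' @param alternative `"two.sided"` (default, conservative) or `"greater"`
#'   (responsive strictly above baseline).
#' @return tibble of class `responsiveness_result`: one row per
#'   (unit, condition, block) with `responsive`, `latency_s` (`NA` unless
#'   responsive), `n_trials`, `min_p`, and a list-column `p_values` (one p
#'   per window). Window centres are stored in `attr(, "window_centers_s")`.
#' @export
test_responsiveness <- function(rates, trials, grouping = NULL,
                                blocks = NULL, alpha = 0.05,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(rates, "binned_rates"))
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (is.null(grouping))
    grouping <- intersect(c("hand", "action", "direction", "conflict"),
                          names(trials))
  if (is.null(blocks)) blocks <- unique(trials$block)

  bc <- rates$bin_centers_s
  post <- which(bc > 0)               # bins in [0, 3)
  nb <- length(post)
  n_win <- nb - 1                     # 200 ms windows, 100 ms step
  win_centers <- (bc[post][seq_len(n_win)] - rates$bin_width_s / 2) + 0.1

  cond_lab <- do.call(paste, c(unname(as.list(
    trials[, grouping, drop = FALSE])), sep = "."))
  out <- list()
  for (blk in blocks) {
    for (cl in sort(unique(cond_lab))) {
      tid <- trials$trial_id[trials$block == blk & cond_lab == cl]
      if (length(tid) < 2) {
        warning("condition ", cl, " in block ", blk,
                " has <2 trials; skipped")
        next
      }
      ti <- match(tid, rates$trial_ids)
      B <- rates$rates[, ti, post, drop = FALSE]
      # window means: adjacent-bin averages
      W <- (B[, , seq_len(n_win), drop = FALSE] +
            B[, , seq_len(n_win) + 1, drop = FALSE]) / 2
      n <- length(ti)
      Wp <- aperm(W, c(2, 1, 3))           # trial x unit x window
      m <- colMeans(Wp)
      m2 <- colMeans(Wp^2)
      s <- sqrt(pmax(m2 - m^2, 0) * n / (n - 1))
      tstat <- m / (s / sqrt(n))
      tstat[s == 0 & m == 0] <- 0
      tstat[s == 0 & m != 0] <- Inf * sign(m[s == 0 & m != 0])
      p <- if (alternative == "two.sided")
        2 * stats::pt(-abs(tstat), df = n - 1)
      else stats::pt(tstat, df = n - 1, lower.tail = FALSE)
      sig <- p < alpha / n_win
      run_start <- vapply(seq_len(nrow(sig)),
                          function(i) first_run3(sig[i, ]), integer(1))
      out[[length(out) + 1]] <- tibble::tibble(
        unit_id = rates$unit_ids,
        region = rates$units$region,
        block = blk, condition = cl,
        responsive = run_start > 0,
        latency_s = ifelse(run_start > 0,
                           win_centers[pmax(run_start, 1)], NA_real_),
        n_trials = n,
        min_p = apply(p, 1, min),
        p_values = lapply(seq_len(nrow(p)), function(i) p[i, ]))
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "window_centers_s") <- win_centers
  attr(res, "alpha") <- alpha
  class(res) <- c("responsiveness_result", class(res))
  res
}

# index of first window of the earliest run of >=3 consecutive TRUE, else 0
first_run3 <- function(sig) {
  r <- rle(as.logical(sig))
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= 3)
  if (!length(hit)) return(0L)
  as.integer(ends[hit[1]] - r$lengths[hit[1]] + 1L)
}

#' Format overlap of responsive units
#'
#' Counts, per region, units responsive (to at least one condition)
#' exclusively during intention, exclusively during observation, or during
#' both formats. The three counts partition the responsive-to-any set.
#'
#' @param res a [test_responsiveness()] result covering both formats.
#' @return tibble with columns `region`, `intention_only`,
#'   `observation_only`, `both`.
#' @export
format_overlap <- function(res) {
  stopifnot(all(c("intention", "observation") %in% unique(res$block)))
  per_unit <- res |>
    dplyr::group_by(.data$unit_id, .data$region, .data$block) |>
    dplyr::summarise(any_resp = any(.data$responsive), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "block", values_from = "any_resp")
  per_unit |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      intention_only = sum(.data$intention & !.data$observation),
      observation_only = sum(!.data$intention & .data$observation),
      both = sum(.data$intention & .data$observation),
      .groups = "drop")
}

#' Compare latency distributions across regions
#'
#' Each responsive (unit, condition) contributes one latency; regional
#' differences are tested with a standard one-way ANOVA, separately per
#' format.
#'
#' @param res a [test_responsiveness()] result.
#' @param block which format to analyse.
#' @return list with `f`, `p`, `df`, and `medians` (tibble of per-region
#'   median latencies and counts).
#' @export
compare_latencies <- function(res, block = "intention") {
  lat <- res[res$block == block & res$responsive, c("region", "latency_s")]
  counts <- table(lat$region)
  empty <- names(counts)[counts < 2]
  if (length(empty)) {
    warning("region(s) with <2 latencies excluded: ",
            paste(empty, collapse = ", "))
    lat <- lat[!lat$region %in% empty, ]
  }
  if (length(unique(lat$region)) < 2)
    stop("need >=2 regions with >=2 latencies each")
  fit <- stats::aov(latency_s ~ region, data = lat)
  an <- summary(fit)[[1]]
  meds <- lat |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(median_latency_s = stats::median(.data$latency_s),
                     n = dplyr::n(), .groups = "drop")
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = unname(an[["Df"]][1:2]), medians = meds)
}
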