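#' Spike-session container
#'
#' Holds per-unit spike times for every trial, plus unit metadata. Spike
#' times are in seconds relative to trial onset and must lie inside the
#' design's trial window. The sorting quality factor (1 = best isolated,
#' 4 = multi-unit) is carried as metadata only and never enters computation.
#'
#' @param units tibble with columns `unit_id`, `region` (e.g. MC, MCM, MCL,
#'   SPL) and `quality_factor` (integer 1..4).
#' @param spikes tibble with columns `unit_id`, `trial_id`, `time_s` (one row
#'   per spike). Units or trials with no spikes simply have no rows.
#' @param trial_ids integer vector of all trial ids covered by the session.
#' @param window two-element trial window in seconds.
#' @return object of class `spike_session`.
#' @export
spike_session <- function(units, spikes, trial_ids,
                          window = c(-0.5, 3.0)) {
  units <- tibble::as_tibble(units)
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("unit_id", "region", "quality_factor") %in% names(units)),
            all(c("unit_id", "trial_id", "time_s") %in% names(spikes)))
  if (nrow(spikes)) {
    if (any(spikes$time_s < window[1] | spikes$time_s >= window[2]))
      stop("spike times outside the trial window [", window[1], ", ",
           window[2], ")")
    if (!all(spikes$unit_id %in% units$unit_id))
      stop("spikes reference unknown unit ids")
  }
  structure(list(units = units, spikes = spikes,
                 trial_ids = as.integer(trial_ids), window = window),
            class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat("<spike_session>", nrow(x$units), "units,", length(x$trial_ids),
      "trials,", nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' LFP-session container
#'
#' @param channels tibble with columns `channel_id`, `region`.
#' @param data numeric array `channel x trial x sample`.
#' @param fs sampling rate in Hz (canonical 1000).
#' @param time_s sample time axis (seconds relative to trial onset); length
#'   must equal `dim(data)[3]`.
#' @param trial_ids integer vector, length `dim(data)[2]`.
#' @return object of class `lfp_session`.
#' @export
lfp_session <- function(channels, data, fs, time_s, trial_ids) {
  channels <- tibble::as_tibble(channels)
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == nrow(channels),
            dim(data)[2] == length(trial_ids),
            dim(data)[3] == length(time_s))
  if (!isTRUE(all.equal(diff(time_s), rep(1 / fs, length(time_s) - 1),
                        tolerance = 1e-6)))
    stop("time axis inconsistent with sampling rate")
  structure(list(channels = channels, data = data, fs = fs,
                 time_s = time_s, trial_ids = as.integer(trial_ids)),
            class = "lfp_session")
}

#' @export
print.lfp_session <- function(x, ...) {
  cat("<lfp_session>", nrow(x$channels), "channels,",
      length(x$trial_ids), "trials @", x$fs, "Hz\n")
  invisible(x)
}

#' Bin spikes into baseline-subtracted net firing rates
#'
#' Converts spike times into the pipeline's common currency: a
#' `units x trials x bins` array of net firing rates in spikes/s. For each
#' trial the mean baseline rate (spike count in the baseline window divided
#' by its width) is subtracted from every post-stimulus bin rate, so a unit
#' with identical baseline and response activity has expected net rate 0.
#'
#' @param spikes a [spike_session()].
#' @param trials trial tibble; only rows with `included == TRUE` are binned.
#' @param bin_width_s bin width, default 0.1 s.
#' @param window two-element analysis window tiled by the bins; must be a
#'   whole number of bins. Default `c(0, 3)` (30 bins). Pass `c(-0.5, 3)` to
#'   retain pre-stimulus bins (needed for trajectory analysis).
#' @param baseline_window_s baseline window, default `c(-0.5, 0)`.
#' @return object of class `binned_rates`: list with `rates` (array
#'   `unit x trial x bin`), `bin_centers_s`, `bin_width_s`,
#'   `baseline_window_s`, `unit_ids`, `trial_ids`, `units` (metadata tibble).
#' @export
bin_rates <- function(spikes, trials, bin_width_s = 0.1,
                      window = c(0, 3), baseline_window_s = c(-0.5, 0)) {
  stopifnot(inherits(spikes, "spike_session"))
  if (window[1] < spikes$window[1] || window[2] > spikes$window[2])
    stop("analysis window outside the recorded trial window")
  n_bins <- (window[2] - window[1]) / bin_width_s
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("window is not a whole number of bins")
  n_bins <- as.integer(round(n_bins))
  trials <- trials[trials$included, , drop = FALSE]
  trial_ids <- trials$trial_id
  unit_ids <- spikes$units$unit_id
  nu <- length(unit_ids); nt <- length(trial_ids)

  sp <- spikes$spikes[spikes$spikes$trial_id %in% trial_ids, , drop = FALSE]
  ui <- match(sp$unit_id, unit_ids)
  ti <- match(sp$trial_id, trial_ids)

  # post-stimulus counts
  bi <- floor((sp$time_s - window[1]) / bin_width_s) + 1
  in_win <- bi >= 1 & bi <= n_bins
  counts <- array(0L, dim = c(nu, nt, n_bins))
  if (any(in_win)) {
    idx <- ui[in_win] + nu * (ti[in_win] - 1) + nu * nt * (bi[in_win] - 1)
    tab <- tabulate(idx, nbins = nu * nt * n_bins)
    counts <- array(tab, dim = c(nu, nt, n_bins))
  }

  # baseline counts per (unit, trial)
  base_w <- baseline_window_s[2] - baseline_window_s[1]
  in_base <- sp$time_s >= baseline_window_s[1] &
             sp$time_s < baseline_window_s[2]
  base <- matrix(0L, nu, nt)
  if (any(in_base)) {
    bidx <- ui[in_base] + nu * (ti[in_base] - 1)
    base <- matrix(tabulate(bidx, nbins = nu * nt), nu, nt)
  }

  rates <- counts / bin_width_s
  rates <- rates - as.vector(base / base_w)   # recycles over bins
  dimnames(rates) <- list(unit_ids, trial_ids, NULL)
  structure(list(rates = rates,
                 bin_centers_s = window[1] + (seq_len(n_bins) - 0.5) *
                   bin_width_s,
                 bin_width_s = bin_width_s,
                 baseline_window_s = baseline_window_s,
                 unit_ids = unit_ids, trial_ids = trial_ids,
                 units = spikes$units),
            class = "binned_rates")
}

#' @export
print.binned_rates <- function(x, ...) {
  cat("<binned_rates>", length(x$unit_ids), "units x",
      length(x$trial_ids), "trials x", length(x$bin_centers_s),
      "bins of", x$bin_width_s, "s\n")
  invisible(x)
}

# mean rate over bins whose window [1,2) etc.; returns unit x trial matrix
window_mean_rates <- function(rates, window) {
  bw <- rates$bin_width_s / 2
  keep <- rates$bin_centers_s - bw >= window[1] - 1e-9 &
          rates$bin_centers_s + bw <= window[2] + 1e-9
  if (!any(keep)) stop("no bins inside window [", window[1], ", ",
                       window[2], ")")
  apply(rates$rates[, , keep, drop = FALSE], c(1, 2), mean)
}

# subset a binned_rates object by unit ids and/or trial ids
subset_rates <- function(rates, unit_ids = NULL, trial_ids = NULL) {
  ui <- if (is.null(unit_ids)) seq_along(rates$unit_ids)
        else match(unit_ids, rates$unit_ids)
  ti <- if (is.null(trial_ids)) seq_along(rates$trial_ids)
        else match(trial_ids, rates$trial_ids)
  if (anyNA(ui)) stop("unknown unit id(s)")
  if (anyNA(ti)) stop("unknown trial id(s)")
  out <- rates
  out$rates <- rates$rates[ui, ti, , drop = FALSE]
  out$unit_ids <- rates$unit_ids[ui]
  out$trial_ids <- rates$trial_ids[ti]
  out$units <- rates$units[ui, , drop = FALSE]
  out
}
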