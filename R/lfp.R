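# ---- FFT helpers ---------------------------------------------------------
# All filtering is frequency-domain with real symmetric responses, hence
# exactly zero-phase; no signal-processing package is available in the
# stack, and the Gaussian band shapes below are themselves the specified
# filter design.

apply_fft_filter <- function(x, H) {
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / length(x)
}

# order-4 Butterworth-magnitude high-pass at fc (zero phase)
highpass_response <- function(n, fs, fc, order = 4) {
  f <- abs(fft_freqs(n, fs))
  h <- ifelse(f == 0, 0, 1 / sqrt(1 + (fc / pmax(f, 1e-12))^(2 * order)))
  h
}

# spectrum-interpolation notch at f0 and harmonics: magnitudes inside
# f0 +/- half_bw are replaced by the linear interpolation of the edge
# magnitudes; phases kept
notch_interpolate <- function(x, fs, f0 = 60, half_bw = 2,
                              n_harmonics = 2) {
  n <- length(x)
  X <- stats::fft(x)
  f <- fft_freqs(n, fs)
  for (h in seq_len(n_harmonics)) {
    fh <- f0 * h
    if (fh >= fs / 2) break
    band <- which(abs(abs(f) - fh) <= half_bw)
    if (!length(band)) next
    for (sgn in c(-1, 1)) {
      idx <- band[sign(f[band]) == sgn | (sgn == 1 & f[band] == 0)]
      if (length(idx) < 2) next
      idx <- idx[order(abs(f[idx]))]
      m <- Mod(X[idx])
      m_interp <- seq(m[1], m[length(m)], length.out = length(m))
      # replace interior magnitudes, preserve phase
      scl <- ifelse(m > 0, m_interp / m, 0)
      X[idx] <- X[idx] * scl
    }
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Preprocess LFP: line-noise suppression, high-pass, artifact flags
#'
#' Suppresses 60 Hz line noise (spectrum interpolation at 60 Hz and
#' harmonics), applies a zero-phase 2 Hz high-pass, and flags trials whose
#' broadband amplitude (per-trial RMS of the high-passed trace, averaged
#' over channels) exceeds two standard deviations above the session mean.
#'
#' @param lfp an [lfp_session()].
#' @param hp_hz high-pass corner frequency.
#' @param line_hz line frequency (`NULL` disables the notch).
#' @param artifact_sd exclusion threshold in SDs of the session RMS.
#' @return list with `lfp` (filtered session) and `excluded` tibble
#'   (trial_id, rms, excluded).
#' @export
preprocess_lfp <- function(lfp, hp_hz = 2, line_hz = 60,
                           artifact_sd = 2) {
  stopifnot(inherits(lfp, "lfp_session"))
  n <- dim(lfp$data)[3]
  if (n < 32) stop("trial too short for filtering (", n, " samples)")
  H <- highpass_response(n, lfp$fs, hp_hz)
  out <- lfp
  for (ci in seq_len(dim(lfp$data)[1])) {
    for (ti in seq_len(dim(lfp$data)[2])) {
      x <- lfp$data[ci, ti, ]
      if (!is.null(line_hz)) x <- notch_interpolate(x, lfp$fs, line_hz)
      out$data[ci, ti, ] <- apply_fft_filter(x, H)
    }
  }
  # per-trial broadband RMS, pooled over channels and samples
  rms_trial <- sqrt(apply(out$data^2, 2, mean))
  thr <- mean(rms_trial) + artifact_sd * stats::sd(rms_trial)
  list(lfp = out,
       excluded = tibble::tibble(trial_id = lfp$trial_ids,
                                 rms = rms_trial,
                                 excluded = rms_trial > thr))
}

#' Morlet time-frequency power, baseline-normalized
#'
#' Complex Morlet wavelet convolution (7-cycle resolution) on a 60-120 Hz
#' grid; the first and last 100 ms of each trial are discarded to limit
#' edge artifacts, power is normalized per frequency by the mean power in
#' the 500 ms pre-stimulus baseline, and the time axis is decimated to
#' 100 Hz for storage.
#'
#' @param lfp a preprocessed [lfp_session()].
#' @param freqs frequency grid in Hz.
#' @param n_cycles wavelet resolution.
#' @param baseline_window_s baseline epoch.
#' @param decimate_to output sampling rate for the power time axis.
#' @return object of class `tf_power`: `power` array
#'   (channel x trial x freq x time), `freqs`, `time_s`, `channels`.
#' @export
morlet_power <- function(lfp, freqs = seq(60, 120, by = 2), n_cycles = 7,
                         baseline_window_s = c(-0.5, 0),
                         decimate_to = 100) {
  stopifnot(inherits(lfp, "lfp_session"))
  n <- dim(lfp$data)[3]
  f_axis <- fft_freqs(n, lfp$fs)
  trim <- lfp$time_s >= min(lfp$time_s) + 0.1 &
          lfp$time_s <= max(lfp$time_s) - 0.1
  dec <- as.integer(round(lfp$fs / decimate_to))
  keep_idx <- which(trim)[seq(1, sum(trim), by = dec)]
  time_out <- lfp$time_s[keep_idx]
  if (!any(time_out >= baseline_window_s[1] &
           time_out < baseline_window_s[2]))
    stop("baseline window missing from the trimmed trial")
  nc <- dim(lfp$data)[1]; nt <- dim(lfp$data)[2]
  P <- array(0, c(nc, nt, length(freqs), length(keep_idx)))
  # analytic Morlet kernels in the frequency domain
  kernels <- lapply(freqs, function(f0) {
    sf <- f0 / n_cycles
    2 * exp(-(f_axis - f0)^2 / (2 * sf^2)) * (f_axis > 0)
  })
  for (ci in seq_len(nc)) for (ti in seq_len(nt)) {
    X <- stats::fft(lfp$data[ci, ti, ])
    for (fi in seq_along(freqs)) {
      w <- stats::fft(X * kernels[[fi]], inverse = TRUE) / n
      P[ci, ti, fi, ] <- Mod(w[keep_idx])^2
    }
  }
  base <- time_out >= baseline_window_s[1] & time_out < baseline_window_s[2]
  for (ci in seq_len(nc)) for (fi in seq_along(freqs)) {
    b <- mean(P[ci, , fi, base])
    P[ci, , fi, ] <- P[ci, , fi, ] / b
  }
  structure(list(power = P, freqs = freqs, time_s = time_out,
                 channels = lfp$channels, trial_ids = lfp$trial_ids),
            class = "tf_power")
}

#' High-gamma filter bank
#'
#' Eight Gaussian (frequency-domain) band-pass filters with centre
#' frequencies log-spaced from 73 to 144 Hz, `f_i = 73 * (144/73)^(i/7)`,
#' and bandwidth scaled at 20% of the centre frequency
#' (full width at half maximum).
#'
#' @param n signal length in samples.
#' @param fs sampling rate.
#' @return list with `centers_hz` and `responses` (list of analytic
#'   one-sided frequency responses).
#' @export
hg_filter_bank <- function(n, fs) {
  centers <- 73 * (144 / 73)^((0:7) / 7)
  f_axis <- fft_freqs(n, fs)
  responses <- lapply(centers, function(f0) {
    fwhm <- 0.2 * f0
    sf <- fwhm / (2 * sqrt(2 * log(2)))
    2 * exp(-(f_axis - f0)^2 / (2 * sf^2)) * (f_axis > 0)
  })
  list(centers_hz = centers, responses = responses)
}

#' Unified high-gamma envelope
#'
#' Bouchard-style extraction: common-average reference per region, eight
#' Gaussian band-pass filters (see [hg_filter_bank()]), analytic amplitude
#' per band, anti-alias low-pass and resampling to 100 Hz, per-channel
#' z-scoring across all time points and trials, hyperbolic-tangent outlier
#' compression, and per-channel SVD across the eight bands with the first
#' left singular vector (sign-fixed to positive mean band loading) as the
#' unified envelope.
#'
#' @param lfp a preprocessed [lfp_session()].
#' @param car apply common-average referencing across channels of the same
#'   region (skipped with a warning when a region has < 2 channels).
#' @param env_fs output envelope rate, Hz.
#' @param tanh_scale compression scale in SD units.
#' @return object of class `hg_envelope`: `env` array
#'   (channel x trial x time), `time_s`, `fs`, `channels`, `band_loadings`.
#' @export
hg_unified_envelope <- function(lfp, car = TRUE, env_fs = 100,
                                tanh_scale = 4) {
  stopifnot(inherits(lfp, "lfp_session"))
  dat <- lfp$data
  nc <- dim(dat)[1]; nt <- dim(dat)[2]; n <- dim(dat)[3]
  if (car) {
    for (rg in unique(lfp$channels$region)) {
      idx <- which(lfp$channels$region == rg)
      if (length(idx) < 2) {
        warning("region ", rg, " has <2 channels; CAR skipped")
        next
      }
      avg <- colMeans(dat[idx, , , drop = FALSE], dims = 1)
      for (ci in idx) dat[ci, , ] <- dat[ci, , ] - avg
    }
  }
  bank <- hg_filter_bank(n, lfp$fs)
  dec <- as.integer(round(lfp$fs / env_fs))
  keep <- seq(1, n, by = dec)
  lp <- {   # anti-alias low-pass below env_fs/2 for the envelope
    f_axis <- fft_freqs(n, lfp$fs)
    as.numeric(abs(f_axis) <= env_fs / 2)
  }
  n_keep <- length(keep)
  env <- array(0, c(nc, nt, n_keep))
  loadings <- matrix(0, nc, 8)
  for (ci in seq_len(nc)) {
    bands <- matrix(0, nt * n_keep, 8)
    for (bi in 1:8) {
      for (ti in seq_len(nt)) {
        analytic <- stats::fft(stats::fft(dat[ci, ti, ]) *
                               bank$responses[[bi]], inverse = TRUE) / n
        amp <- Mod(analytic)
        amp <- apply_fft_filter(amp, lp)
        bands[((ti - 1) * n_keep + 1):(ti * n_keep), bi] <- amp[keep]
      }
    }
    # z-score per band across all timepoints and trials, then compress
    mu <- colMeans(bands)
    sdv <- apply(bands, 2, stats::sd)
    for (bi in 1:8) {
      if (sdv[bi] == 0) {
        warning("degenerate (constant) band envelope; set to zero")
        bands[, bi] <- 0
      } else {
        z <- (bands[, bi] - mu[bi]) / sdv[bi]
        bands[, bi] <- tanh(z / tanh_scale) * tanh_scale
      }
    }
    sv <- svd(bands, nu = 1, nv = 1)
    sgn <- if (mean(sv$v[, 1]) < 0) -1 else 1
    u <- sgn * sv$u[, 1] * sv$d[1]
    loadings[ci, ] <- sgn * sv$v[, 1]
    env[ci, , ] <- matrix(u, nt, n_keep, byrow = TRUE)
  }
  structure(list(env = env, time_s = lfp$time_s[keep], fs = env_fs,
                 channels = lfp$channels, trial_ids = lfp$trial_ids,
                 band_loadings = loadings),
            class = "hg_envelope")
}

#' Convert a high-gamma envelope to the binned-rates container
#'
#' Bins the unified envelope into 100 ms bins and subtracts the per-trial
#' baseline mean, yielding a `binned_rates` object with channels in the
#' unit slots, so the responsiveness, tuning and decoding engines apply
#' unchanged at the channel level.
#'
#' @param env an [hg_unified_envelope()] result.
#' @param bin_width_s bin width.
#' @param window post-stimulus window tiled by bins.
#' @param baseline_window_s baseline epoch.
#' @return a `binned_rates` object (channel-level).
#' @export
hg_to_rates <- function(env, bin_width_s = 0.1, window = c(0, 3),
                        baseline_window_s = c(-0.5, 0)) {
  stopifnot(inherits(env, "hg_envelope"))
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width_s))
  nc <- dim(env$env)[1]; nt <- dim(env$env)[2]
  vals <- array(0, c(nc, nt, n_bins))
  for (b in seq_len(n_bins)) {
    lo <- window[1] + (b - 1) * bin_width_s
    hi <- lo + bin_width_s
    idx <- env$time_s >= lo - 1e-9 & env$time_s < hi - 1e-9
    vals[, , b] <- rowMeans(env$env[, , idx, drop = FALSE], dims = 2)
  }
  bidx <- env$time_s >= baseline_window_s[1] &
          env$time_s < baseline_window_s[2]
  base <- rowMeans(env$env[, , bidx, drop = FALSE], dims = 2)
  vals <- vals - as.vector(base)
  dimnames(vals) <- list(env$channels$channel_id, env$trial_ids, NULL)
  structure(list(rates = vals,
                 bin_centers_s = window[1] +
                   (seq_len(n_bins) - 0.5) * bin_width_s,
                 bin_width_s = bin_width_s,
                 baseline_window_s = baseline_window_s,
                 unit_ids = env$channels$channel_id,
                 trial_ids = env$trial_ids,
                 units = tibble::tibble(unit_id = env$channels$channel_id,
                                        region = env$channels$region,
                                        quality_factor = NA_integer_)),
            class = "binned_rates")
}

#' Select task-relevant high-gamma channels
#'
#' Two-sided paired t-test of the unified envelope in the task window
#' (1-2 s) against the baseline window (0-0.5 s) per channel; channels with
#' p < `alpha` are retained.
#'
#' @param env an [hg_unified_envelope()] result.
#' @param trials trial tibble (only `included` trials used).
#' @param task_window,baseline_window comparison windows in seconds.
#' @param alpha significance level.
#' @return tibble (channel_id, region, t, p, selected).
#' @export
hg_channel_selection <- function(env, trials, task_window = c(1, 2),
                                 baseline_window = c(0, 0.5),
                                 alpha = 0.05) {
  keep_tr <- env$trial_ids %in% trials$trial_id[trials$included]
  tw <- env$time_s >= task_window[1] & env$time_s < task_window[2]
  bw <- env$time_s >= baseline_window[1] & env$time_s < baseline_window[2]
  res <- purrr::map_dfr(seq_len(dim(env$env)[1]), function(ci) {
    a <- rowMeans(env$env[ci, keep_tr, tw])
    b <- rowMeans(env$env[ci, keep_tr, bw])
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(channel_id = env$channels$channel_id[ci],
                   region = env$channels$region[ci],
                   t = unname(tt$statistic), p = tt$p.value)
  })
  res$selected <- res$p < alpha
  res
}

#' High-gamma decoding
#'
#' Delegates to the spiking decoder with 500 ms windows on the unified
#' envelope of the selected channels.
#'
#' @param env an [hg_unified_envelope()] result.
#' @param trials trial tibble.
#' @param channels channel ids to use (e.g. from [hg_channel_selection()]);
#'   default all. An empty selection errors.
#' @param ... passed to [decode_timecourse()].
#' @return a `decoding_result`.
#' @export
hg_decode <- function(env, trials, channels = NULL, label = "action",
                      window_width_s = 0.5, ...) {
  rates <- hg_to_rates(env)
  if (!is.null(channels)) {
    if (!length(channels)) stop("empty channel selection")
    rates <- subset_rates(rates, unit_ids = channels)
  }
  decode_timecourse(rates, trials, label = label,
                    window_width_s = window_width_s, ...)
}

#' High-gamma cross-format decoding
#'
#' @inheritParams hg_decode
#' @param ... passed to [cross_format_decode()].
#' @return a `generalization_map`.
#' @export
hg_cross_format_decode <- function(env, trials, channels = NULL,
                                   label = "action", ...) {
  rates <- hg_to_rates(env)
  if (!is.null(channels)) {
    if (!length(channels)) stop("empty channel selection")
    rates <- subset_rates(rates, unit_ids = channels)
  }
  cross_format_decode(rates, trials, label = label,
                      bin_width_s = 0.5, ...)
}
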