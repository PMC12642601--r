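#' Unit archetype specification
#'
#' Describes the ground-truth coding structure planted in one synthetic unit.
#' Archetypes mirror the taxonomy the model-selection stage recovers:
#'
#' * `unselective` — condition-independent Poisson baseline.
#' * `invariant` — additive tuning to action, hand and direction, identical
#'   across formats.
#' * `shared_action3`, `shared_hand`, `shared_direction` — tuning to one
#'   preferred level of a single factor, identical across formats.
#' * `shared_action6` — tuning to one preferred action-by-direction combination.
#' * `mixed` — an arbitrary (but fixed) condition pattern shared across
#'   formats; generically requires interaction terms.
#' * `idiosyncratic` — independent condition patterns in each format.
#' * `single_intention`, `single_observation` — tuning expressed in one
#'   format only.
#' * `gated_observer` — tuning to the *video* action, expressed only on
#'   trials where the video is behaviourally relevant (observation blocks of
#'   the main/no-probe designs; all trials of the probe design). Emulates
#'   context-gated parietal observation coding.
#'
#' `observation_gain` scales the effect in observation-format trials and
#' defaults to 0.5 for the shared archetypes (observation responses are
#' reduced relative to intention) and 1 otherwise. Note that a gain below 1
#' plants a genuine format-by-factor interaction, so taxonomy-recovery
#' studies should set it to 1 (see the methods vignette).
#'
#' @param archetype one of the archetype names above.
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param effect_size peak rate increment, spikes/s.
#' @param latency_s response onset relative to trial onset.
#' @param response_duration_s boxcar response duration.
#' @param observation_gain multiplier on the effect in observation format.
#' @param preferred named list fixing preferred levels (e.g.
#'   `list(action = "lift")`); unset levels are drawn at simulation time.
#' @param gating for `gated_observer`: `"auto"` (video relevant in
#'   observation blocks of the main/no-probe designs and always in the
#'   probe design), `"on"` (always relevant) or `"off"` (never relevant —
#'   the unit behaves as unselective).
#' @param region region label carried into unit metadata.
#' @param quality_factor sorting-quality metadata (1..4), never used in
#'   computation.
#' @return a list of class `unit_archetype`.
#' @export
unit_archetype <- function(archetype = c("unselective", "invariant",
                                         "shared_action3", "shared_action6",
                                         "shared_hand", "shared_direction",
                                         "mixed", "idiosyncratic",
                                         "single_intention",
                                         "single_observation",
                                         "gated_observer"),
                           baseline_rate = 10, effect_size = 20,
                           latency_s = 1.0, response_duration_s = 1.0,
                           observation_gain = NULL,
                           preferred = list(), region = "SPL",
                           quality_factor = 2L,
                           gating = c("auto", "on", "off")) {
  archetype <- match.arg(archetype)
  gating <- match.arg(gating)
  if (is.null(observation_gain))
    observation_gain <- if (archetype %in%
                            c("invariant", "shared_action3", "shared_action6",
                              "shared_hand", "shared_direction", "mixed"))
      0.5 else 1
  stopifnot(baseline_rate >= 0, effect_size >= 0,
            latency_s >= 0, latency_s < 3,
            response_duration_s > 0,
            observation_gain >= 0, observation_gain <= 1)
  structure(list(archetype = archetype, baseline_rate = baseline_rate,
                 effect_size = effect_size, latency_s = latency_s,
                 response_duration_s = response_duration_s,
                 observation_gain = observation_gain,
                 preferred = preferred, region = region,
                 quality_factor = as.integer(quality_factor),
                 gating = gating),
            class = "unit_archetype")
}

#' Build a population of archetype specs
#'
#' @param mix named integer vector, e.g. `c(shared_action3 = 40,
#'   unselective = 140)`.
#' @param ... passed to every [unit_archetype()] call.
#' @return list of `unit_archetype` objects.
#' @export
archetype_population <- function(mix, ...) {
  dots <- list(...)
  purrr::flatten(purrr::imap(as.list(mix), function(n, a)
    purrr::map(seq_len(n), function(i)
      do.call(unit_archetype, c(list(archetype = a), dots)))))
}

# Relevance of the video stream per trial, by design variant.
video_relevance <- function(design, trials) {
  switch(design$variant,
         main = trials$block == "observation",
         dissociation_noprobe = trials$block == "observation",
         dissociation_probe = rep(TRUE, nrow(trials)))
}

# Per-trial effect amplitude (fraction of effect_size) for one unit.
# Returns a numeric vector over trials; draws preferred levels / condition
# weights from the current RNG stream (seeded by the caller).
archetype_amplitude <- function(spec, design, trials) {
  pick <- function(f) {
    if (!is.null(spec$preferred[[f]])) spec$preferred[[f]]
    else sample(design$factors[[f]], 1)
  }
  obs <- trials$block == "observation"
  gain <- ifelse(obs, spec$observation_gain, 1)
  fx <- factor_names(design)
  has <- function(f) f %in% fx
  a <- switch(
    spec$archetype,
    unselective = rep(0, nrow(trials)),
    invariant = {
      parts <- purrr::map(fx[fx != "conflict"], function(f)
        as.numeric(trials[[f]] == pick(f)))
      Reduce(`+`, parts) / length(parts) * gain
    },
    shared_action3 = as.numeric(trials$action == pick("action")) * gain,
    shared_action6 = {
      if (!has("direction"))
        stop("shared_action6 requires a direction factor")
      as.numeric(trials$action == pick("action") &
                 trials$direction == pick("direction")) * gain
    },
    shared_hand = as.numeric(trials$hand == pick("hand")) * gain,
    shared_direction = {
      if (!has("direction"))
        stop("shared_direction requires a direction factor")
      as.numeric(trials$direction == pick("direction")) * gain
    },
    mixed = {
      cond <- condition_label(trials, design,
                              setdiff(fx, "conflict"))
      lev <- sort(unique(cond))
      w <- stats::runif(length(lev))
      w <- w / max(w)
      w[match(cond, lev)] * gain
    },
    idiosyncratic = {
      cond <- condition_label(trials, design, setdiff(fx, "conflict"))
      lev <- sort(unique(cond))
      w_int <- stats::runif(length(lev)); w_int <- w_int / max(w_int)
      w_obs <- stats::runif(length(lev)); w_obs <- w_obs / max(w_obs)
      ifelse(obs, w_obs[match(cond, lev)], w_int[match(cond, lev)])
    },
    single_intention = as.numeric(trials$action == pick("action")) *
      as.numeric(!obs),
    single_observation = as.numeric(trials$action == pick("action")) *
      as.numeric(obs) ,
    gated_observer = {
      video <- if (design$variant == "main") trials$action
               else derive_video_labels(trials)$video_action
      rel <- switch(spec$gating,
                    auto = video_relevance(design, trials),
                    on = rep(TRUE, nrow(trials)),
                    off = rep(FALSE, nrow(trials)))
      as.numeric(video == pick("action")) * as.numeric(rel)
    })
  a
}

#' Simulate spike trains with planted coding structure
#'
#' Generates inhomogeneous-Poisson spike trains with rate
#' `baseline + effect * boxcar(latency, duration) * format_gain *
#' condition_indicator`, where the indicator follows each unit's archetype.
#'
#' @param design a [task_design()].
#' @param trials trial tibble from [make_design()].
#' @param archetypes list of [unit_archetype()] specs (one per unit).
#' @param seed integer seed.
#' @return list with `spikes` (a [spike_session()]) and `ground_truth`
#'   (tibble: unit id, archetype, parameters, realized preferred levels as a
#'   per-trial amplitude fingerprint is not stored — the amplitude vector is
#'   reproducible from the seed).
#' @export
simulate_spikes <- function(design, trials, archetypes, seed = 1) {
  local_rng(seed)
  win <- design$trial_window_s
  wlen <- diff(win)
  nt <- nrow(trials)
  out_u <- vector("list", length(archetypes))
  out_s <- vector("list", length(archetypes))
  truth <- vector("list", length(archetypes))
  for (i in seq_along(archetypes)) {
    spec <- archetypes[[i]]
    uid <- sprintf("u%04d", i)
    amp <- archetype_amplitude(spec, design, trials) * spec$effect_size
    if (any(spec$baseline_rate + amp < 0))
      stop("negative implied rate for unit ", uid)
    t0 <- spec$latency_s
    t1 <- min(t0 + spec$response_duration_s, win[2])
    n_base <- stats::rpois(nt, spec$baseline_rate * wlen)
    n_extra <- stats::rpois(nt, amp * (t1 - t0))
    times <- c(stats::runif(sum(n_base), win[1], win[2]),
               stats::runif(sum(n_extra), t0, t1))
    trial_of <- c(rep(trials$trial_id, n_base),
                  rep(trials$trial_id, n_extra))
    out_u[[i]] <- tibble::tibble(unit_id = uid, region = spec$region,
                                 quality_factor = spec$quality_factor)
    out_s[[i]] <- tibble::tibble(unit_id = uid, trial_id = trial_of,
                                 time_s = times)
    truth[[i]] <- tibble::tibble(
      unit_id = uid, archetype = spec$archetype,
      baseline_rate = spec$baseline_rate, effect_size = spec$effect_size,
      latency_s = spec$latency_s,
      response_duration_s = spec$response_duration_s,
      observation_gain = spec$observation_gain, region = spec$region)
  }
  spikes_tb <- dplyr::bind_rows(out_s)
  ord <- order(spikes_tb$unit_id, spikes_tb$trial_id, spikes_tb$time_s)
  spikes_tb <- spikes_tb[ord, , drop = FALSE]
  list(spikes = spike_session(dplyr::bind_rows(out_u), spikes_tb,
                              trials$trial_id, win),
       ground_truth = dplyr::bind_rows(truth))
}

#' LFP channel specification
#'
#' @param noise_exponent spectral exponent beta of the 1/f^beta background.
#' @param line_amp_60hz amplitude of the 60 Hz line component.
#' @param hg_band_hz two-element high-gamma carrier band.
#' @param hg_depth modulation depth: carrier envelope is 1 at baseline and
#'   `1 + hg_depth` inside the response window on preferred-condition trials.
#' @param hg_factor factor name carrying the tuning (`NULL` = untuned).
#' @param hg_pref preferred level of `hg_factor` (`NULL` = drawn at
#'   simulation time).
#' @param hg_latency_s,hg_duration_s response window.
#' @param carrier_amp baseline carrier amplitude (noise SD is 1).
#' @param region region label.
#' @return list of class `lfp_channel`.
#' @export
lfp_channel <- function(noise_exponent = 1, line_amp_60hz = 0.5,
                        hg_band_hz = c(73, 144), hg_depth = 0,
                        hg_factor = NULL, hg_pref = NULL,
                        hg_latency_s = 1.0, hg_duration_s = 1.0,
                        carrier_amp = 0.5, region = "MC") {
  stopifnot(hg_depth >= 0, noise_exponent >= 0)
  structure(list(noise_exponent = noise_exponent,
                 line_amp_60hz = line_amp_60hz, hg_band_hz = hg_band_hz,
                 hg_depth = hg_depth, hg_factor = hg_factor,
                 hg_pref = hg_pref, hg_latency_s = hg_latency_s,
                 hg_duration_s = hg_duration_s, carrier_amp = carrier_amp,
                 region = region),
            class = "lfp_channel")
}

# one trial of 1/f^beta noise via spectral synthesis, unit variance
pink_noise <- function(n, fs, beta) {
  f <- seq(0, fs / 2, by = fs / n)
  nf <- length(f)
  mag <- c(0, f[-1]^(-beta / 2))
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- mag * exp(1i * ph)
  spec <- c(half, Conj(rev(half[2:(n - nf + 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

# band-limited white-noise carrier in [lo, hi] Hz, unit variance
band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- fft_freqs(n, fs)
  X[abs(f) < lo | abs(f) > hi] <- 0
  as.numeric(scale(Re(stats::fft(X, inverse = TRUE) / n)))
}

fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Simulate LFP traces with planted high-gamma modulation
#'
#' Each trace is 1/f^beta background noise, a 60 Hz line component, and a
#' band-limited high-gamma carrier whose amplitude envelope is 1 at baseline
#' and `1 + hg_depth` inside the channel's response window on trials of its
#' preferred condition.
#'
#' @param design a [task_design()].
#' @param trials trial tibble.
#' @param channels list of [lfp_channel()] specs.
#' @param fs sampling rate, Hz (>= 500).
#' @param seed integer seed.
#' @return list with `lfp` (an [lfp_session()]) and `ground_truth` tibble.
#' @export
simulate_lfp <- function(design, trials, channels, fs = 1000, seed = 1) {
  stopifnot(fs >= 500)
  local_rng(seed)
  win <- design$trial_window_s
  n <- round(diff(win) * fs)
  time_s <- win[1] + (0:(n - 1)) / fs
  nt <- nrow(trials)
  dat <- array(0, dim = c(length(channels), nt, n))
  truth <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[[ci]]
    pref <- ch$hg_pref
    if (!is.null(ch$hg_factor) && is.null(pref))
      pref <- sample(design$factors[[ch$hg_factor]], 1)
    tuned <- if (is.null(ch$hg_factor)) rep(FALSE, nt)
             else trials[[ch$hg_factor]] == pref
    box <- as.numeric(time_s >= ch$hg_latency_s &
                      time_s < ch$hg_latency_s + ch$hg_duration_s)
    for (ti in seq_len(nt)) {
      env <- 1 + ch$hg_depth * box * as.numeric(tuned[ti])
      dat[ci, ti, ] <-
        pink_noise(n, fs, ch$noise_exponent) +
        ch$line_amp_60hz * sin(2 * pi * 60 * time_s +
                               stats::runif(1, 0, 2 * pi)) +
        ch$carrier_amp * env *
          band_noise(n, fs, ch$hg_band_hz[1], ch$hg_band_hz[2])
    }
    truth[[ci]] <- tibble::tibble(
      channel_id = sprintf("ch%03d", ci), region = ch$region,
      hg_factor = ifelse(is.null(ch$hg_factor), NA_character_,
                         ch$hg_factor),
      hg_pref = ifelse(is.null(pref), NA_character_, pref),
      hg_depth = ch$hg_depth)
  }
  chans <- tibble::tibble(channel_id = sprintf("ch%03d",
                                               seq_along(channels)),
                          region = purrr::map_chr(channels, "region"))
  list(lfp = lfp_session(chans, dat, fs, time_s, trials$trial_id),
       ground_truth = dplyr::bind_rows(truth))
}

#' Simulate a complete session
#'
#' Convenience wrapper: design + trials + spikes (+ optional LFP).
#'
#' @inheritParams make_design
#' @param archetypes list of [unit_archetype()] specs.
#' @param channels optional list of [lfp_channel()] specs.
#' @param seed integer seed (trial order, spikes and LFP derive sub-seeds
#'   from it).
#' @return list with `design`, `trials`, `spikes`, `ground_truth`, and
#'   optionally `lfp`, `lfp_truth`.
#' @export
simulate_session <- function(variant = "main", reps_per_condition = 12,
                             archetypes, channels = NULL, seed = 1, ...) {
  dsn <- make_design(variant, reps_per_condition, seed = seed, ...)
  sim <- simulate_spikes(dsn$design, dsn$trials, archetypes,
                         seed = seed + 1000L)
  out <- list(design = dsn$design, trials = dsn$trials,
              spikes = sim$spikes, ground_truth = sim$ground_truth)
  if (!is.null(channels)) {
    lf <- simulate_lfp(dsn$design, dsn$trials, channels, seed = seed + 2000L)
    out$lfp <- lf$lfp
    out$lfp_truth <- lf$ground_truth
  }
  out
}
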