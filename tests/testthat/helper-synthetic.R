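# shared fixture builders -------------------------------------------------

# a binned_rates object built directly from an array (deterministic tests)
rates_from_array <- function(arr, trial_ids = seq_len(dim(arr)[2]),
                             bin_width_s = 0.1, window_start = 0,
                             regions = "SPL") {
  nu <- dim(arr)[1]
  unit_ids <- sprintf("u%04d", seq_len(nu))
  dimnames(arr) <- list(unit_ids, trial_ids, NULL)
  structure(list(
    rates = arr,
    bin_centers_s = window_start + (seq_len(dim(arr)[3]) - 0.5) *
      bin_width_s,
    bin_width_s = bin_width_s,
    baseline_window_s = c(-0.5, 0),
    unit_ids = unit_ids, trial_ids = trial_ids,
    units = tibble::tibble(unit_id = unit_ids,
                           region = rep_len(regions, nu),
                           quality_factor = 2L)),
    class = "binned_rates")
}

# deterministic spike train at a constant rate (spikes/s) over [t0, t1);
# spikes sit at mid-period offsets so none land on a bin boundary
regular_spikes <- function(rate, t0, t1) {
  if (rate <= 0) return(numeric(0))
  seq(t0 + 0.5 / rate, t1 - 1e-9, by = 1 / rate)
}

# small main-task session with one planted archetype population
quick_session <- function(mix, reps = 6, seed = 1, effect = 20,
                          gain = 1, baseline = 10, ...) {
  simulate_session("main", reps_per_condition = reps,
                   archetypes = archetype_population(
                     mix, effect_size = effect, observation_gain = gain,
                     baseline_rate = baseline, ...),
                   seed = seed)
}

# binned rates where each unit's per-trial window response is
# mu[unit, trial] + N(0, sd); constant across the given bins
gaussian_rates <- function(mu, sd = 1, n_bins = 30, bins_active = 11:20,
                           window_start = 0, seed = 1) {
  set.seed(seed)
  nu <- nrow(mu); nt <- ncol(mu)
  arr <- array(0, c(nu, nt, n_bins))
  vals <- mu + matrix(rnorm(nu * nt, 0, sd), nu, nt)
  for (b in bins_active) arr[, , b] <- vals
  rates_from_array(arr, window_start = window_start)
}

# winner per unit (internal helper surfaced for tests)
best_models_for_test <- function(fit) crossformat:::best_models(fit)
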