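#' Save a session to disk
#'
#' Writes a language-neutral session store: one HDF5 file (`<path>.h5`) with
#' groups `/meta` (design as JSON attribute-free dataset), `/units`,
#' `/spikes` (flat `unit_id` / `trial_id` / `time_s` datasets) and optional
#' `/lfp`, plus a sidecar RFC-4180 CSV trial table (`<path>_trials.csv`) and,
#' when supplied, a ground-truth JSON sidecar (`<path>_truth.json`).
#'
#' @param path store path prefix (no extension).
#' @param design a [task_design()].
#' @param trials trial tibble.
#' @param spikes a [spike_session()].
#' @param lfp optional [lfp_session()]; omitted from the store when `NULL`.
#' @param ground_truth optional list (e.g. planted archetypes), serialized as
#'   JSON alongside.
#' @return `path`, invisibly.
#' @export
save_session <- function(path, design, trials, spikes, lfp = NULL,
                         ground_truth = NULL) {
  h5 <- paste0(path, ".h5")
  if (file.exists(h5)) file.remove(h5)
  rhdf5::h5createFile(h5)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  meta <- jsonlite::toJSON(list(
    variant = design$variant, factors = design$factors,
    blocks = design$blocks,
    event_times_s = as.list(design$event_times_s),
    trial_window_s = design$trial_window_s,
    reps_per_condition = design$reps_per_condition), auto_unbox = TRUE)
  rhdf5::h5createGroup(h5, "meta")
  rhdf5::h5write(as.character(meta), h5, "meta/design_json")

  rhdf5::h5createGroup(h5, "units")
  rhdf5::h5write(spikes$units$unit_id, h5, "units/unit_id")
  rhdf5::h5write(spikes$units$region, h5, "units/region")
  rhdf5::h5write(as.integer(spikes$units$quality_factor), h5,
                 "units/quality_factor")

  rhdf5::h5createGroup(h5, "spikes")
  rhdf5::h5write(spikes$spikes$unit_id, h5, "spikes/unit_id")
  rhdf5::h5write(as.integer(spikes$spikes$trial_id), h5, "spikes/trial_id")
  rhdf5::h5write(spikes$spikes$time_s, h5, "spikes/time_s")
  rhdf5::h5write(as.integer(spikes$trial_ids), h5, "spikes/all_trial_ids")
  rhdf5::h5write(spikes$window, h5, "spikes/window_s")

  if (!is.null(lfp)) {
    rhdf5::h5createGroup(h5, "lfp")
    rhdf5::h5write(lfp$channels$channel_id, h5, "lfp/channel_id")
    rhdf5::h5write(lfp$channels$region, h5, "lfp/region")
    rhdf5::h5write(lfp$data, h5, "lfp/data")
    rhdf5::h5write(lfp$fs, h5, "lfp/fs")
    rhdf5::h5write(lfp$time_s, h5, "lfp/time_s")
    rhdf5::h5write(as.integer(lfp$trial_ids), h5, "lfp/trial_ids")
  }

  utils::write.csv(trials, paste0(path, "_trials.csv"), row.names = FALSE)
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, paste0(path, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session from disk
#'
#' Inverse of [save_session()]. A store without an `/lfp` group yields
#' `lfp = NULL`; a malformed store raises a schema error naming the missing
#' group. Trial labels are validated against the stored design.
#'
#' @param path store path prefix used at save time.
#' @return list with `design`, `trials`, `spikes`, `lfp` (possibly `NULL`)
#'   and `ground_truth` (possibly `NULL`).
#' @export
load_session <- function(path) {
  h5 <- paste0(path, ".h5")
  csv <- paste0(path, "_trials.csv")
  if (!file.exists(h5)) stop("no session file at ", h5)
  if (!file.exists(csv)) stop("missing sidecar trial table ", csv)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(h5, recursive = FALSE)$name
  for (g in c("meta", "units", "spikes"))
    if (!g %in% top) stop("malformed session store: missing group /", g)

  meta <- jsonlite::fromJSON(rhdf5::h5read(h5, "meta/design_json"))
  design <- task_design(meta$variant, meta$reps_per_condition,
                        go_time_s = meta$event_times_s$go,
                        trial_window_s = unlist(meta$trial_window_s))

  units <- tibble::tibble(
    unit_id = as.vector(rhdf5::h5read(h5, "units/unit_id")),
    region = as.vector(rhdf5::h5read(h5, "units/region")),
    quality_factor = as.vector(rhdf5::h5read(h5, "units/quality_factor")))
  sp <- tibble::tibble(
    unit_id = as.vector(rhdf5::h5read(h5, "spikes/unit_id")),
    trial_id = as.vector(rhdf5::h5read(h5, "spikes/trial_id")),
    time_s = as.vector(rhdf5::h5read(h5, "spikes/time_s")))
  spikes <- spike_session(units, sp,
                          as.vector(rhdf5::h5read(h5, "spikes/all_trial_ids")),
                          as.vector(rhdf5::h5read(h5, "spikes/window_s")))

  lfp <- NULL
  if ("lfp" %in% top) {
    lfp <- lfp_session(
      channels = tibble::tibble(
        channel_id = as.vector(rhdf5::h5read(h5, "lfp/channel_id")),
        region = as.vector(rhdf5::h5read(h5, "lfp/region"))),
      data = rhdf5::h5read(h5, "lfp/data"),
      fs = as.vector(rhdf5::h5read(h5, "lfp/fs")),
      time_s = as.vector(rhdf5::h5read(h5, "lfp/time_s")),
      trial_ids = as.vector(rhdf5::h5read(h5, "lfp/trial_ids")))
  }

  trials <- tibble::as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  validate_trials(trials, design)

  truth_path <- paste0(path, "_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::fromJSON(truth_path,
                                                           simplifyVector = FALSE)
           else NULL
  list(design = design, trials = trials, spikes = spikes, lfp = lfp,
       ground_truth = truth)
}
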