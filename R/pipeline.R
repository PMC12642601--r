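#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis pipeline, with defaults
#' equal to the stated analysis choices: 100 ms rate bins with a -500 to
#' 0 ms baseline, 200 ms responsiveness windows with the 3-consecutive
#' rule, 500 ms ANOVA bins, the 1-2 s model window with 5-fold stratified
#' CV and 1000 permutations at FDR q = 0.05, 500 RSA splits, 10-fold LDA
#' decoding with a 95%-variance / 50-component PCA, and 1000-permutation
#' cross-format maps with family-wise corrected masks. The full
#' configuration is echoed into every run manifest for provenance.
#'
#' @param ... overrides of the defaults listed above (see source for key
#'   names).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bin_width_s = 0.1, baseline_window_s = c(-0.5, 0),
    responsiveness_alpha = 0.05,
    anova_bin_width_s = 0.5, anova_correction = "units",
    model_window_s = c(1, 2), model_folds = 5, model_n_perm = 1000,
    fdr_q = 0.05, r2_min = 0.01,
    rsa_n_splits = 500, rsa_window_s = c(1, 2),
    decode_folds = 10, decode_window_s = 0.2, var_keep = 0.95,
    max_pc = 50, crossformat_n_perm = 1000,
    hg_window_s = 0.5, seed = 1,
    stages = c("responsiveness", "tuning", "classify", "rsa", "decode",
               "geometry"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$model_folds < 2 || cfg$decode_folds < 2)
    stop("cross-validation needs at least 2 folds")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a session
#'
#' Executes the requested stages in dependency order on a session (loaded
#' via [load_session()] or simulated via [simulate_session()]), writing one
#' CSV/JSON per stage plus a manifest (inputs, configuration, seed,
#' versions, runtimes) to `out_dir`. Deterministic given the config seed.
#'
#' @param session list with `design`, `trials`, `spikes` (and optionally
#'   `lfp`), or a session-store path prefix for [load_session()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @return (invisibly) a list of stage results; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = tempfile("crossformat_run_")) {
  if (is.character(session)) session <- load_session(session)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   variant = session$design$variant,
                   n_units = nrow(session$spikes$units),
                   n_trials = nrow(session$trials),
                   r_version = as.character(getRversion()),
                   stages = list())
  results <- list()
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[nm]] <<- list(runtime_s = round(proc.time()[3] - t0, 2))
    val
  }

  rates <- t_stage("bin", bin_rates(session$spikes, session$trials,
                                    bin_width_s = config$bin_width_s))
  results$rates <- rates
  wants <- function(s) s %in% config$stages
  dissoc <- session$design$variant != "main"

  if (wants("responsiveness")) {
    res <- t_stage("responsiveness",
                   test_responsiveness(rates, session$trials,
                                       alpha = config$responsiveness_alpha))
    utils::write.csv(
      res[, c("unit_id", "region", "block", "condition", "responsive",
              "latency_s", "min_p")],
      file.path(out_dir, "responsiveness.csv"), row.names = FALSE)
    results$responsiveness <- res
    if (all(c("intention", "observation") %in% res$block)) {
      ov <- format_overlap(res)
      utils::write.csv(ov, file.path(out_dir, "format_overlap.csv"),
                       row.names = FALSE)
      results$format_overlap <- ov
    }
  }
  if (wants("tuning")) {
    tun <- t_stage("tuning",
                   anova_timecourse(rates, session$trials,
                                    bin_width_s = config$anova_bin_width_s,
                                    correction = config$anova_correction))
    utils::write.csv(tuning_counts(tun),
                     file.path(out_dir, "tuning_counts.csv"),
                     row.names = FALSE)
    results$tuning <- tun
  }
  relevant <- rates$unit_ids
  if (wants("classify") && !dissoc) {
    fit <- t_stage("classify_fit",
                   fit_models_cv(rates, session$trials,
                                 window = config$model_window_s,
                                 folds = config$model_folds,
                                 seed = config$seed))
    cls <- t_stage("classify_gate",
                   classify_population(fit, n_perm = config$model_n_perm,
                                       q = config$fdr_q,
                                       r2_min = config$r2_min,
                                       seed = config$seed))
    utils::write.csv(cls, file.path(out_dir, "unit_classification.csv"),
                     row.names = FALSE)
    results$classification <- cls
    relevant <- task_relevant_units(cls)
  }
  if (wants("rsa") && !dissoc && length(relevant) >= 2) {
    rsa <- t_stage("rsa",
                   split_half_rsa(rates, session$trials, units = relevant,
                                  grouping = "action",
                                  n_splits = config$rsa_n_splits,
                                  window = config$rsa_window_s,
                                  seed = config$seed))
    utils::write.csv(as.data.frame(rsa$matrix),
                     file.path(out_dir, "rsa_cross_action.csv"))
    results$rsa <- rsa
  }
  if (wants("decode")) {
    if (dissoc) {
      rep <- t_stage("dissociation",
                     run_dissociation(rates, session$trials,
                                      session$design,
                                      folds = config$decode_folds,
                                      seed = config$seed))
      utils::write.csv(
        rep$decoding[, c("block", "source", "peak_accuracy", "chance")],
        file.path(out_dir, "dissociation_decoding.csv"), row.names = FALSE)
      results$dissociation <- rep
    } else {
      dec <- t_stage("decode",
                     decode_timecourse(rates, session$trials,
                                       label = "action",
                                       blocks = "intention",
                                       window_width_s =
                                         config$decode_window_s,
                                       folds = config$decode_folds,
                                       var_keep = config$var_keep,
                                       max_pc = config$max_pc,
                                       seed = config$seed))
      utils::write.csv(dec$accuracy,
                       file.path(out_dir, "decoding_action_intention.csv"),
                       row.names = FALSE)
      xf <- t_stage("crossformat",
                    cross_format_decode(rates, session$trials,
                                        label = "action",
                                        n_perm = config$crossformat_n_perm,
                                        max_pc = config$max_pc,
                                        seed = config$seed))
      utils::write.csv(xf$accuracy,
                       file.path(out_dir, "crossformat_action_map.csv"),
                       row.names = FALSE)
      results$decoding <- dec
      results$crossformat <- xf
    }
  }
  if (wants("geometry") && !dissoc && length(relevant) >= 3) {
    traj <- t_stage("geometry", {
      r2 <- bin_rates(session$spikes, session$trials,
                      bin_width_s = config$bin_width_s,
                      window = c(-0.5, 3))
      pca_trajectories(r2, session$trials, units = relevant)
    })
    pro <- procrustes_report(traj)
    utils::write.csv(pro[, c("condition", "d")],
                     file.path(out_dir, "procrustes.csv"),
                     row.names = FALSE)
    results$trajectories <- traj
    results$procrustes <- pro
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [pipeline_config()] for the reader; `path`, invisibly, for the
#'   writer.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
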