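#' Derive the video's action and hand labels from conflict type
#'
#' In the dissociation tasks the instructed cue and the concurrently shown
#' video can disagree. The video labels follow deterministically from the
#' instructed labels and the conflict type: the action flips under
#' `action_incong` and `both_incong`, the hand flips under `hand_incong`
#' and `both_incong`. Both factors are binary (slide/rotate, left/right),
#' so applying the same conflict twice is the identity.
#'
#' @param trials dissociation-variant trial tibble (columns `action`,
#'   `hand`, `conflict`).
#' @return tibble with `trial_id`, `video_action`, `video_hand`.
#' @export
derive_video_labels <- function(trials) {
  stopifnot(all(c("action", "hand", "conflict") %in% names(trials)))
  known <- c("congruent", "action_incong", "hand_incong", "both_incong")
  bad <- setdiff(unique(trials$conflict), known)
  if (length(bad))
    stop("unknown conflict level(s): ", paste(bad, collapse = ", "))
  flip_action <- trials$conflict %in% c("action_incong", "both_incong")
  flip_hand <- trials$conflict %in% c("hand_incong", "both_incong")
  other <- function(x, lv) ifelse(x == lv[1], lv[2], lv[1])
  tibble::tibble(
    trial_id = trials$trial_id,
    video_action = ifelse(flip_action,
                          other(trials$action, c("slide", "rotate")),
                          trials$action),
    video_hand = ifelse(flip_hand,
                        other(trials$hand, c("left", "right")),
                        trials$hand))
}

#' Run the dissociation-task analysis battery
#'
#' Composes the tuning and decoding stages for a dissociation-variant
#' session: two-way ANOVA tuning timecourses for the instructed and the
#' video factors, instructed/video/16-way/conflict decoding per block,
#' cross-time generalization for instructed and video labels, and the
#' incongruent-only control rerun.
#'
#' @param rates a [bin_rates()] result from a dissociation session.
#' @param trials dissociation trial tibble.
#' @param design the session's [task_design()].
#' @param folds decoding folds.
#' @param seed integer seed.
#' @param cross_time also compute cross-time maps (slower).
#' @param exclude_probe_window drop windows after probe onset (2.5 s) from
#'   peak-accuracy bookkeeping to avoid saccade-report confounds.
#' @return list of class `dissociation_report` with elements
#'   `tuning_instructed`, `tuning_video`, `decoding` (tibble of
#'   `decoding_result`s per block and source), `confusion16`,
#'   `conflict_decoding`, `incongruent_only`, and optionally `cross_time`.
#' @export
run_dissociation <- function(rates, trials, design, folds = 10, seed = 1,
                             cross_time = FALSE,
                             exclude_probe_window = TRUE) {
  if (!design$variant %in% c("dissociation_noprobe", "dissociation_probe"))
    stop("run_dissociation needs a dissociation-variant session, got '",
         design$variant, "'")
  trials <- add_dissociation_labels(trials)
  blocks <- design$blocks

  tun_instr <- anova_timecourse(rates, trials,
                                factors = c("action", "hand"))
  tun_video <- anova_timecourse(rates, trials,
                                factors = c("video_action", "video_hand"))

  max_c <- if (exclude_probe_window &&
               design$variant == "dissociation_probe") 2.5 else Inf
  peak_in <- function(d) {
    keep <- d$accuracy$window_center_s <= max_c
    i <- which.max(d$accuracy$accuracy[keep])
    list(accuracy = d$accuracy$accuracy[keep][i],
         window_s = d$accuracy$window_center_s[keep][i])
  }

  dec <- purrr::map_dfr(blocks, function(b) {
    purrr::map_dfr(c("instructed", "video"), function(src) {
      d <- dissociation_decode(rates, trials, source = src, blocks = b,
                               folds = folds, seed = seed)
      pk <- peak_in(d)
      tibble::tibble(block = b, source = src,
                     peak_accuracy = pk$accuracy,
                     peak_window_s = pk$window_s,
                     chance = d$chance, result = list(d))
    })
  })

  d16 <- dissociation_decode(rates, trials, source = "trialtype16",
                             folds = min(folds,
                                         min(table(paste(trials$action,
                                                         trials$hand,
                                                         trials$conflict)))),
                             seed = seed)
  dconf <- dissociation_decode(rates, trials, source = "conflict",
                               folds = folds, seed = seed)

  incong <- purrr::map_dfr(blocks, function(b) {
    purrr::map_dfr(c("instructed", "video"), function(src) {
      d <- dissociation_decode(rates, trials, source = src, blocks = b,
                               incongruent_only = TRUE,
                               folds = folds, seed = seed)
      pk <- peak_in(d)
      tibble::tibble(block = b, source = src,
                     peak_accuracy = pk$accuracy, chance = d$chance)
    })
  })

  out <- list(tuning_instructed = tun_instr, tuning_video = tun_video,
              decoding = dec, confusion16 = d16$confusion,
              decoding16 = d16, conflict_decoding = dconf,
              incongruent_only = incong)
  if (cross_time) {
    out$cross_time <- purrr::map(
      stats::setNames(c("instructed", "video"), c("instructed", "video")),
      function(src) {
        tr <- add_dissociation_labels(trials)
        lab <- if (src == "instructed") c("action", "hand")
               else c("video_action", "video_hand")
        cross_time_decode(rates, tr, label = lab, folds = folds,
                          seed = seed)
      })
  }
  class(out) <- "dissociation_report"
  out
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat("<dissociation_report>\n")
  print(x$decoding[, c("block", "source", "peak_accuracy", "chance")])
  invisible(x)
}
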