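#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$window_center_s,
                               y = .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$se,
                                      ymax = .data$accuracy + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "decoding accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.generalization_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test_s, y = .data$train_s,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "test time (s)", y = "train time (s)",
                  title = object$direction) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rsa_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$condition_b,
                               y = .data$condition_a,
                               fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = paste(object$comparison, "RSA:",
                                object$grouping)) +
    ggplot2::theme_minimal()
}

#' Plot tuned-unit counts over time
#'
#' @param res an [anova_timecourse()] result.
#' @return a ggplot.
#' @export
plot_tuning_counts <- function(res) {
  ggplot2::ggplot(tuning_counts(res),
                  ggplot2::aes(x = .data$bin_center_s, y = .data$n_tuned,
                               colour = .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~block) +
    ggplot2::labs(x = "time (s)", y = "tuned units") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~format) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.embedding_report <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$condition,
                               shape = .data$block)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "UMAP-1", y = "UMAP-2") +
    ggplot2::theme_minimal()
}
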