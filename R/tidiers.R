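#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.decoding_result <- function(x, ...) x$accuracy

#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(peak_accuracy = x$peak$accuracy,
                 peak_window_s = x$peak$window_center_s,
                 n_classes = length(x$classes), chance = x$chance)
}

#' @export
tidy.generalization_map <- function(x, ...) {
  g <- expand.grid(train_s = x$train_centers_s,
                   test_s = x$test_centers_s)
  out <- tibble::tibble(train_s = g$train_s, test_s = g$test_s,
                        accuracy = as.vector(x$accuracy))
  if (!is.null(x$p)) {
    out$p <- as.vector(x$p)
    out$significant <- as.vector(x$sig_mask)
  }
  out
}

#' @export
glance.generalization_map <- function(x, ...) {
  tibble::tibble(direction = x$direction,
                 max_accuracy = max(x$accuracy), chance = x$chance,
                 n_significant = if (is.null(x$sig_mask)) NA_integer_
                                 else sum(x$sig_mask))
}

#' @export
tidy.rsa_result <- function(x, ...) {
  g <- expand.grid(row = rownames(x$matrix) %||%
                     seq_len(nrow(x$matrix)),
                   col = colnames(x$matrix) %||%
                     seq_len(ncol(x$matrix)))
  tibble::tibble(condition_a = g$row, condition_b = g$col,
                 correlation = as.vector(x$matrix))
}

#' @export
glance.rsa_result <- function(x, ...) {
  tibble::tibble(comparison = x$comparison, grouping = x$grouping,
                 structure_stat = x$structure_stat,
                 n_splits = x$n_splits)
}

#' @export
tidy.trajectory_set <- function(x, ...) x$trajectories

#' @export
glance.trajectory_set <- function(x, ...) {
  tibble::tibble(grouping = x$grouping,
                 var_combined = x$variance_explained$combined,
                 var_intention = x$variance_explained$intention,
                 var_observation = x$variance_explained$observation)
}

#' @export
tidy.embedding_report <- function(x, ...) x$points

#' @export
print.rsa_result <- function(x, ...) {
  cat("<rsa_result>", x$comparison, "/", x$grouping, ": structure_stat =",
      round(x$structure_stat, 4), "(", x$n_splits, "splits )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
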