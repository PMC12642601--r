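#' Time-resolved factorial ANOVA tuning
#'
#' For each unit (or channel), block and non-overlapping 500 ms time bin,
#' fits a fixed-effects factorial ANOVA of the per-trial bin-mean net rate on
#' the task factors, with all interactions. Type-II sums of squares are used
#' so mildly unbalanced tables (after artifact rejection) remain
#' interpretable; for balanced tables they coincide with the classical
#' ANOVA. Significance uses the divisor stated for this analysis —
#' alpha / number of units — with a per-bin option.
#'
#' A unit is *selectively tuned* to a main effect in a bin iff that effect is
#' significant and no interaction involving it is; significant interactions
#' are counted under the interaction (see [tuning_counts()]).
#'
#' @param rates a [bin_rates()] result.
#' @param trials trial tibble.
#' @param factors factor columns to cross; default all design factors
#'   present (3 for the main task, 2 for dissociation).
#' @param blocks blocks to analyse separately; default all.
#' @param bin_width_s ANOVA bin width, default 0.5 s.
#' @param alpha nominal level.
#' @param correction `"units"` (alpha / number of units, as stated),
#'   `"units_bins"` (additionally / number of bins), or `"none"`.
#' @return tibble of class `tuning_timecourse`: one row per
#'   (unit, block, bin, effect) with `p` and `significant`.
#' @export
anova_timecourse <- function(rates, trials, factors = NULL, blocks = NULL,
                             bin_width_s = 0.5, alpha = 0.05,
                             correction = c("units", "units_bins", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(rates, "binned_rates"))
  trials <- trials[trials$included & trials$trial_id %in% rates$trial_ids, ]
  if (is.null(factors))
    factors <- intersect(c("hand", "action", "direction", "conflict"),
                         names(trials))
  for (f in factors)
    if (length(unique(trials[[f]])) < 2)
      stop("factor '", f, "' has a single observed level")
  if (is.null(blocks)) blocks <- unique(trials$block)

  bc <- rates$bin_centers_s
  post <- which(bc > 0)
  per_big <- as.integer(round(bin_width_s / rates$bin_width_s))
  n_big <- length(post) %/% per_big
  big_centers <- (seq_len(n_big) - 0.5) * bin_width_s

  terms <- factorial_terms(factors)
  nu <- length(rates$unit_ids)
  thr <- switch(correction,
                units = alpha / nu,
                units_bins = alpha / (nu * n_big),
                none = alpha)

  out <- list()
  for (blk in blocks) {
    sub <- trials[trials$block == blk, , drop = FALSE]
    ti <- match(sub$trial_id, rates$trial_ids)
    qrs <- term_qr_set(sub, factors, terms)
    for (b in seq_len(n_big)) {
      bins <- post[((b - 1) * per_big + 1):(b * per_big)]
      Y <- t(rowMeans(rates$rates[, ti, bins, drop = FALSE], dims = 2))
      pv <- type2_pvalues(qrs, Y)     # terms x units
      out[[length(out) + 1]] <- tibble::tibble(
        unit_id = rep(rates$unit_ids, each = length(terms)),
        block = blk, bin_center_s = big_centers[b],
        effect = rep(names(terms), times = nu),
        p = as.vector(pv),
        significant = as.vector(pv) < thr)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "alpha_threshold") <- thr
  attr(res, "factors") <- factors
  class(res) <- c("tuning_timecourse", class(res))
  res
}

# all main effects and interactions of a factor set, as lists of factor names
factorial_terms <- function(factors) {
  k <- length(factors)
  terms <- list()
  for (ord in seq_len(k)) {
    combos <- utils::combn(factors, ord, simplify = FALSE)
    for (cm in combos) terms[[paste(cm, collapse = ":")]] <- cm
  }
  terms
}

# Pre-factorized designs for type-II tests: for each term T, the QR of the
# model containing every term not containing T, and of that model plus T;
# plus the full-model QR for the error term.
term_qr_set <- function(trials, factors, terms) {
  mm <- function(term_list) {
    if (!length(term_list)) return(matrix(1, nrow(trials), 1))
    fml <- stats::as.formula(paste(
      "~", paste(purrr::map_chr(term_list, paste, collapse = ":"),
                 collapse = "+")))
    stats::model.matrix(fml, data = trials)
  }
  contains <- function(a, b) all(b %in% a)   # does term a contain term b?
  full_qr <- qr(mm(terms))
  per_term <- purrr::imap(terms, function(tm, nm) {
    base <- terms[!purrr::map_lgl(terms, contains, b = tm)]
    q1 <- qr(mm(base))
    q2 <- qr(mm(c(base, list(tm))))
    list(q1 = q1, q2 = q2, df = q2$rank - q1$rank)
  })
  list(full = full_qr,
       df_res = nrow(trials) - full_qr$rank,
       per_term = per_term)
}

# Type-II F-test p-values; Y is trials x units, returns terms x units.
type2_pvalues <- function(qrs, Y) {
  Y <- as.matrix(Y)
  rss <- function(qrobj) colSums(qr.resid(qrobj, Y)^2)
  rss_full <- rss(qrs$full)
  df_res <- qrs$df_res
  rows <- lapply(qrs$per_term, function(tq) {
    num <- (rss(tq$q1) - rss(tq$q2)) / tq$df
    f <- num / (rss_full / df_res)
    p <- stats::pf(f, tq$df, df_res, lower.tail = FALSE)
    p[!is.finite(f)] <- NA_real_
    p
  })
  do.call(rbind, rows)
}

#' Count selectively tuned units per category and time bin
#'
#' Main-effect categories count units whose main effect is significant with
#' no significant interaction involving that factor; interaction categories
#' count units with that interaction significant.
#'
#' @param res an [anova_timecourse()] result.
#' @return tibble (block, bin_center_s, effect, n_tuned).
#' @export
tuning_counts <- function(res) {
  factors <- attr(res, "factors")
  wide <- res |>
    dplyr::select("unit_id", "block", "bin_center_s", "effect",
                  "significant") |>
    tidyr::pivot_wider(names_from = "effect", values_from = "significant")
  effects <- setdiff(names(wide), c("unit_id", "block", "bin_center_s"))
  inter <- effects[grepl(":", effects)]
  counts <- purrr::map_dfr(effects, function(e) {
    sel <- if (e %in% inter) {
      isTRUE_v(wide[[e]])
    } else {
      invol <- inter[vapply(strsplit(inter, ":"),
                            function(v) e %in% v, logical(1))]
      any_inter <- Reduce(`|`, c(list(rep(FALSE, nrow(wide))),
                                 lapply(invol,
                                        function(x) isTRUE_v(wide[[x]]))))
      isTRUE_v(wide[[e]]) & !any_inter
    }
    wide |>
      dplyr::mutate(.sel = sel) |>
      dplyr::group_by(.data$block, .data$bin_center_s) |>
      dplyr::summarise(n_tuned = sum(.data$.sel), .groups = "drop") |>
      dplyr::mutate(effect = e)
  })
  counts[, c("block", "bin_center_s", "effect", "n_tuned")]
}

# NA-safe elementwise TRUE test
isTRUE_v <- function(x) !is.na(x) & x
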