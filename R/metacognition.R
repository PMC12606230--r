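#' Type-2 ROC curve from confidence ratings
#'
#' For each confidence criterion splitting the 4-point scale into high/low
#' (`>= 2`, `>= 3`, `>= 4`), computes the type-2 hit rate (proportion of
#' correct trials rated at or above the criterion) and type-2 false-alarm
#' rate (same proportion among incorrect trials). The inverse-cumulative
#' rates, with the (0,0) and (1,1) endpoints appended, trace the type-2 ROC
#' curve whose area is the AUROC-2 metacognitive-sensitivity statistic.
#'
#' The curve is undefined when the trials are all correct or all incorrect;
#' in that case `NULL` is returned with a warning rather than an error, so
#' degenerate subjects can be flagged and dropped downstream.
#'
#' @param confidence Integer confidence ratings in 1..4.
#' @param correct 0/1 correctness indicators, same length.
#' @return A tibble of class `roc2` with columns `criterion` (`NA` for the
#'   appended endpoints), `fa_rate`, `hit_rate`, ordered from (0,0) to (1,1),
#'   and attributes `n_correct` / `n_incorrect`; or `NULL` if undefined.
#' @examples
#' type2_roc(c(4, 3, 2, 3, 1, 1), c(1, 1, 1, 0, 0, 0))
#' @export
type2_roc <- function(confidence, correct) {
  if (length(confidence) != length(correct) || length(confidence) == 0L) {
    abort("`confidence` and `correct` must be non-empty and equal length.")
  }
  keep <- !is.na(confidence) & !is.na(correct)
  confidence <- confidence[keep]
  correct <- correct[keep]
  if (any(!confidence %in% 1:4)) {
    abort("`confidence` must contain only levels 1..4.")
  }
  n_c <- sum(correct == 1)
  n_i <- sum(correct == 0)
  if (n_c == 0L || n_i == 0L) {
    warn("type-2 ROC undefined: need at least one correct and one incorrect trial")
    return(NULL)
  }
  crit <- 4:2 # descending so rates increase from (0,0) to (1,1)
  hit <- vapply(crit, function(k) sum(correct == 1 & confidence >= k) / n_c,
                numeric(1))
  fa <- vapply(crit, function(k) sum(correct == 0 & confidence >= k) / n_i,
               numeric(1))
  out <- tibble::tibble(
    criterion = c(NA_integer_, crit, NA_integer_),
    fa_rate = c(0, fa, 1),
    hit_rate = c(0, hit, 1)
  )
  attr(out, "n_correct") <- n_c
  attr(out, "n_incorrect") <- n_i
  class(out) <- c("roc2", class(out))
  out
}

#' Area under the type-2 ROC curve
#'
#' Trapezoidal area under the piecewise-linear curve through the type-2 ROC
#' points. Equivalently (exactly, not approximately) the probability that a
#' randomly drawn correct trial carries higher confidence than a randomly
#' drawn incorrect trial, counting ties as one half. 0.5 means confidence
#' carries no information about correctness; 1 means perfect metacognitive
#' separation.
#'
#' @param curve A `roc2` curve from [type2_roc()], or a vector of confidence
#'   ratings (then `correct` must be supplied).
#' @param correct Optional 0/1 vector when `curve` is raw confidence.
#' @return The area in `[0, 1]`, or `NA` if the curve is undefined.
#' @examples
#' auroc2(c(4, 4, 1, 1), c(1, 1, 0, 0))
#' @export
auroc2 <- function(curve, correct = NULL) {
  if (!is.null(correct)) {
    curve <- suppressWarnings(type2_roc(curve, correct))
  }
  if (is.null(curve)) return(NA_real_)
  if (!inherits(curve, "roc2")) abort("`curve` must be a `roc2` object.")
  x <- curve$fa_rate
  y <- curve$hit_rate
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Per subject x condition summaries of the dependent variables
#'
#' Computes, for every subject and memory condition in an analysis-ready
#' trial set, the four dependent variables of the design: proportion
#' correct (performance), mean number of items shown (item capacity, with
#' its SD for the set-size-variability controls), mean confidence, and
#' AUROC-2 (metacognitive sensitivity). Subjects whose trials in a condition
#' are all correct or all incorrect get `auroc2 = NA`.
#'
#' @param trials Analysis-ready trials (after [preprocess_trials()]).
#' @return A tibble with one row per subject x condition: `subject_id`,
#'   `condition`, `n_trials`, `accuracy`, `mean_items`, `sd_items`,
#'   `mean_confidence`, `auroc2`.
#' @export
subject_summaries <- function(trials) {
  if (nrow(trials) == 0L) {
    abort("`trials` is empty; nothing to summarize.")
  }
  trials |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      mean_items = mean(.data$n_items),
      sd_items = sd(.data$n_items),
      mean_confidence = mean(.data$confidence),
      auroc2 = auroc2(.data$confidence, .data$correct),
      .groups = "drop"
    )
}

#' @export
#' @rdname type2_roc
#' @param object,x A `roc2` object.
#' @param ... Unused.
autoplot.roc2 <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fa_rate, y = .data$hit_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "type-2 false-alarm rate", y = "type-2 hit rate",
      title = sprintf("Type-2 ROC (AUROC-2 = %.3f)", auroc2(object))
    )
}

#' Condition-wise plot of subject summaries
#'
#' Dot-and-interval display of one summary variable by memory condition,
#' one point per subject.
#'
#' @param summaries Output of [subject_summaries()].
#' @param variable Column to display (default `"auroc2"`).
#' @return A ggplot object.
#' @export
plot_subject_summaries <- function(summaries, variable = "auroc2") {
  if (!variable %in% names(summaries)) {
    abort(sprintf("column `%s` not found in summaries", variable))
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$condition,
                               y = .data[[variable]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_cl_normal,
                          geom = "pointrange", colour = "red") +
    ggplot2::labs(x = "memory condition", y = variable)
}
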