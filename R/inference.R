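#' Paired-samples t-test, tidy result
#'
#' Dependent-samples t-test on `x - y`, reported as a one-row tibble in the
#' layout shared by all frequentist tests in this package. The effect size
#' uses the within-subject convention `d = |t| / sqrt(n)` (Cohen's d on the
#' paired-differences SD scale).
#'
#' @param x,y Paired per-subject values (equal length, `n >= 2`).
#' @param alpha Significance level recorded with the result.
#' @return A one-row tibble: `kind`, `statistic`, `df`, `p_value`,
#'   `mean_difference`, `sd_difference`, `effect_size_d`, `alpha`, `n`.
#' @examples
#' paired_t(rnorm(20, 0.5), rnorm(20))
#' @export
paired_t <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) abort("need at least 2 complete pairs.")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      # identical vectors carry no evidence either way
      return(tibble::tibble(
        kind = "paired_t", statistic = 0, df = n - 1, p_value = 1,
        mean_difference = 0, sd_difference = 0, effect_size_d = 0,
        alpha = alpha, n = n
      ))
    }
    abort("constant non-zero paired differences: t undefined.")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    kind = "paired_t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_difference = mean(d),
    sd_difference = sd(d),
    effect_size_d = cohens_d_from_t(unname(tt$statistic), n),
    alpha = alpha,
    n = n
  )
}

#' Cohen's d from a paired t statistic
#'
#' The within-subject conversion `d = |t| / sqrt(n)`: e.g. t = 4.68 with
#' n = 101 subjects gives d = 0.47.
#'
#' @param t t statistic.
#' @param n Number of subjects (pairs).
#' @return Nonnegative effect size d.
#' @export
cohens_d_from_t <- function(t, n) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  abs(t) / sqrt(n)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests against the lower and upper equivalence
#' bounds. Standardized bounds are interpreted on the paired-differences SD
#' scale (Cohen's d_z, matching the `d = |t| / sqrt(n)` convention) and
#' converted to raw units via the sample SD of the differences. The reported
#' p-value is the larger of the two one-sided p-values, and the reported t
#' statistic is the one-sided statistic attaining it; equivalence is claimed
#' when `p_value < alpha`.
#'
#' @inheritParams paired_t
#' @param lower,upper Equivalence bounds, `lower < upper`.
#' @param standardized If `TRUE` (default) bounds are in d_z units, else raw.
#' @param alpha Per-one-sided-test significance level.
#' @return A one-row tibble as in [paired_t()], plus `bound_lower`,
#'   `bound_upper`, `bounds_scale` and `equivalent`.
#' @examples
#' tost_paired(rnorm(50), rnorm(50), lower = -0.325, upper = 0.325)
#' @export
tost_paired <- function(x, y, lower, upper, standardized = TRUE,
                        alpha = 0.05) {
  if (lower >= upper) abort("`lower` must be < `upper`.")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) abort("need at least 2 complete pairs.")
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) abort("zero variance of paired differences: TOST undefined.")
  raw_l <- if (standardized) lower * sdd else lower
  raw_u <- if (standardized) upper * sdd else upper
  se <- sdd / sqrt(n)
  df <- n - 1
  t_lower <- (mean(d) - raw_l) / se # H0: diff <= lower, reject when large
  t_upper <- (mean(d) - raw_u) / se # H0: diff >= upper, reject when small
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df)
  which_max <- if (p_lower >= p_upper) "lower" else "upper"
  p <- max(p_lower, p_upper)
  tibble::tibble(
    kind = "tost",
    statistic = if (which_max == "lower") t_lower else t_upper,
    df = df,
    p_value = p,
    mean_difference = mean(d),
    sd_difference = sdd,
    effect_size_d = mean(d) / sdd,
    bound_lower = lower,
    bound_upper = upper,
    bounds_scale = if (standardized) "standardized" else "raw",
    alpha = alpha,
    n = n,
    equivalent = p < alpha
  )
}

#' Partial eta-squared from an F statistic
#'
#' `F * df_effect / (F * df_effect + df_error)`, the conversion used to
#' carry effect sizes from previously reported ANOVAs into the power
#' analysis.
#'
#' @param F F statistic (>= 0).
#' @param df_effect,df_error Degrees of freedom (>= 1).
#' @return Partial eta-squared in `[0, 1]`.
#' @export
partial_eta_sq <- function(F, df_effect, df_error) {
  if (any(F < 0)) abort("`F` must be >= 0.")
  if (any(df_effect < 1) || any(df_error < 1)) {
    abort("degrees of freedom must be >= 1.")
  }
  F * df_effect / (F * df_effect + df_error)
}

#' Modal set size of a vector (smaller value on ties)
#' @noRd
modal_set_size <- function(n_items) {
  tab <- table(n_items)
  as.integer(names(tab)[which.max(tab)]) # which.max takes the first = smallest
}

#' Set-size-variability control analyses
#'
#' The three exploratory controls for staircase-induced difficulty mixing:
#'
#' 1. a paired t-test comparing the per-subject SD of the number of items
#'    between conditions;
#' 2. an OLS regression (two rows per subject) of AUROC-2 on the
#'    z-normalized set-size SD, a WM indicator, and their interaction --
#'    normalization makes the WM coefficient the metacognition gap at the
#'    average set-size variability;
#' 3. AUROC-2 recomputed per subject x condition using only trials at that
#'    cell's most frequent set size (ties broken toward the smaller set
#'    size), compared with a paired t-test and a TOST (standardized bounds
#'    +-0.325), both at alpha = 0.025.
#'
#' Subjects whose modal-set-size subset is accuracy-degenerate in either
#' condition are dropped from (3) with a warning.
#'
#' @param summaries Output of [subject_summaries()].
#' @param trials The analysis-ready trials the summaries came from.
#' @param tost_bounds Standardized equivalence bounds for control (3).
#' @param alpha Significance level for the modal-set-size tests (0.025).
#' @return A list with elements `sd_comparison` (TestResult tibble),
#'   `regression` (term/estimate/SE/t/p tibble), `modal_t`, `modal_tost`,
#'   and `modal_summaries`.
#' @export
setsize_variability_analysis <- function(summaries, trials,
                                         tost_bounds = c(-0.325, 0.325),
                                         alpha = 0.025) {
  wide <- summaries |>
    dplyr::select("subject_id", "condition", "sd_items", "auroc2") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("sd_items", "auroc2"))
  if (nrow(wide) < 2) abort("need at least 2 retained subjects.")
  sd_comparison <- paired_t(wide$sd_items_WM, wide$sd_items_IM)

  reg_data <- summaries |>
    dplyr::mutate(
      wm = as.integer(.data$condition == "WM"),
      sd_items_z = as.numeric(scale(.data$sd_items))
    )
  fit <- lm(auroc2 ~ sd_items_z * wm, data = reg_data)
  cf <- summary(fit)$coefficients
  regression <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )

  modal_summaries <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      modal_n_items = modal_set_size(.data$n_items),
      auroc2_modal = auroc2(
        .data$confidence[.data$n_items == modal_set_size(.data$n_items)],
        .data$correct[.data$n_items == modal_set_size(.data$n_items)]
      ),
      .groups = "drop"
    )
  modal_wide <- modal_summaries |>
    dplyr::select("subject_id", "condition", "auroc2_modal") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "auroc2_modal")
  degenerate <- !complete.cases(modal_wide$IM, modal_wide$WM)
  if (any(degenerate)) {
    warn(sprintf(
      "%d subject(s) dropped from the modal-set-size control (degenerate accuracy)",
      sum(degenerate)
    ))
  }
  modal_wide <- modal_wide[!degenerate, , drop = FALSE]
  modal_t <- paired_t(modal_wide$WM, modal_wide$IM, alpha = alpha)
  modal_tost <- tost_paired(modal_wide$WM, modal_wide$IM,
                            lower = tost_bounds[1], upper = tost_bounds[2],
                            standardized = TRUE, alpha = alpha)
  list(
    sd_comparison = sd_comparison,
    regression = regression,
    modal_t = modal_t,
    modal_tost = modal_tost,
    modal_summaries = modal_summaries
  )
}
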