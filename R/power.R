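#' Power of a paired two-sided t-test
#'
#' Exact noncentral-t power: with `n` pairs, standardized effect `d`
#' (paired-differences scale) and two-sided level `alpha`, the test statistic
#' is noncentral t with `df = n - 1` and noncentrality `d * sqrt(n)`; power
#' is the probability it exceeds the two-sided critical value.
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardized effect size (its absolute value is used).
#' @param alpha Two-sided type-I error rate.
#' @param tails Number of tails (2, the design used here; 1 supported).
#' @return Power in `[0, 1]`.
#' @examples
#' power_paired_t(101, 0.325, alpha = 0.025) # 0.837
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  if (any(n < 2)) abort("`n` must be >= 2.")
  d <- abs(d)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    1 - pt(tc, df, ncp)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest integer `n` whose [power_paired_t()] reaches `power`.
#'
#' @inheritParams power_paired_t
#' @param power Target power in (0, 1).
#' @param n_max Search cap, after which a no-solution error is raised.
#' @return An integer sample size.
#' @examples
#' required_n_paired_t(0.325, alpha = 0.025, power = 0.80) # 93
#' @export
required_n_paired_t <- function(d, alpha = 0.05, power = 0.80, tails = 2,
                                n_max = 1e6) {
  stopifnot(power > 0, power < 1)
  if (abs(d) < 1e-12) abort("no finite n reaches the target power at d = 0.")
  # coarse doubling then exact scan keeps this O(log n)
  lo <- 2
  hi <- 4
  while (power_paired_t(hi, d, alpha, tails) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) abort("target power unattainable within `n_max`.")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (power_paired_t(mid, d, alpha, tails) >= power) hi <- mid
    else lo <- mid + 1
  }
  as.integer(hi)
}

#' Sensitivity: detectable effect size of a paired t-test
#'
#' The standardized effect `d` that a paired t-test with `n` pairs detects
#' with the given power at level `alpha` (root of the power function in
#' `d`); the small-telescopes SESOI computation uses `n = 24`,
#' `alpha = 0.05`, `power = 0.33`.
#'
#' @inheritParams required_n_paired_t
#' @param n Number of pairs.
#' @return The effect size d (> 0).
#' @examples
#' sensitivity_d_paired_t(24, alpha = 0.05, power = 0.33) # ~0.325
#' @export
sensitivity_d_paired_t <- function(n, alpha = 0.05, power = 0.80,
                                   tails = 2) {
  if (power < alpha) {
    abort("`power` below `alpha`: no nonnegative detectable effect exists.")
  }
  if (power == alpha) return(0) # the null is 'detected' at the test's size
  uniroot(
    function(d) power_paired_t(n, d, alpha, tails) - power,
    lower = 1e-8, upper = 20, tol = 1e-10
  )$root
}

# exact paired TOST power by integrating the rejection region over the
# sampling distribution of the sd of differences (Owen-Q style)
tost_power_exact <- function(n, lower, upper, alpha, sd_diff, true_diff) {
  df <- n - 1
  tc <- qt(1 - alpha, df)
  width <- (upper - lower) / 2
  s_max <- width * sqrt(n) / tc # beyond this the rejection interval is empty
  f <- function(s) {
    dens <- 2 * s * df * dchisq(s^2 * df / sd_diff^2, df) / sd_diff^2
    lo <- (lower + tc * s / sqrt(n) - true_diff) * sqrt(n) / sd_diff
    hi <- (upper - tc * s / sqrt(n) - true_diff) * sqrt(n) / sd_diff
    pmax(0, pnorm(hi) - pnorm(lo)) * dens
  }
  integrate(f, 0, s_max, rel.tol = 1e-10)$value
}

#' Power or required n of a paired TOST equivalence test
#'
#' Exact power of the two-one-sided-tests procedure for a paired design:
#' the probability that both one-sided t-tests (each at level `alpha`)
#' reject, computed by integrating the joint rejection region over the
#' sampling distribution of the paired-differences SD (equivalent to the
#' Owen's-Q formulation). Standardized bounds are in units of the
#' paired-differences SD (then `sd_diff` is fixed at 1 and `true_diff` is on
#' the same scale); raw bounds require `sd_diff`. If `n` is `NULL`, the
#' smallest `n` reaching `power` is returned instead.
#'
#' @param n Number of pairs, or `NULL` to solve for it.
#' @param lower,upper Equivalence bounds (`lower < upper`).
#' @param alpha Level of each one-sided test.
#' @param true_diff True mean difference (same scale as the bounds).
#' @param sd_diff SD of the paired differences (raw-bound designs).
#' @param standardized If `TRUE` bounds and `true_diff` are in SD units.
#' @param power Target power when solving for `n`.
#' @param n_max Search cap for the sample-size search.
#' @return Power in `[0, 1]`, or the required integer `n`.
#' @examples
#' power_tost_paired(101, -0.05, 0.05, alpha = 0.05,
#'                   sd_diff = 0.01, standardized = FALSE) # > 0.99
#' power_tost_paired(NULL, -0.325, 0.325, alpha = 0.025, power = 0.80)
#' @export
power_tost_paired <- function(n = NULL, lower, upper, alpha = 0.05,
                              true_diff = 0, sd_diff = NULL,
                              standardized = is.null(sd_diff),
                              power = 0.80, n_max = 1e5) {
  if (lower >= upper) abort("`lower` must be < `upper`.")
  if (standardized) {
    sd_diff <- 1
  } else if (is.null(sd_diff)) {
    abort("raw bounds require `sd_diff`.")
  }
  pw <- function(nn) tost_power_exact(nn, lower, upper, alpha, sd_diff,
                                      true_diff)
  if (!is.null(n)) {
    if (n < 2) abort("`n` must be >= 2.")
    return(pw(n))
  }
  stopifnot(power > 0, power < 1)
  lo <- 2
  hi <- 4
  while (pw(hi) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) abort("target power unattainable within `n_max`.")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

#' Simulation-based power for the IM coefficient of the confidence model
#'
#' For each candidate value of the IM coefficient, repeatedly generates
#' confidence datasets from the ordered-probit process (all other
#' generative coefficients fixed), fits the pre-registered random-intercept
#' model, and records how often the Wald test on the IM coefficient is
#' significant; the proportion is the simulated power. Each replicate's
#' Wald statistic is also converted to a Cohen's d via `d = |t| / sqrt(n)`
#' for comparison with published effect sizes.
#'
#' @param beta_grid IM-coefficient values to scan (latent probit scale).
#' @param params An [observer_params()] whose other coefficients define the
#'   generative model; its `beta_im` is overridden by the grid and
#'   meta-noise is zeroed so the data follow the fitted model exactly.
#' @param n_subjects,n_trials Simulated design (study scale: 101 x 400).
#' @param reps Replicates per grid value.
#' @param alpha Wald significance level.
#' @param n_quad Quadrature nodes for the fits.
#' @return A tibble of class `simpower` with one row per grid value:
#'   `beta_im`, `power`, `reps_used` (converged replicates), `mean_d`,
#'   `sd_d`, `n_subjects`, `n_trials`.
#' @export
simulate_ordinal_power <- function(beta_grid,
                                   params = observer_params(),
                                   n_subjects = 101L, n_trials = 400L,
                                   reps = 100L, alpha = 0.05,
                                   n_quad = 7L) {
  params$meta_noise_im <- 0
  params$meta_noise_wm <- 0
  rows <- purrr::map(beta_grid, function(b) {
    params$beta_im <- b
    sig <- logical(0)
    dvals <- numeric(0)
    failed <- 0L
    for (r in seq_len(reps)) {
      dat <- simulate_confidence_data(n_subjects, n_trials, params)
      fit <- tryCatch(
        fit_cumulative_probit(dat, "model1", n_quad = n_quad),
        error = function(e) NULL
      )
      if (is.null(fit)) { failed <- failed + 1L; next }
      td <- tidy(fit)
      row <- td[td$term == "IM", ]
      sig <- c(sig, row$p_value < alpha)
      dvals <- c(dvals, cohens_d_from_t(row$statistic, n_subjects))
    }
    tibble::tibble(
      beta_im = b, power = mean(sig), reps_used = length(sig),
      reps_failed = failed, mean_d = mean(dvals), sd_d = sd(dvals),
      n_subjects = n_subjects, n_trials = n_trials
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("simpower", class(out))
  out
}

#' @export
#' @rdname simulate_ordinal_power
#' @param object,x A `simpower` tibble.
#' @param ... Unused.
autoplot.simpower <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_im, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.80, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "IM coefficient (latent probit scale)",
                  y = "simulated power")
}
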