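test_that("with no subject variance the fit matches a pooled-ML oracle", {
  skip_if_not_installed("MASS")
  set.seed(441)
  dat <- simulate_confidence_data(
    30, 120, observer_params(meta_noise_im = 0, sigma_u = 0)
  )
  pol <- MASS::polr(
    factor(confidence) ~ I(as.numeric(condition == "IM")) + n_items + correct,
    data = dat, method = "probit"
  )
  # variance collapsed to the boundary: the marginal fit is the pooled fit
  fit0 <- fit_cumulative_probit(dat, "model1", n_quad = 7,
                                sigma_fixed = 1e-3)
  expect_true(fit0$boundary)
  expect_lt(max(abs(fit0$beta - coef(pol))), 1e-3)
  expect_lt(max(abs(fit0$tau - pol$zeta)), 1e-3)
  expect_lt(abs(fit0$log_likelihood - as.numeric(logLik(pol))), 1e-2)
  # and the freely estimated variance stays near zero without losing fit
  fit <- fit_cumulative_probit(dat, "model1", n_quad = 7)
  expect_lt(fit$sigma_u, 0.12)
  expect_gte(fit$log_likelihood, as.numeric(logLik(pol)) - 1e-6)
})

test_that("fitted category probabilities sum to one everywhere", {
  set.seed(442)
  dat <- simulate_confidence_data(10, 60)
  for (m in c("model1", "model3")) {
    fit <- fit_cumulative_probit(dat, m, n_quad = 5, se = FALSE)
    pr <- fitted_category_probs(fit)
    expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
    expect_true(all(pr >= 0))
  }
})

test_that("the quadrature is converged at the default node counts", {
  set.seed(443)
  dat <- simulate_confidence_data(15, 80,
                                  observer_params(meta_noise_im = 0,
                                                  sigma_u = 0.6))
  fit <- fit_cumulative_probit(dat, "model1", n_quad = 7, se = FALSE)
  ll20 <- cumprobit_loglik(fit, 20)
  ll50 <- cumprobit_loglik(fit, 50)
  expect_lt(abs(ll20 - ll50) / fit$n_obs, 1e-4)
})

test_that("model-1 fits recover generative coefficients within Wald error", {
  set.seed(444)
  p <- observer_params(meta_noise_im = 0, beta_im = -0.1,
                       beta_n_items = -0.12, beta_accuracy = 1.3,
                       sigma_u = 0.5)
  dat <- simulate_confidence_data(60, 200, p)
  fit <- fit_cumulative_probit(dat, "model1", n_quad = 7)
  truth <- c(IM = -0.1, nItems = -0.12, accuracy = 1.3)
  for (term in names(truth)) {
    expect_lt(abs(fit$beta[[term]] - truth[[term]]),
              3.2 * fit$se_beta[[term]])
  }
  expect_lt(abs(fit$sigma_u - 0.5), 0.15)
})

test_that("estimates survive strong IM-by-set-size correlation", {
  set.seed(445)
  p <- observer_params(meta_noise_im = 0, beta_im = -0.1,
                       beta_n_items = -0.12, beta_accuracy = 1.3,
                       sigma_u = 0.5)
  dat <- simulate_confidence_data(60, 200, p, im_n_items_cor = 0.77)
  fit <- fit_cumulative_probit(dat, "model1", n_quad = 7)
  truth <- c(IM = -0.1, nItems = -0.12, accuracy = 1.3)
  for (term in names(truth)) {
    expect_lt(abs(fit$beta[[term]] - truth[[term]]),
              3.2 * fit$se_beta[[term]])
  }
})

test_that("the Wald test on the IM coefficient holds its size", {
  set.seed(446)
  p <- observer_params(meta_noise_im = 0, beta_im = 0, sigma_u = 0.4)
  hits <- vapply(1:100, function(i) {
    dat <- simulate_confidence_data(20, 80, p)
    fit <- fit_cumulative_probit(dat, "model1", n_quad = 5)
    td <- tidy(fit)
    td$p_value[td$term == "IM"] < 0.05
  }, logical(1))
  # binomial(100, 0.05): reject calibration only far outside sampling noise
  expect_lt(abs(mean(hits) - 0.05), 0.06)
})

test_that("AIC comparison requires matched data and is antisymmetric", {
  set.seed(447)
  dat <- simulate_confidence_data(12, 60)
  f1 <- fit_cumulative_probit(dat, "model1", n_quad = 5, se = FALSE)
  f2 <- fit_cumulative_probit(dat, "model2", n_quad = 5, se = FALSE)
  self <- compare_aic(f1, f1)
  expect_equal(self$delta_aic, 0)
  ab <- compare_aic(f1, f2)
  ba <- compare_aic(f2, f1)
  expect_equal(ab$delta_aic, -ba$delta_aic)
  dat2 <- simulate_confidence_data(12, 50)
  f3 <- fit_cumulative_probit(dat2, "model1", n_quad = 5, se = FALSE)
  expect_error(compare_aic(f1, f3), "identical observation")
  # AIC equals 2k - 2 logLik by construction
  expect_equal(f2$aic, 2 * f2$n_par - 2 * f2$log_likelihood)
})

test_that("AIC prefers the generating complexity class", {
  set.seed(448)
  # heterogeneous subject slopes: the full random-effects model should win
  wins3 <- vapply(1:5, function(i) {
    dat <- make_random_slope_data(24, 120, beta = c(-0.1, -0.12, 1.3, -0.2))
    f2 <- fit_cumulative_probit(dat, "model2", n_quad = 5, se = FALSE)
    f3 <- fit_cumulative_probit(dat, "model3", se = FALSE)
    compare_aic(f2, f3)$preferred == "model3"
  }, logical(1))
  expect_gte(mean(wins3), 0.8)
  # intercept-only generator: the leaner model should win on average
  dat <- simulate_confidence_data(24, 120,
                                  observer_params(meta_noise_im = 0,
                                                  sigma_u = 0.5))
  f2 <- fit_cumulative_probit(dat, "model2", n_quad = 5, se = FALSE)
  f3 <- fit_cumulative_probit(dat, "model3", se = FALSE)
  expect_equal(compare_aic(f2, f3)$preferred, "model2")
})

test_that("per-subject coefficient test has exact df and finds true slopes", {
  set.seed(449)
  dat <- make_random_slope_data(30, 120, beta = c(0.5, -0.12, 1.3, 0),
                                sd_u = c(0.4, 0.15, 0.3, 0.15, 0.05))
  f3 <- fit_cumulative_probit(dat, "model3", se = FALSE)
  res <- subject_coefficient_test(f3, "IM")
  expect_equal(res$df, 29)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_difference, 0)
  expect_error(subject_coefficient_test(f3, "nope"), "random slope")
  f1 <- fit_cumulative_probit(dat, "model1", n_quad = 5, se = FALSE)
  expect_error(subject_coefficient_test(f1, "IM"), "random slope")
})

test_that("tidy and glance expose the broom-style surfaces", {
  set.seed(450)
  dat <- simulate_confidence_data(10, 60)
  fit <- fit_cumulative_probit(dat, "model1", n_quad = 5)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "statistic",
                    "p_value", "coef_type") %in% names(td)))
  expect_setequal(td$term[td$coef_type == "location"],
                  c("IM", "nItems", "accuracy"))
  g <- glance(fit)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_obs, nrow(dat))
})
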