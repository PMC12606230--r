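test_that("analytic power reproduces the design's printed values", {
  expect_equal(required_n_paired_t(0.325, alpha = 0.025, power = 0.80), 93L)
  expect_equal(round(100 * power_paired_t(101, 0.325, alpha = 0.025), 1),
               83.7)
  expect_equal(sensitivity_d_paired_t(24, alpha = 0.05, power = 0.33),
               0.325, tolerance = 0.005)
})

test_that("power function has size alpha and the documented monotonicity", {
  for (a in c(0.025, 0.05)) {
    expect_equal(power_paired_t(40, 0, alpha = a), a, tolerance = 1e-10)
  }
  p_n <- vapply(seq(10, 200, by = 10), power_paired_t, numeric(1),
                d = 0.3, alpha = 0.05)
  expect_true(all(diff(p_n) > 0))
  p_d <- vapply(seq(0.05, 1, by = 0.05), function(d) {
    power_paired_t(30, d, alpha = 0.05)
  }, numeric(1))
  expect_true(all(diff(p_d) > 0))
})

test_that("analytic power agrees with brute-force simulation", {
  set.seed(451)
  reps <- 1e5
  n <- 50
  m <- matrix(rnorm(reps * n, mean = 0.5), reps, n)
  t_stat <- rowMeans(m) / (apply(m, 1, sd) / sqrt(n))
  emp <- mean(abs(t_stat) > qt(0.975, n - 1))
  se <- sqrt(emp * (1 - emp) / reps)
  expect_lt(abs(power_paired_t(50, 0.5, alpha = 0.05) - emp), 3 * se)
})

test_that("required n and sensitivity d invert the power function", {
  for (d in c(0.2, 0.5)) {
    n <- required_n_paired_t(d, alpha = 0.05, power = 0.80)
    expect_gte(power_paired_t(n, d, alpha = 0.05), 0.80)
    expect_lt(power_paired_t(n - 1, d, alpha = 0.05), 0.80)
  }
  expect_equal(required_n_paired_t(50, alpha = 0.05, power = 0.8), 2L)
  expect_error(required_n_paired_t(0, alpha = 0.05, power = 0.8), "d = 0")
  d_star <- sensitivity_d_paired_t(36, alpha = 0.05, power = 0.6)
  expect_equal(power_paired_t(36, d_star, alpha = 0.05), 0.6,
               tolerance = 1e-6)
  expect_equal(sensitivity_d_paired_t(30, alpha = 0.05, power = 0.05), 0)
})

test_that("exact TOST power matches its Monte-Carlo frozen value", {
  # exact computation gives n = 102 for the standardized +-0.325 design at
  # alpha 0.025 (power(101) = 0.7976, Monte-Carlo verified); the published
  # table reports 101 from a large-sample approximation
  expect_equal(power_tost_paired(101, -0.325, 0.325, alpha = 0.025),
               0.7976, tolerance = 5e-4)
  expect_equal(power_tost_paired(NULL, -0.325, 0.325, alpha = 0.025,
                                 power = 0.80), 102L)
})

test_that("TOST power grows with n and bound width, shrinks at the boundary", {
  p_n <- vapply(c(30, 60, 120, 240), function(n) {
    power_tost_paired(n, -0.3, 0.3, alpha = 0.05)
  }, numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_b <- vapply(c(0.2, 0.3, 0.45, 0.7), function(b) {
    power_tost_paired(80, -b, b, alpha = 0.05)
  }, numeric(1))
  expect_true(all(diff(p_b) > 0))
  # true difference on the bound: power collapses to the one-sided size
  expect_equal(power_tost_paired(101, -0.325, 0.325, alpha = 0.025,
                                 true_diff = 0.325), 0.025,
               tolerance = 0.004)
  # raw-bounds control design: essentially certain equivalence
  expect_gt(power_tost_paired(101, -0.05, 0.05, alpha = 0.05,
                              sd_diff = 0.01), 0.99)
})

test_that("simulated ordinal power is near alpha at zero and rises with beta", {
  set.seed(452)
  res <- simulate_ordinal_power(
    beta_grid = c(0, 0.3),
    params = observer_params(sigma_u = 0.4),
    n_subjects = 15, n_trials = 80, reps = 16, alpha = 0.05, n_quad = 5
  )
  expect_equal(nrow(res), 2L)
  p0 <- res$power[res$beta_im == 0]
  expect_lt(p0, 0.05 + 3 * sqrt(0.05 * 0.95 / 16) + 1e-9)
  expect_gt(res$power[res$beta_im == 0.3], p0)
  expect_true(all(res$reps_used == 16))
  expect_true(all(is.finite(res$mean_d)))
})
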