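test_that("paired t matches the textbook formula", {
  set.seed(421)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- paired_t(x, y)
    d <- x - y
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * pt(-abs(t_ref), n - 1)
    expect_equal(res$statistic, t_ref, tolerance = 1e-10)
    expect_equal(res$p_value, p_ref, tolerance = 1e-10)
    expect_equal(res$df, n - 1)
    expect_equal(res$effect_size_d, abs(t_ref) / sqrt(n), tolerance = 1e-10)
  }
})

test_that("identical vectors give t = 0, p = 1; constant shifts keep the sign", {
  x <- rnorm(10)
  res <- paired_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(422)
  for (delta in c(-0.8, 0.5)) {
    y <- rnorm(25)
    res <- paired_t(y + delta + rnorm(25, 0, 0.1), y)
    expect_equal(sign(res$statistic), sign(delta))
  }
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("the d = |t|/sqrt(n) convention reproduces the published values", {
  expect_equal(round(cohens_d_from_t(4.68, 101), 2), 0.47)
  expect_equal(round(cohens_d_from_t(-3.22, 101), 2), 0.32)
  expect_equal(cohens_d_from_t(0, 57), 0)
  expect_error(cohens_d_from_t(1, 0), "n")
})

test_that("paired t holds its nominal size under the null", {
  set.seed(423)
  reps <- 10000
  n <- 20
  m <- matrix(rnorm(reps * n), reps, n)
  mm <- rowMeans(m)
  ss <- apply(m, 1, sd)
  t_stat <- mm / (ss / sqrt(n))
  rate <- mean(2 * pt(-abs(t_stat), n - 1) < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / reps) + 0.002)
  # and through the package function on a subsample
  hits <- vapply(1:500, function(i) {
    paired_t(m[i, ], rep(0, n))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("TOST is symmetric and the max-p convention holds", {
  set.seed(424)
  x <- rnorm(30)
  y <- rnorm(30)
  a <- tost_paired(x, y, -0.4, 0.4)
  b <- tost_paired(y, x, -0.4, 0.4)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # recompute the two one-sided tests by hand
  d <- x - y
  se <- sd(d) / sqrt(30)
  t_l <- (mean(d) + 0.4 * sd(d)) / se
  t_u <- (mean(d) - 0.4 * sd(d)) / se
  expect_equal(a$p_value,
               max(pt(t_l, 29, lower.tail = FALSE), pt(t_u, 29)),
               tolerance = 1e-12)
})

test_that("TOST verdicts move with the bounds", {
  set.seed(425)
  x <- rnorm(40)
  y <- x + rnorm(40, 0, 0.3)
  expect_true(tost_paired(x, y, -Inf, Inf)$equivalent)
  expect_false(tost_paired(x, y, -1e-9, 1e-9)$equivalent)
  # a tight effect far inside wide bounds is equivalent at p < 0.001
  big <- tost_paired(rnorm(200, 0, 0.01), rnorm(200, 0, 0.01),
                     -0.325, 0.325)
  expect_lt(big$p_value, 0.001)
})

test_that("TOST rejects at about its nominal rate on the equivalence boundary", {
  set.seed(426)
  reps <- 10000
  n <- 101
  b <- 0.325
  m <- matrix(rnorm(reps * n, mean = b), reps, n)
  mm <- rowMeans(m)
  ss <- apply(m, 1, sd)
  se <- ss / sqrt(n)
  p <- pmax(pt((mm + b * ss) / se, n - 1, lower.tail = FALSE),
            pt((mm - b * ss) / se, n - 1))
  rate <- mean(p < 0.025)
  expect_lt(abs(rate - 0.025), 2 * sqrt(0.025 * 0.975 / reps) + 0.002)
})

test_that("partial eta squared is the printed ratio", {
  expect_equal(partial_eta_sq(1, 1, 1), 0.5)
  expect_equal(partial_eta_sq(0, 3, 96), 0)
  set.seed(427)
  for (rep in 1:20) {
    F <- runif(1, 0, 20)
    d1 <- sample(1:5, 1)
    d2 <- sample(10:200, 1)
    expect_equal(partial_eta_sq(F, d1, d2), F * d1 / (F * d1 + d2),
                 tolerance = 1e-12)
  }
  expect_error(partial_eta_sq(-1, 1, 10), "F")
})

test_that("paired t and TOST agree with closed-form arithmetic on toy data", {
  x <- c(0.60, 0.55, 0.65)
  y <- c(0.50, 0.52, 0.58)
  d <- x - y
  res <- paired_t(x, y)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  tt <- tost_paired(x, y, -1, 1, standardized = TRUE)
  expect_equal(tt$statistic,
               (mean(d) - sd(d)) / (sd(d) / sqrt(3)), tolerance = 1e-12)
})
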