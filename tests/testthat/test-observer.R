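test_that("slot-model accuracy has the right limits and shape", {
  expect_equal(p_correct(4, capacity = 8, lapse = 0), 1)
  expect_equal(p_correct(10, capacity = 0, lapse = 0), 1 / 10)
  # non-increasing in set size, for several capacities
  for (cap in c(0, 2, 4.5, 7)) {
    p <- p_correct(1:16, capacity = cap, lapse = 0.02)
    expect_true(all(diff(p) <= 1e-12))
  }
  expect_error(p_correct(0, 4), "n_items")
})

test_that("slot-model accuracy matches a brute-force slot simulation", {
  # encode 4 of 8 items uniformly; guess a position uniformly if the probed
  # item was not encoded
  set.seed(402)
  n_mc <- 1e5
  hits <- replicate(n_mc, {
    stored <- sample(8, 4)
    probe <- sample(8, 1)
    if (probe %in% stored) 1L else as.integer(sample(8, 1) == probe)
  })
  p_hat <- mean(hits)
  se <- sqrt(p_hat * (1 - p_hat) / n_mc)
  expect_lt(abs(p_correct(8, capacity = 4, lapse = 0) - p_hat), 3 * se)
})

test_that("staircase follows the 1-up/1-down rule with bounds", {
  s <- staircase_new("IM", start = 8)
  s <- staircase_update(s, "correct")
  expect_equal(s$current_n_items, 9L)
  s <- staircase_update(s, "no_response")
  expect_equal(s$current_n_items, 9L)
  s <- staircase_update(s, "incorrect")
  expect_equal(s$current_n_items, 8L)

  top <- staircase_new("WM", start = 16)
  expect_equal(staircase_update(top, "correct")$current_n_items, 16L)
  bottom <- staircase_new("WM", start = 1)
  expect_equal(staircase_update(bottom, "incorrect")$current_n_items, 1L)
})

test_that("staircase never leaves its bounds on random outcome streams", {
  set.seed(403)
  s <- staircase_new("IM", start = 8)
  outcomes <- sample(c("correct", "incorrect", "no_response"), 2000,
                     replace = TRUE, prob = c(0.45, 0.45, 0.1))
  for (o in outcomes) {
    s <- staircase_update(s, o)
    expect_true(s$current_n_items >= 1 && s$current_n_items <= 16)
  }
  expect_length(s$history, 2000)
})

test_that("degenerate thresholds pin confidence to the bottom level", {
  p <- observer_params(tau = c(10, 11, 12))
  set.seed(404)
  conf <- generate_confidence(rbinom(500, 1, 0.5), 8, "IM", 0, p)
  expect_true(all(conf == 1L))
  bad <- observer_params()
  bad$tau <- c(1, 1, 2)
  expect_error(generate_confidence(1, 8, "IM", 0, bad), "increasing")
})

test_that("empirical confidence frequencies match the closed-form probit", {
  set.seed(405)
  p <- observer_params(meta_noise_im = 0.4, sigma_u = 0.5)
  n_mc <- 1e5
  for (case in list(list(acc = 1, n = 6, cond = "IM", u = 0.3),
                    list(acc = 0, n = 12, cond = "WM", u = -0.5))) {
    conf <- generate_confidence(case$acc, case$n, case$cond, case$u, p)
    conf <- generate_confidence(rep(case$acc, n_mc), case$n, case$cond,
                                case$u, p)
    emp <- tabulate(conf, 4) / n_mc
    thr <- confidence_probs(case$acc, case$n, case$cond, case$u, p)[1, ]
    se <- sqrt(thr * (1 - thr) / n_mc)
    expect_true(all(abs(emp - thr) < 3 * se + 1e-12))
  }
})

test_that("conditions are exchangeable when the generative model is symmetric", {
  set.seed(406)
  p <- observer_params(beta_im = 0, meta_noise_im = 0, meta_noise_wm = 0)
  n_mc <- 1e5
  c_im <- generate_confidence(rep(1, n_mc), 8, "IM", 0, p)
  c_wm <- generate_confidence(rep(1, n_mc), 8, "WM", 0, p)
  tab <- rbind(tabulate(c_im, 4), tabulate(c_wm, 4))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})
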