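test_that("each exclusion rule fires with its documented reason", {
  base <- make_trial_rows(6, staircase_order = 31:36)
  base$rt_decision_s[2] <- 0.10       # fast decision
  base$rt_confidence_s[3] <- 0.12     # fast confidence
  base$rt_decision_s[4] <- NA         # decision timeout
  base$correct[4] <- NA
  base$confidence[4] <- NA
  base$rt_confidence_s[4] <- NA
  base$n_items[5] <- 3L               # too few items
  base$confidence[6] <- NA            # confidence timeout
  base$rt_confidence_s[6] <- NA
  res <- filter_trials(base)
  reasons <- res$report$trial_reasons$reason
  expect_equal(reasons,
               c("kept", "fast_rt", "fast_rt", "timeout", "too_few_items",
                 "timeout"))
  expect_equal(nrow(res$trials), 1L)
})

test_that("practice and burn-in take precedence and counts conserve", {
  trials <- simulate_experiment(experiment_config(n_subjects = 3, seed = 41))
  res <- filter_trials(trials)
  tab <- table(res$report$trial_reasons$reason)
  expect_equal(sum(tab), nrow(trials))
  expect_equal(unname(tab["practice"]), 3L * 2L * 10L)
  expect_equal(unname(tab["burn_in"]), 3L * 2L * 2L * 30L)
  expect_equal(nrow(res$trials) + sum(tab[names(tab) != "kept"]),
               nrow(trials))
  # kept trials pass every rule
  k <- res$trials
  expect_true(all(k$phase == "experimental"))
  expect_true(all(k$staircase_order > 30))
  expect_true(all(k$rt_decision_s >= 0.15 & k$rt_confidence_s >= 0.15))
  expect_true(all(k$n_items >= 4))
})

test_that("clean data leave exactly 400 valid trials per subject", {
  trials <- simulate_experiment(clean_config(n_subjects = 2, seed = 42))
  res <- preprocess_trials(trials)
  per_subj <- dplyr::count(res$trials, subject_id)
  expect_true(all(per_subj$n == 400))
  per_cond <- dplyr::count(res$trials, subject_id, condition)
  expect_true(all(per_cond$n == 200))
})

test_that("filtering is idempotent", {
  trials <- simulate_experiment(experiment_config(n_subjects = 2, seed = 43))
  once <- filter_trials(trials)$trials
  twice <- filter_trials(once)$trials
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("the 180-trial subject rule is a sharp boundary", {
  ok <- dplyr::bind_rows(
    make_trial_rows(180, condition = "IM", staircase_order = 31:210),
    make_trial_rows(200, condition = "WM", staircase_order = 31:230)
  )
  res <- filter_trials(ok)
  out <- exclude_subjects(res$trials, res$report)
  expect_true(all(out$report$subjects$subject_kept))
  expect_equal(nrow(out$trials), 380L)

  short <- dplyr::bind_rows(
    make_trial_rows(179, condition = "IM", staircase_order = 31:209),
    make_trial_rows(200, condition = "WM", staircase_order = 31:230)
  )
  res2 <- filter_trials(short)
  expect_warning(out2 <- exclude_subjects(res2$trials, res2$report),
                 "discarded")
  expect_false(any(out2$report$subjects$subject_kept))
  expect_equal(nrow(out2$trials), 0L)
})

test_that("empty input flows through without errors", {
  empty <- make_trial_rows(0)
  res <- filter_trials(empty)
  out <- exclude_subjects(res$trials, res$report)
  expect_equal(nrow(out$trials), 0L)
})

test_that("exactly-150 ms responses are kept (strict inequality)", {
  tr <- make_trial_rows(2, staircase_order = 31:32,
                        rt_decision_s = c(0.15, 0.1499),
                        rt_confidence_s = 0.15)
  res <- filter_trials(tr)
  expect_equal(res$report$trial_reasons$reason, c("kept", "fast_rt"))
})
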