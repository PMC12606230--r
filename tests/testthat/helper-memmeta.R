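# Shared fixtures and independent oracles, built in code at test time.

# Tie-corrected pairwise-comparison oracle for the type-2 ROC area:
# P(conf_correct > conf_incorrect) + 0.5 * P(tie), by exhaustive enumeration.
pairwise_auroc2 <- function(confidence, correct) {
  cc <- confidence[correct == 1]
  ci <- confidence[correct == 0]
  cmp <- outer(cc, ci, ">") + 0.5 * outer(cc, ci, "==")
  mean(cmp)
}

# Minimal well-formed trial tibble for hand-built preprocessing cases.
make_trial_rows <- function(n, subject_id = 1L, session = 1L,
                            condition = "IM", phase = "experimental",
                            n_items = 8L, correct = 1L, confidence = 3L,
                            rt_decision_s = 1, rt_confidence_s = 0.8,
                            staircase_order = NA_integer_) {
  tibble::tibble(
    subject_id = subject_id, session = session, trial_index = seq_len(n),
    phase = phase, condition = condition, n_items = n_items,
    correct = correct, confidence = confidence,
    rt_decision_s = rt_decision_s, rt_confidence_s = rt_confidence_s,
    staircase_order = staircase_order
  )
}

# A clean full-design experiment: no timeouts, no fast guesses, RTs far from
# every threshold, and capacities whose staircase fixed points keep the set
# size comfortably above 4 items -- so only practice and burn-in exclusions
# apply.
clean_config <- function(n_subjects = 2L, seed = 123L,
                         capacity_im = 7, capacity_wm = 5, ...) {
  experiment_config(
    n_subjects = n_subjects, seed = seed,
    observer = observer_params(
      capacity_im = capacity_im, capacity_wm = capacity_wm,
      rt_params = list(
        p_fast_guess = 0, p_timeout_decision = 0, p_timeout_confidence = 0,
        meanlog_decision = log(0.9), sdlog_decision = 0.1,
        meanlog_confidence = log(0.6), sdlog_confidence = 0.1
      ),
      ...
    )
  )
}

# Trial-level cohort with per-condition set-size SDs under direct control,
# equal metacognitive noise in both conditions (null-contrast generator).
make_setsize_cohort <- function(n_subjects, n_trials, sd_im, sd_wm,
                                params = observer_params(meta_noise_im = 0)) {
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    u <- rnorm(1, 0, params$sigma_u)
    purrr::map_dfr(c("IM", "WM"), function(cond) {
      sdv <- if (cond == "IM") sd_im else sd_wm
      ni <- pmin(pmax(round(rnorm(n_trials, 8, sdv)), 4L), 16L)
      corr <- rbinom(n_trials, 1L, 0.5)
      conf <- generate_confidence(corr, ni, cond, u, params)
      tibble::tibble(
        subject_id = s, condition = cond, n_items = as.integer(ni),
        correct = corr, confidence = conf
      )
    })
  })
}

# Confidence data with heterogeneous per-subject slopes (full random-effects
# generator) for model-recovery checks.
make_random_slope_data <- function(n_subjects, n_trials, beta,
                                   tau = c(-2.3, -1.1, 0.2),
                                   sd_u = c(0.5, 0.4, 0.4, 0.4, 0.1)) {
  # beta: named c(IM, nItems, accuracy, IMxacc); Z order matches the model-3
  # random-effect layout (intercept, IM, accuracy, IM:accuracy, nItems)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    u <- rnorm(5, 0, sd_u)
    im <- rbinom(n_trials, 1L, 0.5)
    ni <- pmin(pmax(round(rnorm(n_trials, 8, 2)), 1L), 16L)
    acc <- rbinom(n_trials, 1L, 0.5)
    eta <- (beta[1] + u[2]) * im + (beta[2] + u[5]) * ni +
      (beta[3] + u[3]) * acc + (beta[4] + u[4]) * im * acc + u[1]
    latent <- eta + rnorm(n_trials)
    tibble::tibble(
      subject_id = s, condition = ifelse(im == 1, "IM", "WM"),
      n_items = as.integer(ni), correct = acc,
      confidence = as.integer(findInterval(latent, tau) + 1L)
    )
  })
}
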