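#' Experiment configuration
#'
#' Bookkeeping of the simulated partial-report experiment: two sessions of
#' 270 trials each (10 practice + 130 experimental trials per memory
#' condition), independent per-condition staircases that restart at each
#' session, and a 30-trial per-condition per-session stabilization (burn-in)
#' window that the analysis later discards -- leaving 400 valid trials per
#' subject (270 x 2 - 2 x 10 practice - 2 x 2 x 30 burn-in).
#'
#' @param n_subjects Number of simulated subjects (study condition: 101).
#' @param sessions_per_subject Number of sessions (2).
#' @param trials_per_session Total trials per session (270).
#' @param practice_per_session Practice trials opening each session (10,
#'   split evenly between conditions).
#' @param staircase_burn_in Experimental trials per condition per session
#'   that the exclusion rules treat as staircase stabilization (30).
#' @param staircase_start Initial set size of each staircase (8).
#' @param observer An [observer_params()] object.
#' @param seed Optional integer seed; if `NULL` the caller's RNG state is
#'   used as-is.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 101L,
                              sessions_per_subject = 2L,
                              trials_per_session = 270L,
                              practice_per_session = 10L,
                              staircase_burn_in = 30L,
                              staircase_start = 8L,
                              observer = observer_params(),
                              seed = NULL) {
  stopifnot(n_subjects >= 1, sessions_per_subject >= 1,
            practice_per_session %% 2 == 0,
            trials_per_session > practice_per_session,
            (trials_per_session - practice_per_session) %% 2 == 0)
  exp_per_cond <- (trials_per_session - practice_per_session) %/% 2L
  if (staircase_burn_in >= exp_per_cond) {
    abort("`staircase_burn_in` must leave experimental trials per condition.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      sessions_per_subject = as.integer(sessions_per_subject),
      trials_per_session = as.integer(trials_per_session),
      practice_per_session = as.integer(practice_per_session),
      staircase_burn_in = as.integer(staircase_burn_in),
      staircase_start = as.integer(staircase_start),
      observer = observer,
      seed = seed
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  per_cond <- (x$trials_per_session - x$practice_per_session) %/% 2L
  valid <- x$sessions_per_subject * 2L * (per_cond - x$staircase_burn_in)
  cat(sprintf(
    "<experiment_config> %d subjects, %d x %d trials (%d practice, %d/cond),\n",
    x$n_subjects, x$sessions_per_subject, x$trials_per_session,
    x$practice_per_session, per_cond
  ))
  cat(sprintf("  burn-in %d/cond/session -> %d valid trials per subject\n",
              x$staircase_burn_in, valid))
  invisible(x)
}

#' Simulate the staircase-controlled partial-report experiment
#'
#' Generates a complete trial-level dataset with the statistical structure
#' the pre-registered analysis assumes. Per subject, a random intercept
#' `u ~ N(0, sigma_u^2)` is shared across both sessions. Each session opens
#' with practice trials and then interleaves the two memory conditions in a
#' random order with exactly 130 experimental trials per condition; two
#' independent 1-up/1-down staircases (one per condition, restarted each
#' session) set the number of items. Accuracy comes from the slot-model
#' observer [p_correct()], confidence from the ordered-probit process
#' [generate_confidence()], and response times from lognormal distributions
#' contaminated with occasional fast guesses (< 150 ms) and deadline
#' timeouts (decision 4 s, confidence 3 s) so that the exclusion rules have
#' something to do. A decision timeout leaves the staircase unchanged and
#' yields no confidence report.
#'
#' @param config An [experiment_config()] object.
#' @return A tibble of trial records with columns `subject_id`, `session`,
#'   `trial_index`, `phase`, `condition`, `n_items`, `correct`, `confidence`,
#'   `rt_decision_s`, `rt_confidence_s`, `staircase_order` (per-condition
#'   per-session experimental trial counter; `NA` on practice trials).
#'   Missing responses are `NA`.
#' @examples
#' trials <- simulate_experiment(experiment_config(n_subjects = 2, seed = 1))
#' dplyr::count(trials, condition, phase)
#' @export
simulate_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must be an `experiment_config` object.")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  obs <- config$observer
  rt <- obs$rt_params
  per_cond <- (config$trials_per_session - config$practice_per_session) %/% 2L
  out <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    u_s <- rnorm(1L, 0, obs$sigma_u)
    sess_out <- vector("list", config$sessions_per_subject)
    for (sess in seq_len(config$sessions_per_subject)) {
      cond_seq <- c(
        sample(rep(c("IM", "WM"), config$practice_per_session / 2L)),
        sample(rep(c("IM", "WM"), each = per_cond))
      )
      phase_seq <- rep(c("practice", "experimental"),
                       c(config$practice_per_session,
                         2L * per_cond))
      n_tr <- config$trials_per_session
      stair <- list(
        IM = staircase_new("IM", start = config$staircase_start),
        WM = staircase_new("WM", start = config$staircase_start)
      )
      sc_count <- c(IM = 0L, WM = 0L)
      n_items <- integer(n_tr)
      correct <- rep(NA_integer_, n_tr)
      confidence <- rep(NA_integer_, n_tr)
      rt_dec <- rep(NA_real_, n_tr)
      rt_conf <- rep(NA_real_, n_tr)
      sc_order <- rep(NA_integer_, n_tr)

      for (t in seq_len(n_tr)) {
        cond <- cond_seq[t]
        n <- stair[[cond]]$current_n_items
        n_items[t] <- n
        if (phase_seq[t] == "experimental") {
          sc_count[cond] <- sc_count[cond] + 1L
          sc_order[t] <- sc_count[cond]
        }
        cap <- if (cond == "IM") obs$capacity_im else obs$capacity_wm

        if (runif(1) < rt$p_timeout_decision) {
          # no decision before 4 s: trial recorded empty, staircase frozen
          stair[[cond]] <- staircase_update(stair[[cond]], "no_response")
          next
        }
        if (runif(1) < rt$p_fast_guess) {
          rt_dec[t] <- runif(1, 0.05, 0.149)
          correct[t] <- rbinom(1L, 1L, 1 / n)
        } else {
          r <- rlnorm(1, rt$meanlog_decision, rt$sdlog_decision)
          if (r >= 4) {
            stair[[cond]] <- staircase_update(stair[[cond]], "no_response")
            next
          }
          rt_dec[t] <- r
          correct[t] <- rbinom(1L, 1L, p_correct(n, cap, obs$lapse))
        }
        stair[[cond]] <- staircase_update(
          stair[[cond]], if (correct[t] == 1L) "correct" else "incorrect"
        )
        if (runif(1) >= rt$p_timeout_confidence) {
          r <- rlnorm(1, rt$meanlog_confidence, rt$sdlog_confidence)
          if (r < 3) {
            rt_conf[t] <- r
            confidence[t] <- generate_confidence(correct[t], n, cond, u_s, obs)
          }
        }
      }
      sess_out[[sess]] <- tibble::tibble(
        subject_id = s, session = sess, trial_index = seq_len(n_tr),
        phase = phase_seq, condition = cond_seq, n_items = n_items,
        correct = correct, confidence = confidence,
        rt_decision_s = rt_dec, rt_confidence_s = rt_conf,
        staircase_order = sc_order
      )
    }
    out[[s]] <- dplyr::bind_rows(sess_out)
  }
  dplyr::bind_rows(out)
}

#' Simulate model-1 style confidence data directly
#'
#' Generates trial-level `(condition, n_items, correct, confidence)` data
#' straight from the ordered-probit confidence process, without running the
#' full staircase experiment: the data-generating layout used for power
#' simulation and parameter-recovery work. Set sizes are drawn from rounded,
#' clamped normal distributions whose condition means can be separated to
#' induce a target point-biserial correlation between the IM indicator and
#' `n_items` (the robustness scenario for correlated predictors).
#'
#' @param n_subjects,n_trials Cohort and per-subject trial counts.
#' @param params An [observer_params()] object; for exact model-1 data use
#'   equal (typically zero) meta-noise in both conditions.
#' @param im_n_items_cor Target correlation between the IM indicator and set
#'   size, in `[0, 1)`; 0 gives identical set-size streams.
#' @param n_items_mean,n_items_sd Centre and spread of the set-size
#'   distribution (items), clamped to `[1, 16]` after rounding.
#' @param p_accuracy Probability of a correct response (staircase-matched
#'   default 0.5).
#' @return A tibble with columns `subject_id`, `condition`, `n_items`,
#'   `correct`, `confidence`, `u_subject`.
#' @export
simulate_confidence_data <- function(n_subjects, n_trials,
                                     params = observer_params(
                                       meta_noise_im = 0
                                     ),
                                     im_n_items_cor = 0,
                                     n_items_mean = 8, n_items_sd = 2,
                                     p_accuracy = 0.5) {
  stopifnot(im_n_items_cor >= 0, im_n_items_cor < 1)
  # balanced conditions: point-biserial r implies a mean split of
  # 2 * sd * r / sqrt(1 - r^2) between condition-specific set-size means
  delta <- 2 * n_items_sd * im_n_items_cor / sqrt(1 - im_n_items_cor^2)
  n_tot <- n_subjects * n_trials
  subject_id <- rep(seq_len(n_subjects), each = n_trials)
  u <- rep(rnorm(n_subjects, 0, params$sigma_u), each = n_trials)
  condition <- ifelse(runif(n_tot) < 0.5, "IM", "WM")
  mu <- n_items_mean + ifelse(condition == "IM", delta / 2, -delta / 2)
  n_items <- pmin(pmax(round(rnorm(n_tot, mu, n_items_sd)), 1L), 16L)
  correct <- rbinom(n_tot, 1L, p_accuracy)
  confidence <- generate_confidence(correct, n_items, condition, u, params)
  tibble::tibble(
    subject_id = subject_id, condition = condition,
    n_items = as.integer(n_items), correct = correct,
    confidence = confidence, u_subject = u
  )
}
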