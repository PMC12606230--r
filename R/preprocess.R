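#' Pre-registered trial exclusion rules
#'
#' Classifies every trial by the first matching exclusion rule and returns
#' the analysis-ready subset. Rules, in reporting precedence:
#'
#' 1. `practice` -- practice-phase trials;
#' 2. `burn_in` -- the first `burn_in` experimental trials of each memory
#'    condition in each session (staircase stabilization);
#' 3. `timeout` -- no decision before 4 s and/or no confidence report before
#'    3 s (encoded as missing responses);
#' 4. `fast_rt` -- decision or confidence RT strictly below 150 ms;
#' 5. `too_few_items` -- fewer than 4 items displayed.
#'
#' Precedence only affects the reason labels: the kept set is the same under
#' any rule order, and re-running the filter on its own output is a no-op.
#' On a clean dataset (no timeouts, fast responses or small arrays) exactly
#' 400 trials per subject survive: 2 sessions x 270 trials - 20 practice -
#' 120 burn-in.
#'
#' @param trials A trial tibble as produced by [simulate_experiment()] or
#'   [read_trials()]. If `staircase_order` is absent it is reconstructed as
#'   the within-session per-condition experimental trial counter.
#' @param burn_in Stabilization trials per condition per session (30).
#' @param rt_min Fast-response threshold in seconds (0.15, strict `<`).
#' @param min_items Minimum number of displayed items (4).
#' @return A list with elements `trials` (kept rows) and `report` (an
#'   `exclusion_report`: per-trial reasons plus per subject x condition
#'   counts of each reason).
#' @export
filter_trials <- function(trials, burn_in = 30L, rt_min = 0.15,
                          min_items = 4L) {
  validate_trials(trials)
  if (!"staircase_order" %in% names(trials) ||
      all(is.na(trials$staircase_order[trials$phase == "experimental"]))) {
    trials <- trials |>
      dplyr::group_by(.data$subject_id, .data$session, .data$condition) |>
      dplyr::mutate(
        staircase_order = dplyr::if_else(
          .data$phase == "experimental",
          cumsum(.data$phase == "experimental"), NA_integer_
        )
      ) |>
      dplyr::ungroup()
  }
  reason <- dplyr::case_when(
    trials$phase == "practice" ~ "practice",
    trials$staircase_order <= burn_in ~ "burn_in",
    is.na(trials$rt_decision_s) | is.na(trials$rt_confidence_s) ~ "timeout",
    trials$rt_decision_s < rt_min | trials$rt_confidence_s < rt_min ~
      "fast_rt",
    trials$n_items < min_items ~ "too_few_items",
    TRUE ~ "kept"
  )
  trial_reasons <- trials |>
    dplyr::select("subject_id", "session", "trial_index", "condition") |>
    dplyr::mutate(reason = reason)
  by_subject <- trial_reasons |>
    dplyr::count(.data$subject_id, .data$condition, .data$reason) |>
    tidyr::pivot_wider(
      names_from = "reason", values_from = "n",
      values_fill = 0L
    )
  for (r in c("practice", "burn_in", "timeout", "fast_rt", "too_few_items",
              "kept")) {
    if (!r %in% names(by_subject)) by_subject[[r]] <- 0L
  }
  by_subject <- by_subject |>
    dplyr::select("subject_id", "condition", "practice", "burn_in",
                  "timeout", "fast_rt", "too_few_items", "kept")
  report <- structure(
    list(
      trial_reasons = trial_reasons,
      by_subject = by_subject,
      n_input = nrow(trials),
      subjects = NULL
    ),
    class = "exclusion_report"
  )
  list(trials = trials[reason == "kept", , drop = FALSE], report = report)
}

#' Pre-registered subject exclusion rule
#'
#' A subject is retained only if, after [filter_trials()], both memory
#' conditions keep at least `min_trials` trials (the registered rule: more
#' than 10% excluded in any condition, i.e. fewer than 180 of the 200
#' possible valid trials, discards the participant).
#'
#' @param trials Kept trials from [filter_trials()].
#' @param report The matching `exclusion_report`.
#' @param min_trials Minimum kept trials per condition (180).
#' @return A list with elements `trials` (rows of retained subjects) and
#'   `report` (updated with a `subjects` tibble carrying `subject_kept`).
#' @export
exclude_subjects <- function(trials, report, min_trials = 180L) {
  if (nrow(trials) == 0L) {
    report$subjects <- tibble::tibble(
      subject_id = integer(), n_im = integer(), n_wm = integer(),
      subject_kept = logical()
    )
    return(list(trials = trials, report = report))
  }
  counts <- trials |>
    dplyr::count(.data$subject_id, .data$condition) |>
    tidyr::pivot_wider(
      names_from = "condition", values_from = "n", values_fill = 0L
    )
  for (cc in c("IM", "WM")) if (!cc %in% names(counts)) counts[[cc]] <- 0L
  subjects <- counts |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      n_im = .data$IM, n_wm = .data$WM,
      subject_kept = .data$IM >= min_trials & .data$WM >= min_trials
    )
  report$subjects <- subjects
  kept_ids <- subjects$subject_id[subjects$subject_kept]
  if (length(kept_ids) < nrow(subjects)) {
    warn(sprintf(
      "%d subject(s) discarded with < %d kept trials in a condition",
      nrow(subjects) - length(kept_ids), min_trials
    ))
  }
  list(
    trials = trials[trials$subject_id %in% kept_ids, , drop = FALSE],
    report = report
  )
}

#' Full pre-registered preprocessing pipeline
#'
#' [filter_trials()] followed by [exclude_subjects()].
#'
#' @inheritParams filter_trials
#' @inheritParams exclude_subjects
#' @return A list with `trials` (analysis-ready rows) and `report`.
#' @export
preprocess_trials <- function(trials, burn_in = 30L, rt_min = 0.15,
                              min_items = 4L, min_trials = 180L) {
  step1 <- filter_trials(trials, burn_in = burn_in, rt_min = rt_min,
                         min_items = min_items)
  exclude_subjects(step1$trials, step1$report, min_trials = min_trials)
}

#' @export
print.exclusion_report <- function(x, ...) {
  tot <- colSums(x$by_subject[, c("practice", "burn_in", "timeout",
                                  "fast_rt", "too_few_items", "kept")])
  cat("<exclusion_report>", x$n_input, "trials\n")
  for (nm in names(tot)) cat(sprintf("  %-14s %d\n", nm, tot[[nm]]))
  if (!is.null(x$subjects)) {
    cat(sprintf("  subjects retained: %d / %d\n",
                sum(x$subjects$subject_kept), nrow(x$subjects)))
  }
  invisible(x)
}
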