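trial_col_types <- function() {
  readr::cols(
    subject_id = readr::col_integer(),
    session = readr::col_integer(),
    trial_index = readr::col_integer(),
    phase = readr::col_character(),
    condition = readr::col_character(),
    n_items = readr::col_integer(),
    correct = readr::col_integer(),
    confidence = readr::col_integer(),
    rt_decision_s = readr::col_double(),
    rt_confidence_s = readr::col_double(),
    staircase_order = readr::col_integer()
  )
}

#' Validate the trial-record schema
#'
#' Checks the documented trial schema: required columns, value ranges
#' (confidence 1..4, correct 0/1, n_items >= 1, non-negative RTs, condition
#' IM/WM, phase practice/experimental) and the rule that a confidence level
#' is only present together with a confidence RT. Violations raise an error
#' naming the offending rows.
#'
#' @param trials A data frame of trial records.
#' @return The input, invisibly, if valid.
#' @export
validate_trials <- function(trials) {
  need <- c("subject_id", "session", "trial_index", "phase", "condition",
            "n_items", "correct", "confidence", "rt_decision_s",
            "rt_confidence_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      abort(sprintf("%s (rows %s)", what,
                    paste(head(which(!ok), 5), collapse = ", ")),
            class = "memmeta_schema_error")
    }
  }
  bad_row(trials$condition %in% c("IM", "WM"),
          "`condition` must be 'IM' or 'WM'")
  bad_row(trials$phase %in% c("practice", "experimental"),
          "`phase` must be 'practice' or 'experimental'")
  bad_row(is.na(trials$n_items) | trials$n_items >= 1,
          "`n_items` must be >= 1")
  bad_row(is.na(trials$correct) | trials$correct %in% 0:1,
          "`correct` must be 0/1 or missing")
  bad_row(is.na(trials$confidence) | trials$confidence %in% 1:4,
          "`confidence` must be in 1..4 or missing")
  bad_row(is.na(trials$rt_decision_s) | trials$rt_decision_s >= 0,
          "`rt_decision_s` must be non-negative")
  bad_row(is.na(trials$rt_confidence_s) | trials$rt_confidence_s >= 0,
          "`rt_confidence_s` must be non-negative")
  bad_row(!(is.na(trials$rt_confidence_s) & !is.na(trials$confidence)),
          "`confidence` present without a confidence RT")
  invisible(trials)
}

#' Read / write trial records as CSV
#'
#' The documented CSV schema of [simulate_experiment()]: one row per trial,
#' missing responses as empty fields. Reading validates the schema and
#' warns on unknown columns; writing is the exact inverse.
#'
#' @param path File path.
#' @return `read_trials()`: a validated tibble of trial records.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, col_types = trial_col_types(),
                            progress = FALSE)
  known <- c(names(trial_col_types()$cols))
  extra <- setdiff(names(trials), known)
  if (length(extra)) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    trials <- trials[known[known %in% names(trials)]]
  }
  if (nrow(trials)) validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @return `write_trials()`: `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Outcome-interpretation rules for the registered design
#'
#' Encodes the pre-registered decision table mapping test outcomes to
#' interpretation tokens, as a pure function so every branch is testable:
#'
#' * `rq1` (metacognition, theta = WM - IM AUROC-2):
#'   `"higher_WM_meta_nonequivalent"` (t significant, positive, TOST not
#'   significant), `"equivalent"` (TOST significant, or t non-significant
#'   with TOST significant), `"higher_IM_meta"` (t significant, negative,
#'   TOST not significant), `"inconclusive"` (neither significant).
#' * `rq2` (inflation): `"inflation"` only when the IM coefficient is
#'   significantly positive *and* RQ1 did not find equal-or-higher IM
#'   metacognition (inflation is read jointly with reduced metacognition);
#'   otherwise `"no_inflation"`.
#' * `rq3` (capacity, theta = WM - IM mean items):
#'   `"higher_IM_capacity"`, `"higher_WM_capacity"` or
#'   `"no_capacity_difference"`.
#' * `control`: `"equivalent"` / `"not_equivalent"`.
#' * `rich_view`: verdict on the rich-and-detailed view; RQ1 outcomes that
#'   would support it (equivalence, or higher IM metacognition) only count
#'   when RQ3 shows the preserved higher IM capacity, otherwise
#'   `"conditional_not_met"`.
#'
#' @param rq1_t_sig,rq1_positive,rq1_equiv Logical outcomes of the RQ1
#'   paired t-test (significance, sign of WM - IM) and TOST.
#' @param rq2_sig,rq2_positive Wald-test outcome for the IM coefficient.
#' @param rq3_sig,rq3_negative Paired-t outcome for item capacity
#'   (negative = IM capacity larger).
#' @param control_equiv Whether the performance TOST claimed equivalence.
#' @return A named list of tokens:
#'   `rq1`, `rq2`, `rq3`, `control`, `rich_view`.
#' @export
interpret_results <- function(rq1_t_sig, rq1_positive, rq1_equiv,
                              rq2_sig, rq2_positive,
                              rq3_sig, rq3_negative,
                              control_equiv) {
  rq1 <- if (rq1_equiv) {
    "equivalent"
  } else if (rq1_t_sig && rq1_positive) {
    "higher_WM_meta_nonequivalent"
  } else if (rq1_t_sig && !rq1_positive) {
    "higher_IM_meta"
  } else {
    "inconclusive"
  }
  rq3 <- if (!rq3_sig) {
    "no_capacity_difference"
  } else if (rq3_negative) {
    "higher_IM_capacity"
  } else {
    "higher_WM_capacity"
  }
  rq2 <- if (rq2_sig && rq2_positive &&
             !rq1 %in% c("equivalent", "higher_IM_meta")) {
    "inflation"
  } else {
    "no_inflation"
  }
  rich_view <- if (rq1 == "higher_WM_meta_nonequivalent") {
    "not_supported"
  } else if (rq1 == "inconclusive") {
    "inconclusive"
  } else if (rq3 == "higher_IM_capacity") {
    "supported"
  } else {
    "conditional_not_met"
  }
  list(
    rq1 = rq1, rq2 = rq2, rq3 = rq3,
    control = if (control_equiv) "equivalent" else "not_equivalent",
    rich_view = rich_view
  )
}

#' Run the full registered analysis pipeline
#'
#' Executes the end-to-end pre-registered analysis on simulated or loaded
#' trial data: exclusion rules, subject summaries, RQ1 (paired t + TOST on
#' AUROC-2, both at alpha 0.025, standardized bounds +-0.325), RQ2
#' (random-intercept cumulative-probit fit; Wald test of the IM
#' coefficient), RQ3 (paired t on mean set size), the performance control
#' (raw-bound TOST, +-0.05), optionally the exploratory suite (set-size
#' variability controls, interaction and full-random-effects confidence
#' models with AIC comparison and the per-subject coefficient test), and
#' the outcome-interpretation tokens.
#'
#' @param input An [experiment_config()] to simulate from, a trial tibble,
#'   or a path to a trial CSV.
#' @param tost_bounds Standardized equivalence bounds for RQ1.
#' @param perf_bounds Raw equivalence bounds for the performance control.
#' @param rq1_alpha Level of each RQ1 test (multiple-comparison corrected).
#' @param alpha Level of the remaining confirmatory tests.
#' @param exploratory Run the exploratory analyses (set-size controls and
#'   models 2-3)? They dominate the run time on large cohorts.
#' @param n_quad Quadrature nodes for the confidence-model fits.
#' @return A `study_report` list: `summaries`, `exclusions`, `rq1`
#'   (t + TOST results), `rq2` (model-1 tidy table), `rq3`, `control`,
#'   `exploratory` (or `NULL`), `tokens`, `provenance`.
#' @examples
#' \donttest{
#' rep <- run_study(experiment_config(n_subjects = 12, seed = 42),
#'                  exploratory = FALSE, n_quad = 5)
#' rep$tokens
#' }
#' @export
run_study <- function(input,
                      tost_bounds = c(-0.325, 0.325),
                      perf_bounds = c(-0.05, 0.05),
                      rq1_alpha = 0.025, alpha = 0.05,
                      exploratory = TRUE, n_quad = 15L) {
  seed_used <- NA_integer_
  if (inherits(input, "experiment_config")) {
    seed_used <- input$seed %||% NA_integer_
    trials <- simulate_experiment(input)
  } else if (is.character(input)) {
    trials <- read_trials(input)
  } else if (is.data.frame(input)) {
    trials <- input
  } else {
    abort("`input` must be a config, a data frame or a CSV path.")
  }

  pre <- preprocess_trials(trials)
  if (nrow(pre$trials) == 0L) {
    abort("all subjects excluded; see the attached exclusion report.",
          class = "memmeta_pipeline_error",
          report = pre$report)
  }
  summaries <- subject_summaries(pre$trials)
  wide <- summaries |>
    tidyr::pivot_wider(
      id_cols = "subject_id", names_from = "condition",
      values_from = c("accuracy", "mean_items", "auroc2", "mean_confidence")
    )

  rq1_t <- paired_t(wide$auroc2_WM, wide$auroc2_IM, alpha = rq1_alpha)
  rq1_tost <- tost_paired(wide$auroc2_WM, wide$auroc2_IM,
                          lower = tost_bounds[1], upper = tost_bounds[2],
                          standardized = TRUE, alpha = rq1_alpha)
  fit1 <- fit_cumulative_probit(pre$trials, "model1", n_quad = n_quad)
  rq2_row <- tidy(fit1) |> dplyr::filter(.data$term == "IM")
  rq3_t <- paired_t(wide$mean_items_WM, wide$mean_items_IM, alpha = alpha)
  control_tost <- tost_paired(wide$accuracy_WM, wide$accuracy_IM,
                              lower = perf_bounds[1], upper = perf_bounds[2],
                              standardized = FALSE, alpha = alpha)

  exploratory_res <- NULL
  if (exploratory) {
    setsize <- setsize_variability_analysis(summaries, pre$trials)
    fit2 <- fit_cumulative_probit(pre$trials, "model2", n_quad = n_quad)
    fit3 <- fit_cumulative_probit(pre$trials, "model3")
    exploratory_res <- list(
      setsize = setsize,
      model2 = fit2, model3 = fit3,
      aic = compare_aic(fit2, fit3),
      subject_im = subject_coefficient_test(fit3, "IM"),
      subject_im_accuracy = subject_coefficient_test(fit3, "IM:accuracy")
    )
  }

  tokens <- interpret_results(
    rq1_t_sig = rq1_t$p_value < rq1_alpha,
    rq1_positive = rq1_t$mean_difference > 0,
    rq1_equiv = rq1_tost$equivalent,
    rq2_sig = rq2_row$p_value < alpha,
    rq2_positive = rq2_row$estimate > 0,
    rq3_sig = rq3_t$p_value < alpha,
    rq3_negative = rq3_t$mean_difference < 0,
    control_equiv = control_tost$equivalent
  )

  structure(
    list(
      summaries = summaries,
      exclusions = pre$report,
      rq1 = list(t_test = rq1_t, tost = rq1_tost),
      rq2 = list(fit = fit1, im_term = rq2_row),
      rq3 = rq3_t,
      control = control_tost,
      exploratory = exploratory_res,
      tokens = tokens,
      provenance = list(
        seed = seed_used,
        n_subjects = length(unique(summaries$subject_id)),
        package_version = as.character(utils::packageVersion("memmeta")),
        input_hash = rlang::hash(trials)
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$provenance$n_subjects, "retained subjects\n")
  cat(sprintf(
    "  RQ1 AUROC-2: t(%d) = %.2f, p = %.3g, d = %.2f; TOST p = %.3g -> %s\n",
    x$rq1$t_test$df, x$rq1$t_test$statistic, x$rq1$t_test$p_value,
    x$rq1$t_test$effect_size_d, x$rq1$tost$p_value, x$tokens$rq1
  ))
  cat(sprintf(
    "  RQ2 confidence: beta_IM = %.3f (SE %.3f), p = %.3g -> %s\n",
    x$rq2$im_term$estimate, x$rq2$im_term$std_error, x$rq2$im_term$p_value,
    x$tokens$rq2
  ))
  cat(sprintf(
    "  RQ3 capacity: t(%d) = %.2f, p = %.3g, d = %.2f -> %s\n",
    x$rq3$df, x$rq3$statistic, x$rq3$p_value, x$rq3$effect_size_d,
    x$tokens$rq3
  ))
  cat(sprintf(
    "  control accuracy TOST: t(%d) = %.2f, p = %.3g -> %s\n",
    x$control$df, x$control$statistic, x$control$p_value, x$tokens$control
  ))
  cat("  rich-view verdict:", x$tokens$rich_view, "\n")
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the test results, tokens and provenance (not the trial-level
#' data) as a structured JSON document keyed by research question.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  payload <- list(
    rq1 = list(t_test = report$rq1$t_test, tost = report$rq1$tost),
    rq2 = report$rq2$im_term,
    rq3 = report$rq3,
    control = report$control,
    tokens = report$tokens,
    exclusions = report$exclusions$by_subject,
    provenance = report$provenance
  )
  if (!is.null(report$exploratory)) {
    payload$exploratory <- list(
      sd_comparison = report$exploratory$setsize$sd_comparison,
      regression = report$exploratory$setsize$regression,
      modal_t = report$exploratory$setsize$modal_t,
      modal_tost = report$exploratory$setsize$modal_tost,
      aic = report$exploratory$aic,
      subject_im = report$exploratory$subject_im
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
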