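#' Create a 1-up/1-down staircase state
#'
#' One staircase per memory condition controls the set size: an item is added
#' after a correct response, removed after an incorrect one, and the set size
#' is left unchanged when no decision is made before the deadline. The walk is
#' clamped to `[lower_bound, upper_bound]`; the design caps the array at 16
#' items. The lower bound is 1 (a zero-item display is meaningless); trials
#' with fewer than 4 items are generated but later removed by the exclusion
#' rules rather than being prevented here.
#'
#' @param condition `"IM"` or `"WM"` label of the staircase.
#' @param start Initial set size (design choice: 8, mid-range).
#' @param lower_bound,upper_bound Clamping bounds on the set size.
#' @return An object of class `staircase_state`.
#' @examples
#' s <- staircase_new("IM")
#' s <- staircase_update(s, "correct")
#' s$current_n_items
#' @export
staircase_new <- function(condition = c("IM", "WM"), start = 8L,
                          lower_bound = 1L, upper_bound = 16L) {
  condition <- match.arg(condition)
  stopifnot(lower_bound >= 1, upper_bound >= lower_bound,
            start >= lower_bound, start <= upper_bound)
  structure(
    list(
      condition = condition,
      current_n_items = as.integer(start),
      lower_bound = as.integer(lower_bound),
      upper_bound = as.integer(upper_bound),
      history = list()
    ),
    class = "staircase_state"
  )
}

#' Advance a staircase after a trial outcome
#'
#' @param state A [staircase_new()] state.
#' @param outcome One of `"correct"` (+1 item), `"incorrect"` (-1 item) or
#'   `"no_response"` (unchanged).
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state,
                             outcome = c("correct", "incorrect",
                                         "no_response")) {
  outcome <- match.arg(outcome)
  step <- switch(outcome, correct = 1L, incorrect = -1L, no_response = 0L)
  new_n <- min(max(state$current_n_items + step, state$lower_bound),
               state$upper_bound)
  state$history[[length(state$history) + 1L]] <-
    list(n_items = state$current_n_items, outcome = outcome)
  state$current_n_items <- new_n
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase_state> %s: n_items %d in [%d, %d], %d trials seen\n",
              x$condition, x$current_n_items, x$lower_bound, x$upper_bound,
              length(x$history)))
  invisible(x)
}

#' Stand-alone staircase run against a slot-model observer
#'
#' Runs a single 1-up/1-down staircase for `n_trials` trials against a
#' [p_correct()] observer, the procedure used to check that post-stabilization
#' accuracy is clamped at 50%.
#'
#' @param n_trials Number of trials to simulate.
#' @param capacity,lapse Observer parameters passed to [p_correct()].
#' @param start,lower_bound,upper_bound Staircase geometry.
#' @return A tibble with columns `trial`, `n_items`, `correct`.
#' @examples
#' set.seed(1)
#' run <- run_staircase(500, capacity = 5)
#' mean(run$correct[-(1:30)])
#' @export
run_staircase <- function(n_trials, capacity, lapse = 0.02, start = 8L,
                          lower_bound = 1L, upper_bound = 16L) {
  n_items <- integer(n_trials)
  correct <- integer(n_trials)
  cur <- as.integer(start)
  for (t in seq_len(n_trials)) {
    n_items[t] <- cur
    correct[t] <- rbinom(1L, 1L, p_correct(cur, capacity, lapse))
    cur <- cur + if (correct[t] == 1L) 1L else -1L
    cur <- min(max(cur, lower_bound), upper_bound)
  }
  tibble::tibble(trial = seq_len(n_trials), n_items = n_items,
                 correct = correct)
}
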