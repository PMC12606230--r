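#' Generative observer parameters
#'
#' Bundles the parameters of the synthetic observer: a slot-style capacity
#' model for identification accuracy, an ordered-probit confidence process
#' with a subject random intercept, condition-specific metacognitive noise,
#' and response-time distributions with contamination.
#'
#' The accuracy process is a slot model: on each trial `min(capacity,
#' n_items)` of the `n_items` letters are stored; if the probed letter was
#' stored the response is correct unless a lapse occurs, otherwise the
#' observer guesses a position uniformly. Confidence arises from a latent
#' normal variable `beta_IM * IM + beta_n_items * n_items + beta_accuracy *
#' accuracy + u_subject + noise` cut at thresholds `tau` into four ordinal
#' levels; the latent noise SD is 1 in the WM reference condition and
#' `1 + meta_noise_*` per condition, so extra meta-noise in one condition
#' degrades its metacognitive sensitivity without touching accuracy.
#'
#' Defaults encode the study conditions the package emulates: IM capacity
#' exceeding WM capacity, confidence coefficients at the values reported for
#' the pre-registered model fit, and extra iconic-memory meta-noise producing
#' higher WM metacognitive sensitivity at matched (staircased) performance.
#'
#' @param capacity_im,capacity_wm Mean number of storable items per condition.
#' @param lapse Probability of a lapse (error despite a stored item).
#' @param beta_im,beta_n_items,beta_accuracy Generative coefficients of the
#'   latent confidence process (probit scale).
#' @param tau Strictly increasing numeric(3): latent thresholds between the
#'   four confidence levels.
#' @param sigma_u SD of the subject random intercept (>= 0).
#' @param meta_noise_im,meta_noise_wm Extra latent confidence noise per
#'   condition (>= 0); latent SD is `1 + meta_noise`.
#' @param rt_params Named list controlling response-time generation: lognormal
#'   `meanlog`/`sdlog` for decision and confidence RTs, `p_fast_guess`
#'   (probability of a < 150 ms contaminant response) and
#'   `p_timeout_decision` / `p_timeout_confidence` (probability of no
#'   response before the 4 s / 3 s deadline).
#'
#' @return An object of class `observer_params` (a named list).
#' @examples
#' observer_params()
#' @export
observer_params <- function(capacity_im = 6,
                            capacity_wm = 3,
                            lapse = 0.02,
                            beta_im = -0.08,
                            beta_n_items = -0.12,
                            beta_accuracy = 1.28,
                            tau = c(-2.3, -1.1, 0.2),
                            sigma_u = 0.5,
                            meta_noise_im = 0.3,
                            meta_noise_wm = 0,
                            rt_params = list()) {
  stopifnot(capacity_im >= 0, capacity_wm >= 0)
  if (lapse < 0 || lapse > 1) abort("`lapse` must be in [0, 1].")
  if (length(tau) != 3L || any(diff(tau) <= 0)) {
    abort("`tau` must be three strictly increasing thresholds.")
  }
  if (sigma_u < 0) abort("`sigma_u` must be >= 0.")
  if (meta_noise_im < 0 || meta_noise_wm < 0) {
    abort("meta-noise parameters must be >= 0.")
  }
  rt_defaults <- list(
    meanlog_decision = log(1.1), sdlog_decision = 0.45,
    meanlog_confidence = log(0.7), sdlog_confidence = 0.40,
    p_fast_guess = 0.03,
    p_timeout_decision = 0.005,
    p_timeout_confidence = 0.005
  )
  rt_params <- utils::modifyList(rt_defaults, rt_params)
  structure(
    list(
      capacity_im = capacity_im, capacity_wm = capacity_wm, lapse = lapse,
      beta_im = beta_im, beta_n_items = beta_n_items,
      beta_accuracy = beta_accuracy, tau = tau, sigma_u = sigma_u,
      meta_noise_im = meta_noise_im, meta_noise_wm = meta_noise_wm,
      rt_params = rt_params
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  capacity IM/WM: %.2f / %.2f, lapse %.3f\n",
              x$capacity_im, x$capacity_wm, x$lapse))
  cat(sprintf("  confidence: beta_IM %.3f, beta_nItems %.3f, beta_acc %.3f\n",
              x$beta_im, x$beta_n_items, x$beta_accuracy))
  cat(sprintf("  tau: %s; sigma_u %.2f; meta-noise IM/WM: %.2f / %.2f\n",
              paste(format(x$tau), collapse = ", "),
              x$sigma_u, x$meta_noise_im, x$meta_noise_wm))
  invisible(x)
}

#' Slot-model probability of a correct identification
#'
#' `p_enc * (1 - lapse) + (1 - p_enc) / n_items` with encoding probability
#' `p_enc = min(capacity, n_items) / n_items`: the probed item is either
#' among the stored slots (correct up to lapses) or its position is guessed
#' uniformly among the `n_items` possible locations. The function is
#' non-increasing in `n_items`, equals 1 at `lapse = 0` when everything fits
#' in capacity, and crosses 0.5 at a set size increasing in capacity -- the
#' fixed point the 1-up/1-down staircase converges to.
#'
#' @param n_items Set size (integer >= 1), vectorised.
#' @param capacity Mean number of storable items (>= 0).
#' @param lapse Lapse probability.
#' @return Probability of a correct response, in (0, 1].
#' @examples
#' p_correct(4:16, capacity = 5)
#' @export
p_correct <- function(n_items, capacity, lapse = 0) {
  if (any(n_items < 1) || any(n_items != round(n_items))) {
    abort("`n_items` must be integers >= 1.")
  }
  stopifnot(capacity >= 0, lapse >= 0, lapse <= 1)
  p_enc <- pmin(capacity, n_items) / n_items
  p_enc * (1 - lapse) + (1 - p_enc) / n_items
}

#' Linear predictor of the latent confidence process
#' @noRd
confidence_eta <- function(accuracy, n_items, condition, u_subject, params) {
  params$beta_im * (condition == "IM") +
    params$beta_n_items * n_items +
    params$beta_accuracy * accuracy +
    u_subject
}

#' Draw ordinal confidence from the generative cumulative-probit process
#'
#' Draws the latent confidence variable (linear predictor plus normal noise
#' with SD `1 + meta_noise(condition)`) and bins it at the thresholds `tau`
#' into levels 1..4. Vectorised over trials; all vector arguments are
#' recycled to a common length.
#'
#' @param accuracy 0/1 correctness of the trial's identification response.
#' @param n_items Set size on the trial.
#' @param condition `"IM"` or `"WM"`.
#' @param u_subject Subject random intercept value(s).
#' @param params An [observer_params()] object.
#' @return Integer confidence levels in 1..4.
#' @export
generate_confidence <- function(accuracy, n_items, condition, u_subject,
                                params = observer_params()) {
  if (any(diff(params$tau) <= 0)) {
    abort("thresholds `tau` must be strictly increasing.")
  }
  n <- max(length(accuracy), length(n_items), length(condition),
           length(u_subject))
  accuracy <- rep_len(accuracy, n)
  n_items <- rep_len(n_items, n)
  condition <- rep_len(condition, n)
  u_subject <- rep_len(u_subject, n)
  eta <- confidence_eta(accuracy, n_items, condition, u_subject, params)
  noise_sd <- 1 + ifelse(condition == "IM",
                         params$meta_noise_im, params$meta_noise_wm)
  latent <- eta + rnorm(n, 0, noise_sd)
  conf <- findInterval(latent, params$tau) + 1L
  as.integer(conf)
}

#' Closed-form confidence category probabilities
#'
#' `P(confidence = k) = Phi((tau_k - eta) / s) - Phi((tau_{k-1} - eta) / s)`
#' with `s = 1 + meta_noise(condition)`; the oracle counterpart of
#' [generate_confidence()] used for calibration checks and power work.
#'
#' @inheritParams generate_confidence
#' @return A numeric matrix with one row per trial and 4 columns.
#' @export
confidence_probs <- function(accuracy, n_items, condition, u_subject,
                             params = observer_params()) {
  n <- max(length(accuracy), length(n_items), length(condition),
           length(u_subject))
  accuracy <- rep_len(accuracy, n)
  n_items <- rep_len(n_items, n)
  condition <- rep_len(condition, n)
  u_subject <- rep_len(u_subject, n)
  eta <- confidence_eta(accuracy, n_items, condition, u_subject, params)
  s <- 1 + ifelse(condition == "IM", params$meta_noise_im,
                  params$meta_noise_wm)
  cuts <- cbind(-Inf, matrix(params$tau, n, 3, byrow = TRUE), Inf)
  cum <- pnorm((cuts - eta) / s)
  cum[, -1, drop = FALSE] - cum[, -5, drop = FALSE]
}
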