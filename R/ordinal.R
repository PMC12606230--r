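#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch nodes/weights for the physicists' Hermite weight
#' `exp(-x^2)`, computed from the symmetric tridiagonal Jacobi matrix.
#'
#' @param n Number of quadrature nodes.
#' @return A list with `nodes` and `weights`.
#' @keywords internal
#' @export
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# model design matrices; thresholds absorb the intercept so X has none
cp_design <- function(trials, model) {
  im <- as.numeric(trials$condition == "IM")
  acc <- as.numeric(trials$correct)
  ni <- as.numeric(trials$n_items)
  X <- switch(model,
    model1 = cbind(IM = im, nItems = ni, accuracy = acc),
    model2 = ,
    model3 = cbind(IM = im, nItems = ni, accuracy = acc,
                   "IM:accuracy" = im * acc)
  )
  Z <- NULL
  if (model == "model3") {
    Z <- cbind("(Intercept)" = 1, IM = im, accuracy = acc,
               "IM:accuracy" = im * acc, nItems = ni)
  }
  list(X = X, Z = Z)
}

cp_start_values <- function(y, X) {
  cum <- cumsum(prop.table(table(factor(y, levels = 1:4))))[1:3]
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  tau0 <- qnorm(cum)
  d <- pmax(diff(tau0), 1e-2)
  start <- c(tau0[1], log(d), rep(0, ncol(X)))
  fit <- optim(
    start,
    fn = function(th) cp_pooled_nll(th, y, X)$nll,
    gr = function(th) cp_pooled_nll(th, y, X)$grad,
    method = "BFGS", control = list(maxit = 200)
  )
  fit$par
}

#' Fit a cumulative-probit mixed regression of confidence
#'
#' Maximum (approximate) marginal likelihood for the ordered-probit models
#' of confidence used in the registered analysis:
#'
#' * `model1`: `confidence ~ IM + nItems + accuracy + (1 | subject)` -- the
#'   pre-registered specification;
#' * `model2`: adds the `IM:accuracy` interaction, still with a random
#'   intercept;
#' * `model3`: the `model2` fixed effects with a correlated random
#'   intercept and random slopes for all predictors.
#'
#' The latent confidence variable is cut by three free thresholds (no global
#' intercept, the conventional cumulative-link identification). Scalar
#' random intercepts are integrated out with adaptive Gauss-Hermite
#' quadrature (`n_quad` nodes, iteratively re-adapted at the current
#' conditional modes until the estimate is a fixed point); the
#' five-dimensional random effect of `model3` uses a Laplace approximation.
#' Standard errors come from the inverse observed information of the
#' marginal likelihood; p-values are Wald. The random-effect variance is
#' optimized on the log (model 1/2) or log-Cholesky (model 3) scale, and a
#' variance estimated at its lower boundary is flagged, not an error.
#'
#' @param trials A trial-level data frame with columns `subject_id`,
#'   `condition` ("IM"/"WM"), `n_items`, `correct` (0/1) and `confidence`
#'   (1..4); rows with missing values in these columns are dropped.
#' @param model One of `"model1"`, `"model2"`, `"model3"`.
#' @param n_quad Number of adaptive quadrature nodes (model 1/2).
#' @param center_items If `TRUE`, `nItems` is mean-centred before fitting
#'   (the registered analysis enters it raw).
#' @param max_rounds Maximum node re-adaptation rounds.
#' @param se Compute standard errors (numerical observed information)?
#'   Skipping them speeds up fits needed only for log-likelihood/AIC work.
#' @param sigma_fixed Optionally hold the random-intercept SD fixed at this
#'   value instead of estimating it (model 1/2 only); at a value near zero
#'   the marginal fit coincides with the pooled no-random-effects ML fit.
#' @return An object of class `cumprobit_fit`; see [tidy.cumprobit_fit()],
#'   [glance.cumprobit_fit()], [compare_aic()], [subject_coefficient_test()].
#' @examples
#' \donttest{
#' set.seed(7)
#' dat <- simulate_confidence_data(20, 60)
#' fit <- fit_cumulative_probit(dat, "model1", n_quad = 7)
#' tidy(fit)
#' }
#' @export
fit_cumulative_probit <- function(trials,
                                  model = c("model1", "model2", "model3"),
                                  n_quad = 15L, center_items = FALSE,
                                  max_rounds = 10L, se = TRUE,
                                  sigma_fixed = NULL) {
  model <- match.arg(model)
  need <- c("subject_id", "condition", "n_items", "correct", "confidence")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(paste0("`trials` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  trials <- trials[complete.cases(trials[need]), need]
  if (!all(trials$confidence %in% 1:4)) {
    abort("`confidence` must contain only levels 1..4.")
  }
  trials <- trials[order(trials$subject_id), , drop = FALSE]
  if (center_items) trials$n_items <- trials$n_items - mean(trials$n_items)
  subj <- unique(trials$subject_id)
  if (length(subj) < 2) abort("need at least 2 subjects.")
  sidx <- match(trials$subject_id, subj)
  sub_len <- as.integer(tabulate(sidx, nbins = length(subj)))
  sub_start <- as.integer(c(0L, cumsum(sub_len)[-length(sub_len)]))
  y <- as.integer(trials$confidence)
  des <- cp_design(trials, model)
  X <- des$X
  p <- ncol(X)
  S <- length(subj)

  pooled <- cp_start_values(y, X)

  if (model %in% c("model1", "model2")) {
    gh <- gauss_hermite(n_quad)
    theta <- c(pooled, log(sigma_fixed %||% 0.4))
    K <- length(theta)
    lower <- c(rep(-Inf, K - 1),
               log(sigma_fixed %||% 1e-3))
    upper <- c(rep(Inf, K - 1),
               if (is.null(sigma_fixed)) Inf else log(sigma_fixed))
    uhat <- rep(0, S)
    conv <- 1L
    rounds <- 0L
    nodes <- NULL
    make_nodes <- function(th) {
      ad <- cp_adapt_scalar(th, y, X, sub_start, sub_len, uhat)
      uhat <<- ad$uhat
      list(
        uq = outer(ad$uhat, rep(1, n_quad)) +
          sqrt(2) * outer(ad$shat, gh$nodes),
        logpref = matrix(log(gh$weights) + gh$nodes^2, S, n_quad,
                         byrow = TRUE) + log(sqrt(2) * ad$shat),
        shat = ad$shat
      )
    }
    cache <- new.env(parent = emptyenv())
    objfun <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        res <- cp_aghq_nll(th, y, X, sub_start, sub_len, nodes$uq,
                           nodes$logpref, TRUE)
        cache$key <- key
        cache$res <- res
      }
      cache$res
    }
    for (r in seq_len(max_rounds)) {
      rounds <- r
      nodes <- make_nodes(theta)
      cache$key <- NULL
      opt <- nlminb(theta, function(th) objfun(th)$nll,
                    gradient = function(th) objfun(th)$grad,
                    lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 800,
                                   rel.tol = 1e-9))
      delta <- max(abs(opt$par - theta))
      theta <- opt$par
      # re-adapt until the estimate is a fixed point of the node placement;
      # 1e-4 on the parameter scale is far below any reported precision
      # (standard errors here are two orders of magnitude larger)
      if (delta < 1e-4) { conv <- 0L; break }
    }
    nodes <- make_nodes(theta)
    cache$key <- NULL
    final <- objfun(theta)
    loglik <- -final$nll
    # observed information: central differences of the analytic gradient
    # (a fixed sigma is treated as known, not a parameter)
    Kf <- if (is.null(sigma_fixed)) K else K - 1L
    vc <- matrix(NA_real_, K, K)
    if (se) {
      H <- matrix(NA_real_, Kf, Kf)
      for (j in seq_len(Kf)) {
        h <- 1e-5 * (1 + abs(theta[j]))
        tp <- theta; tp[j] <- tp[j] + h
        tm <- theta; tm[j] <- tm[j] - h
        gp <- cp_aghq_nll(tp, y, X, sub_start, sub_len, nodes$uq,
                          nodes$logpref, TRUE)$grad
        gm <- cp_aghq_nll(tm, y, X, sub_start, sub_len, nodes$uq,
                          nodes$logpref, TRUE)$grad
        H[, j] <- (gp[seq_len(Kf)] - gm[seq_len(Kf)]) / (2 * h)
      }
      H <- (H + t(H)) / 2
      vc[seq_len(Kf), seq_len(Kf)] <- tryCatch(
        solve(H), error = function(e) matrix(NA_real_, Kf, Kf)
      )
    }
    sigma_u <- exp(theta[K])
    boundary <- sigma_u <= 1.5e-3
    tau_hat <- c(theta[1], theta[1] + exp(theta[2]),
                 theta[1] + exp(theta[2]) + exp(theta[3]))
    Jtau <- rbind(c(1, 0, 0), c(1, exp(theta[2]), 0),
                  c(1, exp(theta[2]), exp(theta[3])))
    se_tau <- sqrt(pmax(diag(Jtau %*% vc[1:3, 1:3] %*% t(Jtau)), 0))
    beta_hat <- theta[3 + seq_len(p)]
    se_beta <- sqrt(diag(vc)[3 + seq_len(p)])
    ranef <- tibble::tibble(
      subject_id = subj, mode = uhat, cond_sd = nodes$shat
    )
    n_par <- 3 + p + if (is.null(sigma_fixed)) 1L else 0L
    fit <- list(
      model = model, theta = theta, vcov = vc,
      tau = tau_hat, se_tau = se_tau,
      beta = setNames(beta_hat, colnames(X)),
      se_beta = setNames(se_beta, colnames(X)),
      sigma_u = sigma_u, Sigma = matrix(sigma_u^2, 1, 1,
                                        dimnames = list("(Intercept)",
                                                        "(Intercept)")),
      log_likelihood = loglik, aic = 2 * n_par - 2 * loglik,
      n_par = n_par, n_obs = length(y), n_subjects = S,
      ranef = ranef, convergence = conv, rounds = rounds,
      boundary = boundary, n_quad = n_quad,
      data = list(y = y, X = X, Z = NULL, sub_start = sub_start,
                  sub_len = sub_len, subjects = subj)
    )
  } else {
    # model 3: Laplace with a 5-dimensional correlated random effect
    q <- ncol(des$Z)
    nL <- q * (q + 1) / 2
    diag_pos <- cumsum(c(1, rev(seq_len(q - 1) + 1)))[seq_len(q)]
    lstart <- rep(0, nL)
    lstart[diag_pos] <- log(0.3)
    theta <- c(pooled, lstart)
    K <- length(theta)
    Uenv <- new.env(parent = emptyenv())
    Uenv$U <- matrix(0, S, q)
    objfun <- function(th) {
      res <- cp_laplace_nll(th, y, X, des$Z, sub_start, sub_len, Uenv$U)
      if (isTRUE(res$ok)) Uenv$U <- res$U
      res$nll
    }
    opt <- nlminb(theta, objfun,
                  control = list(iter.max = 400, eval.max = 1200,
                                 rel.tol = 1e-9))
    theta <- opt$par
    conv <- opt$convergence
    loglik <- -objfun(theta)
    vc <- matrix(NA_real_, K, K)
    if (se) {
      H <- pracma::hessian(objfun, theta)
      H <- (H + t(H)) / 2
      vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, K, K))
    }
    L <- matrix(0, q, q)
    idx <- 3 + ncol(X)
    for (j in seq_len(q)) for (i in j:q) {
      idx <- idx + 1
      L[i, j] <- if (i == j) exp(theta[idx]) else theta[idx]
    }
    Sigma <- L %*% t(L)
    dimnames(Sigma) <- list(colnames(des$Z), colnames(des$Z))
    tau_hat <- c(theta[1], theta[1] + exp(theta[2]),
                 theta[1] + exp(theta[2]) + exp(theta[3]))
    Jtau <- rbind(c(1, 0, 0), c(1, exp(theta[2]), 0),
                  c(1, exp(theta[2]), exp(theta[3])))
    se_tau <- sqrt(pmax(diag(Jtau %*% vc[1:3, 1:3] %*% t(Jtau)), 0))
    p <- ncol(X)
    beta_hat <- theta[3 + seq_len(p)]
    se_beta <- sqrt(diag(vc)[3 + seq_len(p)])
    ranef <- tibble::as_tibble(as.data.frame(Uenv$U))
    names(ranef) <- colnames(des$Z)
    ranef <- dplyr::bind_cols(tibble::tibble(subject_id = subj), ranef)
    n_par <- 3 + p + nL
    fit <- list(
      model = model, theta = theta, vcov = vc,
      tau = tau_hat, se_tau = se_tau,
      beta = setNames(beta_hat, colnames(X)),
      se_beta = setNames(se_beta, colnames(X)),
      sigma_u = sqrt(diag(Sigma))[1], Sigma = Sigma,
      log_likelihood = loglik, aic = 2 * n_par - 2 * loglik,
      n_par = n_par, n_obs = length(y), n_subjects = S,
      ranef = ranef, convergence = conv, rounds = 1L,
      boundary = any(diag(Sigma) <= (1.5e-3)^2), n_quad = NA_integer_,
      data = list(y = y, X = X, Z = des$Z, sub_start = sub_start,
                  sub_len = sub_len, subjects = subj)
    )
  }
  class(fit) <- "cumprobit_fit"
  fit
}

#' @export
print.cumprobit_fit <- function(x, ...) {
  cat(sprintf("<cumprobit_fit> %s: %d obs, %d subjects\n",
              x$model, x$n_obs, x$n_subjects))
  cat(sprintf("  logLik %.2f, AIC %.2f (%d parameters)%s\n",
              x$log_likelihood, x$aic, x$n_par,
              if (x$boundary) " [variance at boundary]" else ""))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy method for cumulative-probit fits
#'
#' @param x A `cumprobit_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`
#'   (Wald z), `p_value` and `coef_type` (`"location"`, `"threshold"` or
#'   `"variance"`).
#' @export
tidy.cumprobit_fit <- function(x, ...) {
  z <- x$beta / x$se_beta
  loc <- tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std_error = unname(x$se_beta), statistic = unname(z),
    p_value = 2 * pnorm(-abs(unname(z))), coef_type = "location"
  )
  thr <- tibble::tibble(
    term = paste0("tau", 1:3), estimate = x$tau, std_error = x$se_tau,
    statistic = NA_real_, p_value = NA_real_, coef_type = "threshold"
  )
  vr <- tibble::tibble(
    term = paste0("sd_", rownames(x$Sigma)),
    estimate = sqrt(diag(x$Sigma)),
    std_error = NA_real_, statistic = NA_real_, p_value = NA_real_,
    coef_type = "variance"
  )
  dplyr::bind_rows(loc, thr, vr)
}

#' Glance method for cumulative-probit fits
#'
#' @inheritParams tidy.cumprobit_fit
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.cumprobit_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, log_likelihood = x$log_likelihood, aic = x$aic,
    n_par = x$n_par, n_obs = x$n_obs, n_subjects = x$n_subjects,
    sigma_u = x$sigma_u, convergence = x$convergence,
    boundary = x$boundary
  )
}

#' Fitted category probabilities at the conditional modes
#'
#' Returns the 4 cumulative-probit category probabilities
#' `Phi(tau_k - eta) - Phi(tau_{k-1} - eta)` per observation, with the
#' linear predictor evaluated at each subject's conditional mode.
#'
#' @param fit A `cumprobit_fit`.
#' @return A numeric matrix, `n_obs` x 4, rows summing to 1.
#' @export
fitted_category_probs <- function(fit) {
  d <- fit$data
  eta <- drop(d$X %*% fit$beta)
  sidx <- rep(seq_along(d$sub_len), d$sub_len)
  if (fit$model == "model3") {
    U <- as.matrix(fit$ranef[, -1])
    eta <- eta + rowSums(d$Z * U[sidx, , drop = FALSE])
  } else {
    eta <- eta + fit$ranef$mode[sidx]
  }
  cuts <- c(-Inf, fit$tau, Inf)
  cum <- vapply(cuts, function(ct) pnorm(ct - eta), numeric(length(eta)))
  cum[, -1, drop = FALSE] - cum[, -5, drop = FALSE]
}

#' Recompute the marginal log-likelihood with a given node count
#'
#' Re-adapts the quadrature at the fitted parameters and evaluates the
#' marginal log-likelihood with `n_quad` nodes; a convergence diagnostic for
#' the quadrature approximation (model 1/2 fits only).
#'
#' @param fit A scalar-random-intercept `cumprobit_fit`.
#' @param n_quad Number of Gauss-Hermite nodes.
#' @return The marginal log-likelihood.
#' @export
cumprobit_loglik <- function(fit, n_quad = fit$n_quad) {
  if (fit$model == "model3") {
    abort("quadrature diagnostics apply to scalar-intercept fits only.")
  }
  d <- fit$data
  gh <- gauss_hermite(n_quad)
  S <- length(d$sub_len)
  ad <- cp_adapt_scalar(fit$theta, d$y, d$X, d$sub_start, d$sub_len,
                        rep(0, S))
  uq <- outer(ad$uhat, rep(1, n_quad)) + sqrt(2) * outer(ad$shat, gh$nodes)
  logpref <- matrix(log(gh$weights) + gh$nodes^2, S, n_quad, byrow = TRUE) +
    log(sqrt(2) * ad$shat)
  -cp_aghq_nll(fit$theta, d$y, d$X, d$sub_start, d$sub_len, uq, logpref,
               FALSE)$nll
}

#' AIC comparison of two confidence-model fits
#'
#' @param fit_a,fit_b `cumprobit_fit` objects fitted to the same
#'   observations.
#' @return A one-row tibble with both AICs, `delta_aic` (= AIC_a - AIC_b)
#'   and the `preferred` model label (lower AIC).
#' @export
compare_aic <- function(fit_a, fit_b) {
  if (fit_a$n_obs != fit_b$n_obs) {
    abort("fits must be on identical observation sets (n_obs differs).")
  }
  tibble::tibble(
    model_a = fit_a$model, model_b = fit_b$model,
    aic_a = fit_a$aic, aic_b = fit_b$aic,
    delta_aic = fit_a$aic - fit_b$aic,
    preferred = if (fit_a$aic <= fit_b$aic) fit_a$model else fit_b$model
  )
}

#' One-sample t-test on per-subject random-slope coefficients
#'
#' For a term with a random slope, forms each subject's coefficient as the
#' fixed effect plus the subject's empirical-Bayes conditional mode, and
#' t-tests the distribution of these values against zero
#' (`df = n_subjects - 1`, `d = |t| / sqrt(n)`).
#'
#' @param fit A `model3` `cumprobit_fit`.
#' @param term A fixed-effect term that also has a random slope (e.g.
#'   `"IM"` or `"IM:accuracy"`).
#' @return A one-row TestResult tibble (as in [paired_t()]) plus the
#'   per-subject values as the `"subject_coefs"` attribute.
#' @export
subject_coefficient_test <- function(fit, term = "IM") {
  if (fit$model != "model3" || !term %in% names(fit$ranef)) {
    abort(sprintf("`%s` has no random slope in this fit.", term))
  }
  if (!term %in% names(fit$beta)) {
    abort(sprintf("`%s` is not a fixed-effect term.", term))
  }
  vals <- fit$beta[[term]] + fit$ranef[[term]]
  tt <- t.test(vals)
  out <- tibble::tibble(
    kind = "subject_coef_t", term = term,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_difference = mean(vals),
    sd_difference = sd(vals),
    effect_size_d = cohens_d_from_t(unname(tt$statistic), length(vals)),
    alpha = 0.05, n = length(vals)
  )
  attr(out, "subject_coefs") <- vals
  out
}
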