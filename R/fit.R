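#' Fit the Avrami risk function to cohort incidence data
#'
#' Nonlinear least-squares fit of the three-parameter risk curve
#' `y = C * (1 - exp(-alpha * m^k))` to cumulative cancer incidence
#' against mean oncogenic mutation count. Any of the parameters can be
#' held fixed (the registry fits in this field are often reported at a
#' fixed critical index `k` and scale `C`, with `alpha` free).
#'
#' Internally the objective is minimised over `(log alpha, k, log C)` —
#' the log parameterisation tames the strong `alpha`/`k` trade-off — by
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) from a deterministic 3x3x3
#' multi-start grid centred on data-driven guesses (`C0` just above the
#' largest response, `k0 = 4`, `alpha0` from the Avrami-plot intercept).
#' The optional Poisson-deviance loss (for responses that are raw case
#' counts) uses bounded quasi-Newton instead.
#'
#' @param data A [cohort()] data frame (or any data frame with columns
#'   `mutations` and `response`; a data frame with `age` only is converted
#'   using `rate`).
#' @param fix_k Optional fixed value for the critical index `k`.
#' @param fix_scale Optional fixed value for the scale `C`.
#' @param loss `"squared"` (default) for least squares on the responses,
#'   or `"poisson"` for Poisson deviance.
#' @param weights Optional nonnegative per-point weights for the squared
#'   loss.
#' @param rate Mutations-per-year rate used only if `data` lacks a
#'   `mutations` column (default 0.053).
#' @param start Optional named vector `c(alpha=, k=, scale=)` overriding
#'   the multi-start grid with a single starting point.
#' @return An object of class `"avrami_fit"` with components `params`
#'   ([avrami_params()]), `fixed` (named logical mask), `rss`, `n_points`,
#'   `converged`, `fitted.values`, `residuals`, `data`, `loss`.
#' @examples
#' cohort <- generate_cohort(avrami_params(0.0087, 4.4, 155), noise_sd = 0)
#' fit <- fit_avrami(cohort)
#' coef(fit)
#' @seealso [profile_k()], [bootstrap_ci()]
#' @export
fit_avrami <- function(data, fix_k = NULL, fix_scale = NULL,
                       loss = c("squared", "poisson"), weights = NULL,
                       rate = 0.053, start = NULL) {
  loss <- match.arg(loss)
  d <- resolve_fit_data(data, rate)
  m <- d$mutations
  y <- d$response
  n <- length(y)
  if (length(unique(m)) < 4L) {
    stop("at least 4 points with distinct mutation counts are required",
         call. = FALSE)
  }
  if (all(y == 0)) {
    stop("all responses are zero: the scale parameter is unidentifiable ",
         "(C -> 0 boundary)", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  weights <- check_nonneg_vector(weights, "weights")
  if (length(weights) != n) {
    stop("`weights` must have one entry per data point", call. = FALSE)
  }

  fixed <- c(alpha = FALSE, k = !is.null(fix_k), scale = !is.null(fix_scale))
  fixed_vals <- c(
    alpha = NA_real_,
    k = if (fixed[["k"]]) check_scalar(fix_k, "fix_k", lower = 0,
                                       strict_lower = TRUE) else NA_real_,
    scale = if (fixed[["scale"]]) check_scalar(fix_scale, "fix_scale",
                                               lower = 0,
                                               strict_lower = TRUE) else NA_real_
  )
  n_free <- sum(!fixed)
  if (n < n_free + 1L) {
    stop("need more data points than free parameters (", n_free,
         " free, ", n, " points)", call. = FALSE)
  }

  starts <- if (is.null(start)) {
    start_grid(m, y, fixed, fixed_vals)
  } else {
    list(theta_full(start[["alpha"]],
                    if (fixed[["k"]]) fixed_vals[["k"]] else start[["k"]],
                    if (fixed[["scale"]]) fixed_vals[["scale"]] else start[["scale"]]))
  }

  # theta = (log alpha, k, log C); optimise the free coordinates only
  free_idx <- which(!fixed)
  lower <- c(log(1e-14), 0.5, log(1e-12))[free_idx]
  upper <- c(log(1e6), 10, log(1e12))[free_idx]
  sw <- sqrt(weights)

  objective_rss <- function(theta) {
    p <- params_from_theta(theta, fixed, fixed_vals, free_idx)
    sum(weights * (y - p$scale * -expm1(-p$alpha * m^p$k))^2)
  }

  best <- NULL
  for (s in starts) {
    th0 <- pmin(pmax(s[free_idx], lower), upper)
    res <- if (loss == "squared") {
      tryCatch({
        lmfit <- minpack.lm::nls.lm(
          par = th0,
          fn = function(theta) {
            p <- params_from_theta(theta, fixed, fixed_vals, free_idx)
            sw * (y - p$scale * -expm1(-p$alpha * m^p$k))
          },
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(
            maxiter = 400, ftol = 1e-15, ptol = 1e-15, gtol = 0))
        list(theta = lmfit$par, value = objective_rss(lmfit$par),
             ok = lmfit$info %in% 1:4)
      }, error = function(e) NULL)
    } else {
      tryCatch({
        op <- stats::optim(
          th0,
          fn = function(theta) {
            p <- params_from_theta(theta, fixed, fixed_vals, free_idx)
            mu_hat <- pmax(p$scale * -expm1(-p$alpha * m^p$k), 1e-12)
            2 * sum(ifelse(y > 0, y * log(y / mu_hat), 0) - (y - mu_hat))
          },
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500, factr = 1e3))
        list(theta = op$par, value = op$value, ok = op$convergence == 0)
      }, error = function(e) NULL)
    }
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop("optimisation failed from every start; check the data scale ",
         "and the fixed parameter values", call. = FALSE)
  }

  p <- params_from_theta(best$theta, fixed, fixed_vals, free_idx)
  params <- avrami_params(p$alpha, p$k, p$scale)
  fitted_vals <- avrami_risk(m, params)
  resid <- y - fitted_vals

  structure(
    list(params = params, fixed = fixed,
         rss = sum(weights * resid^2),
         objective = best$value, loss = loss,
         n_points = n, converged = isTRUE(best$ok),
         fitted.values = fitted_vals, residuals = resid,
         weights = weights, data = d, rate = d_rate(data, rate),
         call = match.call()),
    class = "avrami_fit"
  )
}

# -- internal helpers ------------------------------------------------------

theta_full <- function(alpha, k, scale) c(log(alpha), k, log(scale))

params_from_theta <- function(theta_free, fixed, fixed_vals, free_idx) {
  th <- c(alpha = NA_real_, k = NA_real_, scale = NA_real_)
  th[free_idx] <- theta_free
  list(
    alpha = if (fixed[["alpha"]]) fixed_vals[["alpha"]] else exp(th[["alpha"]]),
    k = if (fixed[["k"]]) fixed_vals[["k"]] else th[["k"]],
    scale = if (fixed[["scale"]]) fixed_vals[["scale"]] else exp(th[["scale"]])
  )
}

# deterministic 3x3x3 multi-start grid around data-driven guesses
start_grid <- function(m, y, fixed, fixed_vals) {
  C0 <- if (fixed[["scale"]]) fixed_vals[["scale"]] else 1.05 * max(y)
  k0 <- if (fixed[["k"]]) fixed_vals[["k"]] else 4
  frac <- y / (if (fixed[["scale"]]) max(C0, 1.001 * max(y)) else C0)
  use <- frac > 0.01 & frac < 0.99 & m > 0
  log_a0 <- if (sum(use) >= 2) {
    mean(avrami_transform(frac[use]) - k0 * log(m[use]))
  } else {
    log(log(2)) - k0 * log(max(stats::median(m), 1e-6))
  }
  a_set <- exp(log_a0 + c(-2, 0, 2))
  k_set <- if (fixed[["k"]]) k0 else pmin(pmax(k0 + c(-2, 0, 2), 0.6), 10)
  c_set <- if (fixed[["scale"]]) C0 else C0 * c(1, 1.3, 3)
  starts <- list()
  for (a in a_set) for (k in unique(k_set)) for (C in unique(c_set)) {
    starts[[length(starts) + 1L]] <- theta_full(a, k, C)
  }
  starts
}

resolve_fit_data <- function(data, rate) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame (see `cohort()`)", call. = FALSE)
  }
  if (!"response" %in% names(data)) {
    stop("`data` must have a `response` column", call. = FALSE)
  }
  if ("mutations" %in% names(data)) {
    mutations <- check_nonneg_vector(data$mutations, "mutations")
  } else if ("age" %in% names(data)) {
    mutations <- mutations_from_age(data$age, rate)
  } else {
    stop("`data` must have a `mutations` or `age` column", call. = FALSE)
  }
  response <- check_nonneg_vector(data$response, "response")
  if (length(mutations) != length(response)) {
    stop("`mutations` and `response` lengths differ", call. = FALSE)
  }
  data.frame(mutations = mutations, response = response)
}

d_rate <- function(data, rate) {
  r <- attr(data, "rate", exact = TRUE)
  if (is.null(r)) rate else r
}

# -- methods ---------------------------------------------------------------

#' @export
print.avrami_fit <- function(x, digits = 5, ...) {
  cat("Avrami risk-curve fit: y = C (1 - exp(-alpha m^k))\n")
  est <- coef(x)
  tags <- ifelse(x$fixed, "(fixed)", "")
  for (i in seq_along(est)) {
    cat(sprintf("  %-5s = %s %s\n", names(est)[i],
                format(est[i], digits = digits), tags[i]))
  }
  cat(sprintf("  RSS = %s on %d points%s%s\n",
              format(x$rss, digits = digits), x$n_points,
              if (x$loss == "poisson") " (Poisson-deviance fit)" else "",
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
coef.avrami_fit <- function(object, ...) {
  c(alpha = object$params$alpha, k = object$params$k,
    scale = object$params$scale)
}

#' @export
fitted.avrami_fit <- function(object, ...) object$fitted.values

#' @export
residuals.avrami_fit <- function(object, ...) object$residuals

#' Predict from a fitted Avrami risk curve
#'
#' @param object An `"avrami_fit"`.
#' @param newdata Optional data frame with a `mutations` or `age` column
#'   (ages are converted at the fit's rate); defaults to the fitted data.
#' @param type `"response"` (risk, in cohort units) or `"probability"`
#'   (the unscaled transformation probability).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.avrami_fit <- function(object, newdata = NULL,
                               type = c("response", "probability"), ...) {
  type <- match.arg(type)
  m <- if (is.null(newdata)) {
    object$data$mutations
  } else if (is.data.frame(newdata) && "mutations" %in% names(newdata)) {
    check_nonneg_vector(newdata$mutations, "mutations")
  } else if (is.data.frame(newdata) && "age" %in% names(newdata)) {
    mutations_from_age(newdata$age, object$rate)
  } else if (is.numeric(newdata)) {
    check_nonneg_vector(newdata, "newdata")
  } else {
    stop("`newdata` must be numeric or a data frame with `mutations` or `age`",
         call. = FALSE)
  }
  if (type == "response") avrami_risk(m, object$params)
  else transformation_probability(m, object$params)
}

#' @export
summary.avrami_fit <- function(object, ...) {
  thr <- effective_threshold(object$params)
  structure(
    list(fit = object, coef = coef(object),
         sigma = sqrt(object$rss / max(1, object$n_points - sum(!object$fixed))),
         threshold = thr),
    class = "summary.avrami_fit"
  )
}

#' @export
print.summary.avrami_fit <- function(x, digits = 5, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  residual SD = %s\n", format(x$sigma, digits = digits)))
  cat(sprintf(
    "  effective threshold: mode %.3g mutations, central 90%% in [%.3g, %.3g]\n",
    x$threshold$mode, x$threshold$lower, x$threshold$upper))
  invisible(x)
}

#' Simulate response vectors from a fitted Avrami risk curve
#'
#' Draws Gaussian noise with the fit's residual standard deviation around
#' the fitted curve (truncated at zero), one column per simulation — the
#' standard parametric-simulation contract for model objects.
#'
#' @param object An `"avrami_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.avrami_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- summary(object)$sigma
  mu <- object$fitted.values
  with_seed(seed, {
    out <- as.data.frame(replicate(
      nsim, pmax(0, stats::rnorm(length(mu), mu, sigma)), simplify = FALSE),
      col.names = paste0("sim_", seq_len(nsim)))
    out
  })
}

#' Plot a fitted Avrami risk curve over the data
#'
#' @param x An `"avrami_fit"`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.avrami_fit <- function(x, n_grid = 200, ...) {
  m <- x$data$mutations
  graphics::plot(m, x$data$response,
                 xlab = "oncogenic mutations m",
                 ylab = "cumulative incidence",
                 main = "Avrami risk-curve fit", ...)
  mg <- seq(0, max(m) * 1.05, length.out = n_grid)
  graphics::lines(mg, avrami_risk(mg, x$params))
  invisible(x)
}

#' Profile the fit over a grid of fixed critical indices
#'
#' Re-fits the risk curve once per value of a `k` grid, holding `k` (and
#' optionally `C`) fixed, and reports the fitted `alpha`, `C` and residual
#' sum of squares. The RSS column reproduces the fixed-k model-selection
#' procedure used for registry fits (e.g. comparing k = 4.0, 4.1, ..., 4.4
#' and reading off which fits best); the choice among them is left to the
#' user.
#'
#' @inheritParams fit_avrami
#' @param k_grid Nonempty vector of positive `k` values.
#' @return A data frame with columns `k`, `alpha`, `scale`, `rss`,
#'   `converged`, one row per grid value.
#' @examples
#' cohort <- generate_cohort(avrami_params(0.0087, 4.4, 155), noise_sd = 0)
#' profile_k(cohort, k_grid = seq(4.0, 4.5, by = 0.1), fix_scale = 155)
#' @export
profile_k <- function(data, k_grid, fix_scale = NULL,
                      loss = c("squared", "poisson"), weights = NULL,
                      rate = 0.053) {
  loss <- match.arg(loss)
  k_grid <- check_nonneg_vector(k_grid, "k_grid")
  if (length(k_grid) < 1L) stop("`k_grid` must be nonempty", call. = FALSE)
  rows <- lapply(k_grid, function(k) {
    fit <- tryCatch(
      fit_avrami(data, fix_k = k, fix_scale = fix_scale, loss = loss,
                 weights = weights, rate = rate),
      error = function(e) {
        stop("profile fit failed at k = ", format(k), ": ",
             conditionMessage(e), call. = FALSE)
      })
    data.frame(k = k, alpha = fit$params$alpha, scale = fit$params$scale,
               rss = fit$rss, converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Case-resampling bootstrap confidence intervals for a fit
#'
#' Resamples the data points with replacement, refits the model with the
#' same fixed-parameter mask (starting each refit from the point
#' estimate), and returns empirical percentile intervals for the
#' parameters. Case resampling (rather than residual resampling) is used
#' because cohort tables are small sets of cumulative counts with
#' heterogeneous precision.
#'
#' @param data The data the fit was computed from (`NULL` to reuse the
#'   data stored in the fit).
#' @param fit The `"avrami_fit"` to assess (must have converged).
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; identical seeds give identical
#'   intervals.
#' @return A matrix with rows `alpha`, `k`, `scale` and columns `lower`,
#'   `upper`, with attributes `level`, `n_boot` and `n_failed`. Fixed
#'   parameters get degenerate intervals at their fixed value.
#' @export
bootstrap_ci <- function(data = NULL, fit, n_boot = 999, level = 0.95,
                         seed = NULL) {
  stopifnot(inherits(fit, "avrami_fit"))
  if (!fit$converged) {
    stop("`fit` did not converge; bootstrap intervals would be meaningless",
         call. = FALSE)
  }
  n_boot <- check_scalar(n_boot, "n_boot", lower = 100)
  level <- check_scalar(level, "level", lower = 0, upper = 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  d <- if (is.null(data)) fit$data else resolve_fit_data(data, fit$rate)
  n <- nrow(d)
  est <- coef(fit)
  fk <- if (fit$fixed[["k"]]) fit$params$k else NULL
  fs <- if (fit$fixed[["scale"]]) fit$params$scale else NULL

  draws <- with_seed(seed, {
    idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(idx_mat, 2, function(idx) {
      tryCatch({
        bf <- fit_avrami(d[idx, , drop = FALSE], fix_k = fk, fix_scale = fs,
                         loss = fit$loss, start = est)
        coef(bf)
      }, error = function(e) c(alpha = NA_real_, k = NA_real_,
                               scale = NA_real_))
    })
  })
  n_failed <- sum(is.na(draws[1, ]))
  if (n_failed > 0.2 * n_boot) {
    stop(sprintf(
      "bootstrap unstable: %d of %d resample fits failed (%.0f%% > 20%%)",
      n_failed, n_boot, 100 * n_failed / n_boot), call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(draws, 1, stats::quantile, probs = probs, na.rm = TRUE))
  dimnames(ci) <- list(c("alpha", "k", "scale"), c("lower", "upper"))
  attr(ci, "level") <- level
  attr(ci, "n_boot") <- as.integer(n_boot)
  attr(ci, "n_failed") <- as.integer(n_failed)
  ci
}
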