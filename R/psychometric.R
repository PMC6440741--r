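#' Two-parameter logistic psychometric function
#'
#' The observer model used throughout the package maps stimulus intensity
#' `x` (mA) to detection probability
#' \deqn{p(x) = \frac{1}{1 + \exp(-4 s (x - t_{50}))}}
#' parameterised by the 50% detection threshold `t50` (mA) and the slope
#' `s` of the psychometric function evaluated at `t50` (1/mA). The factor 4
#' makes `s` literally equal to \eqn{dp/dx} at threshold.
#'
#' @name psychometric
NULL

new_psychfit <- function(t50, slope, n_trials = NA_integer_,
                         log_likelihood = NA_real_) {
  stopifnot(is.finite(t50), is.finite(slope), slope > 0)
  structure(
    list(t50 = t50, slope = slope, n_trials = n_trials,
         log_likelihood = log_likelihood),
    class = "psychfit"
  )
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Logistic psychometric fit: t50 = %.4g mA, slope = %.4g /mA",
              x$t50, x$slope))
  if (!is.na(x$n_trials)) {
    cat(sprintf(" (n = %d, logLik = %.2f)", x$n_trials, x$log_likelihood))
  }
  cat("\n")
  invisible(x)
}

psychfit_loglik <- function(t50, slope, x, y) {
  eta <- 4 * slope * (x - t50)
  # log p and log(1-p) via plogis for numerical stability in the tails
  sum(ifelse(y == 1,
             stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Fit a logistic psychometric function by maximum likelihood
#'
#' Fits the two-parameter logistic observer (see [psychometric]) to binary
#' detection data by bounded quasi-Newton optimisation (`L-BFGS-B`) from a
#' grid of starting values. The slope is capped (default 50 /mA) and `t50`
#' box-constrained to the tested intensity range, guarding against the
#' divergent MLE of perfectly separated data. Ties between converged starts
#' are broken by highest likelihood, then smallest slope.
#'
#' @param intensities Numeric vector of stimulus intensities (mA).
#' @param detected Binary vector (0/1 or logical) of detection outcomes.
#' @param slope_max Upper bound on the slope (1/mA).
#' @return A `psychfit` object with elements `t50`, `slope`, `n_trials`,
#'   `log_likelihood`.
#' @examples
#' x <- rep(seq(1.7, 3.1, by = 0.1), each = 20)
#' p <- 1 / (1 + exp(-4 * 2 * (x - 2.4)))
#' set.seed(1)
#' fit <- fit_logistic(x, rbinom(length(x), 1, p))
#' @export
fit_logistic <- function(intensities, detected, slope_max = 50) {
  x <- as.numeric(intensities)
  y <- as.numeric(detected)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(x)) < 2L) {
    stop("degenerate design: fewer than 2 distinct intensities", call. = FALSE)
  }
  if (all(y == y[1L])) {
    stop("non-identifiable fit: all outcomes identical", call. = FALSE)
  }
  rng <- range(x)
  span <- diff(rng)
  lower <- c(rng[1L] - 0.5 * span, 1e-3)
  upper <- c(rng[2L] + 0.5 * span, slope_max)
  nll <- function(par) -psychfit_loglik(par[1L], par[2L], x, y)
  starts <- expand.grid(
    t50 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    slope = c(0.5, 2, 8) / max(span, 1e-6)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-10 ||
        (abs(fit$value - best$value) <= 1e-10 && fit$par[2L] < best$par[2L])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed from all starts", call. = FALSE)
  new_psychfit(best$par[1L], best$par[2L], n_trials = length(y),
               log_likelihood = -best$value)
}

#' Detection probability at a stimulus intensity
#'
#' @param fit A `psychfit` object.
#' @param x Stimulus intensity (mA), vectorised.
#' @return Detection probability in (0, 1).
#' @export
detection_probability <- function(fit, x) {
  stopifnot(inherits(fit, "psychfit"), all(is.finite(x)))
  stats::plogis(4 * fit$slope * (x - fit$t50))
}

#' Expected stimulus uncertainty at a stimulus intensity
#'
#' The slope of the psychometric function at `x`: the derivative of the
#' detection-probability curve, an inverse-U-shaped function of intensity
#' that is maximal at threshold and symmetric about it. Trials near
#' threshold are maximally susceptible to perceptual fluctuation; this
#' quantity is the "expected uncertainty" modulator of the uncertainty GLM.
#'
#' @inheritParams detection_probability
#' @return Slope value (1/mA), positive.
#' @export
uncertainty_value <- function(fit, x) {
  p <- detection_probability(fit, x)
  4 * fit$slope * p * (1 - p)
}

#' Average psychometric fits across runs
#'
#' The per-participant observer is the unweighted arithmetic mean of the
#' run-wise fitted thresholds and slopes.
#'
#' @param fits List of `psychfit` objects.
#' @return A single `psychfit`.
#' @export
average_fits <- function(fits) {
  if (length(fits) == 0L) stop("empty list of fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "psychfit")))
  n <- vapply(fits, function(f) f$n_trials, integer(1))
  new_psychfit(
    mean(vapply(fits, function(f) f$t50, numeric(1))),
    mean(vapply(fits, function(f) f$slope, numeric(1))),
    n_trials = if (all(is.na(n))) NA_integer_ else sum(n, na.rm = TRUE)
  )
}

#' Derive the 10-level stimulus intensity grid from a psychometric fit
#'
#' Solves the fitted function for the intensities giving 1% (`T01`) and 99%
#' (`T99`) detection probability and spaces ten levels equidistantly so that
#' level 2 = `T01` and level 9 = `T99`; the common step is
#' `(T99 - T01) / 7`. This samples each observer's full dynamic range with
#' margin at both ends for threshold drift.
#'
#' @param fit A `psychfit` object.
#' @return A list of class `intensity_grid`: `levels` (10 intensities, mA),
#'   `step` (mA), `t01`, `t99`.
#' @export
derive_intensity_grid <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  if (fit$slope <= 0) stop("non-positive slope", call. = FALSE)
  # p = .01 -> 4 s (x - t50) = logit(.01)
  t01 <- fit$t50 + stats::qlogis(0.01) / (4 * fit$slope)
  t99 <- fit$t50 + stats::qlogis(0.99) / (4 * fit$slope)
  step <- (t99 - t01) / 7
  levels <- t01 + (seq_len(10) - 2) * step
  structure(list(levels = levels, step = step, t01 = t01, t99 = t99),
            class = "intensity_grid")
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("Intensity grid: 10 levels, step %.4g mA (T01 = %.4g, T99 = %.4g)\n",
              x$step, x$t01, x$t99))
  print(round(x$levels, 4))
  invisible(x)
}

#' Participant exclusion rule on the fitted dynamic range
#'
#' A participant is excluded when their run-averaged psychometric function
#' shows detection probability > 10% at intensity level 1 or < 90% at level
#' 10 — i.e. when the experiment failed to sample their full dynamic range
#' (threshold drift, criterion change). Both inequalities are strict.
#'
#' @param avg_fit Run-averaged `psychfit`.
#' @param grid The participant's `intensity_grid`.
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
exclusion_check <- function(avg_fit, grid) {
  stopifnot(inherits(grid, "intensity_grid"))
  p1 <- detection_probability(avg_fit, grid$levels[1L])
  p10 <- detection_probability(avg_fit, grid$levels[10L])
  !(p1 > 0.10 || p10 < 0.90)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.psychfit <- function(x, ...) {
  tibble::tibble(term = c("t50", "slope"),
                 estimate = c(x$t50, x$slope),
                 unit = c("mA", "1/mA"))
}

#' One-row summary of a psychometric fit
#'
#' @inheritParams tidy.psychfit
#' @return A one-row tibble (`t50`, `slope`, `n_trials`, `log_likelihood`).
#' @export
glance.psychfit <- function(x, ...) {
  tibble::tibble(t50 = x$t50, slope = x$slope, n_trials = x$n_trials,
                 log_likelihood = x$log_likelihood)
}

#' Plot a fitted psychometric function
#'
#' @param object A `psychfit`.
#' @param grid Optional `intensity_grid` whose levels are marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychfit <- function(object, grid = NULL, ...) {
  rng <- if (is.null(grid)) {
    object$t50 + c(-1.5, 1.5) * (stats::qlogis(0.99) / (4 * object$slope))
  } else {
    range(grid$levels) + c(-0.5, 0.5) * grid$step
  }
  df <- tibble::tibble(x = seq(rng[1L], rng[2L], length.out = 201))
  df$p <- detection_probability(object, df$x)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Stimulus intensity (mA)", y = "P(detection)") +
    ggplot2::ylim(0, 1)
  if (!is.null(grid)) {
    gg <- gg + ggplot2::geom_vline(xintercept = grid$levels,
                                   linetype = "dotted", alpha = 0.5)
  }
  gg
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
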