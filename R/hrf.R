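#' Canonical double-gamma haemodynamic response function
#'
#' The canonical BOLD impulse response: a gamma density peaking at 6 s minus
#' a scaled (1/6) gamma undershoot peaking at 16 s, normalised to unit peak.
#'
#' @param t Time in seconds (vectorised).
#' @param peak,undershoot Peak times (s) of the response and undershoot
#'   gamma components.
#' @param ratio Undershoot amplitude ratio.
#' @return HRF values, unit peak amplitude.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max_hrf(peak, undershoot, ratio)
}

max_hrf <- function(peak, undershoot, ratio) {
  tt <- seq(0, 30, by = 0.01)
  max(stats::dgamma(tt, shape = peak, rate = 1) -
        ratio * stats::dgamma(tt, shape = undershoot, rate = 1))
}

#' Temporal derivative of the canonical HRF
#'
#' Central finite difference of [canonical_hrf]; used as the temporal
#' derivative nuisance column of the design matrix.
#'
#' @inheritParams canonical_hrf
#' @return Derivative values (1/s).
#' @export
canonical_hrf_derivative <- function(t, peak = 6, undershoot = 16,
                                     ratio = 1 / 6) {
  dt <- 1e-3
  (canonical_hrf(t + dt, peak, undershoot, ratio) -
     canonical_hrf(pmax(t - dt, 0), peak, undershoot, ratio)) / (2 * dt)
}

#' Convolve weighted event impulses with an HRF and sample at the TR
#'
#' Events are binned on a microtime grid (default 0.1 s), weighted, convolved
#' with the kernel, and the result sampled at scan acquisition times
#' `(0, TR, 2 TR, ...)`.
#'
#' @param onsets Event onsets in seconds.
#' @param weights Per-event weights (modulator values); default all 1.
#' @param n_vols Number of volumes.
#' @param tr Repetition time in seconds.
#' @param kernel HRF function of time, default [canonical_hrf].
#' @param dt Microtime resolution in seconds.
#' @return Numeric vector of length `n_vols`.
#' @export
convolve_events <- function(onsets, weights = NULL, n_vols, tr = 2,
                            kernel = canonical_hrf, dt = 0.1) {
  if (is.null(weights)) weights <- rep(1, length(onsets))
  stopifnot(length(weights) == length(onsets))
  t_max <- n_vols * tr + 32
  grid <- seq(0, t_max, by = dt)
  impulses <- numeric(length(grid))
  bins <- pmin(floor(onsets / dt) + 1L, length(grid))
  for (i in seq_along(bins)) impulses[bins[i]] <- impulses[bins[i]] + weights[i]
  k <- kernel(seq(0, 32, by = dt))
  conv <- stats::convolve(impulses, rev(k), type = "open")[seq_along(grid)]
  scan_t <- (seq_len(n_vols) - 1L) * tr
  conv[pmin(floor(scan_t / dt) + 1L, length(grid))]
}
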