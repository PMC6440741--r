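#' Prior settings for the conjugate Bayesian GLM
#'
#' The GLM is fit under a normal–inverse-gamma conjugate prior:
#' \eqn{\beta | \sigma^2 \sim N(0, \sigma^2 V_0)}, \eqn{\sigma^2 \sim
#' IG(a_0, b_0)}. The default is a unit-information g-prior,
#' \eqn{V_0 = g (X^T X)^{-1}} with \eqn{g = n}, which carries the
#' information of one observation and makes model evidence invariant to
#' column rescaling; `a0`/`b0` are kept vague so the noise level is learnt
#' from the data.
#'
#' @param g g-prior scale; `NULL` (default) uses the number of scans.
#' @param a0,b0 Inverse-gamma shape/rate for the noise variance.
#' @param V0 Explicit prior covariance scale matrix (overrides `g`).
#' @return A list of class `glm_prior`.
#' @export
glm_prior <- function(g = NULL, a0 = 1e-3, b0 = 1e-3, V0 = NULL) {
  structure(list(g = g, a0 = a0, b0 = b0, V0 = V0), class = "glm_prior")
}

resolve_V0 <- function(prior, X) {
  if (!is.null(prior$V0)) return(prior$V0)
  g <- if (is.null(prior$g)) nrow(X) else prior$g
  XtX <- crossprod(X)
  g * solve(XtX)
}

#' Build a first-level parametric-modulation design matrix
#'
#' One onset regressor models all trial onsets; it is parametrically
#' modulated by exactly one z-scored experimental regressor (the model's
#' modulator). Temporal derivatives of both, the z-scored reaction-time
#' modulation, optional nuisance columns, and a constant complete the
#' matrix. Rank is checked and an error names the collinear columns.
#'
#' @param trials One run's trial table (used for onsets of all non-null
#'   trials).
#' @param modulator Name of the modulator column in `regressors` (one of
#'   `"intensity"`, `"detection"`, `"p_detect"`, `"uncertainty"`,
#'   `"report"`), or `NULL` for an onsets-only model.
#' @param regressors The run's [build_regressors()] tibble.
#' @param n_vols,tr Scan geometry.
#' @param nuisance Optional matrix of nuisance time courses (e.g. motion
#'   surrogates, tissue PCs), `n_vols` rows.
#' @param derivatives Include temporal-derivative columns (default TRUE).
#' @param rt Include the RT modulation column (default TRUE).
#' @return Numeric matrix (`n_vols` x columns) with named columns, constant
#'   last; attribute `"tr"` carries the TR.
#' @export
build_design_matrix <- function(trials, modulator, regressors,
                                n_vols, tr = 2, nuisance = NULL,
                                derivatives = TRUE, rt = TRUE) {
  onsets <- regressors$onset
  if (max(onsets) >= n_vols * tr) {
    stop("onsets extend beyond the scan duration", call. = FALSE)
  }
  cols <- list(onset = convolve_events(onsets, NULL, n_vols, tr))
  if (!is.null(modulator)) {
    w <- regressors[[modulator]]
    if (is.null(w)) stop("unknown modulator: ", modulator, call. = FALSE)
    cols[[modulator]] <- convolve_events(onsets, w, n_vols, tr)
  }
  if (derivatives) {
    cols$onset_deriv <- convolve_events(onsets, NULL, n_vols, tr,
                                        kernel = canonical_hrf_derivative)
    if (!is.null(modulator)) {
      cols[[paste0(modulator, "_deriv")]] <-
        convolve_events(onsets, regressors[[modulator]], n_vols, tr,
                        kernel = canonical_hrf_derivative)
    }
  }
  if (rt) cols$rt <- convolve_events(onsets, regressors$rt_z, n_vols, tr)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_vols)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    }
    for (j in seq_len(ncol(nuisance))) cols[[colnames(nuisance)[j]]] <- nuisance[, j]
  }
  cols$constant <- rep(1, n_vols)
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(X, "tr") <- tr
  X
}

#' Top principal components of a masked time series
#'
#' The first `k` principal-component time courses (unit variance) of the
#' voxels inside a tissue mask; used as nuisance regressors standing in for
#' white-matter and CSF signals.
#'
#' @param timeseries Volumes x voxels matrix.
#' @param mask Logical or index vector selecting mask voxels (columns).
#' @param k Number of components (default 5).
#' @return Matrix (`volumes` x `k`) of component scores, each unit variance.
#' @export
compute_nuisance_pcs <- function(timeseries, mask, k = 5L) {
  sub <- timeseries[, mask, drop = FALSE]
  if (ncol(sub) < k) stop("fewer than ", k, " voxels in mask", call. = FALSE)
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sds <- apply(scores, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(scores, 2L, sds, "/")
}

#' Fit the conjugate Bayesian GLM to one time series
#'
#' Exact closed-form posterior and log marginal likelihood (model evidence)
#' under the normal–inverse-gamma prior of [glm_prior]. With
#' \eqn{V_n = (V_0^{-1} + X^T X)^{-1}}, \eqn{m_n = V_n X^T y},
#' \eqn{a_n = a_0 + n/2}, \eqn{b_n = b_0 + (y^T y - m_n^T V_n^{-1} m_n)/2}:
#' \deqn{\log p(y) = -\tfrac{n}{2}\log 2\pi
#'   + \tfrac12 \log\frac{|V_n|}{|V_0|}
#'   + a_0 \log b_0 - a_n \log b_n + \log\Gamma(a_n) - \log\Gamma(a_0).}
#'
#' @param y Numeric response vector (one voxel's time series).
#' @param X Design matrix (rows = length of `y`).
#' @param prior A [glm_prior].
#' @return A list of class `bglm` with `beta_mean`, `beta_cov` (posterior
#'   covariance of beta, \eqn{b_n/(a_n-1) V_n}), `a_n`, `b_n`,
#'   `log_evidence`, `prior`.
#' @export
fit_bayesian_glm <- function(y, X, prior = glm_prior()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    stop("non-finite data", call. = FALSE)
  }
  n <- length(y)
  V0 <- resolve_V0(prior, X)
  V0i <- solve(V0)
  Vni <- V0i + crossprod(X)
  Vn <- solve(Vni)
  Vn <- (Vn + t(Vn)) / 2
  mn <- Vn %*% crossprod(X, y)
  an <- prior$a0 + n / 2
  bn <- prior$b0 + 0.5 * (sum(y^2) - sum(mn * (Vni %*% mn)))
  ld_Vn <- determinant(Vn, logarithm = TRUE)$modulus
  ld_V0 <- determinant(V0, logarithm = TRUE)$modulus
  log_ev <- -n / 2 * log(2 * pi) + 0.5 * (ld_Vn - ld_V0) +
    prior$a0 * log(prior$b0) - an * log(bn) + lgamma(an) - lgamma(prior$a0)
  structure(list(beta_mean = as.numeric(mn),
                 beta_cov = bn / (an - 1) * Vn,
                 a_n = an, b_n = bn,
                 log_evidence = as.numeric(log_ev),
                 names = colnames(X), prior = prior),
            class = "bglm")
}

#' @export
print.bglm <- function(x, ...) {
  cat(sprintf("Conjugate Bayesian GLM: %d coefficients, log evidence %.3f\n",
              length(x$beta_mean), x$log_evidence))
  invisible(x)
}

#' Tidy a Bayesian GLM fit
#'
#' @param x A `bglm` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.bglm <- function(x, ...) {
  tibble::tibble(
    term = if (is.null(x$names)) paste0("b", seq_along(x$beta_mean)) else x$names,
    estimate = x$beta_mean,
    std.error = sqrt(diag(x$beta_cov))
  )
}

#' One-row summary of a Bayesian GLM fit
#'
#' @inheritParams tidy.bglm
#' @return One-row tibble with `log_evidence`, `sigma2_mean`, `df`.
#' @export
glance.bglm <- function(x, ...) {
  tibble::tibble(log_evidence = x$log_evidence,
                 sigma2_mean = x$b_n / (x$a_n - 1),
                 df = length(x$beta_mean))
}

# Vectorised conjugate GLM over many voxels sharing one design matrix.
# Returns log evidence (length V) and posterior-mean betas (p x V).
fit_bglm_matrix <- function(Y, X, prior = glm_prior()) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n)
  V0 <- resolve_V0(prior, X)
  V0i <- solve(V0)
  Vni <- V0i + crossprod(X)
  Vn <- solve(Vni)
  B <- crossprod(X, Y)                        # p x V
  Mn <- Vn %*% B
  an <- prior$a0 + n / 2
  bn <- prior$b0 + 0.5 * (colSums(Y^2) - colSums(Mn * (Vni %*% Mn)))
  ld_Vn <- determinant(Vn, logarithm = TRUE)$modulus
  ld_V0 <- determinant(V0, logarithm = TRUE)$modulus
  log_ev <- -n / 2 * log(2 * pi) + 0.5 * as.numeric(ld_Vn - ld_V0) +
    prior$a0 * log(prior$b0) - an * log(bn) + lgamma(an) - lgamma(prior$a0)
  list(log_evidence = as.numeric(log_ev), beta = Mn, a_n = an, b_n = bn)
}

# AR(1) coefficient of a residual matrix (lag-1 autocorrelation pooled
# across columns by median).
estimate_ar1 <- function(R) {
  n <- nrow(R)
  num <- colSums(R[-1L, , drop = FALSE] * R[-n, , drop = FALSE])
  den <- colSums(R^2)
  stats::median(num / pmax(den, .Machine$double.eps))
}

# Exact AR(1) whitening transform applied to the rows of M.
whiten_ar1 <- function(M, rho) {
  M <- as.matrix(M)
  n <- nrow(M)
  W <- rbind(sqrt(1 - rho^2) * M[1L, , drop = FALSE],
             M[-1L, , drop = FALSE] - rho * M[-n, , drop = FALSE])
  W
}

#' Fit per-model log-evidence and beta maps for one subject
#'
#' For each candidate model, builds the run-wise design matrices (onset +
#' that model's modulator + derivatives + RT + constant, plus any supplied
#' nuisance columns), optionally prewhitens with a pooled AR(1) coefficient
#' estimated from OLS residuals, fits the conjugate Bayesian GLM to every
#' voxel, sums log evidence over runs (runs are conditionally independent)
#' and averages the modulator betas across runs.
#'
#' @param subject One element of a [simulate_cohort()] `subjects` list (or
#'   any list with `regressors` per run and `bold` per run).
#' @param config The cohort's `sim_config`.
#' @param prior A [glm_prior].
#' @param models Character vector of modulator names (default all five).
#' @param whiten Prewhiten with a pooled AR(1) estimate (default TRUE).
#' @param nuisance Optional list (per run) of nuisance matrices.
#' @return A list of class `evidence_maps`: `log_evidence` and `beta` —
#'   named lists of 3-D arrays (one per model) — plus `dim` and
#'   `voxel_size_mm`.
#' @export
fit_evidence_maps <- function(subject, config, prior = glm_prior(),
                              models = MODEL_NAMES, whiten = TRUE,
                              nuisance = NULL) {
  dm <- config$dim
  n_vox <- prod(dm)
  logE <- purrr::map(models, ~numeric(n_vox)) |> rlang::set_names(models)
  beta <- purrr::map(models, ~numeric(n_vox)) |> rlang::set_names(models)
  runs <- names(subject$regressors)
  run_trials <- split(subject$trials, subject$trials$run)
  for (r in seq_along(runs)) {
    Y <- subject$bold[[r]]$bold
    Yc <- sweep(Y, 2L, colMeans(Y))  # centre; constant column absorbs rest
    nuis_r <- if (is.null(nuisance)) NULL else nuisance[[r]]
    for (m in models) {
      X <- build_design_matrix(run_trials[[r]], m, subject$regressors[[r]],
                               n_vols = config$n_vols, tr = config$tr,
                               nuisance = nuis_r)
      if (whiten) {
        ols <- Yc - X %*% qr.solve(X, Yc)
        rho <- estimate_ar1(ols)
        Xw <- whiten_ar1(X, rho)
        Yw <- whiten_ar1(Yc, rho)
      } else {
        Xw <- X; Yw <- Yc
      }
      fit <- fit_bglm_matrix(Yw, Xw, prior)
      logE[[m]] <- logE[[m]] + fit$log_evidence
      beta[[m]] <- beta[[m]] + fit$beta[which(colnames(X) == m), ] / length(runs)
    }
  }
  structure(list(
    log_evidence = purrr::map(logE, ~array(.x, dm)),
    beta = purrr::map(beta, ~array(.x, dm)),
    dim = dm, voxel_size_mm = config$voxel_size_mm
  ), class = "evidence_maps")
}

gauss_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

conv1d_renorm <- function(mat, k) {
  # convolve each column with k, renormalising at the edges so a constant
  # input stays constant
  n <- nrow(mat)
  half <- (length(k) - 1L) / 2L
  pad <- matrix(0, half, ncol(mat))
  padded <- rbind(pad, mat, pad)
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  out <- apply(padded, 2L, function(col) {
    stats::convolve(col, k, type = "filter")
  })
  norm <- stats::convolve(ones, k, type = "filter")
  sweep(matrix(out, n, ncol(mat)), 1L, norm, "/")
}

#' Gaussian-smooth a 3-D volume
#'
#' Separable Gaussian smoothing with FWHM specified in millimetres,
#' edge-renormalised (a constant volume is unchanged).
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Full width at half maximum, mm.
#' @param voxel_mm Isotropic voxel size, mm.
#' @return Smoothed array of the same dimension.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_mm = 3) {
  stopifnot(length(dim(vol)) == 3L, voxel_mm > 0)
  if (fwhm_mm <= 0) return(vol)
  if (fwhm_mm < voxel_mm) {
    warning("fwhm smaller than voxel size; smoothing is a near no-op")
  }
  k <- gauss_kernel_1d(fwhm_mm, voxel_mm)
  dm <- dim(vol)
  a <- vol
  # dim 1
  a <- array(conv1d_renorm(matrix(a, dm[1L]), k), dm)
  # dim 2
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(conv1d_renorm(matrix(a, dm[2L]), k), dm[c(2L, 1L, 3L)])
  a <- aperm(a, c(2L, 1L, 3L))
  # dim 3
  a <- aperm(a, c(3L, 2L, 1L))
  a <- array(conv1d_renorm(matrix(a, dm[3L]), k), dm[c(3L, 2L, 1L)])
  aperm(a, c(3L, 2L, 1L))
}

#' Smooth a subject's evidence (and beta) maps
#'
#' Applies [smooth_volume] to every per-model log-evidence and beta volume.
#' This is the spatial-regularisation step of the pipeline: soft pooling of
#' evidence across neighbouring voxels before group-level model selection
#' (default 8 mm FWHM).
#'
#' @param maps An `evidence_maps` object.
#' @param fwhm_mm FWHM in mm (default 8).
#' @return The smoothed `evidence_maps`.
#' @export
smooth_evidence_maps <- function(maps, fwhm_mm = 8) {
  stopifnot(inherits(maps, "evidence_maps"), fwhm_mm >= 0)
  maps$log_evidence <- purrr::map(maps$log_evidence, smooth_volume,
                                  fwhm_mm = fwhm_mm,
                                  voxel_mm = maps$voxel_size_mm)
  maps$beta <- purrr::map(maps$beta, smooth_volume, fwhm_mm = fwhm_mm,
                          voxel_mm = maps$voxel_size_mm)
  maps
}
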