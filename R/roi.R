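#' Subject-level model probability peak inside an ROI
#'
#' At every ROI voxel the model's posterior probability is its evidence
#' share, \eqn{\exp(\log E_m - \mathrm{logsumexp}_k \log E_k)}; the peak is
#' the argmax over the ROI, ties broken deterministically by lowest linear
#' index.
#'
#' @param roi_mask Logical 3-D array (or integer index vector) selecting ROI
#'   voxels.
#' @param maps The subject's (smoothed) `evidence_maps`.
#' @param model Model name whose probability defines the peak.
#' @return One-row tibble: `x`, `y`, `z`, `index` (linear voxel index),
#'   `probability`.
#' @export
find_subject_peak <- function(roi_mask, maps, model) {
  stopifnot(inherits(maps, "evidence_maps"),
            model %in% names(maps$log_evidence))
  idx <- if (is.logical(roi_mask)) which(roi_mask) else as.integer(roi_mask)
  if (length(idx) == 0L) stop("empty ROI", call. = FALSE)
  L <- vapply(maps$log_evidence, function(a) as.numeric(a)[idx],
              numeric(length(idx)))
  L <- matrix(L, nrow = length(idx))
  m <- apply(L, 1L, max)
  prob <- exp(L[, match(model, names(maps$log_evidence))] - m) /
    rowSums(exp(L - m))
  best <- which.max(prob)               # which.max takes the first maximum
  peak <- idx[best]
  co <- arrayInd(peak, maps$dim)
  tibble::tibble(x = co[1L], y = co[2L], z = co[3L], index = peak,
                 probability = prob[best])
}

#' Split family clusters among member models
#'
#' Group ROI masks for the members of a family: within the family's
#' supra-threshold clusters, each voxel is assigned to the member model
#' with the highest model-level EP (argmax over members).
#'
#' @param ep_maps An `ep_maps` object carrying model-level EP maps.
#' @param clusters A `cluster_set` from thresholding the family EP map.
#' @param members Character vector of member model names.
#' @return Named list of logical 3-D masks, one per member.
#' @export
split_family_clusters <- function(ep_maps, clusters, members) {
  stopifnot(all(members %in% names(ep_maps$ep)))
  inside <- clusters$labels > 0L
  member_ep <- vapply(members, function(m) as.numeric(ep_maps$ep[[m]]),
                      numeric(prod(ep_maps$dim)))
  win <- max.col(member_ep, ties.method = "first")
  purrr::map(stats::setNames(seq_along(members), members), function(k) {
    array(inside & win == k, ep_maps$dim)
  })
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default-prior Bayes factor for a non-zero mean: Cauchy prior with scale
#' `r` on the standardised effect size, Jeffreys prior on the variance.
#' Computed by the standard one-dimensional integral over the g-prior
#' mixing variable.
#'
#' @param values Numeric vector (e.g. per-subject betas or paired
#'   differences).
#' @param r Cauchy prior scale (default 0.707).
#' @return Named list: `bf10`, `bf01` (reciprocal), `t`, `n`.
#' @export
jzs_onesample_bf <- function(values, r = 0.707) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance", call. = FALSE)
  t <- mean(x) / (s / sqrt(n))
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_null) *
      r / sqrt(2 * pi) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  bf10 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  list(bf10 = bf10, bf01 = 1 / bf10, t = t, n = n)
}

#' Bayes factor for association in a 2x2 contingency table
#'
#' Tests independence of two binary variables (e.g. target detection and
#' match/mismatch report). Under the joint-multinomial sampling model the
#' alternative places a Dirichlet(`a`,...,`a`) prior on the four cell
#' probabilities; the independence null factorises the cell probabilities
#' into row and column margins, each with a Dirichlet(`a`, `a`) prior. With
#' `fixed_margins = TRUE` the row margins are conditioned on
#' (independent-binomial rows vs one common binomial).
#'
#' @param table 2x2 matrix (or 4-vector, row-major) of non-negative integer
#'   counts.
#' @param a Prior concentration (default 1, uniform).
#' @param fixed_margins Use the fixed-row-margin (binomial) variant.
#' @return Named list: `bf10` (association), `bf01` (independence).
#' @export
bayes_association_bf <- function(table, a = 1, fixed_margins = FALSE) {
  y <- if (is.matrix(table)) {
    matrix(as.numeric(table), 2L, 2L)
  } else {
    matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  }
  stopifnot(all(y >= 0), all(y == round(y)))
  n <- sum(y)
  if (n == 0) stop("all-zero table", call. = FALSE)
  rs <- rowSums(y); cs <- colSums(y)
  lbeta_vec <- function(av) sum(lgamma(av)) - lgamma(sum(av))
  if (fixed_margins) {
    # rows fixed: H1 independent Beta-binomial rows, H0 one shared theta
    log_m1 <- sum(vapply(seq_len(2L), function(i) {
      lbeta_vec(y[i, ] + a) - lbeta_vec(c(a, a))
    }, numeric(1)))
    log_m0 <- lbeta_vec(cs + a) - lbeta_vec(c(a, a))
  } else {
    log_m1 <- lbeta_vec(as.numeric(y) + a) - lbeta_vec(rep(a, 4L))
    log_m0 <- (lbeta_vec(rs + a) - lbeta_vec(c(a, a))) +
      (lbeta_vec(cs + a) - lbeta_vec(c(a, a)))
  }
  bf10 <- exp(log_m1 - log_m0)
  list(bf10 = bf10, bf01 = 1 / bf10)
}

#' Categorise a Bayes factor
#'
#' Standard evidence bands: 1 < BF < 3 negligible, 3 < BF < 20 positive,
#' 20 < BF < 150 strong, BF > 150 very strong. Pass whichever direction's
#' Bayes factor (BF10 or BF01) you are quantifying; values at or below 1
#' (evidence pointing the other way) are reported as negligible. Band
#' boundaries are resolved downward (BF = 3 is negligible).
#'
#' @param bf Positive Bayes factor (vectorised).
#' @return Character vector: `"negligible"`, `"positive"`, `"strong"` or
#'   `"very strong"`.
#' @export
classify_evidence <- function(bf) {
  stopifnot(all(bf > 0))
  cut(bf, breaks = c(0, 3, 20, 150, Inf),
      labels = c("negligible", "positive", "strong", "very strong"),
      right = TRUE) |> as.character()
}

sphere_indices <- function(centre, dim, radius_mm, voxel_mm) {
  r_vox <- radius_mm / voxel_mm
  span <- floor(r_vox)
  off <- expand.grid(dx = -span:span, dy = -span:span, dz = -span:span)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r_vox^2, , drop = FALSE]
  x <- centre[1L] + off$dx; y <- centre[2L] + off$dy; z <- centre[3L] + off$dz
  ok <- x >= 1L & x <= dim[1L] & y >= 1L & y <= dim[2L] & z >= 1L & z <= dim[3L]
  if (!any(ok)) stop("sphere does not intersect the volume", call. = FALSE)
  as.integer((z[ok] - 1L) * dim[1L] * dim[2L] + (y[ok] - 1L) * dim[1L] + x[ok])
}

#' Extract stimulus-response profiles from spheres at subject peaks
#'
#' For each subject, averages the ten level-wise beta volumes over a sphere
#' (default 4 mm radius; membership by centre-to-centre distance in mm)
#' centred on that subject's model probability peak, then summarises across
#' subjects.
#'
#' @param peaks Tibble of subject peaks (one row per subject, columns
#'   `x`, `y`, `z` as from [find_subject_peak]).
#' @param beta_volumes List (per subject) of lists of ten 3-D beta arrays
#'   (as from [fit_ten_level_glm]).
#' @param radius_mm Sphere radius in mm (default 4).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return A list of class `srp`: `per_subject` (tibble `subject`, `level`,
#'   `beta`) and `group` (tibble `level`, `mean`, `se`).
#' @export
extract_srp <- function(peaks, beta_volumes, radius_mm = 4, voxel_mm = 3) {
  stopifnot(nrow(peaks) == length(beta_volumes))
  per_subject <- purrr::map_dfr(seq_len(nrow(peaks)), function(s) {
    vols <- beta_volumes[[s]]
    dm <- dim(vols[[1L]])
    idx <- sphere_indices(c(peaks$x[s], peaks$y[s], peaks$z[s]),
                          dm, radius_mm, voxel_mm)
    tibble::tibble(subject = s, level = seq_along(vols),
                   beta = vapply(vols, function(v) mean(v[idx]), numeric(1)))
  })
  group <- per_subject |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(mean = mean(.data$beta),
                     se = stats::sd(.data$beta) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(per_subject = per_subject, group = group), class = "srp")
}

#' @export
print.srp <- function(x, ...) {
  cat("Stimulus-response profile over 10 intensity levels\n")
  print(x$group)
  invisible(x)
}

#' Plot a stimulus-response profile
#'
#' @param object An `srp`.
#' @param ... Unused.
#' @return A ggplot object: group mean +- SE over the ten levels.
#' @export
autoplot.srp <- function(object, ...) {
  ggplot2::ggplot(object$group,
                  ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Intensity level", y = "Beta (a.u.)")
}

#' Classify the shape of a stimulus-response profile
#'
#' Least-squares shape fitting: the group SRP is regressed on each
#' candidate shape over levels 1-10 — linear ramp, sigmoid (logistic in
#' level centred between levels 5 and 6) and inverse-U (the sigmoid's
#' derivative) — and the best-fitting shape (lowest residual sum of
#' squares; all templates have two parameters, so the comparison is fair)
#' is retained only if it beats the flat (intercept-only) null at an
#' F-test with level `alpha`. Flat is the null hypothesis: with only ten
#' points and three competing templates, an unguarded fit comparison would
#' routinely promote noise wobble in genuinely flat profiles to a shape.
#'
#' @param srp_mean Numeric vector of 10 group-mean betas, or an `srp`.
#' @param steepness Logistic steepness (per level) of the sigmoid template.
#' @param alpha Significance level of the shape-vs-flat F-test (default
#'   0.01, conservative against the three-template multiplicity).
#' @return Character scalar: `"linear"`, `"sigmoid"`, `"inverse_u"` or
#'   `"flat"`.
#' @export
classify_srp_shape <- function(srp_mean, steepness = 1.2, alpha = 0.01) {
  y <- if (inherits(srp_mean, "srp")) srp_mean$group$mean else as.numeric(srp_mean)
  stopifnot(length(y) == 10L)
  l <- 1:10
  shapes <- list(
    linear = l,
    sigmoid = stats::plogis(steepness * (l - 5.5)),
    inverse_u = stats::dlogis(steepness * (l - 5.5))
  )
  rss <- vapply(shapes, function(s) {
    sum(stats::lm(y ~ s)$residuals^2)
  }, numeric(1))
  rss_flat <- sum((y - mean(y))^2)
  best <- names(rss)[which.min(rss)]
  f_stat <- (rss_flat - rss[[best]]) / (rss[[best]] / (10 - 2))
  if (!is.finite(f_stat) || f_stat < stats::qf(1 - alpha, 1, 8)) {
    return("flat")
  }
  best
}

#' Fit the ten-level GLM and return level-wise beta volumes
#'
#' A second first-level model for profile extraction: ten onset regressors,
#' one per intensity level, plus the RT modulation and constant (and any
#' nuisance columns), fitted with the same conjugate Bayesian machinery as
#' the main analysis; the resulting beta volumes are smoothed (default
#' 8 mm FWHM).
#'
#' @param subject One cohort subject (needs `trials`, `regressors`, `bold`).
#' @param config The cohort's `sim_config`.
#' @param prior A [glm_prior].
#' @param fwhm_mm Smoothing FWHM for the beta volumes (0 disables).
#' @param whiten Prewhiten with a pooled AR(1) estimate.
#' @return List of ten 3-D beta arrays (signal units), run-averaged.
#' @export
fit_ten_level_glm <- function(subject, config, prior = glm_prior(),
                              fwhm_mm = 8, whiten = TRUE) {
  dm <- config$dim
  run_trials <- split(subject$trials, subject$trials$run)
  n_runs <- length(run_trials)
  betas <- purrr::map(1:10, ~numeric(prod(dm)))
  for (r in seq_len(n_runs)) {
    tr <- dplyr::filter(run_trials[[r]], !.data$is_null)
    if (!all(1:10 %in% tr$level)) {
      stop("missing intensity level in run ", r, call. = FALSE)
    }
    cols <- purrr::map(1:10, function(lv) {
      convolve_events(tr$onset[tr$level == lv], NULL, config$n_vols, config$tr)
    })
    names(cols) <- paste0("level", 1:10)
    cols$rt <- convolve_events(tr$onset, subject$regressors[[r]]$rt_z,
                               config$n_vols, config$tr)
    cols$constant <- rep(1, config$n_vols)
    X <- do.call(cbind, cols)
    Y <- subject$bold[[r]]$bold
    Yc <- sweep(Y, 2L, colMeans(Y))
    if (whiten) {
      ols <- Yc - X %*% qr.solve(X, Yc)
      rho <- estimate_ar1(ols)
      Xw <- whiten_ar1(X, rho)
      Yw <- whiten_ar1(Yc, rho)
    } else {
      Xw <- X; Yw <- Yc
    }
    fit <- fit_bglm_matrix(Yw, Xw, prior)
    for (lv in 1:10) betas[[lv]] <- betas[[lv]] + fit$beta[lv, ] / n_runs
  }
  purrr::map(betas, function(b) {
    v <- array(b, dm)
    if (fwhm_mm > 0) smooth_volume(v, fwhm_mm, config$voxel_size_mm) else v
  })
}
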