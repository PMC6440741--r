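make_run_fixture <- function(seed = 91L) {
  fit <- example_fit()
  grid <- derive_intensity_grid(fit)
  cfg <- tiny_cohort_config()
  trials <- build_trial_table(grid, n_runs = 1L, seed = seed)
  trials <- simulate_behaviour(fit, trials, cfg, seed = seed + 1L)
  list(trials = trials, regressors = build_regressors(trials, fit),
       cfg = cfg)
}

test_that("design matrix has the documented columns and full rank", {
  fx <- make_run_fixture()
  X <- build_design_matrix(fx$trials, "intensity", fx$regressors,
                           n_vols = fx$cfg$n_vols, tr = fx$cfg$tr)
  expect_identical(colnames(X),
                   c("onset", "intensity", "onset_deriv", "intensity_deriv",
                     "rt", "constant"))
  expect_equal(qr(X)$rank, ncol(X))
  # z-scored modulator stays near-orthogonal to the constant
  expect_lt(abs(mean(X[, "intensity"])), 0.01)
  # no-derivative / no-rt variants prune the expected columns
  X2 <- build_design_matrix(fx$trials, "uncertainty", fx$regressors,
                            n_vols = fx$cfg$n_vols, tr = fx$cfg$tr,
                            derivatives = FALSE, rt = FALSE)
  expect_identical(colnames(X2), c("onset", "uncertainty", "constant"))
})

test_that("collinear columns are named in the rank-deficiency error", {
  fx <- make_run_fixture()
  base <- build_design_matrix(fx$trials, "intensity", fx$regressors,
                              n_vols = fx$cfg$n_vols, tr = fx$cfg$tr)
  dup <- matrix(base[, "onset"], ncol = 1,
                dimnames = list(NULL, "copy_of_onset"))
  expect_error(
    build_design_matrix(fx$trials, "intensity", fx$regressors,
                        n_vols = fx$cfg$n_vols, tr = fx$cfg$tr,
                        nuisance = dup),
    "collinear")
})

test_that("nuisance PCs match an SVD oracle and are orthonormal", {
  set.seed(95)
  ts <- matrix(rnorm(10 * 50), 10, 50)
  pcs <- compute_nuisance_pcs(ts, seq_len(50), k = 5L)
  expect_equal(dim(pcs), c(10L, 5L))
  expect_true(all(abs(apply(pcs, 2, stats::sd) - 1) < 1e-10))
  cors <- crossprod(scale(pcs, center = TRUE, scale = FALSE))
  expect_true(all(abs(cors[upper.tri(cors)]) < 1e-8))
  # SVD oracle: same column spaces, component by component
  sv <- svd(scale(ts, center = TRUE, scale = FALSE))
  for (j in 1:5) {
    expect_equal(abs(stats::cor(pcs[, j], sv$u[, j])), 1, tolerance = 1e-8)
  }
  # rank-1 structure: PC1 carries essentially all variance
  ts1 <- outer(rnorm(10), rnorm(50)) + matrix(rnorm(500, 0, 1e-8), 10)
  p <- stats::prcomp(ts1)
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 0.999)
  expect_error(compute_nuisance_pcs(ts, 1:3, k = 5L), "fewer than 5")
})

test_that("log evidence matches the brute-force quadrature oracle", {
  set.seed(42)
  n <- 12L
  X <- cbind(mod = rnorm(n), constant = 1)
  for (i in 1:3) {
    y <- 0.5 * X[, 1] + 0.3 + rnorm(n, 0, c(0.5, 1, 2)[i])
    prior <- glm_prior(g = n)
    fit <- fit_bayesian_glm(y, X, prior)
    oracle <- quad_evidence_oracle(y, X, prior)
    expect_lt(abs(fit$log_evidence - oracle), 1e-3)
  }
})

test_that("identical designs yield identical evidence; nuisance order is irrelevant", {
  fx <- make_run_fixture()
  set.seed(97)
  y <- rnorm(fx$cfg$n_vols)
  X <- build_design_matrix(fx$trials, "detection", fx$regressors,
                           n_vols = fx$cfg$n_vols, tr = fx$cfg$tr)
  e1 <- fit_bayesian_glm(y, X)$log_evidence
  e2 <- fit_bayesian_glm(y, X)$log_evidence
  expect_lt(abs(e1 - e2), 1e-10)
  # permuting nuisance columns leaves evidence unchanged
  nuis <- matrix(rnorm(fx$cfg$n_vols * 3), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  Xa <- build_design_matrix(fx$trials, "detection", fx$regressors,
                            n_vols = fx$cfg$n_vols, tr = fx$cfg$tr,
                            nuisance = nuis)
  Xb <- build_design_matrix(fx$trials, "detection", fx$regressors,
                            n_vols = fx$cfg$n_vols, tr = fx$cfg$tr,
                            nuisance = nuis[, c(3, 1, 2)])
  pr <- glm_prior(g = 100)
  expect_lt(abs(fit_bayesian_glm(y, Xa, pr)$log_evidence -
                  fit_bayesian_glm(y, Xb, pr)$log_evidence), 1e-8)
})

test_that("flat-prior limit converges to ordinary least squares", {
  set.seed(98)
  n <- 60L
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), constant = 1)
  y <- X %*% c(1.2, -0.7, 0.4) + rnorm(n, 0, 0.5)
  ols <- qr.solve(X, y)
  post <- fit_bayesian_glm(as.numeric(y), X, glm_prior(g = 1e10))
  expect_lt(max(abs(post$beta_mean - as.numeric(ols))), 1e-6)
  expect_true(isSymmetric(post$beta_cov, tol = 1e-12))
  expect_true(all(eigen(post$beta_cov, only.values = TRUE)$values > 0))
})

test_that("posterior beta sign tracks the generating amplitude", {
  fx <- make_run_fixture(seed = 99L)
  X <- build_design_matrix(fx$trials, "intensity", fx$regressors,
                           n_vols = fx$cfg$n_vols, tr = fx$cfg$tr)
  set.seed(100)
  for (amp in c(0.5, 1, 3)) {
    hits <- mean(replicate(40, {
      y <- amp * X[, "intensity"] + rnorm(fx$cfg$n_vols)
      fit_bayesian_glm(y, X)$beta_mean[2L] > 0
    }))
    if (amp >= 1) expect_gt(hits, 0.95) else expect_gt(hits, 0.7)
  }
})

test_that("the generating model earns the highest evidence on average", {
  # power/evidence check: data generated under the intensity model
  fx <- make_run_fixture(seed = 103L)
  cfg <- fx$cfg
  Xg <- purrr::map(
    c("intensity", "detection", "uncertainty"),
    ~build_design_matrix(fx$trials, .x, fx$regressors,
                         n_vols = cfg$n_vols, tr = cfg$tr))
  set.seed(104)
  n_vox <- 60L
  Y <- matrix(rnorm(cfg$n_vols * n_vox), cfg$n_vols, n_vox) +
    outer(Xg[[1L]][, 2L], rep(1, n_vox))
  fits <- purrr::map(Xg, ~detectbms:::fit_bglm_matrix(Y, .x))
  dE_det <- mean(fits[[1L]]$log_evidence - fits[[2L]]$log_evidence)
  dE_unc <- mean(fits[[1L]]$log_evidence - fits[[3L]]$log_evidence)
  expect_gt(dE_det, 0)
  expect_gt(dE_unc, 0)
  # vectorised fit agrees with the single-series fit
  single <- fit_bayesian_glm(Y[, 1L], Xg[[1L]])
  expect_equal(fits[[1L]]$log_evidence[1L], single$log_evidence,
               tolerance = 1e-10)
  expect_equal(as.numeric(fits[[1L]]$beta[, 1L]), single$beta_mean,
               tolerance = 1e-10)
})

test_that("evidence-map smoothing is mass-preserving and idempotent at zero", {
  vol <- array(0, c(20, 20, 20))
  vol[10, 10, 10] <- 10
  sm <- smooth_volume(vol, fwhm_mm = 8, voxel_mm = 3)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-6)
  expect_lt(max(sm), max(vol))
  expect_identical(smooth_volume(vol, fwhm_mm = 0), vol)
  const <- array(3.7, c(8, 8, 8))
  expect_equal(smooth_volume(const, fwhm_mm = 8, voxel_mm = 3), const,
               tolerance = 1e-12)
  expect_warning(smooth_volume(vol, fwhm_mm = 1, voxel_mm = 3),
                 "no-op")
})

test_that("AR(1) prewhitening recovers the innovation structure", {
  set.seed(105)
  rho <- 0.35
  n <- 400L
  e <- as.numeric(stats::filter(rnorm(n), rho, method = "recursive"))
  R <- matrix(e, ncol = 1)
  rho_hat <- detectbms:::estimate_ar1(R)
  expect_lt(abs(rho_hat - rho), 0.1)
  W <- detectbms:::whiten_ar1(R, rho)
  v <- W[-1, 1]
  expect_lt(abs(sum(v[-1] * v[-length(v)]) / sum(v^2)), 0.1)
})
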