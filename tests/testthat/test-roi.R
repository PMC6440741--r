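fake_maps <- function(dm = c(4L, 4L, 4L), seed = 121L) {
  set.seed(seed)
  structure(list(
    log_evidence = purrr::map(rlang::set_names(MODEL_NAMES),
                              ~array(rnorm(prod(dm)), dm)),
    beta = purrr::map(rlang::set_names(MODEL_NAMES),
                      ~array(rnorm(prod(dm)), dm)),
    dim = dm, voxel_size_mm = 3
  ), class = "evidence_maps")
}

test_that("subject probability peaks are softmax argmaxes with stable ties", {
  maps <- fake_maps()
  mask <- array(FALSE, maps$dim)
  mask[2, 2, 2] <- TRUE
  pk <- find_subject_peak(mask, maps, "intensity")
  expect_equal(c(pk$x, pk$y, pk$z), c(2, 2, 2))
  expect_true(pk$probability > 0 && pk$probability < 1)
  # probabilities over models sum to 1 at the peak voxel
  L <- vapply(maps$log_evidence, function(a) a[2, 2, 2], numeric(1))
  expect_equal(sum(exp(L - max(L)) / sum(exp(L - max(L)))), 1,
               tolerance = 1e-12)
  expect_equal(pk$probability,
               unname(exp(L["intensity"] - max(L)) / sum(exp(L - max(L)))),
               tolerance = 1e-12)
  expect_error(find_subject_peak(array(FALSE, maps$dim), maps, "report"),
               "empty ROI")
  # deterministic tie-break: equal evidence everywhere -> lowest index
  tied <- maps
  for (m in MODEL_NAMES) tied$log_evidence[[m]] <- array(0, maps$dim)
  full <- array(TRUE, maps$dim)
  expect_equal(find_subject_peak(full, tied, "report")$index, 1L)
})

test_that("JZS Bayes factor matches the quadrature oracle on five fixtures", {
  set.seed(122)
  fixtures <- list(rnorm(10, 0.5, 1), rnorm(8, 0, 1), rnorm(20, 0.3, 0.7),
                   rnorm(12, -0.8, 1.5), rnorm(27, 0.15, 1))
  for (x in fixtures) {
    bf <- jzs_onesample_bf(x)
    oracle <- jzs_quad_oracle(x, r = 0.707)
    expect_lt(abs(bf$bf10 - oracle) / oracle, 1e-3)
    expect_equal(bf$bf10 * bf$bf01, 1, tolerance = 1e-12)
  }
})

test_that("JZS Bayes factor behaves like a default-prior t-test", {
  x0 <- c(-2, -1, 0, 1, 2) * 0.7 + 0   # sample mean exactly 0
  expect_lt(jzs_onesample_bf(x0)$bf10, 1)
  set.seed(123)
  x <- rnorm(15, 0.6, 1)
  expect_equal(jzs_onesample_bf(x * 3.7)$bf10, jzs_onesample_bf(x)$bf10,
               tolerance = 1e-12)
  # monotone in |mean|/sd at fixed n
  base <- scale(rnorm(12))[, 1]
  bfs <- vapply(c(0, 0.3, 0.6, 1, 1.5),
                function(m) jzs_onesample_bf(base + m)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_onesample_bf(rep(1, 5)), "zero variance")
  expect_error(jzs_onesample_bf(1), "at least 2")
})

test_that("association Bayes factor matches a Monte-Carlo oracle and is symmetric", {
  fixtures <- list(matrix(c(12, 3, 4, 11), 2), matrix(c(5, 5, 5, 5), 2),
                   matrix(c(20, 2, 3, 15), 2), matrix(c(8, 1, 9, 2), 2),
                   matrix(c(3, 7, 6, 4), 2))
  for (y in fixtures) {
    bf <- bayes_association_bf(y)
    oracle <- contingency_mc_oracle(y)
    expect_lt(abs(bf$bf10 - oracle) / oracle, 0.05)
    expect_equal(bf$bf10 * bf$bf01, 1, tolerance = 1e-12)
    tbf <- bayes_association_bf(t(y))
    expect_equal(bf$bf10, tbf$bf10, tolerance = 1e-12)
  }
  # margins exactly proportional at large n -> independence favoured
  indep <- matrix(c(50, 50, 50, 50), 2)
  expect_gt(bayes_association_bf(indep)$bf01, 1)
  expect_error(bayes_association_bf(matrix(0, 2, 2)), "all-zero")
})

test_that("evidence categories follow the published bands", {
  expect_identical(classify_evidence(88.01), "strong")
  expect_identical(classify_evidence(2), "negligible")
  expect_identical(classify_evidence(6114.09), "very strong")
  expect_identical(classify_evidence(c(1.5, 10, 100, 151)),
                   c("negligible", "positive", "strong", "very strong"))
  expect_error(classify_evidence(-1))
})

test_that("SRP spheres honour radius and degenerate volumes", {
  dm <- c(9L, 9L, 9L)
  const_vols <- purrr::map(1:10, ~array(.x / 10, dm))
  peaks <- tibble::tibble(x = 5L, y = 5L, z = 5L)
  # radius below voxel size -> centre voxel only
  idx <- detectbms:::sphere_indices(c(5L, 5L, 5L), dm, radius_mm = 2,
                                    voxel_mm = 3)
  expect_length(idx, 1L)
  srp <- extract_srp(peaks, list(const_vols), radius_mm = 4, voxel_mm = 3)
  expect_equal(srp$group$mean, (1:10) / 10, tolerance = 1e-12)
  # 4 mm radius on a 3 mm grid: centre + 6 face neighbours
  idx4 <- detectbms:::sphere_indices(c(5L, 5L, 5L), dm, 4, 3)
  expect_length(idx4, 7L)
  expect_error(detectbms:::sphere_indices(c(-10L, 1L, 1L), dm, 2, 3),
               "sphere")
})

test_that("SRP shape classification separates the four canonical profiles", {
  l <- 1:10
  expect_identical(classify_srp_shape(0.05 * l), "linear")
  expect_identical(classify_srp_shape(stats::plogis(1.3 * (l - 5.5))),
                   "sigmoid")
  expect_identical(classify_srp_shape(stats::dlogis(1.1 * (l - 5.5))),
                   "inverse_u")
  # flat profile with a deterministic, shape-uncorrelated perturbation
  wiggle <- rep(c(1e-4, -1e-4), 5)
  expect_identical(classify_srp_shape(rep(0.2, 10) + wiggle), "flat")
})

test_that("family clusters split among members by EP argmax", {
  dm <- c(4L, 4L, 1L)
  ep_obj <- list(
    ep = list(intensity = array(0, dm), detection = array(0, dm),
              p_detect = array(0, dm)),
    dim = dm
  )
  ep_obj$ep$intensity[1:2, , 1] <- 0.9
  ep_obj$ep$detection[3:4, , 1] <- 0.9
  labels <- array(0L, dm); labels[, 1:2, 1] <- 1L
  clusters <- list(labels = labels)
  masks <- split_family_clusters(ep_obj, clusters,
                                 c("intensity", "detection", "p_detect"))
  expect_true(all(masks$intensity[1:2, 1:2, 1]))
  expect_true(all(masks$detection[3:4, 1:2, 1]))
  expect_false(any(masks$p_detect))
  expect_false(any(masks$intensity & masks$detection))
})

test_that("the ten-level GLM reproduces the single-onset fit under equal amplitudes", {
  fit <- example_fit()
  grid <- derive_intensity_grid(fit)
  cfg <- tiny_cohort_config()
  trials <- build_trial_table(grid, n_runs = 1L, seed = 131L)
  trials <- simulate_behaviour(fit, trials, cfg, seed = 132L)
  tr <- dplyr::filter(trials, !is_null)
  # linearity: the level columns sum to the all-onsets column
  cols <- purrr::map(1:10, function(lv) {
    convolve_events(tr$onset[tr$level == lv], NULL, cfg$n_vols, cfg$tr)
  })
  all_onsets <- convolve_events(tr$onset, NULL, cfg$n_vols, cfg$tr)
  expect_lt(max(abs(Reduce(`+`, cols) - all_onsets)), 1e-6)
})
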