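test_that("rfx_bms respects symmetry, shift-invariance and the alpha identity", {
  n <- 6L; K <- 4L
  L <- matrix(rep(rnorm(n), K), n, K)     # identical evidences per subject
  post <- rfx_bms(L, alpha0 = 1)
  expect_equal(post$expected_freq, rep(1 / K, K), tolerance = 1e-8)
  expect_equal(sum(post$alpha), sum(post$alpha0) + n, tolerance = 1e-8)

  set.seed(111)
  L2 <- matrix(rnorm(8 * 3, 0, 4), 8, 3)
  p1 <- rfx_bms(L2)
  L2[3L, ] <- L2[3L, ] + 57.3             # per-subject constant shift
  p2 <- rfx_bms(L2)
  expect_equal(p1$expected_freq, p2$expected_freq, tolerance = 1e-7)
})

test_that("a dominant model collects the expected frequency mass", {
  set.seed(112)
  n <- 10L
  L <- matrix(rnorm(n * 2, 0, 1), n, 2)
  L[, 2L] <- L[, 2L] + 20                 # model 2 dominates by >= 20 nats
  post <- rfx_bms(L, alpha0 = 1)
  # every subject assigned to model 2: alpha -> (1, 11), frequency 11/12
  expect_gt(post$expected_freq[2L], 0.9)
  expect_equal(which.max(post$expected_freq), 2L)
  gb <- gibbs_bms_oracle(L, n_iter = 20000L, burn = 2000L)
  expect_lt(max(abs(post$expected_freq - gb)), 0.02)
})

test_that("variational frequencies agree with the Gibbs oracle", {
  # one quick fixture here; five fixtures at full chain length run in the
  # acceptance suite
  set.seed(2024)
  L <- matrix(rnorm(8 * 3, 0, 5), 8, 3)
  vb <- rfx_bms(L, alpha0 = 1)
  gb <- gibbs_bms_oracle(L, n_iter = 30000L, burn = 3000L)
  expect_lt(max(abs(vb$expected_freq - gb)), 0.02)
})

test_that("raising one subject's evidence never lowers that model's frequency", {
  set.seed(113)
  for (rep in 1:5) {
    L <- matrix(rnorm(6 * 3, 0, 2), 6, 3)
    base <- rfx_bms(L)$expected_freq[1L]
    L[2L, 1L] <- L[2L, 1L] + runif(1, 0.5, 5)
    expect_gte(rfx_bms(L)$expected_freq[1L], base - 1e-9)
  }
})

test_that("exceedance probabilities: symmetry, K = 2 exact form, unit sum", {
  sym <- list(alpha = c(3, 3, 3))
  ep <- exceedance_probabilities(sym, n_samples = 2e5, seed = 5L)
  expect_equal(sum(ep), 1, tolerance = 1e-12)
  expect_true(all(abs(ep - 1 / 3) < 0.01))

  two <- list(alpha = c(8, 2))
  exact <- exceedance_probabilities(two)          # closed form
  expect_equal(exact[1L], 1 - stats::pbeta(0.5, 8, 2), tolerance = 1e-12)
  mc <- exceedance_probabilities(two, n_samples = 4e5, seed = 6L,
                                 exact_k2 = FALSE)
  expect_lt(abs(mc[1L] - exact[1L]), 0.005)
})

test_that("family partitions validate and the prior mass is family-equalised", {
  part <- default_partition()
  expect_identical(sort(unlist(part, use.names = FALSE)), sort(MODEL_NAMES))
  expect_error(family_partition(a = c("intensity"), models = MODEL_NAMES),
               "cover")
  expect_error(
    family_partition(a = c("intensity", "detection"),
                     b = c("detection", "p_detect", "uncertainty", "report"),
                     models = MODEL_NAMES),
    "disjoint")

  set.seed(114)
  L <- matrix(rnorm(6 * 5, 0, 0.01), 6, 5,
              dimnames = list(NULL, MODEL_NAMES))
  fam <- family_bms(L, part, n_samples = 2e5, seed = 7L)
  # prior-adjustment arithmetic: the 3-member family shares one unit of
  # prior mass, so each family's prior expectation is 1/3
  a0 <- fam$bms$alpha0
  expect_equal(unname(a0[match(c("intensity", "detection", "p_detect"),
                               MODEL_NAMES)]), rep(1 / 3, 3))
  expect_equal(unname(a0[match("uncertainty", MODEL_NAMES)]), 1)
  fam_prior <- vapply(part, function(m) sum(a0[match(m, MODEL_NAMES)]),
                      numeric(1))
  expect_equal(unname(fam_prior / sum(fam_prior)), rep(1 / 3, 3))
})

test_that("all-singleton partition reduces family EPs to model EPs", {
  set.seed(115)
  L <- matrix(rnorm(8 * 3, 0, 2), 8, 3,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  singletons <- family_partition(m1 = "m1", m2 = "m2", m3 = "m3",
                                 models = c("m1", "m2", "m3"))
  fam <- family_bms(L, singletons, n_samples = 3e5, seed = 8L)
  expect_true(all(abs(fam$family_ep - fam$model_ep) < 0.01))
})

test_that("voxel-wise BMS reduces to matrix BMS and is subject-exchangeable", {
  set.seed(116)
  n_sub <- 6L
  mk_maps <- function(perm = seq_len(n_sub)) {
    purrr::map(perm, function(s) {
      set.seed(300 + s)
      structure(list(
        log_evidence = purrr::map(rlang::set_names(MODEL_NAMES),
                                  ~array(rnorm(1, 0, 3), c(1L, 1L, 1L))),
        dim = c(1L, 1L, 1L), voxel_size_mm = 3
      ), class = "evidence_maps")
    })
  }
  maps <- mk_maps()
  ep <- run_bms_maps(maps, n_samples = 2e5, seed = 9L)
  L <- t(vapply(maps, function(m) {
    vapply(m$log_evidence, function(a) a[1L], numeric(1))
  }, numeric(5L)))
  colnames(L) <- MODEL_NAMES
  direct <- exceedance_probabilities(rfx_bms(L), n_samples = 2e5, seed = 9L)
  ep_vec <- vapply(ep$ep, function(a) a[1L], numeric(1))
  expect_true(all(abs(ep_vec - direct) < 0.01))

  perm_ep <- run_bms_maps(mk_maps(c(4L, 1L, 6L, 2L, 5L, 3L)),
                          n_samples = 2e5, seed = 9L)
  perm_vec <- vapply(perm_ep$ep, function(a) a[1L], numeric(1))
  expect_true(all(abs(ep_vec - perm_vec) < 0.01))

  misaligned <- mk_maps()
  misaligned[[2L]]$dim <- c(2L, 1L, 1L)
  expect_error(run_bms_maps(misaligned), "aligned")
})

test_that("EP thresholding honours extent, boundary and connectivity rules", {
  ep <- array(0.5, c(12, 12, 12))
  expect_equal(nrow(threshold_ep_map(ep)$table), 0L)

  # 49-voxel blob rejected, 50-voxel blob kept at k_min = 50
  blob49 <- array(0, c(12, 12, 12))
  blob49[1:7, 1:7, 1L][seq_len(49L)] <- 1
  expect_equal(nrow(threshold_ep_map(blob49, 0.99, 50L)$table), 0L)
  blob50 <- blob49
  blob50[1L, 1L, 2L] <- 1
  tab <- threshold_ep_map(blob50, 0.99, 50L)$table
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size, 50L)

  # two blobs separated by sub-threshold voxels -> two labels
  two <- array(0, c(12, 12, 12))
  two[1:4, 1:4, 1:4] <- 1
  two[9:12, 9:12, 9:12] <- 1
  res <- threshold_ep_map(two, 0.99, 10L)
  expect_equal(nrow(res$table), 2L)

  # diagonal contact: connected under 26-connectivity, not under 6
  diag2 <- array(0, c(6, 6, 6))
  diag2[1:2, 1:2, 1:2] <- 1
  diag2[3:4, 3:4, 3:4] <- 1
  expect_equal(nrow(threshold_ep_map(diag2, 0.99, 2L, connectivity = 26L)$table), 1L)
  expect_equal(nrow(threshold_ep_map(diag2, 0.99, 2L, connectivity = 6L)$table), 2L)
})

test_that("per-voxel EPs always sum to one within Monte-Carlo tolerance", {
  set.seed(117)
  maps <- purrr::map(1:4, function(s) {
    structure(list(
      log_evidence = purrr::map(rlang::set_names(MODEL_NAMES),
                                ~array(rnorm(8, 0, 2), c(2L, 2L, 2L))),
      dim = c(2L, 2L, 2L), voxel_size_mm = 3
    ), class = "evidence_maps")
  })
  ep <- run_bms_maps(maps, partition = default_partition(),
                     n_samples = 20000L, seed = 10L)
  tot <- Reduce(`+`, ep$ep)
  expect_true(all(abs(tot - 1) < 0.01))
  fam_tot <- Reduce(`+`, ep$family_ep)
  expect_true(all(abs(fam_tot - 1) < 0.01))
})
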