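# Independent oracles used to validate the closed-form / variational
# implementations. Each one computes the target quantity by brute force
# (grid search, quadrature, Gibbs sampling, plain Monte Carlo) and shares
# no code path with the implementation it checks.

# Exhaustive grid-search MLE for the two-parameter logistic observer.
grid_mle_oracle <- function(x, y, t50_range, slope_range,
                            n_t50 = 121L, n_slope = 121L) {
  t50s <- seq(t50_range[1L], t50_range[2L], length.out = n_t50)
  slopes <- seq(slope_range[1L], slope_range[2L], length.out = n_slope)
  best <- c(ll = -Inf, t50 = NA_real_, slope = NA_real_)
  for (s in slopes) {
    eta <- 4 * s * outer(x, t50s, "-")
    ll <- colSums(y * stats::plogis(eta, log.p = TRUE) +
                    (1 - y) * stats::plogis(-eta, log.p = TRUE))
    j <- which.max(ll)
    if (ll[j] > best["ll"]) best <- c(ll = ll[j], t50 = t50s[j], slope = s)
  }
  list(t50 = unname(best["t50"]), slope = unname(best["slope"]),
       cell = c(diff(t50s)[1L], diff(slopes)[1L]))
}

# Brute-force quadrature of the marginal likelihood of the conjugate
# normal-inverse-gamma GLM on a 2-column design: Simpson grid over the two
# regression weights nested in a Simpson grid over log noise variance.
quad_evidence_oracle <- function(y, X, prior) {
  stopifnot(ncol(X) == 2L)
  n <- length(y); p <- 2L
  V0 <- if (!is.null(prior$V0)) {
    prior$V0
  } else {
    g <- if (is.null(prior$g)) n else prior$g
    g * solve(crossprod(X))
  }
  V0i <- solve(V0)
  ols <- qr.solve(X, y)
  hw <- 12 * sqrt(diag(solve(crossprod(X))) * max(stats::var(y), 1e-6))
  b1 <- seq(ols[1L] - hw[1L], ols[1L] + hw[1L], length.out = 161L)
  b2 <- seq(ols[2L] - hw[2L], ols[2L] + hw[2L], length.out = 161L)
  gr <- as.matrix(expand.grid(b1, b2))
  SSR <- colSums((y - X %*% t(gr))^2)
  q <- rowSums((gr %*% V0i) * gr)
  simp <- function(m) {
    w <- rep(c(2, 4), length.out = m); w[1L] <- 1; w[m] <- 1; w / 3
  }
  lw2 <- log(as.numeric(outer(simp(161L) * diff(b1)[1L],
                              simp(161L) * diff(b2)[1L])))
  lsu <- function(v) { mm <- max(v); mm + log(sum(exp(v - mm))) }
  u <- seq(log(stats::var(y)) - 8, log(stats::var(y)) + 6,
           length.out = 241L)
  wu <- simp(241L) * diff(u)[1L]
  vals <- vapply(u, function(lu) {
    s2 <- exp(lu)
    lsu(-(SSR + q) / (2 * s2) + lw2) - (n + p) / 2 * log(2 * pi * s2) -
      0.5 * as.numeric(determinant(V0)$modulus) +
      prior$a0 * log(prior$b0) - lgamma(prior$a0) -
      (prior$a0 + 1) * lu - prior$b0 / s2 + lu
  }, numeric(1))
  lsu(vals + log(wu))
}

# Gibbs sampler over (model frequencies, subject assignments) for the
# random-effects model-selection posterior; Rao-Blackwellised estimate of
# the expected model frequencies.
gibbs_bms_oracle <- function(L, alpha0 = 1, n_iter = 60000L, burn = 5000L) {
  n <- nrow(L); K <- ncol(L)
  r <- rep(1 / K, K)
  acc <- numeric(K); kept <- 0L
  for (it in seq_len(n_iter)) {
    lw <- sweep(L, 2L, log(r), "+")
    pm <- exp(lw - apply(lw, 1L, max))
    pm <- pm / rowSums(pm)
    m <- apply(pm, 1L, function(p) sample.int(K, 1L, prob = p))
    cnt <- tabulate(m, K)
    g <- stats::rgamma(K, alpha0 + cnt)
    r <- g / sum(g)
    if (it > burn) { acc <- acc + (alpha0 + cnt); kept <- kept + 1L }
  }
  a <- acc / kept
  a / sum(a)
}

# Double quadrature of the marginal likelihoods of the one-sample t-test:
# effect size delta with a Cauchy(0, r) prior nested in log-sigma with a
# Jeffreys prior (the 1/sigma factor cancels against the log-scale
# Jacobian).
jzs_quad_oracle <- function(x, r = 0.707) {
  n <- length(x)
  dhat <- mean(x) / stats::sd(x)
  se <- 1 / sqrt(n)
  simp <- function(m) {
    w <- rep(c(2, 4), length.out = m); w[1L] <- 1; w[m] <- 1; w / 3
  }
  deltas <- seq(dhat - 15 * se, dhat + 15 * se, length.out = 2001L)
  wd <- simp(2001L) * diff(deltas)[1L]
  ls_grid <- seq(log(stats::sd(x)) - 4, log(stats::sd(x)) + 4,
                 length.out = 801L)
  wl <- simp(801L) * diff(ls_grid)[1L]
  loglik_mat <- function(delta_vec, sigma) {
    # sum_i log N(x_i; delta*sigma, sigma) for each delta
    -n / 2 * log(2 * pi * sigma^2) -
      vapply(delta_vec, function(d) sum((x - d * sigma)^2), numeric(1)) /
      (2 * sigma^2)
  }
  lsu <- function(v) { mm <- max(v); mm + log(sum(exp(v - mm))) }
  num_terms <- vapply(ls_grid, function(ls) {
    s <- exp(ls)
    lsu(loglik_mat(deltas, s) + stats::dcauchy(deltas, 0, r, log = TRUE) +
          log(wd))
  }, numeric(1))
  log_num <- lsu(num_terms + log(wl))
  den_terms <- vapply(ls_grid, function(ls) {
    s <- exp(ls)
    -n / 2 * log(2 * pi * s^2) - sum(x^2) / (2 * s^2)
  }, numeric(1))
  log_den <- lsu(den_terms + log(wl))
  exp(log_num - log_den)
}

# Plain Monte-Carlo estimate of both marginal likelihoods of the 2x2
# association test by sampling cell/margin probabilities from their
# Dirichlet priors.
contingency_mc_oracle <- function(y, n_draws = 2e5, seed = 99L) {
  set.seed(seed)
  n <- sum(y)
  lmn <- lgamma(n + 1) - sum(lgamma(y + 1))
  rdir <- function(m, a) {
    g <- matrix(stats::rgamma(m * length(a), rep(a, each = m)), m)
    g / rowSums(g)
  }
  th <- rdir(n_draws, rep(1, 4))
  l1 <- lmn + as.numeric(log(th) %*% as.numeric(y))
  lm1 <- log(mean(exp(l1 - max(l1)))) + max(l1)
  r <- rdir(n_draws, c(1, 1)); cc <- rdir(n_draws, c(1, 1))
  rs <- rowSums(y); cs <- colSums(y)
  l0 <- lmn + log(r[, 1]) * rs[1] + log(r[, 2]) * rs[2] +
    log(cc[, 1]) * cs[1] + log(cc[, 2]) * cs[2]
  lm0 <- log(mean(exp(l0 - max(l0)))) + max(l0)
  exp(lm1 - lm0)
}
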