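test_that("coal_density is a proper density with the stated structure", {
  for (theta in c(0.05, 0.1, 0.7)) {
    ## normalization by nested deterministic quadrature
    inner <- function(t2) vapply(t2, function(u)
      stats::integrate(function(t3) coal_density(rep(u, length(t3)), t3, theta),
                       0, u, rel.tol = 1e-10)$value, numeric(1))
    total <- stats::integrate(inner, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    ## factorization into the two stage densities
    t3 <- 0.21 * theta; t2 <- 0.9 * theta
    expect_equal(coal_density(t2, t3, theta),
                 (6 / theta) * exp(-6 * t3 / theta) *
                   (2 / theta) * exp(-2 * (t2 - t3) / theta),
                 tolerance = 1e-12)
    ## implied means
    m3 <- stats::integrate(function(t2) vapply(t2, function(u)
      stats::integrate(function(t3) t3 * coal_density(rep(u, length(t3)), t3,
                                                      theta),
                       0, u, rel.tol = 1e-10)$value, numeric(1)),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(m3, theta / 6, tolerance = 1e-6)
  }
  expect_error(coal_density(0.1, 0.2, 0.1), "t3")
  expect_error(coal_density(0.1, 0.05, -1), "theta")
})

test_that("marginal likelihood matches Monte-Carlo integration", {
  set.seed(47)
  cases <- list(pattern_counts(nxxx = 1),
                pattern_counts(nxxx = 80, nyxx = 8, nxyx = 5, nxxy = 6,
                               nxyz = 1))
  for (counts in cases) for (theta in c(0.05, 0.1, 0.3)) {
    mc <- oracle_mc_marginal(unclass(counts), theta, "L", n = 2e5)
    q <- marginal_loglik_theta(counts, theta, "L")
    expect_lt(abs(q - mc$value), 3 * mc$se)
  }
})

test_that("quadrature is stable under refinement and symmetric in L/R", {
  counts <- pattern_counts(nxxx = 160, nyxx = 12, nxyx = 9, nxxy = 9,
                           nxyz = 10)
  for (theta in c(0.02, 0.1, 1)) {
    v64 <- marginal_loglik_theta(counts, theta, "L", nodes = 64)
    v128 <- marginal_loglik_theta(counts, theta, "L", nodes = 128)
    expect_lt(abs(v64 - v128), 1e-8 * max(1, abs(v64)))
    expect_equal(marginal_loglik_theta(counts, theta, "L"),
                 marginal_loglik_theta(counts, theta, "R"),
                 tolerance = 1e-12)
  }
})

test_that("the marginal likelihood has an interior optimum for typical data", {
  set.seed(53)
  tt <- simulate_fig2_times(0.1, 1e-5, 200, reps = 1)
  counts <- simulate_pattern_counts(tt, 100, 100)$combined
  lg <- seq(log(1e-3), log(10), length.out = 40)
  v <- marginal_loglik_theta(counts, exp(lg), "L")
  i <- which.max(v)
  expect_gt(i, 1)
  expect_lt(i, 40)
})

test_that("mle_theta agrees with the dense grid-search oracle", {
  set.seed(59)
  for (i in 1:3) {
    tt <- simulate_fig2_times(0.1, 1e-5, 200, reps = 1)
    counts <- simulate_pattern_counts(tt, 100, 100)$combined
    fit <- mle_theta(counts, "L")
    ref <- oracle_mle_theta(counts, "L")
    expect_lt(abs(fit$theta_hat - ref), 1e-3)
    expect_false(fit$boundary)
    ## doubling the counts keeps the estimate finite and positive
    fit2 <- mle_theta(as_pattern_counts(unclass(counts) * 2L), "L")
    expect_true(is.finite(fit2$theta_hat) && fit2$theta_hat > 0)
  }
})

test_that("mle_times recovers generating parameters from expected counts", {
  n <- 1e6
  for (t2 in c(0.05, 0.12, 0.3)) for (ratio in c(0.2, 0.5, 0.9)) {
    t3 <- ratio * t2
    for (top in c("L", "R")) {
      counts <- as_pattern_counts(round(pattern_prob_row(top, t2, t3) * n))
      fit <- mle_times(counts, top)
      expect_lt(abs(fit$t2_hat - t2), 1e-4)
      expect_lt(abs(fit$t3_hat - t3), 1e-4)
      expect_true(fit$converged)
    }
  }
})

test_that("mle_times matches a coarse grid oracle on noisy counts", {
  set.seed(61)
  tt <- simulate_fig2_times(0.1, 1e-5, 200, reps = 1)
  counts <- simulate_pattern_counts(tt, 400, 400)$combined
  fit <- mle_times(counts, "L")
  ref <- oracle_mle_times(counts, "L")
  ## the optimizer must be at least as good as the dense grid
  expect_gte(fit$loglik_at_max, ref$loglik - 1e-6)
  expect_lt(abs(fit$t2_hat - ref$t2), 0.01)
})

test_that("boundary cases are diagnosed, not hidden", {
  fit0 <- mle_times(pattern_counts(nxxx = 25), "L")
  expect_identical(c(fit0$t2_hat, fit0$t3_hat), c(0, 0))
  expect_true(fit0$boundary)
  ## pure-noise data push t3 toward t2 (or times to the box edge):
  ## flagged rather than raised
  fitz <- mle_times(pattern_counts(nxyz = 30), "L")
  expect_true(fitz$boundary)
  expect_error(mle_times(pattern_counts(), "L"), "at least one")
  expect_error(mle_theta(pattern_counts(), "L"), "at least one")
})

test_that("theta label symmetry holds for single-tree data", {
  set.seed(67)
  thetas <- matrix(NA_real_, 20, 2)
  for (i in 1:20) {
    t3 <- rexp(1, 6 / 0.1); t2 <- t3 + rexp(1, 2 / 0.1)
    cL <- as_pattern_counts(drop(rmultinom(1, 200, pattern_prob_row("L", t2, t3))))
    swapped <- unclass(cL)[c("xxx", "xyz", "yxx", "xxy", "xyx")]
    names(swapped) <- pattern_levels()
    cR <- as_pattern_counts(swapped)
    thetas[i, 1] <- mle_theta(cL, "L")$theta_hat
    thetas[i, 2] <- mle_theta(cR, "R")$theta_hat
  }
  ## identical data up to the label swap must give identical estimates
  expect_equal(thetas[, 1], thetas[, 2], tolerance = 1e-6)
})
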