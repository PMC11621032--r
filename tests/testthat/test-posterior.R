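# Posterior utilities: scaled speeds, periods, delays, the SVD point
# estimator, and interval-based comparisons.

fake_samples <- function(omega_draws, log_gamma = 0, ng = 5,
                         n = length(omega_draws)) {
  list(log_beta = matrix(0.7, n, ng),
       log_gamma = matrix(log_gamma, n, ng),
       nu_omega = array(omega_draws, c(n, 1, 1)),
       alpha_u = matrix(0.5, n, ng), n_draws = n)
}

test_that("scaled speed converts with the mean half-life and is linear", {
  # gamma = ln 2 gives unit physical half-life
  sm <- fake_samples(rep(0.4, 10), log_gamma = log(log(2)))
  expect_equal(scaled_speed(sm), rep(0.4, 10))
  # doubling gamma halves half-lives, halving the scaled speed
  sm2 <- fake_samples(rep(0.4, 10), log_gamma = log(2 * log(2)))
  expect_equal(scaled_speed(sm2), rep(0.2, 10))
  # lifetime convention: 1/gamma
  sm3 <- fake_samples(rep(0.4, 10), log_gamma = 0)
  expect_equal(scaled_speed(sm3, half_life = "lifetime"), rep(0.4, 10))
})

test_that("period is exact for constant speed and matches high-resolution
           quadrature for periodic speed", {
  sm <- fake_samples(rep(0.4, 50), log_gamma = log(log(2)))
  per <- cell_cycle_period(sm)
  expect_equal(per$mean, 2 * pi / 0.4, tolerance = 1e-12)
  expect_true(per$ci_lo <= per$mean && per$mean <= per$ci_hi)
  # assumed half-life scales linearly
  per2 <- cell_cycle_period(sm, mean_half_life_hours = 2)
  expect_equal(per2$mean, 2 * per$mean, tolerance = 1e-12)
  # one-harmonic speed: compare the 20-point trapezoid to 10000-point
  n <- 20
  w <- array(0, c(n, 1, 3))
  w[, 1, 1] <- 0.4; w[, 1, 2] <- 0.1
  smp <- list(log_beta = matrix(0.7, n, 4),
              log_gamma = matrix(log(log(2)), n, 4),
              nu_omega = w, alpha_u = matrix(0.5, n, 4), n_draws = n)
  per3 <- cell_cycle_period(smp, n_grid = 20)
  grid <- seq(0, 2 * pi, length.out = 10000)
  exact <- pracma::trapz(grid, 1 / (0.4 + 0.1 * cos(grid)))
  # 20-point trapezoid truncation error only
  expect_equal(per3$mean, exact, tolerance = 1e-3)
  # draws with non-positive speed on the grid are excluded with a warning
  w2 <- w; w2[1, 1, 1] <- -0.1
  smp2 <- smp; smp2$nu_omega <- w2
  expect_warning(per4 <- cell_cycle_period(smp2), "excluded")
  expect_equal(per4$n_excluded, 1)
})

test_that("delays wrap correctly and are antisymmetric", {
  mk <- function(peaks, amp = 1) {
    ng <- length(peaks)
    structure(list(nu_loc = cbind(1, amp * cos(peaks), amp * sin(peaks)),
                   k = 1, gene_ids = sprintf("g%d", seq_len(ng))),
              class = "cv_manifold_fit")
  }
  fs <- mk(c(1.3, 0.1)); fu <- mk(c(1.0, 6.2))
  dl <- us_delays(fs, fu)
  expect_equal(dl$delay[1], 0.3, tolerance = 1e-9)
  expect_equal(dl$delay[2], 0.1 - 6.2 + 2 * pi, tolerance = 1e-9)  # +0.183
  # antisymmetry
  dl_rev <- us_delays(fu, fs)
  expect_equal(dl_rev$delay, -dl$delay, tolerance = 1e-9)
  # near-zero amplitude flagged
  f0 <- mk(c(1.0, 2.0), amp = 1e-4)
  dl0 <- us_delays(fs, f0)
  expect_true(all(!dl0$defined))
  expect_true(all(is.na(dl0$delay)))
})

test_that("tan(delay) tracks omega/gamma on simulated single-harmonic fits", {
  truth <- sample_truth(2000, 1, seed = 307)
  truth$nu <- matrix(c(2.5, 0.08, 0), 1)
  gam <- 1.1; omega <- 0.35
  truth$kin <- kinetic_params(0.7, log(gam))
  # analytic peaks of the expectation curves via dense grids
  grid <- seq(0, 2 * pi, length.out = 20001)[-20001]
  u <- expected_unspliced(grid, truth$nu, truth$kin, omega)[, 1]
  s <- expected_spliced(grid, truth$nu)[, 1]
  lag <- (grid[which.max(s)] - grid[which.max(u)] + pi) %% (2 * pi) - pi
  expect_equal(tan(lag), omega / gam, tolerance = 0.03)
})

test_that("SVD point estimator recovers exact and noisy rank-1 structure and
           is permutation/duplication invariant", {
  delta <- outer(c(0.5, 1.0), rep(1, 10))
  pe <- point_estimate_period(delta)
  expect_equal(pe$omega_star, c(0.5, 1.0), tolerance = 1e-12)
  expect_equal(pe$period, c(4 * pi, 2 * pi), tolerance = 1e-12)
  expect_gt(mean(pe$v), 0)
  # small noise
  set.seed(14)
  tau <- runif(40, 0.5, 1.5)
  d2 <- outer(c(0.3, 0.6, 0.9), tau) + matrix(rnorm(120, sd = 0.02), 3)
  pe2 <- point_estimate_period(d2)
  # against the noiseless value (least-squares rank-1 of the clean matrix)
  clean <- point_estimate_period(outer(c(0.3, 0.6, 0.9), tau))
  expect_lt(max(abs(pe2$omega_star / clean$omega_star - 1)), 0.05)
  # permutation and duplication of gene columns
  perm <- sample(40)
  expect_equal(point_estimate_period(d2[, perm])$omega_star, pe2$omega_star,
               tolerance = 1e-9)
  dup <- point_estimate_period(cbind(d2, d2))
  expect_equal(dup$omega_star / dup$omega_star[1],
               pe2$omega_star / pe2$omega_star[1], tolerance = 1e-9)
  expect_error(point_estimate_period(matrix(0, 2, 5)), "rank-1")
  expect_error(point_estimate_period(matrix(1, 2, 1)), "at least 2")
})

test_that("rank-1 delay structure holds across an omega sweep of the
           structured simulator", {
  omegas <- c(0.2, 0.4, 0.8)
  truth0 <- sample_truth(10, 30, seed = 311)
  gam <- exp(truth0$kin$log_gamma)
  delta <- t(sapply(omegas, function(w) tan(atan2(w, gam))))
  pe <- point_estimate_period(delta)
  expect_gt(cor(pe$omega_star, omegas), 0.95)
})

test_that("nonzero test uses strict interval exclusion", {
  sm <- fake_samples(seq(0, 1, length.out = 101), log_gamma = log(log(2)))
  # 5th percentile is exactly 0.05 > 0 -> significant
  expect_true(test_nonzero(sm_fit <- structure(
    list(samples = sm, nt = 1, cond_levels = "all"),
    class = "cv_velocity_fit"))$significant)
  # interval touching zero exactly -> not significant
  sm0 <- fake_samples(c(rep(0, 6), seq(0.1, 1, length.out = 95)),
                      log_gamma = log(log(2)))
  fit0 <- structure(list(samples = sm0, nt = 1, cond_levels = "all"),
                    class = "cv_velocity_fit")
  expect_false(test_nonzero(fit0)$significant)
})

test_that("2D KDE KL divergence is near zero for matched samples and grows
           with separation", {
  skip_if_not_installed("MASS")
  set.seed(17)
  a <- cbind(rnorm(2000), rnorm(2000))
  b <- cbind(rnorm(2000), rnorm(2000))
  c2 <- cbind(rnorm(2000, 3), rnorm(2000))
  kl_ab <- kl_divergence_2d(a, b)
  kl_ac <- kl_divergence_2d(a, c2)
  expect_lt(kl_ab, 0.2)
  expect_gt(kl_ac, kl_ab + 0.5)
})
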