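# Manifold learning: empirical-Bayes priors, SVI gradient consistency,
# conditioning, alignment, and phase recovery on a moderate simulation.

test_that("empirical-Bayes priors follow the stated moment formulas", {
  sim <- small_sim()
  pr <- init_priors(sim$data)
  expect_equal(unname(pr$mu_nu[, 1]),
               unname(log(pmax(colMeans(sim$data$S), 1e-4))))
  expect_true(all(pr$mu_nu[, 2:3] == 0))
  sdS <- unname(apply(sim$data$S, 2, sd))
  expect_equal(unname(pr$sd_nu[, 1]), pmax(sdS / 2, 0.01))
  expect_equal(unname(pr$sd_nu[, 2]), pmax(sdS / 4, 0.01))
  # every phase-prior location has norm epsilon = 5
  expect_equal(unname(sqrt(rowSums(pr$prior_xy^2))), rep(5, nrow(sim$data$S)))
  # zero-variance gene gets the floored sd
  d2 <- sim$data
  d2$S[, 1] <- 3L
  pr2 <- init_priors(count_dataset(d2$S, d2$U))
  expect_equal(unname(pr2$sd_nu[1, ]), rep(0.01, 3))
})

test_that("prior rotation maximizes phase/depth correlation over the grid", {
  sim <- small_sim(300, 25, seed = 103)
  pr <- init_priors(sim$data)
  depth <- rowSums(sim$data$S)
  r_chosen <- cor(pr$Phi, depth)
  # exhaustive oracle over the same grid
  Phi0 <- wrap_phase(pr$orientation * (pr$Phi - pr$rotation))
  shifts <- seq(0, 2 * pi, length.out = 361)[-361]
  best <- max(sapply(c(1, -1), function(o)
    sapply(shifts, function(s) cor(wrap_phase(o * Phi0 + s), depth))))
  expect_equal(r_chosen, best, tolerance = 1e-10)
})

test_that("manifold ELBO gradients agree with finite differences", {
  sim <- small_sim(8, 4, seed = 107)
  S <- sim$data$S
  ng <- 4; nc <- 8; F <- 3
  set.seed(5)
  pm <- matrix(rnorm(ng * F), ng, F)
  psd <- matrix(runif(ng * F, 0.3, 1), ng, F)
  pxy <- 5 * cbind(cos(runif(nc)), sin(runif(nc)))
  l <- pxy + rnorm(nc * 2, sd = 0.3)
  m_nu <- pm + rnorm(ng * F, sd = 0.2)
  ls_nu <- matrix(log(0.2), ng, F)
  la <- rnorm(ng, 0, 0.3)
  eps_xy <- matrix(rnorm(nc * 2), nc)
  eps_nu <- matrix(rnorm(ng * F), ng, F)
  f <- function(l., m., ls., la.) {
    circvelo:::manifold_elbo_cpp(S, rep(0L, nc), 1L, 1L, pm, psd, pxy,
      l., m., ls., la., matrix(0, 1, ng), TRUE, TRUE, numeric(nc),
      matrix(0, ng, F), FALSE, matrix(0, 0, 0), matrix(0, 0, 0),
      eps_xy, eps_nu)
  }
  base <- f(l, m_nu, ls_nu, la)
  expect_grad_matches(base$g_l, function(x) f(matrix(x, nc), m_nu, ls_nu, la)$elbo,
                      as.vector(l))
  expect_grad_matches(base$g_m_nu, function(x) f(l, matrix(x, ng), ls_nu, la)$elbo,
                      as.vector(m_nu))
  expect_grad_matches(base$g_ls_nu, function(x) f(l, m_nu, matrix(x, ng), la)$elbo,
                      as.vector(ls_nu))
  expect_grad_matches(base$g_la, function(x) f(l, m_nu, ls_nu, x)$elbo, la)
})

test_that("alignment resolves rotation and reflection with closed form", {
  sim <- small_sim(150, 10, seed = 109)
  fit <- fit_manifold(sim$data, n_steps = 300, seed = 1)
  # identity
  al0 <- align_to_truth(fit, fit$phi_mean)
  expect_equal(al0$phi_mean, fit$phi_mean, tolerance = 1e-8)
  expect_equal(attr(al0, "rotation"), 0, tolerance = 1e-8)
  # pure rotation
  ref <- wrap_phase(fit$phi_mean + 1.0)
  al1 <- align_to_truth(fit, ref)
  expect_equal(circular_corrcoef(al1$phi_mean, ref), 1.0, tolerance = 1e-8)
  expect_false(attr(al1, "reflected"))
  # reflection
  ref2 <- wrap_phase(-fit$phi_mean + 0.4)
  al2 <- align_to_truth(fit, ref2)
  expect_true(attr(al2, "reflected"))
  expect_equal(circular_corrcoef(al2$phi_mean, ref2), 1.0, tolerance = 1e-8)
  # harmonics transform consistently: the expectation surface at aligned
  # phases matches the original surface at original phases
  s_old <- expected_spliced(fit$phi_mean, fit$nu_loc)
  s_new <- expected_spliced(al2$phi_mean, al2$nu_loc)
  expect_equal(s_new, s_old, tolerance = 1e-6)
})

test_that("conditioning on phases or harmonics fixes them exactly", {
  sim <- small_sim(120, 12, seed = 113)
  phi0 <- sim$truth$phi
  fit <- fit_manifold(sim$data, n_steps = 200, seed = 2,
                      condition_on = list(phi = phi0))
  expect_equal(fit$phi_mean, wrap_phase(phi0))
  fit2 <- fit_manifold(sim$data, n_steps = 200, seed = 2,
                       condition_on = list(nu = sim$truth$nu))
  expect_equal(fit2$nu_loc, sim$truth$nu, ignore_attr = TRUE)
})

test_that("phase coverage behaves at the degenerate extremes", {
  sim <- small_sim(80, 8, seed = 127)
  fit <- fit_manifold(sim$data, n_steps = 200, seed = 3)
  # effectively point-mass posterior located at the truth covers everything
  fit_pm <- fit
  fit_pm$phi_mean <- sim$truth$phi
  fit_pm$phi_xy_loc <- 1e5 * cbind(cos(sim$truth$phi), sin(sim$truth$phi))
  expect_equal(posterior_phase_coverage(fit_pm, sim$truth$phi,
                                        n_samples = 200), 1.0)
  # very wide posterior (tiny location norm) covers nearly everything
  fit_w <- fit
  fit_w$phi_xy_loc <- fit$phi_xy_loc * 1e-4
  expect_gt(posterior_phase_coverage(fit_w, sim$truth$phi, n_samples = 200),
            0.85)
})

test_that("moderate simulation recovers phases, harmonics, batch offsets and
           supports transfer learning", {
  truth <- sample_truth(600, 60, omega_gt = 0.4, seed = 131)
  data <- sample_counts(truth)
  fit <- fit_manifold(data, n_steps = 2500, seed = 4)
  al <- align_to_truth(fit, truth$phi)
  expect_gt(circular_corrcoef(al$phi_mean, truth$phi), 0.9)
  expect_gt(cor(al$nu_loc[, 1], truth$nu[, 1]), 0.9)
  # a second seed gives the same geometry up to rotation/reflection
  fit_b <- fit_manifold(data, n_steps = 2500, seed = 44)
  al_b <- align_to_truth(fit_b, truth$phi)
  expect_gt(circular_corrcoef(al_b$phi_mean, al$phi_mean), 0.95)
  # loss decreases and stays finite
  expect_true(all(is.finite(fit$elbo_trace)))
  expect_lt(tail(fit$elbo_trace, 1), fit$elbo_trace[1])
  # transfer learning: fix harmonics from this fit, refit phases on a second
  # replicate drawn from the same truth
  data2 <- sample_counts(truth, seed = 999)
  fit2 <- fit_manifold(data2, n_steps = 3000, seed = 5,
                       condition_on = list(nu = al$nu_loc))
  al2 <- align_to_truth(fit2, truth$phi)
  expect_gt(circular_corrcoef(al2$phi_mean, truth$phi), 0.9)
  # batch offsets: shift one batch's expression and recover the offset sign
  off <- 0.5
  half <- seq_len(300)
  truth_b <- truth
  truth_b$nu <- truth$nu
  db <- data
  db$S[half, ] <- sample_counts(truth, seed = 77)$S[half, ] +
    matrix(rpois(300 * 60, exp(log(0.6) + truth$nu[, 1])), 300, byrow = TRUE)
  datb <- count_dataset(db$S, db$U,
                        batch = rep(c("b", "a"), c(300, 300)))
  fitb <- fit_manifold(datb, n_steps = 1500, seed = 6)
  expect_equal(nrow(fitb$delta_nu), 2)
  expect_true(all(fitb$delta_nu[1, ] == 0))
  expect_gt(mean(fitb$delta_nu[2, ]), 0)   # batch "b" has inflated counts
})
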