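# Velocity learning: ELBO gradient consistency for both guides, recovery on
# simulations, null behaviour, guide comparison, and the HMC backend
# cross-checked against a brute-force grid posterior.

make_vel_fixture <- function(nc = 8, ng = 4, seed = 211) {
  sim <- small_sim(nc, ng, seed = seed)
  list(sim = sim,
       log_sbar = log(expected_spliced(sim$truth$phi, sim$truth$nu)),
       W = fourier_basis_derivative(sim$truth$phi, 1) %*% t(sim$truth$nu))
}

test_that("mean-field velocity ELBO gradients agree with finite differences", {
  fx <- make_vel_fixture()
  nc <- 8; ng <- 4
  set.seed(6)
  Zw <- matrix(1, nc, 1); cond <- rep(0L, nc)
  m_lb <- rnorm(ng, 2, 0.2); ls_lb <- rep(log(0.2), ng)
  m_lg <- rnorm(ng, 0, 0.2); ls_lg <- rep(log(0.15), ng)
  m_w <- matrix(0.3, 1, 1); ls_w <- matrix(log(0.1), 1, 1)
  la <- rnorm(ng, 0, 0.2)
  eb <- rnorm(ng); eg <- rnorm(ng); ew <- matrix(rnorm(1), 1, 1)
  f <- function(m_lb., ls_lb., m_lg., ls_lg., m_w., ls_w., la.) {
    circvelo:::velocity_elbo_meanfield_cpp(fx$sim$data$U, fx$log_sbar, fx$W,
      Zw, cond, 1L, 1e-5, 2, 3, 0, 0.5, 0, 3,
      m_lb., ls_lb., m_lg., ls_lg., m_w., ls_w., la., eb, eg, ew)
  }
  b <- f(m_lb, ls_lb, m_lg, ls_lg, m_w, ls_w, la)
  expect_grad_matches(b$g_m_lb, function(x) f(x, ls_lb, m_lg, ls_lg, m_w, ls_w, la)$elbo, m_lb)
  expect_grad_matches(b$g_ls_lb, function(x) f(m_lb, x, m_lg, ls_lg, m_w, ls_w, la)$elbo, ls_lb)
  expect_grad_matches(b$g_m_lg, function(x) f(m_lb, ls_lb, x, ls_lg, m_w, ls_w, la)$elbo, m_lg)
  expect_grad_matches(b$g_ls_lg, function(x) f(m_lb, ls_lb, m_lg, x, m_w, ls_w, la)$elbo, ls_lg)
  expect_grad_matches(b$g_m_w, function(x) f(m_lb, ls_lb, m_lg, ls_lg, matrix(x, 1), ls_w, la)$elbo,
                      as.vector(m_w))
  expect_grad_matches(b$g_la, function(x) f(m_lb, ls_lb, m_lg, ls_lg, m_w, ls_w, x)$elbo, la)
})

test_that("LRMN velocity ELBO gradients agree with finite differences", {
  fx <- make_vel_fixture(seed = 223)
  nc <- 8; ng <- 4; n <- ng + 1; rank <- 3
  set.seed(7)
  Zw <- matrix(1, nc, 1); cond <- rep(0L, nc)
  m0 <- rnorm(n, 0, 0.2)
  Fm <- matrix(rnorm(n * rank, sd = 0.1), n, rank)
  ld <- rnorm(n, log(0.05), 0.2)
  mu_b <- rnorm(ng, 2, 0.2); lsb <- rep(log(0.2), ng)
  qr <- rnorm(ng, 0, 0.5); la <- rnorm(ng, 0, 0.2)
  e1 <- rnorm(rank); e2 <- rnorm(n); e3 <- rnorm(ng)
  f <- function(m., Fm., ld., mu_b., lsb., qr., la.) {
    circvelo:::velocity_elbo_lrmn_cpp(fx$sim$data$U, fx$log_sbar, fx$W, Zw,
      cond, 1L, 1e-5, 2, 3, 0, 0.5, 0, 3,
      m., Fm., ld., mu_b., lsb., qr., la., e1, e2, e3)
  }
  b <- f(m0, Fm, ld, mu_b, lsb, qr, la)
  expect_grad_matches(b$g_m, function(x) f(x, Fm, ld, mu_b, lsb, qr, la)$elbo, m0)
  expect_grad_matches(b$g_Fm, function(x) f(m0, matrix(x, n), ld, mu_b, lsb, qr, la)$elbo,
                      as.vector(Fm))
  expect_grad_matches(b$g_ld, function(x) f(m0, Fm, x, mu_b, lsb, qr, la)$elbo, ld)
  expect_grad_matches(b$g_mu_b, function(x) f(m0, Fm, ld, x, lsb, qr, la)$elbo, mu_b)
  expect_grad_matches(b$g_lsb, function(x) f(m0, Fm, ld, mu_b, x, qr, la)$elbo, lsb)
  expect_grad_matches(b$g_qr, function(x) f(m0, Fm, ld, mu_b, lsb, x, la)$elbo, qr)
  expect_grad_matches(b$g_la, function(x) f(m0, Fm, ld, mu_b, lsb, qr, x)$elbo, la)
})

test_that("velocity learning recovers speed and kinetic ratios on a moderate
           simulation, and a null simulation yields no credible velocity", {
  truth <- sample_truth(800, 80, omega_gt = 0.4, seed = 227)
  data <- sample_counts(truth)
  fit <- fit_velocity(data, manifold_from_truth(truth), "constant",
                      "meanfield", n_steps = 4000, seed = 8)
  expect_lt(velocity_percent_error(fit$omega, 0.4), 30)
  rt <- exp(truth$kin$log_gamma - truth$kin$log_beta)
  expect_gt(cor(fit$gamma_beta_ratio, rt), 0.98)
  expect_true(test_nonzero(fit)$significant)
  # posterior predictive sanity: fitted unspliced means track observed U
  kin_hat <- kinetic_params(fit$log_beta, fit$log_gamma)
  u_hat <- expected_unspliced(truth$phi, truth$nu, kin_hat,
                              matrix(fit$omega, 1, 1))
  pred_cor <- vapply(seq_len(80), function(g)
    suppressWarnings(cor(u_hat[, g], data$U[, g])), numeric(1))
  expect_gt(median(pred_cor, na.rm = TRUE), 0.3)
  # correlation structure re-emerges without being imposed
  expect_gt(cor(fit$log_beta, colSums(data$S)), 0)

  # null velocity, fit with the uncertainty-preserving LRMN guide
  truth0 <- sample_truth(800, 80, omega_gt = 0, seed = 229)
  fit0 <- fit_velocity(sample_counts(truth0), manifold_from_truth(truth0),
                       "constant", "lrmn", n_steps = 4000, seed = 9)
  expect_lt(abs(fit0$omega), 0.1)
  ci <- quantile(fit0$samples$nu_omega[, 1, 1], c(0.05, 0.95))
  expect_true(ci[1] <= 0 && ci[2] >= 0)
  expect_false(test_nonzero(fit0)$significant)
})

test_that("LRMN intervals are at least as wide as mean-field and the guides
           agree on the posterior-mean speed", {
  truth <- sample_truth(500, 50, omega_gt = 0.4, seed = 233)
  data <- sample_counts(truth)
  cg <- compare_guides(data, manifold_from_truth(truth), n_steps = 4000,
                       seed = 10)
  expect_gte(cg$ci_width_lrmn, cg$ci_width_meanfield)
  # agreement within the union of intervals
  sp_mf <- scaled_speed(cg$fit_meanfield)
  sp_lr <- scaled_speed(cg$fit_lrmn)
  lohi <- range(quantile(sp_mf, c(0.05, 0.95)), quantile(sp_lr, c(0.05, 0.95)))
  expect_true(mean(sp_mf) >= lohi[1] && mean(sp_mf) <= lohi[2])
  expect_true(mean(sp_lr) >= lohi[1] && mean(sp_lr) <= lohi[2])
  # single-condition constant model: one speed column
  expect_equal(ncol(cg$gene_corr_table), 1)
  # LRMN couples log beta and log gamma strongly (positively) per gene
  cc <- vapply(seq_len(50), function(g)
    cor(cg$fit_lrmn$samples$log_beta[, g], cg$fit_lrmn$samples$log_gamma[, g]),
    numeric(1))
  expect_gt(mean(cc), 0.5)
})

test_that("HMC agrees with the SVI posterior and with a brute-force grid on
           a near-degenerate problem", {
  truth <- sample_truth(400, 25, omega_gt = 0.4, seed = 239)
  data <- sample_counts(truth)
  man <- manifold_from_truth(truth)
  sv <- fit_velocity(data, man, "constant", "meanfield", n_steps = 10000,
                     seed = 11)
  lr <- fit_velocity(data, man, "constant", "lrmn", n_steps = 10000, seed = 11)
  mc <- fit_velocity_mcmc(data, man, "constant", init = sv, warmup = 400,
                          samples = 300, seed = 11)
  ci_lr <- quantile(lr$samples$nu_omega[, 1, 1], c(0.05, 0.95))
  expect_true(mc$omega >= ci_lr[1] && mc$omega <= ci_lr[2])
  # joint draws preserve the beta-gamma coupling
  cc <- vapply(seq_len(25), function(g)
    cor(mc$samples$log_beta[, g], mc$samples$log_gamma[, g]), numeric(1))
  expect_gt(mean(cc), 0.5)

  # one informative gene, many cells: profile posterior over (log gamma,
  # omega) on a dense grid with the other parameters held at the MCMC means
  truth1 <- sample_truth(2000, 1, seed = 241)
  truth1$nu <- matrix(c(2.5, 1.0, 0.4), 1)
  truth1$kin <- kinetic_params(0.7, 0)
  truth1$alpha_s <- 0.1; truth1$alpha_u <- 0.1
  data1 <- sample_counts(truth1)
  man1 <- manifold_from_truth(truth1)
  sv1 <- fit_velocity(data1, man1, "constant", "meanfield", n_steps = 3000,
                      seed = 12)
  mc1 <- suppressWarnings(
    fit_velocity_mcmc(data1, man1, "constant", init = sv1, warmup = 400,
                      samples = 400, seed = 12))
  lb_hat <- mean(mc1$samples$log_beta[, 1])
  la_hat <- log(mean(mc1$samples$alpha_u[, 1]))
  lg_grid <- seq(-1, 1, length.out = 121)
  w_grid <- seq(0.05, 1.2, length.out = 121)
  s1 <- expected_spliced(truth1$phi, truth1$nu)
  W1 <- fourier_basis_derivative(truth1$phi, 1) %*% t(truth1$nu)
  logpost <- outer(lg_grid, w_grid, Vectorize(function(lg, w) {
    u <- s1 / exp(lb_hat) * pmax(w * W1 + exp(lg), 1e-5)
    sum(dnbinom(data1$U[, 1], size = exp(-la_hat), mu = u, log = TRUE)) +
      dnorm(lg, 0, 0.5, log = TRUE) + dnorm(w, 0, 3, log = TRUE) +
      dnorm(lb_hat, 2, 3, log = TRUE)
  }))
  idx <- which(logpost == max(logpost), arr.ind = TRUE)
  res_lg <- diff(lg_grid[1:2]); res_w <- diff(w_grid[1:2])
  expect_lt(abs(mean(mc1$samples$log_gamma[, 1]) - lg_grid[idx[1]]),
            10 * res_lg + 3 * sd(mc1$samples$log_gamma[, 1]))
  expect_lt(abs(mean(mc1$samples$nu_omega[, 1, 1]) - w_grid[idx[2]]),
            10 * res_w + 3 * sd(mc1$samples$nu_omega[, 1, 1]))
})

test_that("multi-condition fits share kinetics and separate speed blocks", {
  truth <- sample_truth(600, 40, omega_gt = 0.4, seed = 251)
  # second half of the cells evolve at a different speed but share the genes
  truth_b <- truth
  truth_b$nu_omega <- matrix(0.8, 1, 1)
  d_a <- sample_counts(truth, seed = 301)
  d_b <- sample_counts(truth_b, seed = 302)
  data <- count_dataset(rbind(d_a$S, d_b$S), rbind(d_a$U, d_b$U),
                        batch = rep(c("slow", "fast"), each = 600))
  truth2 <- truth
  truth2$phi <- c(truth$phi, truth$phi)
  man <- manifold_from_truth(truth2)
  fit <- fit_velocity(data, man, "constant", "meanfield", n_steps = 4000,
                      seed = 13)
  expect_equal(fit$nt, 2)
  expect_equal(sort(fit$cond_levels), c("fast", "slow"))
  i_f <- which(fit$cond_levels == "fast"); i_s <- which(fit$cond_levels == "slow")
  expect_gt(fit$omega[i_f], fit$omega[i_s])
  cmp <- compare_conditions(fit, "fast", "slow")
  expect_true(cmp$significant)
  same <- compare_conditions(fit, "fast", "fast")
  expect_equal(same$overlap_fraction, 1.0)
  expect_true(same$ci_difference[1] <= 0 && same$ci_difference[2] >= 0)
})

test_that("the periodic speed model recovers the phase-average speed and a
           shrunken first harmonic of the right sign", {
  truth <- sample_truth(1200, 120, omega_gt = c(0.4, 0.12, 0), seed = 263)
  data <- sample_counts(truth)
  fit <- fit_velocity(data, manifold_from_truth(truth), model = "periodic",
                      guide = "meanfield", n_steps = 6000, seed = 18)
  w <- colMeans(fit$samples$nu_omega[, 1, ])
  expect_equal(length(w), 3)
  expect_lt(velocity_percent_error(w[1], 0.4), 25)
  # the N(0, 0.05^2) prior shrinks the harmonic; sign should survive
  expect_gt(w[2], 0)
  expect_lt(abs(w[3]), 0.1)
})
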