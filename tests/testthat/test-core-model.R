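# Deterministic core: Fourier basis, expected counts, angular speed.

test_that("fourier basis reproduces trigonometric values and column order", {
  expect_equal(as.vector(fourier_basis(0, 1)), c(1, 1, 0))
  expect_equal(as.vector(fourier_basis(pi / 2, 1)), c(1, 0, 1))
  # k = 2 at pi/3: [1, cos, sin, cos 2phi, sin 2phi]
  expect_equal(as.vector(fourier_basis(pi / 3, 2)),
               c(1, 0.5, sqrt(3) / 2, -0.5, sqrt(3) / 2))
  expect_true(all(fourier_basis(runif(10, 0, 2 * pi), 3)[, 1] == 1))
  expect_error(fourier_basis(0, -1), "non-negative")
})

test_that("basis derivative matches finite differences and is zero in the
           constant column", {
  expect_equal(as.vector(fourier_basis_derivative(0, 1)), c(0, 0, 1))
  expect_equal(as.vector(fourier_basis_derivative(pi / 2, 1)), c(0, -1, 0))
  set.seed(1)
  phi <- runif(100, 0, 2 * pi)
  h <- 1e-6
  for (k in c(1, 3)) {
    num <- (fourier_basis(phi + h, k) - fourier_basis(phi - h, k)) / (2 * h)
    expect_lt(max(abs(num - fourier_basis_derivative(phi, k))), 1e-6)
  }
})

test_that("expected spliced counts follow the log-linear harmonic model", {
  # constant gene
  expect_equal(as.vector(expected_spliced(c(0, 1, 4), c(log(5), 0, 0))),
               rep(5, 3))
  expect_equal(as.vector(expected_spliced(0, c(0, 1, 0))), exp(1))
  # direct evaluation
  expect_equal(as.vector(expected_spliced(pi / 4, c(0.5, 0.3, -0.2))),
               exp(0.5 + 0.3 * cos(pi / 4) - 0.2 * sin(pi / 4)))
  expect_error(expected_spliced(0, c(NA, 0, 0)), "finite")
})

test_that("angular speed is the linear harmonic expansion", {
  expect_equal(angular_speed(c(0, 1, 2), 0.4), rep(0.4, 3))
  expect_equal(angular_speed(0, c(0.4, 0.1, 0)), 0.5)
  expect_equal(angular_speed(pi / 2, c(0.4, 0.1, -0.05)), 0.35)
})

test_that("zero velocity reduces the unspliced mean to the steady state", {
  set.seed(2)
  nu <- cbind(rnorm(5, 1), rnorm(5, 0, 0.5), rnorm(5, 0, 0.5))
  kin <- kinetic_params(rnorm(5, 0.7, 0.3), rnorm(5, 0, 0.3))
  phi <- runif(20, 0, 2 * pi)
  u <- expected_unspliced(phi, nu, kin, matrix(0, 1, 1))
  s <- expected_spliced(phi, nu)
  ratio <- exp(kin$log_gamma - kin$log_beta)
  expect_equal(u, sweep(s, 2, ratio, "*"), tolerance = 1e-12)
  # constant gene: derivative term vanishes for any omega
  nu_c <- matrix(c(1.2, 0, 0), 1)
  kin_c <- kinetic_params(0.5, -0.1)
  u_c <- expected_unspliced(phi, nu_c, kin_c, c(0.7, 0.1, -0.2))
  expect_equal(as.vector(u_c),
               rep(exp(1.2) * exp(-0.1) / exp(0.5), 20))
})

test_that("expectations are strictly positive and 2*pi-periodic", {
  set.seed(3)
  nu <- cbind(rnorm(4), rnorm(4), rnorm(4))
  kin <- kinetic_params(rnorm(4), rnorm(4))
  phi <- runif(15, 0, 2 * pi)
  w <- c(0.4, 0.2, -0.1)
  u1 <- expected_unspliced(phi, nu, kin, w)
  expect_true(all(u1 > 0))
  expect_true(all(expected_spliced(phi, nu) > 0))
  expect_equal(u1, expected_unspliced(phi + 2 * pi, nu, kin, w),
               tolerance = 1e-12)
  expect_equal(expected_spliced(phi, nu),
               expected_spliced(phi + 2 * pi, nu), tolerance = 1e-12)
})

test_that("unspliced/spliced peak lag follows tan(lag) = omega/gamma for a
           weak single harmonic", {
  # small amplitude so the log-harmonic is approximately sinusoidal
  nu <- matrix(c(2, 0.05, 0), 1)
  gam <- 1
  omega <- 0.3
  kin <- kinetic_params(log(2), log(gam))
  grid <- seq(0, 2 * pi, length.out = 20001)[-20001]
  s <- expected_spliced(grid, nu)[, 1]
  u <- expected_unspliced(grid, nu, kin, omega)[, 1]
  lag <- (grid[which.max(s)] - grid[which.max(u)] + pi) %% (2 * pi) - pi
  expect_equal(tan(lag), omega / gam, tolerance = 0.02)
})
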