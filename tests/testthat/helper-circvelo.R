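# Shared fixtures: small simulated datasets built in code, and a central
# finite-difference harness used by the gradient-consistency tests.

small_sim <- function(n_cells = 200, n_genes = 20, omega = 0.4, seed = 101) {
  truth <- sample_truth(n_cells, n_genes, omega_gt = omega, seed = seed)
  list(truth = truth, data = sample_counts(truth))
}

# central finite differences of f (scalar-valued) at x
fd_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

expect_grad_matches <- function(analytic, f, x, tol = 1e-5) {
  expect_lt(max(abs(fd_grad(f, x) - as.vector(analytic))), tol)
}
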