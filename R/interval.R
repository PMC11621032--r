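# Proof-of-principle 1D nonperiodic extension: cubic B-spline geometry over a
# fixed, externally supplied pseudotime coordinate with a constant scalar
# velocity. The pseudotime itself is never computed here.

#' Clamped B-spline knot vector
#'
#' Clamped (repeated-end) uniform knots over `range` for `n_basis` basis
#' functions of the given degree; length `n_basis + degree + 1`.
#'
#' @param n_basis basis dimension (default 5).
#' @param degree spline degree (default 3, cubic).
#' @param range interval endpoints.
#' @return the knot vector.
#' @export
bspline_knots <- function(n_basis = 5, degree = 3, range = c(0, 10)) {
  stopifnot(n_basis > degree)
  interior <- n_basis - degree - 1
  c(rep(range[1], degree + 1),
    if (interior > 0)
      seq(range[1], range[2], length.out = interior + 2)[-c(1, interior + 2)],
    rep(range[2], degree + 1))
}

# Cox-de Boor recursion with the 0/0 := 0 convention; the last interval is
# closed so the basis spans the full closed range.
cox_de_boor <- function(t, knots, degree) {
  n_basis <- length(knots) - degree - 1
  hi <- max(knots)
  B <- matrix(0, length(t), length(knots) - 1)
  for (i in seq_len(length(knots) - 1)) {
    B[, i] <- as.numeric(t >= knots[i] & t < knots[i + 1])
    if (knots[i] < hi && knots[i + 1] == hi)
      B[t == hi, i] <- 1       # close the right end
  }
  if (degree == 0) return(B[, seq_len(n_basis), drop = FALSE])
  for (p in seq_len(degree)) {
    Bp <- matrix(0, length(t), length(knots) - p - 1)
    for (i in seq_len(length(knots) - p - 1)) {
      d1 <- knots[i + p] - knots[i]
      d2 <- knots[i + p + 1] - knots[i + 1]
      if (d1 > 0) Bp[, i] <- Bp[, i] + (t - knots[i]) / d1 * B[, i]
      if (d2 > 0) Bp[, i] <- Bp[, i] + (knots[i + p + 1] - t) / d2 * B[, i + 1]
    }
    B <- Bp
  }
  B[, seq_len(n_basis), drop = FALSE]
}

#' B-spline basis over a pseudotime interval
#'
#' Evaluates the clamped B-spline basis by the Cox-de Boor recursion. On the
#' interior the basis functions form a partition of unity.
#'
#' @param t pseudotime vector, within the knot range.
#' @param n_basis basis dimension (default 5).
#' @param degree spline degree (default 3).
#' @param knots optional knot vector (default: clamped uniform over
#'   `range(t)` extended to `range` if supplied).
#' @param range interval for default knots (default `range(t)`).
#' @return matrix, `length(t)` x `n_basis`.
#' @export
bspline_basis <- function(t, n_basis = 5, degree = 3, knots = NULL,
                          range = NULL) {
  if (is.null(knots)) {
    if (is.null(range)) range <- base::range(t)
    knots <- bspline_knots(n_basis, degree, range)
  }
  if (any(t < min(knots)) || any(t > max(knots)))
    stop("pseudotime values outside the knot range", call. = FALSE)
  B <- cox_de_boor(t, knots, degree)
  attr(B, "knots") <- knots
  attr(B, "degree") <- degree
  B
}

#' Derivative of the B-spline basis
#'
#' Standard degree-reduction formula
#' `B'_{p,i} = p/(t_{i+p}-t_i) B_{p-1,i} - p/(t_{i+p+1}-t_{i+1}) B_{p-1,i+1}`.
#'
#' @inheritParams bspline_basis
#' @return matrix of the same shape as [bspline_basis()].
#' @export
bspline_basis_derivative <- function(t, n_basis = 5, degree = 3, knots = NULL,
                                     range = NULL) {
  if (is.null(knots)) {
    if (is.null(range)) range <- base::range(t)
    knots <- bspline_knots(n_basis, degree, range)
  }
  if (degree == 0) return(matrix(0, length(t), n_basis))
  Blow <- cox_de_boor(t, knots, degree - 1)  # n_basis + 1 columns available
  Bfull <- matrix(0, length(t), length(knots) - degree)
  Bfull[, seq_len(ncol(Blow))] <- Blow
  D <- matrix(0, length(t), n_basis)
  for (i in seq_len(n_basis)) {
    d1 <- knots[i + degree] - knots[i]
    d2 <- knots[i + degree + 1] - knots[i + 1]
    if (d1 > 0) D[, i] <- D[, i] + degree / d1 * Bfull[, i]
    if (d2 > 0) D[, i] <- D[, i] - degree / d2 * Bfull[, i + 1]
  }
  D
}

#' Simulate counts on a pseudotime interval
#'
#' Reuses the structured correlated-coefficient scheme of [sample_truth()]:
#' gene curves are half-cycle harmonics of the rescaled pseudotime (so each
#' gene rises and falls once over the interval), and unspliced expectations
#' follow the same first-order kinetics with a constant scalar velocity.
#'
#' @param n_cells,n_genes sizes.
#' @param omega_gt constant ground-truth velocity.
#' @param seed integer seed.
#' @param range pseudotime interval.
#' @return list: `data` (a [count_dataset()]), `truth` (with `pseudotime`,
#'   curves and kinetics).
#' @export
simulate_interval <- function(n_cells, n_genes, omega_gt = 0.4, seed = 0,
                              range = c(0, 10)) {
  truth <- sample_truth(n_cells, n_genes, omega_gt = omega_gt, seed = seed)
  pt <- sort(runif(n_cells, range[1], range[2]))
  span <- diff(range)
  # half-cycle angular coordinate and its pseudotime derivative
  theta <- pi * (pt - range[1]) / span
  dtheta <- pi / span
  Zi <- cbind(1, cos(theta), sin(theta))
  Zd <- cbind(0, -sin(theta), cos(theta)) * dtheta
  logs <- Zi %*% t(truth$nu)
  dlogs <- Zd %*% t(truth$nu)
  s <- exp(logs)
  gam <- exp(truth$kin$log_gamma)
  bet <- exp(truth$kin$log_beta)
  inner <- pmax(sweep(dlogs * omega_gt, 2, gam, "+"), 1e-5)
  u <- sweep(s * inner, 2, bet, "/")
  S <- rnb_matrix(s, truth$alpha_s)
  U <- rnb_matrix(u, truth$alpha_u)
  truth$pseudotime <- pt
  truth$logs <- logs
  truth$range <- range
  list(data = count_dataset(S, U), truth = truth)
}

#' Fit the interval (B-spline) model
#'
#' Two stages mirroring the periodic pipeline: (1) spline coefficients `w_gf`
#' of the log spliced expectation are learned conditioned on the supplied
#' pseudotime (NB likelihood, SVI); (2) kinetic parameters, unspliced
#' dispersion and a constant scalar velocity are learned from unspliced
#' counts with the geometry fixed. Priors and optimizer match the periodic
#' model except the spline coefficients get a broad `N(0, 3^2)` prior and the
#' scalar speed a single `N(0, 3^2)`.
#'
#' @param data a [count_dataset()].
#' @param pseudotime per-cell coordinate; values outside `[0, 10]` are
#'   linearly rescaled with a warning.
#' @param n_basis,degree spline dimension and degree (defaults 5, cubic).
#' @param n_steps_manifold,n_steps_velocity SVI iterations per stage.
#' @param lr,clip,seed,relu_floor,n_samples as in [fit_velocity()].
#' @return a `cv_interval_fit`: `w` (gene x basis coefficients), `omega`
#'   (posterior mean scalar velocity), `log_beta`, `log_gamma`, `samples`,
#'   `knots`, traces per stage.
#' @export
fit_interval <- function(data, pseudotime, n_basis = 5, degree = 3,
                         n_steps_manifold = 2000, n_steps_velocity = 6000,
                         lr = c(0.03, 0.005), clip = Inf, seed = 0,
                         relu_floor = 1e-5, n_samples = 500) {
  stopifnot(inherits(data, "cv_dataset"),
            length(pseudotime) == nrow(data$S))
  if (min(pseudotime) < 0 || max(pseudotime) > 10) {
    warning("pseudotime rescaled to [0, 10]")
    r <- range(pseudotime)
    pseudotime <- (pseudotime - r[1]) / diff(r) * 10
  }
  knots <- bspline_knots(n_basis, degree, c(0, 10))
  B <- bspline_basis(pseudotime, n_basis, degree, knots)
  Bd <- bspline_basis_derivative(pseudotime, n_basis, degree, knots)
  nc <- nrow(data$S); ng <- ncol(data$S)

  set.seed(seed)
  st1 <- manifold_svi_cpp(
    S = data$S, batch = rep(0L, nc), nb = 1L, k = 0L,
    prior_mu = matrix(0, ng, n_basis), prior_sd = matrix(3, ng, n_basis),
    prior_xy = matrix(0, nc, 2),
    l0 = matrix(0, nc, 2), m_nu0 = matrix(0, ng, n_basis),
    ls_nu0 = matrix(log(0.1), ng, n_basis), la0 = rep(log(0.5), ng),
    dnu0 = matrix(0, 1, ng),
    learn_phi = FALSE, learn_nu = TRUE,
    phi_fixed = numeric(nc), nu_fixed = matrix(0, ng, n_basis),
    fixed_basis = TRUE, Zfix = B, Zdfix = Bd,
    n_steps = n_steps_manifold, lr0 = lr[1], lr1 = lr[2], clip = clip,
    early_stop = FALSE)
  w <- st1$m_nu

  log_sbar <- B %*% t(w)
  W <- Bd %*% t(w)
  st2 <- velocity_svi_meanfield_cpp(
    U = data$U, log_sbar = log_sbar, W = W, Zw = matrix(1, nc, 1),
    cond = rep(0L, nc), nt = 1L, relu_floor = relu_floor,
    pm_lb = 2, ps_lb = 3, pm_lg = 0, ps_lg = 0.5,
    pm_w = 0, ps_w = 3,
    m_lb0 = rep(2, ng), ls_lb0 = rep(log(0.1), ng),
    m_lg0 = rep(0, ng), ls_lg0 = rep(log(0.1), ng),
    m_w0 = matrix(0, 1, 1), ls_w0 = matrix(log(0.1), 1, 1),
    la0 = rep(log(0.5), ng),
    n_steps = n_steps_velocity, lr0 = lr[1], lr1 = lr[2], clip = clip,
    early_stop = FALSE)

  fit <- structure(list(guide = "meanfield", model = "constant", params = st2,
                        ng = ng, nt = 1L, Fw = 1L, cond_levels = "all",
                        gene_ids = data$gene_ids, relu_floor = relu_floor,
                        elbo_trace = st2$trace, n_iter = st2$n_iter,
                        seed = seed),
                   class = "cv_velocity_fit")
  fit$samples <- sample_velocity_posterior(fit, n_samples, seed = seed + 1L)
  fit <- summarize_velocity_fit(fit)
  structure(list(w = w, w_scale = exp(st1$ls_nu), knots = knots,
                 degree = degree, pseudotime = pseudotime,
                 alpha_s = exp(st1$la),
                 omega = unname(fit$omega), log_beta = fit$log_beta,
                 log_gamma = fit$log_gamma,
                 gamma_beta_ratio = fit$gamma_beta_ratio,
                 alpha_u = fit$alpha_u, samples = fit$samples,
                 velocity_fit = fit,
                 trace_manifold = st1$trace, trace_velocity = st2$trace),
            class = "cv_interval_fit")
}

#' @export
print.cv_interval_fit <- function(x, ...) {
  cat(sprintf("cv_interval_fit: %d genes, %d spline basis functions, omega = %.3f\n",
              length(x$log_beta), ncol(x$w), x$omega))
  invisible(x)
}
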