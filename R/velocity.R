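# Velocity learning: kinetic parameters (beta_g, gamma_g), unspliced noise
# and angular-speed harmonics nu_omega from unspliced counts, conditioned on
# the posterior means of the manifold stage. Three posterior backends:
# mean-field SVI, SVI with a low-rank multivariate normal (LRMN) guide
# coupling log gamma and nu_omega (rank 5) with a conditional-normal
# log beta, and Hamiltonian Monte Carlo initialized from an SVI fit.

velocity_priors <- function(Fw) {
  list(pm_lb = 2, ps_lb = 3, pm_lg = 0, ps_lg = 0.5,
       pm_w = rep(0, Fw),
       ps_w = if (Fw == 1) 3 else c(3, rep(0.05, Fw - 1)))
}

# shared preparation of the fixed (manifold-derived) surfaces
velocity_inputs <- function(data, manifold, model) {
  if (!inherits(manifold, "cv_manifold_fit"))
    stop("'manifold' must be a cv_manifold_fit (or manifold_from_truth())",
         call. = FALSE)
  if (length(manifold$phi_mean) != nrow(data$U) ||
      nrow(manifold$nu_loc) != ncol(data$U))
    stop("manifold fit does not cover the cells/genes of the data",
         call. = FALSE)
  phi <- manifold$phi_mean
  log_sbar <- manifold_log_s(manifold)
  W <- fourier_basis_derivative(phi, manifold$k) %*% t(manifold$nu_loc)
  Zw <- if (model == "constant") matrix(1, length(phi), 1)
        else fourier_basis(phi, 1)
  cond <- if (is.null(data$batch)) rep(1L, length(phi))
          else as.integer(factor(data$batch))
  list(phi = phi, log_sbar = log_sbar, W = W, Zw = Zw,
       cond = cond, nt = max(cond),
       cond_levels = if (is.null(data$batch)) "all"
                     else levels(factor(data$batch)))
}

#' Fit velocity kinetics and angular speed by SVI
#'
#' Maximizes the ELBO of the unspliced NB model with the expected unspliced
#' surface `u = s/beta * relu(omega(phi) dlog s/dphi + gamma)`, holding `phi`
#' and the gene harmonics at their manifold posterior means. The constant
#' model learns one speed coefficient per condition; the periodic model
#' learns three harmonics per condition. Conditions (from `data$batch`)
#' share gene-level kinetics and dispersions and differ only in their speed
#' block.
#'
#' @param data a [count_dataset()].
#' @param manifold a `cv_manifold_fit` covering the same cells/genes (use
#'   [manifold_from_truth()] to condition on simulated ground truth).
#' @param model `"constant"` or `"periodic"` angular-speed parametrization.
#' @param guide `"meanfield"` or `"lrmn"` variational family.
#' @param n_steps SVI iterations (default 10000).
#' @param lr learning-rate endpoints (geometric decay).
#' @param clip optional L2 norm bound per gradient block (`Inf` disables).
#' @param seed RNG seed.
#' @param relu_floor floor of the relu argument in the unspliced mean.
#' @param rank rank of the LRMN factor (default 5).
#' @param n_samples posterior draws collected after training (default 500).
#' @param early_stop as in [fit_manifold()].
#' @return a `cv_velocity_fit` with posterior summaries (`log_beta`,
#'   `log_gamma`, `gamma_beta_ratio`, `omega`, `alpha_u`), the guide
#'   parameters, 500 joint posterior `samples`, the loss trace, and the
#'   condition labels.
#' @export
fit_velocity <- function(data, manifold, model = c("constant", "periodic"),
                         guide = c("meanfield", "lrmn"), n_steps = 10000,
                         lr = c(0.03, 0.005), clip = Inf, seed = 0,
                         relu_floor = 1e-5, rank = 5, n_samples = 500,
                         early_stop = FALSE) {
  stopifnot(inherits(data, "cv_dataset"))
  model <- match.arg(model)
  guide <- match.arg(guide)
  inp <- velocity_inputs(data, manifold, model)
  ng <- ncol(data$U)
  Fw <- ncol(inp$Zw)
  pr <- velocity_priors(Fw)
  set.seed(seed)
  if (guide == "meanfield") {
    res <- velocity_svi_meanfield_cpp(
      U = data$U, log_sbar = inp$log_sbar, W = inp$W, Zw = inp$Zw,
      cond = inp$cond - 1L, nt = inp$nt, relu_floor = relu_floor,
      pm_lb = pr$pm_lb, ps_lb = pr$ps_lb, pm_lg = pr$pm_lg, ps_lg = pr$ps_lg,
      pm_w = pr$pm_w, ps_w = pr$ps_w,
      m_lb0 = rep(2, ng), ls_lb0 = rep(log(0.1), ng),
      m_lg0 = rep(0, ng), ls_lg0 = rep(log(0.1), ng),
      m_w0 = matrix(0, inp$nt, Fw), ls_w0 = matrix(log(0.1), inp$nt, Fw),
      la0 = rep(log(0.5), ng),
      n_steps = n_steps, lr0 = lr[1], lr1 = lr[2], clip = clip,
      early_stop = early_stop)
  } else {
    n <- ng + inp$nt * Fw
    res <- velocity_svi_lrmn_cpp(
      U = data$U, log_sbar = inp$log_sbar, W = inp$W, Zw = inp$Zw,
      cond = inp$cond - 1L, nt = inp$nt, relu_floor = relu_floor,
      pm_lb = pr$pm_lb, ps_lb = pr$ps_lb, pm_lg = pr$pm_lg, ps_lg = pr$ps_lg,
      pm_w = pr$pm_w, ps_w = pr$ps_w,
      m0 = rep(0, n), Fm0 = matrix(rnorm(n * rank, sd = 0.01), n, rank),
      ld0 = rep(log(0.01), n), mu_b0 = rep(2, ng),
      lsb0 = rep(log(0.1), ng), qr0 = rep(0, ng), la0 = rep(log(0.5), ng),
      n_steps = n_steps, lr0 = lr[1], lr1 = lr[2], clip = clip,
      early_stop = early_stop)
  }
  fit <- structure(list(guide = guide, model = model, params = res,
                        ng = ng, nt = inp$nt, Fw = Fw,
                        cond_levels = inp$cond_levels,
                        gene_ids = data$gene_ids,
                        relu_floor = relu_floor,
                        elbo_trace = res$trace, n_iter = res$n_iter,
                        seed = seed),
                   class = "cv_velocity_fit")
  fit$samples <- sample_velocity_posterior(fit, n_samples, seed = seed + 1L)
  summarize_velocity_fit(fit)
}

# draw joint posterior samples from the fitted guide
sample_velocity_posterior <- function(fit, n_draws = 500, seed = 0) {
  set.seed(seed)
  p <- fit$params
  ng <- fit$ng; nt <- fit$nt; Fw <- fit$Fw
  if (fit$guide == "meanfield") {
    lb <- sweep(matrix(rnorm(n_draws * ng), n_draws), 2,
                exp(as.vector(p$ls_lb)), "*") +
      matrix(as.vector(p$m_lb), n_draws, ng, byrow = TRUE)
    lg <- sweep(matrix(rnorm(n_draws * ng), n_draws), 2,
                exp(as.vector(p$ls_lg)), "*") +
      matrix(as.vector(p$m_lg), n_draws, ng, byrow = TRUE)
    w <- array(0, c(n_draws, nt, Fw))
    for (t in seq_len(nt)) for (f in seq_len(Fw))
      w[, t, f] <- rnorm(n_draws, p$m_w[t, f], exp(p$ls_w[t, f]))
  } else if (fit$guide == "lrmn") {
    n <- ng + nt * Fw
    d <- exp(as.vector(p$ld))
    rank <- ncol(p$Fm)
    e1 <- matrix(rnorm(n_draws * rank), n_draws)
    e2 <- matrix(rnorm(n_draws * n), n_draws)
    x <- e1 %*% t(p$Fm) + sweep(e2, 2, sqrt(d), "*")
    x <- sweep(x, 2, as.vector(p$m), "+")
    lg <- x[, seq_len(ng), drop = FALSE]
    w <- array(0, c(n_draws, nt, Fw))
    for (t in seq_len(nt)) for (f in seq_len(Fw))
      w[, t, f] <- x[, ng + (t - 1) * Fw + f]
    varx <- rowSums(p$Fm^2) + d
    sgam <- sqrt(varx[seq_len(ng)])
    rho <- 1 / (1 + exp(-as.vector(p$qr)))
    sb <- exp(as.vector(p$lsb))
    dxg <- sweep(lg, 2, as.vector(p$m)[seq_len(ng)], "-")
    lb <- sweep(dxg, 2, rho * sb / sgam, "*") +
      sweep(matrix(rnorm(n_draws * ng), n_draws), 2, sb * sqrt(1 - rho^2), "*")
    lb <- sweep(lb, 2, as.vector(p$mu_b), "+")
  } else stop("unknown guide ", fit$guide)
  list(log_beta = lb, log_gamma = lg, nu_omega = w,
       alpha_u = matrix(exp(as.vector(p$la)), nrow(lb), ng, byrow = TRUE),
       n_draws = n_draws)
}

summarize_velocity_fit <- function(fit) {
  sm <- fit$samples
  fit$log_beta <- colMeans(sm$log_beta)
  fit$log_gamma <- colMeans(sm$log_gamma)
  fit$gamma_beta_ratio <- colMeans(exp(sm$log_gamma - sm$log_beta))
  fit$alpha_u <- sm$alpha_u[1, ]
  fit$omega <- apply(sm$nu_omega[, , 1, drop = FALSE], 2, mean)
  names(fit$omega) <- fit$cond_levels
  fit
}

#' @export
print.cv_velocity_fit <- function(x, ...) {
  cat(sprintf("cv_velocity_fit (%s, %s model): %d genes, %d condition(s)\n",
              x$guide, x$model, x$ng, x$nt))
  for (t in seq_len(x$nt))
    cat(sprintf("  omega[%s] posterior mean %.3f\n", x$cond_levels[t],
                x$omega[t]))
  invisible(x)
}

#' Posterior sampling of velocity parameters by Hamiltonian Monte Carlo
#'
#' Samples `(log beta, log gamma, nu_omega, alpha)` from the unspliced-model
#' posterior with a Hamiltonian kernel (leapfrog integration, dual-averaging
#' step-size adaptation, diagonal mass from the SVI posterior scales),
#' initialized at the mean posterior estimates of an SVI fit.
#'
#' @param data,manifold,model as in [fit_velocity()].
#' @param init an SVI `cv_velocity_fit` used for initialization and mass.
#' @param warmup,samples warmup and retained iterations (defaults 2000/500).
#' @param leapfrog base number of leapfrog steps (jittered upward).
#' @param target_accept dual-averaging target acceptance rate.
#' @param seed RNG seed.
#' @param max_divergence_frac warn when the fraction of divergent
#'   transitions exceeds this.
#' @return a `cv_velocity_fit` with `guide = "mcmc"` whose samples are the
#'   joint MCMC draws (cross-parameter correlations preserved).
#' @export
fit_velocity_mcmc <- function(data, manifold, model = c("constant", "periodic"),
                              init, warmup = 2000, samples = 500,
                              leapfrog = 12, target_accept = 0.8, seed = 0,
                              max_divergence_frac = 0.1) {
  stopifnot(inherits(data, "cv_dataset"), inherits(init, "cv_velocity_fit"))
  model <- match.arg(model)
  inp <- velocity_inputs(data, manifold, model)
  ng <- ncol(data$U); Fw <- ncol(inp$Zw)
  pr <- velocity_priors(Fw)
  sm <- init$samples
  w_mean <- apply(sm$nu_omega, c(2, 3), mean)
  theta0 <- c(colMeans(sm$log_beta), colMeans(sm$log_gamma),
              as.vector(t(w_mean)), log(init$alpha_u + 1e-8))
  sds <- c(apply(sm$log_beta, 2, sd), apply(sm$log_gamma, 2, sd),
           as.vector(t(apply(sm$nu_omega, c(2, 3), sd))), rep(0.05, ng))
  minv <- pmax(sds, 1e-3)^2
  set.seed(seed)
  res <- velocity_hmc_cpp(
    U = data$U, log_sbar = inp$log_sbar, W = inp$W, Zw = inp$Zw,
    cond = inp$cond - 1L, nt = inp$nt, relu_floor = init$relu_floor,
    pm_lb = pr$pm_lb, ps_lb = pr$ps_lb, pm_lg = pr$pm_lg, ps_lg = pr$ps_lg,
    pm_w = pr$pm_w, ps_w = pr$ps_w,
    theta0 = theta0, minv = minv, n_warmup = warmup, n_samples = samples,
    n_leapfrog = leapfrog, target_accept = target_accept)
  div_frac <- res$divergences / (warmup + samples)
  if (div_frac > max_divergence_frac)
    warning(sprintf("%d divergent transitions (%.1f%% of iterations)",
                    res$divergences, 100 * div_frac))
  S <- res$samples
  nw <- inp$nt * Fw
  w <- array(0, c(samples, inp$nt, Fw))
  for (t in seq_len(inp$nt)) for (f in seq_len(Fw))
    w[, t, f] <- S[, 2 * ng + (t - 1) * Fw + f]
  fit <- structure(list(guide = "mcmc", model = model, params = res,
                        ng = ng, nt = inp$nt, Fw = Fw,
                        cond_levels = inp$cond_levels,
                        gene_ids = data$gene_ids,
                        relu_floor = init$relu_floor,
                        elbo_trace = numeric(0), n_iter = warmup + samples,
                        accept_rate = res$accept_rate,
                        divergences = res$divergences,
                        seed = seed),
                   class = "cv_velocity_fit")
  fit$samples <- list(log_beta = S[, seq_len(ng), drop = FALSE],
                      log_gamma = S[, ng + seq_len(ng), drop = FALSE],
                      nu_omega = w,
                      alpha_u = exp(S[, 2 * ng + nw + seq_len(ng), drop = FALSE]),
                      n_draws = samples)
  summarize_velocity_fit(fit)
}

#' Compare the mean-field and LRMN variational families
#'
#' Fits both guides on identical inputs and seed, and reports the 5-95%
#' credible-interval width of the scaled speed per guide together with
#' per-gene posterior-sample correlations between `log gamma_g` and the
#' zeroth speed harmonic (zero by construction under mean-field; structured
#' under LRMN).
#'
#' @param data,manifold,model,n_steps,seed as in [fit_velocity()].
#' @param condition condition index for the speed summary.
#' @return list with `ci_width_meanfield`, `ci_width_lrmn`, a per-gene
#'   `gene_corr_table` (one speed column per condition), and both fits.
#' @export
compare_guides <- function(data, manifold, model = "constant",
                           n_steps = 10000, seed = 0, condition = 1) {
  fit_mf <- fit_velocity(data, manifold, model, guide = "meanfield",
                         n_steps = n_steps, seed = seed)
  fit_lr <- fit_velocity(data, manifold, model, guide = "lrmn",
                         n_steps = n_steps, seed = seed)
  ci_w <- function(fit) {
    sp <- scaled_speed(fit, condition = condition)
    diff(quantile(sp, c(0.05, 0.95), names = FALSE))
  }
  ct <- sapply(seq_len(fit_lr$nt), function(t)
    vapply(seq_len(fit_lr$ng), function(g)
      cor(fit_lr$samples$log_gamma[, g], fit_lr$samples$nu_omega[, t, 1]),
      numeric(1)))
  colnames(ct) <- fit_lr$cond_levels
  rownames(ct) <- fit_lr$gene_ids
  list(ci_width_meanfield = ci_w(fit_mf), ci_width_lrmn = ci_w(fit_lr),
       gene_corr_table = ct, fit_meanfield = fit_mf, fit_lrmn = fit_lr)
}
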