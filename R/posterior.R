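# Posterior utilities: biology-scale speeds and periods, unspliced-spliced
# delays, the approximate SVD point estimator, and credible-interval
# comparisons between conditions.

get_samples <- function(x) {
  if (inherits(x, "cv_velocity_fit")) x$samples
  else if (is.list(x) && !is.null(x$nu_omega)) x
  else stop("expected a cv_velocity_fit or its posterior samples",
            call. = FALSE)
}

# per-draw mean half-life over genes (hours per assumed time unit)
mean_half_life <- function(log_gamma_draws,
                           half_life = c("physical", "lifetime")) {
  half_life <- match.arg(half_life)
  fac <- if (half_life == "physical") log(2) else 1
  rowMeans(fac * exp(-log_gamma_draws))
}

#' Posterior draws of the scaled angular speed
#'
#' Each draw's speed (the phase-average of `omega(phi)`, i.e. the zeroth
#' harmonic) is multiplied by that draw's mean degradation half-life,
#' `mean_g(ln 2 / gamma_g)` (`half_life = "physical"`, default) or the mean
#' lifetime `mean_g(1 / gamma_g)` (`"lifetime"`), giving radians per mean
#' half-life (rpmh).
#'
#' @param x a `cv_velocity_fit` or its posterior samples.
#' @param condition condition index.
#' @param half_life `"physical"` (ln2/gamma) or `"lifetime"` (1/gamma).
#' @return numeric vector of per-draw scaled speeds.
#' @export
scaled_speed <- function(x, condition = 1,
                         half_life = c("physical", "lifetime")) {
  sm <- get_samples(x)
  if (!length(sm$nu_omega)) stop("no posterior samples", call. = FALSE)
  sm$nu_omega[, condition, 1] * mean_half_life(sm$log_gamma, half_life)
}

#' Cell cycle period with credible interval
#'
#' Per posterior draw, the period is the trapezoidal integral of
#' `1 / omega_scaled(phi)` over a 20-point phase grid on `[0, 2*pi]`,
#' converted to hours with an assumed mean half-life. Draws with a
#' non-positive speed anywhere on the grid are excluded (and counted). For a
#' constant speed the quadrature is exact: `T = 2*pi / omega`.
#'
#' @param x a `cv_velocity_fit` or its posterior samples.
#' @param condition condition index.
#' @param mean_half_life_hours assumed mean degradation half-life in hours
#'   (the field's convention: about 1 h).
#' @param n_grid phase-grid size (default 20).
#' @param half_life as in [scaled_speed()].
#' @param probs credible-interval percentiles.
#' @return a `cv_period` list: `mean`, `ci_lo`, `ci_hi` (hours),
#'   `mean_half_lives` (same, in units of mean half-lives), `n_excluded`.
#' @export
cell_cycle_period <- function(x, condition = 1, mean_half_life_hours = 1.0,
                              n_grid = 20, half_life = c("physical", "lifetime"),
                              probs = c(0.05, 0.95)) {
  sm <- get_samples(x)
  grid <- seq(0, 2 * pi, length.out = n_grid)
  Fw <- dim(sm$nu_omega)[3]
  Zg <- fourier_basis(grid, (Fw - 1) / 2)
  mhl <- mean_half_life(sm$log_gamma, half_life)
  wdraws <- sm$nu_omega[, condition, , drop = TRUE]
  if (is.null(dim(wdraws))) wdraws <- matrix(wdraws, ncol = 1)
  omega_grid <- wdraws %*% t(Zg) * mhl          # draws x grid, rpmh
  ok <- apply(omega_grid > 0, 1, all)
  if (!any(ok))
    stop("no posterior draw has positive speed on the whole grid",
         call. = FALSE)
  if (!all(ok))
    warning(sprintf("%d draw(s) with non-positive speed excluded",
                    sum(!ok)))
  periods <- apply(omega_grid[ok, , drop = FALSE], 1, function(w)
    pracma::trapz(grid, 1 / w)) * mean_half_life_hours
  qs <- quantile(periods, probs, names = FALSE)
  structure(list(mean = mean(periods), ci_lo = qs[1], ci_hi = qs[2],
                 mean_half_lives = mean(periods) / mean_half_life_hours,
                 mean_half_life_hours = mean_half_life_hours,
                 n_excluded = sum(!ok), n_draws = sum(ok)),
            class = "cv_period")
}

#' @export
print.cv_period <- function(x, ...) {
  cat(sprintf("cell cycle period: %.2f h (%.0f%% CI %.2f-%.2f) at %.2g h mean half-life\n",
              x$mean, 90, x$ci_lo, x$ci_hi, x$mean_half_life_hours))
  if (x$n_excluded > 0)
    cat(sprintf("  %d non-positive-speed draw(s) excluded\n", x$n_excluded))
  invisible(x)
}

# peak phase of one fit's log-expectation curves; closed form for k = 1
peak_phases <- function(fit, n_grid = 1024) {
  nu <- fit$nu_loc
  if (fit$k == 1) {
    peak <- atan2(nu[, 3], nu[, 2])
    amp <- sqrt(nu[, 2]^2 + nu[, 3]^2)
  } else {
    grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
    curves <- fourier_basis(grid, fit$k) %*% t(nu)
    peak <- grid[apply(curves, 2, which.max)]
    amp <- (apply(curves, 2, max) - apply(curves, 2, min)) / 2
  }
  list(peak = wrap_phase(peak), amplitude = amp)
}

#' Unspliced-spliced phase delays
#'
#' Per-gene difference between the peak phases of the spliced and unspliced
#' expectation curves, wrapped to `(-pi, pi]`. For single-harmonic genes
#' under constant speed the delay obeys `tan(delay) = omega / gamma`. The
#' unspliced fit must have been obtained with phases conditioned on the
#' spliced fit. Genes with first-harmonic amplitude below `min_amplitude`
#' in either layer have an undefined peak and are flagged.
#'
#' @param manifold_s,manifold_u manifold fits on spliced and unspliced
#'   counts over the same genes.
#' @param min_amplitude amplitude floor below which the delay is undefined.
#' @return data frame: `gene`, `peak_spliced`, `peak_unspliced`, `delay`,
#'   `amplitude_spliced`, `amplitude_unspliced`, `defined`.
#' @export
us_delays <- function(manifold_s, manifold_u, min_amplitude = 0.05) {
  stopifnot(inherits(manifold_s, "cv_manifold_fit"),
            inherits(manifold_u, "cv_manifold_fit"))
  if (nrow(manifold_s$nu_loc) != nrow(manifold_u$nu_loc))
    stop("fits disagree on the gene set", call. = FALSE)
  ps <- peak_phases(manifold_s)
  pu <- peak_phases(manifold_u)
  defined <- ps$amplitude >= min_amplitude & pu$amplitude >= min_amplitude
  delay <- wrap_pm(ps$peak - pu$peak)
  delay[!defined] <- NA_real_
  data.frame(gene = manifold_s$gene_ids,
             peak_spliced = ps$peak, peak_unspliced = pu$peak,
             delay = delay,
             amplitude_spliced = ps$amplitude,
             amplitude_unspliced = pu$amplitude,
             defined = defined, row.names = NULL)
}

#' Approximate SVD point estimate of condition-wise speed and period
#'
#' Under first-order kinetics with condition-independent gene lifetimes, the
#' matrix of `tan(delay)` values factorizes as `delta_cg = omega_c * tau_g`
#' (rank 1). The leading singular triple, oriented so the gene-side mean is
#' positive, yields `omega*_c = u_c d mean(v_g)` in units of inverse mean
#' lifetimes and `T*_c = 2*pi / omega*_c`.
#'
#' @param delta conditions x genes matrix of `tan(delay)` values (at least 2
#'   genes; finite).
#' @return list with `omega_star`, `period` (per condition), and the leading
#'   singular triple.
#' @export
point_estimate_period <- function(delta) {
  delta <- as.matrix(delta)
  if (ncol(delta) < 2) stop("need at least 2 genes", call. = FALSE)
  check_finite(delta, "delta")
  if (all(delta == 0)) stop("all-zero delay matrix has no rank-1 structure",
                            call. = FALSE)
  sv <- svd(delta)
  u <- sv$u[, 1]; d <- sv$d[1]; v <- sv$v[, 1]
  if (mean(v) < 0) { u <- -u; v <- -v }
  omega_star <- u * d * mean(v)
  list(omega_star = omega_star, period = 2 * pi / omega_star,
       u = u, d = d, v = v)
}

# overlapping coefficient of two empirical distributions on a shared
# histogram
overlap_coefficient <- function(a, b, bins = 50) {
  br <- seq(min(a, b), max(a, b), length.out = bins + 1)
  if (br[1] == br[bins + 1]) return(1.0)
  pa <- tabulate(findInterval(a, br, rightmost.closed = TRUE), bins) / length(a)
  pb <- tabulate(findInterval(b, br, rightmost.closed = TRUE), bins) / length(b)
  sum(pmin(pa, pb))
}

#' Credible-interval comparison of two conditions
#'
#' Reports 5-95% scaled-speed intervals per condition, the interval of the
#' per-draw difference, and the overlapping coefficient of the two empirical
#' sample distributions (shared 50-bin histogram). The difference is flagged
#' significant when its interval strictly excludes zero.
#'
#' @param fit a multi-condition `cv_velocity_fit`.
#' @param cond_a,cond_b condition indices or labels.
#' @param probs interval percentiles.
#' @param bins histogram bins for the overlap.
#' @param half_life as in [scaled_speed()].
#' @return list: `ci_a`, `ci_b`, `ci_difference`, `overlap_fraction`,
#'   `significant`.
#' @export
compare_conditions <- function(fit, cond_a, cond_b, probs = c(0.05, 0.95),
                               bins = 50, half_life = "physical") {
  resolve <- function(cc) {
    if (is.character(cc)) cc <- match(cc, fit$cond_levels)
    if (is.na(cc) || cc < 1 || cc > fit$nt) stop("unknown condition")
    cc
  }
  a <- scaled_speed(fit, resolve(cond_a), half_life)
  b <- scaled_speed(fit, resolve(cond_b), half_life)
  dd <- a - b
  ci_d <- quantile(dd, probs, names = FALSE)
  list(ci_a = quantile(a, probs, names = FALSE),
       ci_b = quantile(b, probs, names = FALSE),
       ci_difference = ci_d,
       overlap_fraction = overlap_coefficient(a, b, bins),
       significant = ci_d[1] > 0 || ci_d[2] < 0)
}

#' Credible test for a nonzero velocity
#'
#' @param fit a `cv_velocity_fit`.
#' @param condition condition index or label.
#' @param probs interval percentiles (default 5-95%).
#' @param half_life as in [scaled_speed()].
#' @return list: `ci` and `significant` (`TRUE` iff the interval strictly
#'   excludes zero; an interval touching zero is not significant).
#' @export
test_nonzero <- function(fit, condition = 1, probs = c(0.05, 0.95),
                         half_life = "physical") {
  if (is.character(condition)) condition <- match(condition, fit$cond_levels)
  sp <- scaled_speed(fit, condition, half_life)
  ci <- quantile(sp, probs, names = FALSE)
  list(ci = ci, significant = ci[1] > 0 || ci[2] < 0)
}

#' Sample-based KL divergence between two 2D posteriors
#'
#' Kernel-density estimate of `KL(P || Q)` from two draws of a parameter
#' pair (for example `(log gamma_g, nu_omega_0)` under the LRMN guide
#' versus MCMC), evaluated on a shared grid. Intended as a qualitative
#' diagnostic of how closely a variational family tracks the MCMC
#' posterior; the values depend on the bandwidth and grid and are not
#' reproducible targets.
#'
#' @param a,b two-column matrices of draws from P and Q.
#' @param n_grid grid resolution per axis (default 50).
#' @return the estimated KL divergence in nats (non-negative up to
#'   discretization error).
#' @export
kl_divergence_2d <- function(a, b, n_grid = 50) {
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("kl_divergence_2d requires the MASS package")
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2)
  lims <- c(range(a[, 1], b[, 1]), range(a[, 2], b[, 2]))
  da <- MASS::kde2d(a[, 1], a[, 2], n = n_grid, lims = lims)
  db <- MASS::kde2d(b[, 1], b[, 2], n = n_grid, lims = lims)
  p <- da$z / sum(da$z)
  q <- db$z / sum(db$z)
  keep <- p > 1e-12
  sum(p[keep] * (log(p[keep]) - log(pmax(q[keep], 1e-12))))
}
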