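# Deterministic mathematical core shared by the simulator and both inference
# stages: circular Fourier basis, expected spliced/unspliced counts, and the
# angular-speed function.

#' Wrap angles onto the circle
#'
#' @param phi numeric vector of angles in radians.
#' @return angles wrapped to `[0, 2*pi)`.
#' @export
wrap_phase <- function(phi) phi %% (2 * pi)

# wrapped difference mapped to (-pi, pi]
wrap_pm <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

#' Circular Fourier basis
#'
#' Evaluates the harmonic design vector `zeta(phi) = (1, cos(phi), sin(phi),
#' ..., cos(k*phi), sin(k*phi))` for each phase, the basis in which log
#' expected spliced expression is linear.
#'
#' @param phi numeric vector of phases (radians).
#' @param k number of harmonics (non-negative integer; default 1).
#' @return matrix with `length(phi)` rows and `2k + 1` columns, ordered
#'   `[1, cos(phi), sin(phi), ..., cos(k*phi), sin(k*phi)]`.
#' @export
fourier_basis <- function(phi, k = 1) {
  if (length(k) != 1 || is.na(k) || k < 0 || k != round(k))
    stop("'k' must be a single non-negative integer", call. = FALSE)
  check_finite(phi, "phi")
  Z <- matrix(1, length(phi), 2 * k + 1)
  if (k > 0) {
    for (h in seq_len(k)) {
      Z[, 2 * h]     <- cos(h * phi)
      Z[, 2 * h + 1] <- sin(h * phi)
    }
  }
  colnames(Z) <- fourier_colnames(k)
  Z
}

#' Derivative of the circular Fourier basis
#'
#' Entrywise derivative of [fourier_basis()] with respect to the phase; the
#' first column (constant term) is identically zero.
#'
#' @inheritParams fourier_basis
#' @return matrix of the same shape as [fourier_basis()].
#' @export
fourier_basis_derivative <- function(phi, k = 1) {
  if (length(k) != 1 || is.na(k) || k < 0 || k != round(k))
    stop("'k' must be a single non-negative integer", call. = FALSE)
  check_finite(phi, "phi")
  Zd <- matrix(0, length(phi), 2 * k + 1)
  if (k > 0) {
    for (h in seq_len(k)) {
      Zd[, 2 * h]     <- -h * sin(h * phi)
      Zd[, 2 * h + 1] <-  h * cos(h * phi)
    }
  }
  colnames(Zd) <- fourier_colnames(k)
  Zd
}

fourier_colnames <- function(k) {
  nm <- "a0"
  if (k > 0) nm <- c(nm, as.vector(rbind(paste0("a", 1:k), paste0("b", 1:k))))
  nm
}

as_nu_matrix <- function(nu) {
  if (is.null(dim(nu))) nu <- matrix(nu, nrow = 1)
  check_finite(nu, "Fourier coefficients")
  if (ncol(nu) %% 2 != 1)
    stop("coefficient matrix must have 2k + 1 columns", call. = FALSE)
  nu
}

#' Expected spliced counts on the circular manifold
#'
#' `s_g(phi) = exp(sum_f nu_gf zeta_f(phi))`: strictly positive expected
#' spliced expression for each cell x gene combination.
#'
#' @param phi phases (radians), one per cell.
#' @param nu gene x (2k+1) matrix of Fourier coefficients (a single gene may
#'   be given as a vector).
#' @return positive matrix, cells x genes.
#' @export
expected_spliced <- function(phi, nu) {
  nu <- as_nu_matrix(nu)
  k <- (ncol(nu) - 1) / 2
  exp(fourier_basis(phi, k) %*% t(nu))
}

#' Angular speed along the cell cycle
#'
#' Evaluates `omega(phi) = nu_omega . zeta(phi)` (linear, not log,
#' parametrization). A single coefficient gives the constant-speed model.
#'
#' @param phi phases (radians).
#' @param nu_omega numeric vector of speed harmonics `[w0, w1cos, w1sin, ...]`
#'   (length `2k + 1`), or a one-row matrix.
#' @return numeric vector of per-cell speeds (may be locally negative for a
#'   strongly periodic parametrization; the unspliced mean applies a relu).
#' @export
angular_speed <- function(phi, nu_omega) {
  nu_omega <- as_nu_matrix(nu_omega)
  if (nrow(nu_omega) != 1)
    stop("'nu_omega' must describe a single speed function; ",
         "per-condition rows are handled by the fitting routines",
         call. = FALSE)
  k <- (ncol(nu_omega) - 1) / 2
  as.vector(fourier_basis(phi, k) %*% t(nu_omega))
}

#' Kinetic parameter bundle
#'
#' @param log_beta per-gene log splicing rate (log 1/h).
#' @param log_gamma per-gene log degradation rate (log 1/h).
#' @return a `cv_kinetics` list.
#' @export
kinetic_params <- function(log_beta, log_gamma) {
  check_finite(log_beta, "log_beta")
  check_finite(log_gamma, "log_gamma")
  if (length(log_beta) != length(log_gamma))
    stop("'log_beta' and 'log_gamma' must have equal length", call. = FALSE)
  structure(list(log_beta = log_beta, log_gamma = log_gamma),
            class = "cv_kinetics")
}

#' Expected unspliced counts on the circular manifold
#'
#' Combines the manifold geometry with first-order splicing kinetics:
#' `u_g(phi) = s_g(phi)/beta_g * relu(omega(phi) * sum_f nu_gf
#' d/dphi zeta_f(phi) + gamma_g)`. The relu argument is floored at
#' `relu_floor` so the log of the mean stays finite in the likelihood.
#'
#' @inheritParams expected_spliced
#' @param kin a [kinetic_params()] bundle.
#' @param nu_omega angular-speed harmonics as in [angular_speed()].
#' @param relu_floor positive floor applied to `omega * dlogs + gamma`.
#' @return positive matrix, cells x genes.
#' @export
expected_unspliced <- function(phi, nu, kin, nu_omega, relu_floor = 1e-5) {
  nu <- as_nu_matrix(nu)
  if (!inherits(kin, "cv_kinetics")) stop("'kin' must be a kinetic_params()")
  if (nrow(nu) != length(kin$log_beta))
    stop("kinetics and coefficient matrix disagree on gene count")
  k <- (ncol(nu) - 1) / 2
  s <- expected_spliced(phi, nu)
  dlogs <- fourier_basis_derivative(phi, k) %*% t(nu)
  omega <- angular_speed(phi, nu_omega)
  inner <- pmax(dlogs * omega + rep(exp(kin$log_gamma), each = length(phi)),
                relu_floor)
  s * inner / rep(exp(kin$log_beta), each = length(phi))
}
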