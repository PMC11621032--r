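# End-to-end simulation benchmarks mirroring the sensitivity analyses:
# phase/harmonic recovery, velocity accuracy at fixed and swept speeds,
# small-data robustness and noncycling contamination. Default sizes are
# chosen to complete in minutes on one CPU (see the methods vignette); every
# function takes an explicit integer seed and derives per-replicate seeds by
# small offsets.

#' Phase-recovery benchmark on structured simulations
#'
#' Simulates `n_reps` datasets (uniform phases, correlated truth, constant
#' ground-truth speed), runs manifold learning on each, aligns to the truth
#' (rotation/reflection gauge) and reports the circular correlation of the
#' phases, the Pearson correlation of the zeroth harmonic, and the pooled
#' 5-95% credible-interval coverage of the true phases.
#'
#' @param n_reps replicate simulations (default 3).
#' @param n_cells,n_genes simulation size (defaults 3000 x 300).
#' @param omega ground-truth constant speed (default 0.4).
#' @param n_steps manifold SVI iterations (default 5000).
#' @param seed base integer seed.
#' @return list: `per_rep` data frame (`circ_corr`, `nu0_corr`, `coverage`),
#'   `coverage_pooled`, and the `sims` and aligned `fits` for downstream
#'   stages.
#' @export
benchmark_phase_recovery <- function(n_reps = 3, n_cells = 3000,
                                     n_genes = 300, omega = 0.4,
                                     n_steps = 5000, seed = 0) {
  sims <- list(); fits <- list()
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    truth <- sample_truth(n_cells, n_genes, omega_gt = omega, seed = seed + i)
    data <- sample_counts(truth)
    fit <- fit_manifold(data, n_steps = n_steps, seed = seed + 50 + i)
    al <- align_to_truth(fit, truth$phi)
    rows[[i]] <- data.frame(
      rep = i,
      circ_corr = circular_corrcoef(al$phi_mean, truth$phi),
      nu0_corr = cor(al$nu_loc[, 1], truth$nu[, 1]),
      coverage = posterior_phase_coverage(al, truth$phi,
                                          seed = seed + 80 + i))
    sims[[i]] <- list(truth = truth, data = data)
    fits[[i]] <- al
  }
  per_rep <- do.call(rbind, rows)
  list(per_rep = per_rep, coverage_pooled = mean(per_rep$coverage),
       sims = sims, fits = fits)
}

#' Velocity-recovery benchmark conditioned on the simulated truth
#'
#' For each simulation, runs velocity learning (constant-speed model,
#' mean-field SVI) conditioned on the true phases and harmonics, and reports
#' the constant-speed percent error and the Pearson correlation of the
#' estimated gamma/beta ratios with the truth.
#'
#' @param sims list of `list(truth, data)` as returned by
#'   [benchmark_phase_recovery()].
#' @param n_steps velocity SVI iterations (default 10000).
#' @param seed base integer seed.
#' @return data frame with `omega_hat`, `pct_err`, `ratio_corr` per
#'   simulation.
#' @export
benchmark_velocity_recovery <- function(sims, n_steps = 10000, seed = 0) {
  rows <- lapply(seq_along(sims), function(i) {
    truth <- sims[[i]]$truth
    fit <- fit_velocity(sims[[i]]$data, manifold_from_truth(truth),
                        model = "constant", guide = "meanfield",
                        n_steps = n_steps, seed = seed + 60 + i)
    rt <- exp(truth$kin$log_gamma - truth$kin$log_beta)
    data.frame(rep = i, omega_hat = unname(fit$omega),
               pct_err = velocity_percent_error(unname(fit$omega),
                                                truth$nu_omega[1, 1]),
               ratio_corr = cor(fit$gamma_beta_ratio, rt))
  })
  do.call(rbind, rows)
}

#' Velocity accuracy across a sweep of ground-truth speeds
#'
#' Replicate simulations share truth parameters within a replicate (the
#' seed fixes gene harmonics and kinetics) and differ only in the
#' ground-truth speed; velocity learning is conditioned on the truth per
#' dataset.
#'
#' @param omegas ground-truth speeds (default `c(0.1, 0.4, 0.8, 1.5)`).
#' @param n_reps replicates per speed (default 2).
#' @param n_cells,n_genes simulation size (defaults 1500 x 200).
#' @param n_steps velocity SVI iterations.
#' @param seed base integer seed.
#' @return data frame with `omega`, `rep`, `omega_hat`, `pct_err`,
#'   `ratio_corr` per fit.
#' @export
benchmark_omega_sweep <- function(omegas = c(0.1, 0.4, 0.8, 1.5), n_reps = 2,
                                  n_cells = 1500, n_genes = 200,
                                  n_steps = 10000, seed = 0) {
  rows <- list()
  for (r in seq_len(n_reps)) {
    for (w in omegas) {
      truth <- sample_truth(n_cells, n_genes, omega_gt = w, seed = seed + 10 + r)
      data <- sample_counts(truth, seed = seed + 20 + r + round(100 * w))
      fit <- fit_velocity(data, manifold_from_truth(truth),
                          model = "constant", guide = "meanfield",
                          n_steps = n_steps, seed = seed + 30 + r)
      rt <- exp(truth$kin$log_gamma - truth$kin$log_beta)
      rows[[length(rows) + 1]] <- data.frame(
        omega = w, rep = r, omega_hat = unname(fit$omega),
        pct_err = if (w > 0)
          velocity_percent_error(unname(fit$omega), w) else NA_real_,
        ratio_corr = cor(fit$gamma_beta_ratio, rt))
    }
  }
  do.call(rbind, rows)
}

#' Small-data robustness of manifold learning
#'
#' Subsamples one structured simulation to few cells (keeping all genes) and
#' separately to few genes (keeping all cells) and reports the aligned
#' circular correlation of each manifold fit.
#'
#' @param n_cells,n_genes full simulation size (defaults 3000 x 300).
#' @param few_cells,few_genes subsample sizes (defaults 100 each).
#' @param omega ground-truth speed.
#' @param n_steps manifold SVI iterations.
#' @param seed base integer seed.
#' @return list with `circ_corr_cells` and `circ_corr_genes`.
#' @export
benchmark_small_data <- function(n_cells = 3000, n_genes = 300,
                                 few_cells = 100, few_genes = 100,
                                 omega = 0.4, n_steps = 5000, seed = 0) {
  truth <- sample_truth(n_cells, n_genes, omega_gt = omega, seed = seed + 5)
  data <- sample_counts(truth)
  d_cells <- dataset_subset(data, cells = seq_len(few_cells))
  f_cells <- fit_manifold(d_cells, n_steps = n_steps, seed = seed + 6)
  cc_cells <- circular_corrcoef(
    align_to_truth(f_cells, truth$phi[seq_len(few_cells)])$phi_mean,
    truth$phi[seq_len(few_cells)])
  d_genes <- dataset_subset(data, genes = seq_len(few_genes))
  f_genes <- fit_manifold(d_genes, n_steps = n_steps, seed = seed + 7)
  cc_genes <- circular_corrcoef(align_to_truth(f_genes, truth$phi)$phi_mean,
                                truth$phi)
  list(circ_corr_cells = cc_cells, circ_corr_genes = cc_genes)
}

#' Robustness to noncycling (zero-velocity) contamination
#'
#' Spikes zero-velocity cells into a cycling simulation, runs the full
#' two-stage pipeline on the mixture (manifold learning, gauge alignment to
#' the truth, velocity learning), and reports the circular correlation on
#' the cycling subpopulation and the constant-speed percent error.
#'
#' @param n_cycling,n_genes cycling-population size (defaults 1000 x 300).
#' @param ratio noncycling cells per 100 cycling cells (default 50).
#' @param omega ground-truth speed of the cycling cells.
#' @param n_steps_manifold,n_steps_velocity SVI iterations per stage.
#' @param seed base integer seed.
#' @return list with `circ_corr`, `omega_hat`, `pct_err`.
#' @export
benchmark_contamination <- function(n_cycling = 1000, n_genes = 300,
                                    ratio = 50, omega = 0.4,
                                    n_steps_manifold = 5000,
                                    n_steps_velocity = 10000, seed = 0) {
  truth <- sample_truth(n_cycling, n_genes, omega_gt = omega, seed = seed + 8)
  mix <- spike_noncycling(sample_counts(truth), truth, ratio)
  fit <- fit_manifold(mix$data, n_steps = n_steps_manifold, seed = seed + 9)
  al <- align_to_truth(fit, mix$truth$phi)
  cyc <- mix$truth$is_cycling
  cc <- circular_corrcoef(al$phi_mean[cyc], mix$truth$phi[cyc])
  vf <- fit_velocity(mix$data, al, model = "constant", guide = "meanfield",
                     n_steps = n_steps_velocity, seed = seed + 12)
  list(circ_corr = cc, omega_hat = unname(vf$omega),
       pct_err = velocity_percent_error(unname(vf$omega), omega))
}
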