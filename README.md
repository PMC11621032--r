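# circvelo

Manifold-constrained RNA velocity for periodic processes, with the cell
cycle as the primary target, plus a proof-of-principle extension to bounded
pseudotime intervals.

## The problem and who this is for

Single-cell RNA-seq measures spliced (mature) and unspliced (nascent) UMI
counts per gene. Their balance carries dynamical information: unspliced RNA
is spliced at rate β<sub>g</sub> and spliced RNA degrades at rate
γ<sub>g</sub>, so ds<sub>g</sub>/dt = β<sub>g</sub>u<sub>g</sub> −
γ<sub>g</sub>s<sub>g</sub>. Generic RNA velocity estimators treat every
gene independently in the full expression space and are notoriously
fragile. For a process whose geometry is known — the cell cycle is a circle
— the dynamics can instead be constrained to a one-dimensional latent
manifold, turning velocity estimation into a small, well-posed Bayesian
inference problem. circvelo is for computational biologists who want
per-cell cell cycle phases, per-gene expression harmonics, splicing and
degradation kinetics, and a proliferation speed (with honest posterior
uncertainty) from standard spliced/unspliced count matrices.

## The model

Each cell has a circular phase φ<sub>c</sub> ∈ [0, 2π). Log expected
spliced expression is a truncated Fourier series,

    log s_g(φ) = Σ_f ν_gf ζ_f(φ),     ζ(φ) = (1, cos φ, sin φ, …),

and cells progress at an angular speed ω(φ) (constant or one harmonic), so
the rate equation gives the expected unspliced counts

    u_g(φ) = s_g(φ)/β_g · relu( ω(φ) Σ_f ν_gf ∂_φ ζ_f(φ) + γ_g ).

Counts are negative binomial around these expectations with per-gene
dispersions. Inference is two-stage stochastic variational inference:
**manifold learning** (phases + harmonics from spliced counts; projected
normal phase posteriors, empirical-Bayes priors anchored by PCA and total
UMIs) followed by **velocity learning** (β, γ, ω, dispersion from unspliced
counts), with a mean-field or a low-rank multivariate normal (LRMN)
variational family and a Hamiltonian Monte Carlo backend. Only
γ<sub>g</sub>/β<sub>g</sub> and the speed relative to the kinetic timescale
are identifiable, so speeds are reported in radians per mean half-life
(rpmh) and converted to hours under an assumed mean half-life. The
single-harmonic delay relation tan(Δφ<sub>g</sub>) = ω/γ<sub>g</sub> also
yields a closed-form SVD point estimate of per-condition speeds from a
delay matrix. See the methods vignette
(`vignettes/manifold-constrained-velocity.Rmd`) for the full account.

## Worked example

All inputs are synthetic — the package ships a structured simulator with
correlated gene harmonics and kinetic rates:

```r
library(circvelo)

# simulate a cycling population: 1,000 cells x 150 genes, true speed 0.4
truth <- sample_truth(n_cells = 1000, n_genes = 150, omega_gt = 0.4, seed = 7)
data  <- sample_counts(truth)
data
#> cv_dataset: 1000 cells x 150 genes
#>   mean spliced 5.69, mean unspliced 2.66 UMIs/cell/gene

# stage 1: manifold learning (phases + gene harmonics from spliced counts)
fit <- fit_manifold(data, n_steps = 5000, seed = 7)
aligned <- align_to_truth(fit, truth$phi)   # resolve rotation/reflection
circular_corrcoef(aligned$phi_mean, truth$phi)
#> [1] 0.9920045

# stage 2: velocity learning with the LRMN guide
vel <- fit_velocity(data, fit, model = "constant", guide = "lrmn", seed = 7)
vel
#> cv_velocity_fit (lrmn, constant model): 150 genes, 1 condition(s)
#>   omega[all] posterior mean 0.475

test_nonzero(vel)$ci          # 5-95% interval of the scaled speed (rpmh)
#> [1] 0.2694492 0.3499621

cell_cycle_period(vel, mean_half_life_hours = 1)
#> cell cycle period: 20.48 h (90% CI 17.95-23.32) at 1 h mean half-life
```

The phase estimate matches the simulated truth almost perfectly (circular
correlation 0.99). The recovered speed (0.475 vs. a true 0.4) scales to
about 0.31 rpmh under this simulation's half-lives; the credible interval
excludes zero, and under a 1 h mean half-life the implied cell cycle period
is about 20 h with a 90% interval of 18–23 h — the scale expected of
cultured mammalian cells.

Datasets are read and written as paired MatrixMarket or TSV layers
(`read_dataset()`, `write_dataset()`); `filter_genes()` / `filter_by_fit()`
implement the standard gene QC, and `inst/cli/circvelo` provides a thin
command-line wrapper (`simulate`, `manifold`, `velocity`, `analyze`,
`benchmark`).

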