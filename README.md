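# cgflow — data-free, energy-based coarse-graining with normalizing flows

`cgflow` trains a generative coarse-grained model of a Boltzmann
distribution p(x) ∝ exp(−βU(x)) **using only the energy U(x) and its
forces** — no molecular-dynamics trajectories, no precollected data. It is
aimed at molecular-modelling researchers who need equilibrium samples and
coarse-grained representations of multimodal targets where plain
reverse-KL training of a flow collapses onto a single metastable state.

## The model

The configuration x is reparameterized through a learnable linear
bijection

    x = A_φ (z, X),      A_φ right stochastic (rows are softmaxes of φ)

into *slow* coordinates z, whose marginal q_θ(z) is a rational-quadratic
spline normalizing flow over a truncated-normal base (multimodal by
construction capacity), and *fast* coordinates X with a unimodal
conditional q_θ(X|z) = N(μ_θ(z), diag σ²_θ(z)). Training minimizes the
reverse Kullback–Leibler divergence

    L(θ, φ) = β⟨U_φ⟩_q + ⟨log q_θ(X|z)⟩ + ⟨log q_θ(z)⟩ + log Z_β,
    U_φ = U(f_φ(X, z)) − β⁻¹ log K_φ,

by pathwise Monte-Carlo gradients in which each sample costs exactly one
energy and one force evaluation (forces are cached and reused as the
adjoint of the energy term). Mode collapse is countered by an adaptive
tempering schedule: β grows from ≈0 to β_target in increments chosen so
the relative change of the KL divergence stays below a threshold
(δKL_max), capped by Δβ_max; the model is checkpointed at every accepted
β. Trained models produce independent one-shot samples, free energies
A(z) = −β⁻¹ log q_θ(z), and unbiased observable estimates via
self-normalized importance sampling.

Everything — spline flows, backpropagation, the tempering schedule — is
implemented in R with a small Rcpp hot path for the spline transforms
and the conditioner networks (the pure-R reference implementations stay
in the package and the two routes are cross-checked in the tests); there is no autodiff dependency, and the
analytic gradients are gated against finite-difference oracles in the
test suite.

## Worked example: the asymmetric double well

The built-in target U(x) = x₁⁴/4 − 3x₁² + x₁ + x₂²/2 has two metastable
basins near x₁ = ∓2.5 separated by a barrier; at β = 1 the left basin
holds ≈99% of the mass and x₁ is the slow coordinate. Training (a few
minutes on one CPU at this reduced budget):

```r
library(cgflow)
p   <- preset("dw")                         # published double-well settings
m   <- do.call(cg_model, c(p$model, list(seed = 101)))
cfg <- p$config
cfg$n_samples <- 250L; cfg$L <- 100L        # reduced budget
cfg$L_initial <- 4000L; cfg$n_kl <- 1000L; cfg$seed <- 101L
cfg$early_stop <- FALSE                     # let the map train all L steps
tg  <- target_double_well()
res <- train(m, tg, p$schedule, cfg)

round(solve(materialize(res$model$mixing))[1, ], 3)  # inverse map: z from x
#> [1]  1.02 -0.02

q   <- dw_quadrature_marginal()             # analytic reference
q$left_mass
#> [1] 0.9916537
reweighted_expectation(res$model, tg, beta = 1,
                       function(x) as.numeric(x[, 1] < q$barrier),
                       M = 20000, seed = 108)
#> <is_report> estimate = 0.991965 +/- 0.00055 (ESS 19449.8 / 20000, beta = 1)
```

Read: the learned slow coordinate is z ≈ 1.02·x₁ − 0.02·x₂ — the model
*discovered* that x₁ is the reaction coordinate. The reweighted left-basin
mass (0.9920 ± 0.0006) reproduces the quadrature value 0.99165 within
Monte-Carlo error, and the effective sample size of the importance weights
(≈97% of M) shows the one-shot sampler is a near-perfect proposal for the
target at β = 1.

The three-mode Gaussian-mixture target (`build_gmm_target()`), the
20-dimensional tempering-necessity contrast, molecular pseudo-atom maps
(`block_size = 3`), observables (radius of gyration, RMSD, bond and
diversity scores) and the `inst/cli/cgflow.R` command line
(`train` / `sample` / `evaluate` / `presets`, JSON configs, CSV/XYZ
output) are documented in the methods vignette
(`vignettes/energy-based-coarse-graining.Rmd`).

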