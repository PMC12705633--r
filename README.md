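# petprecon

MAP reconstruction for PET count data with a mixed diagonal–circulant
preconditioner.

Penalized (MAP) PET reconstruction minimizes
`Φ(λ) = −L(λ) + β R(λ)` with the Poisson log-likelihood
`−L(λ) = Σᵢ ȳᵢ − yᵢ log ȳᵢ`, `ȳᵢ = Σⱼ aᵢ cᵢⱼ λⱼ + bᵢ`. The Hessian diagonal of
`−L` spans several orders of magnitude (attenuation factors `aᵢ ∈ (0,1]` enter
squared, and `1/ȳᵢ` varies between body-crossing and background LORs), so
gradient-based optimization is notoriously slow. This package is for people
studying or prototyping reconstruction algorithms: it provides, on top of a
self-contained parallel-beam forward model with an exact adjoint,

- the **unconstrained** Poisson gradient
  `Σᵢ aᵢ cᵢⱼ (ȳᵢ − yᵢ)/max(ȳᵢ, bᵢ)` — identical to the exact gradient inside
  the object, and free of the cold-region positivity bias of multiplicative
  algorithms;
- a **smooth relative difference prior**
  `M = Σⱼ Σ_ξ kⱼk_ξ (λⱼ−λ_ξ)² / sqrt(λⱼ²+λ_ξ²+γ²(λⱼ−λ_ξ)²+ε²)` with analytic
  gradient and Hessian (any γ), well defined for negative activities;
- a frozen **preconditioner** `s = D F⁻¹ T F D g`, with
  `D = diag(η^{-1/2})` from the expected Hessian diagonal at the
  initialization and `T` an apodized (optionally TOF-damped) 2D ramp filter;
- optimizers: **PCG** (full method), its ablations **PG**, **DCG**, **DG**,
  OSEM initialization, and a **BSREM** comparator — each PCG iteration costs
  exactly one forward and one back projection;
- NEMA-IQ-like / brain-like / thorax-like **digital phantoms** with seeded
  Poisson acquisition simulation, VOI masks, and convergence **metrics**
  (normalized RMSE, VOI errors) traced per iteration.

## Worked example

```r
library(petprecon)
spec <- phantom_spec("nema_like", seed = 42)       # 5e6 prompts, 10:1 spheres
geom <- default_geometry(spec)                     # 128x128, 2 mm, 96 angles
prob <- benchmark_problem(spec, geom)              # simulate + OSEM initialize
cfg  <- recon_config("PCG", n_iter = 10, beta = prob$beta_mid, rdp = prob$rdp)
rec  <- run_reconstruction(prob$data, geom, cfg, init = prob$init,
                           ref = prob$data$truth, mask = prob$mask,
                           vois = prob$vois[c("sphere_10mm", "sphere_37mm")])
round(rec$trace[, c("iteration", "objective", "grad_norm", "rmse",
                    "voi_sphere_10mm", "voi_sphere_37mm")], 4)
```

```
   iteration objective grad_norm    rmse voi_sphere_10mm voi_sphere_37mm
1          1 -25903474  655.4865 39.0195         -0.1929         -0.0196
2          2 -25906919  306.9996 32.0842          0.0551          0.0240
3          3 -25907910  268.3228 31.7940          0.1483          0.0300
4          4 -25908671  279.0182 33.3616          0.2045          0.0225
5          5 -25909315  238.0173 36.4793          0.2059          0.0104
6          6 -25909634   77.7706 38.7391          0.1830          0.0054
7          7 -25909937   68.3598 40.8408          0.1328          0.0061
8          8 -25910093   50.4288 42.1383          0.0964          0.0073
9          9 -25910224   67.1416 43.3736          0.0647          0.0077
10        10 -25910323   60.6054 44.4310          0.0448          0.0060
```

The objective decreases monotonically while the gradient norm falls by an
order of magnitude in 10 iterations. `voi_sphere_*` is the relative error of
the mean activity in each sphere against the noise-free truth: the 37 mm
sphere is recovered to better than 1% within a few iterations; the 10 mm
sphere (only ~9 voxels after mask erosion at this grid) rings before settling
— by iteration 10 it is within ~4% of the noisy data's own estimate of that
mean. The whole-object `rmse` column is measured against the *noise-free*
truth, so it reflects the noise the (lightly regularized) MAP solution itself
absorbs, not algorithm error; convergence comparisons between algorithms use
a converged reference at the same β instead (see
`reference_reconstruction()` / `run_convergence_study()`).

A command-line driver wrapping the same functions lives at
`inst/cli/petprecon.R`:

```sh
Rscript inst/cli/petprecon.R simulate    --out out/ --seed 1
Rscript inst/cli/petprecon.R reconstruct --algo pcg --iters 10 --out out/
Rscript inst/cli/petprecon.R benchmark   --iters 20 --out out/
Rscript inst/cli/petprecon.R plot        --traces out/ --metric rmse --out out/
```

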