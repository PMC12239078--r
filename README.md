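# mucodiff

Quantitative analysis of the diffusion barrier of mucus hydrogels and
their synthetic mimics (artificial colonic mucus models benchmarked
against native mucus). The package implements the full measurement
chain a mucus-barrier characterisation study needs, as reusable,
tested R functions:

* **Rheology** — gel-state classification (G′ vs G″), tan δ,
  shear-thinning power-law flow index, and the theoretical mesh size of
  the gel network from the storage modulus,
  ξ = (k_B·T / G′)^(1/3) (cubic-lattice scaling), with the exact
  inverse G′ = k_B·T / ξ³.
* **FRAP** — double normalization of bleach/reference/background ROI
  traces, I_norm(t) = (I_ref,pre / (I_ref − I_back)) · (I_frap − I_back)
  / I_frap,pre, and nonlinear fitting of the circular-spot recovery
  model F(t) = a₀ + a₁·e^(−x)[I₀(x) + I₁(x)], x = τ / (2(t − t_bleach)),
  giving D = w²/τ for a bleach spot of radius w.
* **Particle tracking** — time-averaged MSD of gapped trajectories,
  ⟨Δr²(τ)⟩ = ⟨[x(t+τ)−x(t)]² + [y(t+τ)−y(t)]²⟩, effective diffusivity
  D_eff = MSD/(2nτ), Stokes–Einstein reference D_w = k_B·T/(6πηr), the
  hindrance ratio D_w/D_eff, anomalous-exponent fitting
  MSD = 4·D₀·τ^α (log–log slope), and transport-mode classification
  (immobile / subdiffusive / diffusive / active by α bins).
* **Pore morphometry** — fixed-threshold binarization of cryo-SEM
  micrographs (pore band 0–75 of 8-bit gray), 8-connected pore
  labeling, Feret max/min diameters by rotating calipers on the convex
  hull, and Kruskal–Wallis cross-validation of microscopy pore sizes
  against the rheological mesh size.
* **Binding** — dissociation constants from thermophoresis-style
  dilution series via the ligand-depletion (quadratic) isotherm.
* **Statistics** — tie-corrected Kruskal–Wallis and Wilcoxon
  signed-rank tests with exact small-sample enumeration, and a
  per-matrix summary table builder.
* **Synthetic data** — seeded generators for every input modality
  (fractional-Brownian trajectory ensembles with localization noise,
  dropout and immobile fractions; FRAP traces with acquisition decay;
  pore micrographs with analytic Feret ground truth; power-law rheology
  sweeps; binding dilution series), so the entire pipeline is testable
  without instrument data.

## Worked example

```r
library(mucodiff)

## oscillatory sweep of a weak gel -> state + mesh size
sw <- gen_rheology_sweep(rheology_sim_spec(g0 = 120, loss_ratio = 0.3, seed = 11))
classify_gel(sw$sweep)
#> Gel-state classification: viscoelastic-solid
#>   viscoelastic-solid: 20 points
#>   no crossover
mesh_size_from_modulus(median(sw$sweep$g_prime_pa))[1, ]
#> Theoretical mesh size (cubic-lattice estimate)
#>   T = 310.15 K
#>  G' [Pa] xi [nm]
#>    130.2   32.04

## subdiffusive 200-particle ensemble, tracked at 1 Hz
traj <- gen_trajectories(trajectory_sim_spec(
  n_particles = 200, n_frames = 100, alpha = 0.5, d0 = 0.05,
  dropout_prob = 0.1, seed = 11
))
track_analyze(traj, tracking_config(frame_filter = 10))
#> Particle-tracking summary over 200 particles
#>   median alpha = 0.482 (subdiffusive), median D_eff = 0.05033 um^2/s
#>   MSD(first lag) range [0.1437, 0.2715] um^2; D_eff range [0.03592, 0.06787] um^2/s
#>   transport modes: immobile 0.0%, subdiffusive 100.0%, diffusive 0.0%, active 0.0%

## FRAP recovery of a 20 um bleach spot
fit_recovery(gen_frap_trace(frap_sim_spec(d = 1, w = 10, noise_sd = 0.01, seed = 11)), w = 10)
#> Circular-spot FRAP fit
#>   a0 = 0.1944, a1 = 0.7632, tau = 97.1 s (w = 10 um)
#>   D = w^2/tau = 1.03 um^2/s
#>   residual norm 0.213 over 294 post-bleach samples; converged: TRUE

## Kd from a 12-point twofold dilution series
fit_kd(gen_binding_series(binding_sim_spec(kd = 0.5, noise_sd = 1, seed = 11)))
#> Quadratic binding-isotherm fit
#>   Kd = 0.4918 mg/mL (ligand 0), f_unbound = 799.8, f_bound = 898.9
#>   residual norm 3.01 over 12 points
```

The tracking summary reads: the designed anomalous exponent (0.5) is
recovered as the ensemble median (0.482), every particle falls in the
subdiffusive transport bin, and the median effective diffusivity
matches the designed generalized diffusivity at the 1 s lag. The FRAP
fit recovers the designed D = 1 µm²/s within 3% at 1% noise, and the
Kd fit recovers the designed 0.5 mg/mL within 2%.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mucodiff.R", package = "mucodiff"))')" \
  simulate trajectories --alpha 0.5 --seed 1 --out traj.csv
# subcommands: simulate | rheology | frap | track | pores | mst | report
```

Every artifact is accompanied by a `.provenance.json` sidecar (tool
version, configuration including all seeds, input digests); reruns with
the same configuration and seed are byte-identical.

## Vignette

`vignettes/mucus-barrier-analysis.Rmd` documents the models, their
assumptions, the parameter conventions (units, defaults and why), what
the synthetic generators do and do not emulate, and the numerical
design choices.
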