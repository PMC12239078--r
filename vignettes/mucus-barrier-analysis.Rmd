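---
title: "Methods: quantifying the mucus diffusion barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the mucus diffusion barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mucodiff)
```

Mucus is a viscoelastic hydrogel whose polymer network obstructs the
diffusion of particles and macromolecules. Artificial mucus models are
accepted as mimics only if they reproduce the native barrier across
independent measurement modalities: bulk rheology, the network length
scale, tracer diffusion, and molecular binding. `mucodiff` implements
each of those analyses and the synthetic data needed to validate them.
This vignette documents the models, their assumptions, the parameter
conventions, and the numerical design choices.

## Rheology and the theoretical mesh size

An oscillatory frequency sweep measures the storage modulus G′ (elastic
response) and loss modulus G″ (viscous response). A point with G′ > G″
behaves as a viscoelastic solid; `classify_gel()` labels every
frequency, takes a majority vote for the overall state, and locates
crossovers by linear interpolation of G′ − G″ in log frequency — the
convention by which gel/sol transitions are read off sweeps.
`tan_delta()` returns G″/G′, and `shear_thinning_check()` fits
log₁₀ η against log₁₀ γ̇; a power-law fluid η = k·γ̇^(n−1) yields slope
n − 1, so slope < 0 is shear thinning. A slope within 1e-8 of zero is
treated as constant viscosity (a numerical guard, not a physical
threshold).

The mesh size follows the cubic-lattice thermal-energy scaling

$$\xi = \left(\frac{k_B T}{G'}\right)^{1/3},$$

which assigns one k_B·T of elastic energy per network cell of volume
ξ³. The assumptions are worth keeping in mind: affine rubber
elasticity, a cubic lattice, and G′ taken in the linear viscoelastic
region. `modulus_from_mesh_size()` is the exact inverse, used to ask
whether a microscopy-derived pore size is consistent with the measured
modulus. k_B is the exact SI value 1.380649e-23 J/K; the default
temperature is 310.15 K (37 °C, the physiological measurement
temperature) and always overridable.

**Unit policy.** Moduli are ingested in Pa. Stiff-gel tables often
print MPa; `mesh_size_from_modulus(..., modulus_unit = "MPa")` converts
explicitly, because a silent factor-1e6 error is the dominant failure
mode of this formula (it moves ξ by a factor of 100).

## FRAP

A circular spot of radius w (default 10 µm, i.e. a 20 µm diameter
bleach region) is photobleached and its fluorescence recovery recorded
together with an unbleached reference spot and a background region.
`double_normalize()` corrects the bleach signal for background and for
acquisition photobleaching; the prebleach mean of the normalized curve
is ~1, so amplitudes read as fractions of the prebleach intensity.
Prebleach means are computed over all samples before `t_bleach`; if a
trace has none they must be supplied explicitly.

`fit_recovery()` fits the diffusion-dominated recovery of a uniform
circular spot,

$$F(t) = a_0 + a_1 e^{-x}\left[I_0(x) + I_1(x)\right], \qquad
x = \frac{\tau}{2(t - t_\mathrm{bleach})}, \qquad \tau = \frac{w^2}{D},$$

with I₀, I₁ modified Bessel functions of the first kind. This is the
classic circular-spot solution: writing τ_D = w²/(4D), the argument is
2τ_D/(t − t_bleach), and the tests assert the two parameterizations
agree numerically. The floor a₀ reflects the immobile fraction and
bleach depth; a₀ + a₁ is the recovered plateau.

Numerical choices:

* The product e^(−x)(I₀ + I₁) is evaluated with exponentially scaled
  Bessel functions; the naive product overflows just after the bleach,
  where x is large.
* Starting values are derived deterministically from the curve
  (a₀ ← first post-bleach value, a₁ ← last-decile plateau − a₀,
  τ ← 1.1 × half-recovery time), so fits are reproducible without
  random restarts.
* Box bounds a₀, a₁ ∈ [0, 1.5] and τ ∈ [1e-3 × median Δt, 1e6 s] keep
  the Levenberg–Marquardt search in the physical regime; an estimate at
  a bound, a non-convergent fit, or a negligible recovery amplitude
  (τ then being unidentifiable) is flagged rather than silently
  returned.
* The fit uses samples with t > t_bleach (the bleach frame itself is
  excluded); this is configurable by passing a pre-normalized series.

The trace should cover several recovery times: τ for D = 0.1 µm²/s and
w = 10 µm is 1000 s, so slow tracers need proportionally long traces
(the package's recovery tests use 5τ).

## Particle tracking

Input is a long table `particle, frame, x_um, y_um` with 0-based,
possibly gapped frames — the output format of standard
detection/linking tools (positions in µm; pixel-unit files are
converted with the pixel size, default 0.114 µm at a 182.83 µm frame
width, a typical 1 Hz spinning-disk configuration).

The chain mirrors standard multiple-particle-tracking practice:

1. `truncate_to_analysis_time()` keeps frames with
   t = frame × Δt < AT. Shortening the window to ~10% of the video
   reduces drift- and linking-error accumulation.
2. `apply_frame_filter()` keeps particles detected in ≥ FF frames.
   After truncation to a 10-frame window, FF = 10 retains only
   gap-free-in-window trajectories.
3. `compute_msd()` computes the time-averaged MSD with overlapping
   windows over all frame pairs present; gaps contribute only pairs
   where both frames exist, with no interpolation.
4. `fit_alpha()` regresses log₁₀ MSD on log₁₀ τ over the short-lag
   window: lags up to `msd_fit_fraction` (default 0.10) of the maximum
   available lag, never fewer than 2 lag points. The slope is α, the
   intercept gives D₀ = 10^intercept/4, and D_eff = MSD(Δt)/(4Δt) is
   attached from the first lag (n = 2 dimensions).
5. `classify_transport()` bins α into immobile [0, 0.2), subdiffusive
   [0.2, 0.9), diffusive [0.9, 1.2), active [1.2, ∞). The printed
   conventions leave measure-zero gaps between bins (0.199/0.2 etc.);
   contiguous left-closed bins assign every finite α
   deterministically. Negative estimates — a finite-sample artifact of
   flat MSD curves — clamp to immobile with a flag.
6. `transport_mode_ratios()` reports percentages over retained
   particles (summing to 100); active-transport particles can be
   excluded first, as is common when drift cannot be ruled out.

Ensemble summaries use medians throughout: single-particle D_eff
distributions in gels are heavy-tailed, and the median is the robust
location estimate.

**Short windows and the ensemble class.** A 10-frame window gives at
most 9 displacement pairs per lag, so the per-particle α estimate has
an irreducible spread of roughly ±0.4–0.5. Because the subdiffusive bin
(width 0.7) is 3.5× wider than the diffusive bin (width 0.3), a
Brownian ensemble analyzed in 10-frame windows shows a subdiffusive
per-particle plurality even when the ensemble median is 1.0 — a
bin-geometry effect, not a property of the sample. `track_analyze()`
therefore also reports `ensemble_class`, the transport class of the
ensemble median α, which is the statistically meaningful statement
about the typical particle at short analysis times. For the same
reason, pure-localization-noise (immobile) samples are only reliably
recognized per particle on long windows: over 100 frames the flat MSD
pins per-particle α near 0, while over 10 frames it is
indistinguishable from weak subdiffusion.

`stokes_einstein_dw()` supplies the free-diffusion reference
D_w = k_B·T/(6πηr); water at 37 °C (η = 6.9e-4 Pa·s) is the default
medium, and `dw_deff_ratio()` quantifies hindrance.

## Pore morphometry

Cryo-SEM pores image dark against the sputter-coated network.
`binarize()` applies a fixed, inclusive intensity band [0, 75] of the
8-bit range to all images alike — fidelity to fixed-threshold particle
analysis; adaptive thresholds would break comparability across images,
so they are deliberately not offered (the band itself is a parameter).
Non-8-bit input is rejected rather than rescaled implicitly, because a
fixed threshold only means something on a fixed intensity scale.

`label_pores()` extracts 8-connected components (diagonal contact
joins, the particle-analyzer convention), converts areas with the pixel
scale (nm/px, supplied as metadata — never inferred from a scalebar
graphic), drops components below an area of `min_size`² (the noise
floor, default 0.1 nm, interpreted as an area-equivalent minimum), and
flags border-touching pores (retained by default). The circularity
filter [0, 1] admits every shape and exists as an explicit
pass-through. Feret diameters are measured on the convex hull of the
pixel *corner* points, so a single pixel has Feret min = scale and
Feret max = √2 × scale; Feret max is the hull diameter and Feret min
the smallest edge-perpendicular width (rotating calipers). Rasterized
shapes carry a ±2 px error budget against analytic ground truth.

`compare_feret_max_min()` runs the paired Wilcoxon signed-rank test on
(Feret max, Feret min) per pore — a significant difference indicates
elongated pores. `cross_validate_pore_size()` compares pore/mesh-size
samples across methods (theoretical from G′, binarization, optionally
manual measurements read from a hand-measured table) with the
Kruskal–Wallis test; agreement at the chosen significance level
supports the measured network length scale.

## Binding isotherm

Thermophoresis-style titrations record a normalized fluorescence
response against a serial dilution of the target
(`serial_dilution()`: cᵢ = c_max/fᵢ). The module is agnostic about
whether the response is initial fluorescence or a thermophoresis-trace
ratio — any monotone concentration–response series fits. Because the
vendor software's model equation is not published, the package fits the
standard law-of-mass-action isotherm with ligand depletion
(`binding_isotherm()`):

$$FB = \frac{(L + T + K_d) - \sqrt{(L + T + K_d)^2 - 4LT}}{2L},$$

evaluated in the stable form 2T/(S + √(S² − 4LT)), which is exact as
L → 0 (reducing to T/(T + K_d)). Mixed units are fitted as-is: with a
micromolar dye ligand titrated by mg/mL of mucin, K_d is reported in
the target's mass-concentration units. The baseline direction (binding
raising or lowering the response) is fitted, not assumed.

`fit_kd()` profiles K_d on a log₁₀ scale across the measured
concentration range ±3 decades: for each candidate K_d the optimal
(f_unbound, f_bound) are a linear regression on the bound fraction, and
the 1-D profile is minimized by golden-section search — deterministic,
derivative-free, and immune to amplitude/baseline trade-off
instability. Flat series are flagged non-identifiable; a K_d at the
search bound is flagged.

## Rank statistics

`kruskal_wallis()` computes the tie-corrected H and, for total n ≤ 10,
an exact permutation p-value by enumerating all assignments of the
observed ranks to the group sizes; larger samples use the χ²
approximation (df = k − 1). The exact enumeration is validated against
the published critical value for group sizes (3, 3, 4). Note the χ²
approximation at n = 10 deviates from the exact p by up to ~0.07 in
mid-range p values; near the 0.05 decision region the two agree within
0.02. `wilcoxon_signed_rank()` drops zero differences (Wilcoxon's
original treatment), average-ranks ties, uses the exact signed-rank
null distribution for n ≤ 25 without ties, and otherwise a
tie-corrected normal approximation with continuity correction. No
multiple-comparison correction is applied by default (omnibus tests are
reported unadjusted); `p.adjust` composes externally when needed.

`build_summary()` assembles per-matrix rows (MSD and D_eff ranges,
transport ratios, pore medians, gel class, K_d) with `NA` for stages
not run — columns are traceable to module outputs, never fabricated.

## Synthetic data: what it emulates, and what it does not

All generators are seeded and byte-reproducible; identical spec + seed
gives identical output, and the caller's RNG state is untouched.

* `gen_trajectories()` draws mobile particles from fractional Brownian
  motion with Hurst index α/2, synthesized by multiplying standard
  normals with the Cholesky factor of the fractional-Gaussian-noise
  increment covariance — exact to the target
  E[Δr²(τ)] = 4·D₀·τ^α at every lag, with one factorization shared
  across the ensemble (O(m³) once, m = frames − 1). Localization noise
  (default sd 0.02 µm, a typical centroid precision; the tracking
  literature rarely states it, so this is a package default, not a
  measured value) is added to positions, as centroid trackers report.
  Dropout removes frames independently; immobile particles are pure
  noise about a fixed point. Not emulated: binding-mediated
  immobilization kinetics, mode switching within a trajectory, drift,
  or boundary effects — transport-mode mixtures are composed from
  `immobile_fraction` and α choices.
* `gen_frap_trace()` follows the circular-spot model exactly after the
  bleach, with acquisition decay on the bleach and reference channels
  and Gaussian noise on all three. It does not simulate diffusion
  during the bleach, anomalous-diffusion recovery, or ROI geometry.
* `gen_pore_image()` places non-overlapping ellipses (rejection
  sampling, bounded retries) with intensity bands on either side of the
  pore threshold, and records analytic Feret ground truth (2a, 2b for
  semi-axes a ≥ b). Real micrograph texture, charging and sublimation
  artifacts are out of scope — passing the round trip shows the
  geometry pipeline is correct, not that thresholding real images at
  [0, 75] is optimal.
* `gen_rheology_sweep()` and `gen_binding_series()` produce power-law
  sweeps/flow curves and quadratic-isotherm series with the stated
  noise models.

Consequently, green tests demonstrate estimator correctness under the
models' own assumptions; they do not validate those assumptions on
real instrument data.

## Problem sizes and reproducibility

The validation suite uses ensembles of 500 particles × 100 frames for
exponent-recovery studies (designs α ∈ {0.3, 0.5, 1.0} with 10%
dropout, analysis time 10 s, frame filter 10), 20-seed repetitions for
FRAP (D ∈ {0.1, 1, 10} µm²/s at 1% noise) and K_d (12-point twofold
series at 1% noise) recovery, 50 random gapped trajectories against
the brute-force MSD oracle, and 30 random convex blobs against a
0.05°-grid projection oracle for Feret diameters — sizes at which the
recovery distributions are stable while the whole suite runs in about
a minute. `scripts/acceptance.R` recomputes all of it from one seed.

## Known limitations

* The mesh-size formula is a scaling estimate; its cubic-lattice
  prefactor is not calibrated to a specific polymer architecture.
* The FRAP model assumes a uniform circular bleach profile and pure
  diffusion; reaction-dominated or anomalous recovery will bias D.
* α classification bins are conventional, and near-boundary estimates
  are assigned deterministically but remain estimates with
  finite-sample spread (see the short-window discussion above).
* The minimum-width Feret of a rasterized shape is only defined up to
  the pixelation of the outline; sub-pixel agreement with analytic
  shapes should not be expected.
* K_d from mass-concentration titrations of a heterogeneous mucin
  mixture is an effective, not a molecular, constant; its unit follows
  the titration axis.
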