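---
title: "Modelling a linac photon phase space with a single virtual source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a linac photon phase space with a single virtual source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmbeam)
```

## The modelling problem

A phase-space file (PSF) scored on a plane below a linac head records, per
particle, the species, kinetic energy, position and direction cosines.
`vsmbeam` condenses such a file into a generative model — a virtual source
located exactly on the scoring plane — whose samples are statistically
exchangeable with the file's particles.  The model is *single-source*: no
sub-sources at the target, flattening filter or collimators, and therefore
no geometric information beyond the plane itself.

Four conditional factors make up the model, mirroring how the variables
depend on one another: position (rotationally symmetric), energy given
radius, direction given position and energy, and species.  This vignette
documents the estimation choices behind each factor, the sampling chain,
and what the accompanying tests do and do not establish.

## Inverse-CDF splines (position and energy)

The radial density is histogrammed at 0.1 mm, integrated, and inverted;
the inverse CDF is least-squares fitted with a B-spline of polynomial
order 4 over 30 segments, and each energy spectrum likewise with order 5
over 12 segments.  Two numerical choices matter:

* **Knot placement.**  Interior knots are placed at equal arclength along
  the normalised quantile curve rather than equally spaced in probability.
  A flattened beam concentrates most probability in a slowly varying core
  while the quantile function bends sharply at the field shoulder and
  again along the sparse scatter tail; equal-probability knots starve
  exactly those bends.  Arclength placement cut the closed-loop radial KS
  distance roughly sixfold at 10⁶ particles.
* **Monotonicity.**  The fitted spline is evaluated on a dense grid
  (2001 points) and projected onto nondecreasing values; evaluation then
  interpolates that grid.  Degenerate inputs (a point-like or
  single-valued distribution, or a bin with fewer distinct values than
  basis functions) skip the spline and invert the empirical CDF directly.

Energy spectra are binned in 35 radial intervals — 25 × 2 mm to 50 mm,
9 × 5 mm to 95 mm, one open bin beyond — and under-populated bins
(fewer than 100 particles by default) borrow the nearest populated bin's
spectrum with a warning.

## Direction statistics and surfaces

Per 1 mm² bin of a 141 × 141 grid (extent ±70.5 mm, photons only) the
builder computes the mean direction cosines, their sample standard
deviation and standard error, and three Pearson correlations (energy vs
each lateral cosine, and between the lateral cosines).  Seven weighted
polynomial surfaces summarise these maps; weighted least squares with
inverse-variance weights `1/se²` counters the strong heteroscedasticity
between core bins (thousands of photons) and rim bins (a handful).

The *spread ambiguity*: one reading of the per-bin dispersion statistic
makes it the standard error of the mean, which is also reused as the
sampling spread of individual photons.  Using the standard error as the
spread would collapse the beam's angular width as the bin occupancy grows,
which contradicts the observed dose agreement of such models.  The builder
therefore stores both: the sample standard deviation feeds the spread
surfaces (`sigma_mode = "sd"`, default), the standard error feeds the fit
weights; `sigma_mode = "se"` reproduces the literal reading.

The mean-cosine surfaces are piecewise: a linear surface `{1, k, k'}`
inside the primary region and a restricted cubic
`{1, k, k', k², kk', k³, k²k'}` outside.  The primary region is the set of
bins holding at least 20% of the maximum bin count, and the boundary
radius `T` is the largest circle about the axis containing only primary
bins.  With moderate counts, Poisson speckle biases this rule twice: the
observed maximum overshoots the fluence plateau (pulling the threshold
up), and single down-fluctuated bins puncture the region (pulling `T`
in).  Both are pure small-sample artefacts, so the rule is applied to a
3 × 3 box-smoothed count map by default (`smooth = 1`); on a
well-populated grid the plateau is flat on that scale and the smoothed and
raw rules coincide.  At 10⁶ particles the smoothed rule lands within
about half a millimetre of the asymptotic boundary where the raw rule
loses two millimetres.

Spread and correlation surfaces are single full-plane polynomials of
total degree 4, 3 and 5 respectively (degrees chosen for the three
statistics by adjusted R², which the builder records per fit).  The
cross-correlation surface, which has no variance of its own, is weighted
by `1/(se_x·se_y)`.  Correlation evaluations are clamped to [−1, 1] and
spreads to ≥ 0.  Bins with fewer than 10 photons, zero variance, or
undefined correlations are excluded from all fits.

## The correlated sampling chain

Energy and direction are coupled through their generating uniforms: `U₄`
(the quantile of the direction deviation) is correlated to `U₃` (the
energy quantile) with the sum-of-uniforms construction
`U₄ = F_s(U₃ + c·V)`, where `F_s` is the exact trapezoidal CDF of the sum
— so `U₄` is exactly uniform by the probability-integral transform, for
every `c`.  The map from `c` to the realised correlation is tabulated by
Monte Carlo (10⁶ pairs per point, c = 0, 0.2, …, 10) and inverted by
monotone interpolation.  Negative correlations use the reflection
`1 − U₄`.

Three refinements keep the closed loop quantitatively honest:

* **Correlation scale.**  The surfaces prescribe `corr(e, v)`, but the
  chain operates on transformed variables: the deviation is
  `N = √2·erfinv(2U₄ − 1)` and the energy is `E⁻¹(U₃)`.  To first order
  the realised correlation is the *normal-score* coupling of the SOU pair
  attenuated by `λ_h = cor(E_h⁻¹(U), qnorm(U))`, a property of the bin's
  spectrum computed at build time.  The calibration therefore tabulates
  the normal-score coupling alongside the uniform-scale one, and the
  sampler requests `|ρ|/λ_h` on that scale.  Without this, realised
  energy–direction correlations overshoot their targets by roughly 20%.
* **Weak couplings.**  Couplings below what c = 10 can produce are
  realised exactly by mixing the weakest chain with independent draws in
  the proportion that yields the requested correlation, instead of
  rounding them down to independence.
* **Lateral mix.**  `N_Ux ← ρᵛ·N_Uy + √(1 − ρᵛ²)·N_Ux` correlates the two
  deviations, but both arrive already correlated through the shared `U₃`
  (by the product of their normal-score couplings, `m`).  Mixing with the
  raw `ρᵛ` double-counts `m`; the sampler solves
  `a + √(1 − a²)·m = ρᵛ` for the mix coefficient instead
  (`compensate_rho_v = FALSE` restores the literal one-sided mix).

The `√2` in the deviate is deliberate: `erfinv` alone maps a uniform to a
normal of variance ½, so scaling by `√2` makes `ε = N·σ` reproduce the
fitted spread exactly (`use_sqrt2 = FALSE` disables it for comparison
with implementations that omit the factor).

Directions are completed with `vz = +√(1 − vx² − vy²)`.  Draws that would
leave the unit sphere are redrawn (up to 100 attempts) and then clamped by
renormalisation; for realistic spread maps this path triggers on far less
than 0.1% of particles and the counts are attached to the output.

Particle type is an independent Bernoulli draw from the stored photon
fraction; positrons, which the reader accepts, are counted with electrons.
Electrons are sampled through the same position/energy/direction machinery
— the single-source philosophy — differing only in label.

## The synthetic beam and what the tests show

The generator emulates a flattened 6 MV beam scored 160 mm below a
point-like focus: positions from a super-Gaussian core
(`exp(−(r/40.50)⁸)`, calibrated together with a 1.7% uniform halo of
radius 150 mm so that the 20%-of-maximum fluence radius sits at 43 mm and
encloses 95.62% of the photons asymptotically), energies from a gamma
spectrum (shape 1.6, mean 1.75 MeV on axis, softening by 0.3% per mm off
axis, floored at 25%), directions along the focal ray with correlated
Gaussian cosine noise (σ = 0.005), and 0.7% electron contamination with
three times the angular noise and a softer spectrum.  The
energy–direction correlation is injected by shrinking the transverse ray
component as the energy quantile rises — high-energy photons diverge less
— with the coupling solved analytically so the bin-level correlation
reaches 0.3 at 40 mm off axis.  All of these fields are returned in
closed form by `synthetic_ground_truth()`.

Two statistical facts shape how recovery is scored at 10⁶ particles:

* 1 mm² bins hold at most a few hundred photons, so per-bin correlation
  estimates carry standard errors of order 0.07 — larger than the
  tolerance being checked.  Spread and correlation recovery is therefore
  scored on 10 mm blocks holding at least 5 × 10³ photons per side, and on
  *residuals* about the fitted mean-cosine field, since the field's
  variation across a block would otherwise masquerade as noise
  correlation (`direction_residual_stats()`).
* Similarly, energy-spectrum KS distances are computed per radial *group*
  of the 35 bins, pooled until each group holds at least 2 × 10⁴
  particles on both sides.

With those estimators, the acceptance suite at 10⁶ build / 10⁶ generate
verifies: radial KS < 0.01, pooled energy KS < 0.02 per group, per-bin
mean cosines within 0.005 (bins with ≥ 100 photons), residual spreads
within 10%, residual correlations within 0.07, species fractions within
binomial noise, and the primary-region statistics within 1.5 mm / 1.5
percentage points of the asymptotic design values (the residual bias of
the smoothed threshold rule at this density).

What passing does **not** show: the generator is rotationally symmetric
by construction, its spectra are smooth gamma families rather than real
bremsstrahlung spectra with characteristic lines, its halo is uniform
rather than collimator-structured, and its correlations are stationary on
the 10 mm scale.  Recovery of this beam demonstrates the estimation and
sampling machinery, not fidelity to any particular accelerator; a real
PSF remains the input of record for commissioning work.

## Gamma analysis

The gamma index combines dose difference (normalised to `dose_pct`% of
the global reference maximum by default, per-pixel with
`global_norm = FALSE`) and distance-to-agreement: per reference pixel at
or above the 10% low-dose threshold, the evaluated plane — bilinearly
upsampled to a step of at most 0.1 × DTA — is searched within a radius of
3 × DTA for the minimising combination.  Evaluation is one-sided
(reference against evaluated), as in standard practice.  On constructed
64 × 64 planes the implementation agrees with an exhaustive brute-force
search to within 0.01 in gamma; identical planes pass at 100%, a 0.5 mm
shift passes a 1 mm DTA everywhere, and a 10% rescale of a flat plane
fails a 3% criterion everywhere, pinning both terms of the metric.

Dose planes are *consumed*, never computed: the five square-field
surrogate pairs (`make_synthetic_dose_planes()`) are analytic flattened
fields with error-function penumbrae, Monte-Carlo-like multiplicative
noise (0.4%), a 1% calibration offset and a 0.3 mm shift between the
pair — perturbations sized like those between two independent dose
calculations of the same beam.  They exercise the engine at commissioning
scale (every field passes ≥ 95% at 3%/1 mm, and 3%/2 mm is never
stricter); they are stand-ins, not dose calculations.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| Radial histogram bin | 0.1 mm | resolves the fluence shoulder |
| Radial spline | 30 segments, order 4 | matches the quantile curve's complexity |
| Energy splines | 12 segments, order 5, 35 bins | per-bin spectra are smooth |
| Direction grid | 141 × 141 × 1 mm² | 1 mm² bins over ±70.5 mm |
| Primary threshold | 20% of smoothed max | separates plateau from scatter |
| SOU calibration | c ∈ [0, 10] step 0.2, n = 10⁶ | correlation noise ≈ 0.001 |
| Closed-loop checks | 10⁶ build / 10⁶ generate | per-bin and per-block SEs below the tolerances |

The full test suite runs in under two minutes on one CPU; the acceptance
script in about one.

## Known limitations

Direction surfaces extrapolate polynomially outside the ±70.5 mm grid;
positions beyond it inherit the secondary-region branch.  The grid size is
fixed rather than adaptive.  The SOU floor (c = 10) bounds how weak a
correlation the pure chain can express; the mixture construction covers
the remainder exactly but adds one Bernoulli draw per particle.  Gamma
analysis is 2D only, with no DVH or 3D extension.
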