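---
title: "Models and methods: ssDNA elasticity and secondary structure from pulling curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ssDNA elasticity and secondary structure from pulling curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltfec)
```

## The measurement and its processing

A constant-velocity optical-tweezers pull records force `f` and
trap–pipette distance `x_d` while a single ssDNA tether is stretched. In
the force range of interest the trap is harmonic, so the molecular
extension is

```
x = x_d − f / k
```

with `k` the trap stiffness (0.07 pN/nm by default; a config constant,
not something this package estimates). `fdc_to_fec()` applies this
per-sample; `fec_to_fdc()` inverts it exactly.

Raw traces are acquired at 200 Hz and carry instrument noise that is
well approximated as white on these timescales. `bandwidth_filter()`
reduces them to the analysis bandwidth (2 Hz by default) by
non-overlapping boxcar averaging — the simplest reduction consistent
with quoting a bandwidth, chosen over IIR alternatives (e.g. Bessel)
because it has an exactly known gain on white noise (`sqrt` of the block
size) and keeps samples statistically independent. The trade-off is a
boxcar's imperfect stop-band; for monotone quasi-static ramps this is
immaterial.

Units are fixed package-wide: pN, nm, pN·nm, mM, with
`k_BT = 4.114 pN nm` at 298.15 K (experiments are at 25 °C) scaled
linearly in temperature.

## Elasticity models

Four force–extension relations are implemented behind one generic pair,
`model_extension()` / `model_force()`:

**Inextensible WLC (Marko–Siggia).**
`f = (k_BT/L_p) [ 1/(4(1−z)²) − 1/4 + z ]`, `z = x/L_c`. The inverse
(extension at force) has no closed form; it is computed by 60 steps of
vectorised bisection on `z ∈ [0, 1)` plus three Newton polishing steps —
the function is strictly increasing and convex near `z = 1`, so the
bracket never fails and the round-trip error is at the 1e-12 level.

**Extensible WLC.** The enthalpic correction enters multiplicatively,
`x = x_WLC(f) · (1 + f/K)`. This is the common convention for adding a
stretch modulus to the Marko–Siggia form and reduces to the
inextensible model as `K → ∞`.

**Extensible FJC.**
`x = L_c [ coth(b) − 1/b ] (1 + f/K)` with `b = f L_K / k_BT`. For
`b < 1e-4` the Langevin function is evaluated by its series
`b/3 − b³/45` to avoid catastrophic cancellation.

**Thick chain (TC).** At low salt (≤ 50 mM monovalent) the Debye length
exceeds the persistence length and the filament behaves as a
self-avoiding tube: the FEC falls *below* the WLC at low force. We model
this as a discrete chain of bonds of length `l` whose local radius of
curvature is bounded below by the tube radius `Δ`: three consecutive
beads must fit on a circle of radius ≥ `Δ`, restricting the turning
angle `γ` between successive bonds to `sin(γ/2) ≤ l/(2Δ)`. Under
tension each bond carries the weight `exp(f l cosθ / k_BT)`; the mean
relative extension of the infinite chain is `⟨cosθ⟩` under the dominant
eigenfunction of the azimuthally reduced transfer operator. We solve
this exactly by Gauss–Legendre quadrature in `cosθ` (48 nodes) and
power iteration warm-started along the force grid. Design points:

* when `Δ ≤ l/2` the constraint is inactive and the model collapses
  *exactly* to the discrete FJC of segment `l` (Langevin function) —
  the natural thin-chain limit;
* `Δ` and `l` shape the force dependence independently (`l` sets the
  force scale `f l/k_BT`, `Δ/l` the angular restriction), so a
  three-parameter fit `(Δ, l, L_c)` is identifiable — verified by
  noiseless and noisy round trips;
* non-local excluded volume (distant-segment collisions) is not
  modelled; at stretching forces ≥ 0.5 pN local curvature dominates.
  An optional intrinsic bending stiffness (`Lp_local`) can be added to
  the kernel but defaults to zero: all stiffness from thickness.

The published thick-chain literature offers several approximants; the
pipeline is agnostic — any relation exposed through
`model_extension()` can be fitted — and this tube-constrained discrete
chain is the package's documented choice.

**Debye length.** `debye_length()` uses
`λ = sqrt(ε_r ε_0 k_BT / (2 N_A e² I))` with `ε_r = 78.3` (water,
25 °C) and ionic strength `I = c_eff` for 1:1 salt and `3c + offset`
for 2:1 salt. It is a diagnostic utility, not part of any fit.

## Fitting conventions

`fit_model()` minimises **squared force residuals at the measured
extensions**. Force is the directly measured quantity (extension is
derived through the trap correction), and on the steep elastic branch
force residuals weight the informative high-force region sensibly.
Models natively supply `x(f)`; the residual builder inverts them — the
WLC in closed form, the extensible models by monotone bisection, the
thick chain through a 60-point log-spaced force-grid interpolant
(rebuilt per parameter evaluation; the transfer operator is too costly
to invert per sample). Optimisation is Levenberg–Marquardt
(`minpack.lm::nls.lm`) with positivity bounds, `ftol = ptol = 1e-12`.

Default window 10–40 pN, endpoints inclusive: below ~10 pN secondary
structure (high salt) or excluded volume (low salt) contaminates the
elastic response; the thick-chain fit instead uses the whole measured
range (0.5–40 pN), which is where its physics lives. Initial guesses —
`L_p = 1` nm, `L_c = 1.05 ×` max extension, `L_K = 1.5` nm,
`K = 700` pN, `(Δ, l) = (0.8, 1.3)` nm — sit in the physically expected
ranges for ssDNA and are not data-dependent beyond the extension scale.

Two dispersions are reported and must not be conflated: per-fit standard
errors from the linearised covariance `(JᵀJ)⁻¹s²` (within-curve,
noise-driven) and, via `aggregate_fits()`, the molecule-to-molecule
standard deviation over replicate curves, which is what per-condition
tables quote and is typically an order of magnitude larger.

Fixing versus freeing parameters: `fixed = list(Lc = 7857)` pins the
Ex-FJC contour length to the crystallographic value
(0.5756 nm/base × 13650 bases); with the contour length free the
inextensible WLC describes 10–40 pN data adequately, and refitting such
data with the extensible WLC drives `K` to effective inextensibility,
moving `L_p` by < 3% and `L_c` by < 1%. The converse is *not* true —
data generated with a genuine `K ≈ 700` pN and fitted inextensibly
shifts `L_p` by ~20% — so the near-agreement of the two fits is
evidence the data are WLC-consistent, not a general identity.

## Secondary-structure quantification

Below ~10 pN, transient base pairing sequesters part of the chain and
the FEC develops a shoulder. The analysis inverts that logic:

1. fix `L_p` from the 10–40 pN fit;
2. at each force on a grid (0.5–10 pN, 0.25 pN steps) interpolate the
   measured extension from the 2 Hz-filtered FEC (linear interpolation
   on force-sorted samples, ties averaged) and compute
   `L̃_c(f) = x(f) / z_WLC(f; L_p)`;
3. the unpaired fraction is `n(f) = L̃_c(f) / L_c`, with `L_c` from the
   high-force fit.

`n > 1` is impossible under a paired/unpaired partition; it occurs at
low salt, where excluded volume stiffens the chain beyond the WLC.
Such points are flagged, retained for inspection, and excluded from
sigmoid fitting.

The melting transition is summarised by the logistic

```
n(f) = x0 + (1 − x0) / (1 + exp(−(f − fc)/δ))
```

with the exact midpoint property `n(fc) = (1 + x0)/2`. One honest
caveat: `x0` equals the zero-force fraction only in the sharp-transition
limit `fc ≫ δ`; for broad low-salt transitions (`fc < δ`) the literal
`n(0)` exceeds `x0` appreciably (by ~0.25 for the broadest published
parameter set). The fit is bounded (`x0 ∈ [0,1]`, `δ ≥ 0.05` pN,
`fc ∈ [0,20]` pN), unweighted, and refuses monotonically decreasing
input as unphysical. Above a salt-dependent critical concentration
(65 mM monovalent, 0 divalent), `x0` follows the power law
`x0 = scale·(c − c*)^(−γ)`, fitted as an OLS line in log–log space.

## Salt scaling

The persistence length decomposes as
`L_p(c) = L_p(0) + A · c_eff^(−ν/2)`. Conventions that matter:

* `c_eff` adds the 9 mM monovalent buffer background to nominal NaCl
  concentrations; divalent concentrations are used as-is (monovalent
  competition is negligible in the studied range);
* concentrations enter in **mM** — the amplitude `A` is only meaningful
  under a stated unit convention;
* `ν = 1` (electrostatic term proportional to the Debye length) is an
  unweighted OLS line in `c_eff^{-1/2}`; the free-ν fit is
  Levenberg–Marquardt with all three parameters free, unweighted.

The divalent/monovalent equivalence factor is the scale `s` minimising
the squared distance between the divalent points evaluated at `s·c` and
the fitted monovalent line (1-D minimisation in `log10 s`); the analytic
estimate `(A_mono/A_div)²` is reported alongside. With the packaged
tables both land at order 100. `kuhn_trend()` fits `L_K` against
`log10 c_eff` and, when a matching `L_p` series is given, reports the
semiflexible-correspondence ratios `L_K/(2L_p)` (≈ 0.8–0.9 here).

## The synthetic generator

`generate_fec()` emulates the experiment's statistical structure, not
its microscopic physics:

* **Kinematics.** The trap retracts at 30 nm/s; the trap+molecule series
  compliance maps trap motion to a force ramp, discretised quasi-
  statically (no bead Langevin dynamics) and sampled at 200 Hz.
* **Elasticity.** Extension at each sampled force is the exact model
  value (dense-grid monotone spline only for the thick chain).
* **Secondary structure** enters as a force-dependent contour length
  `L_c · n(f)` with `n` the logistic above — deliberately the exact
  inverse of the analysis assumption, so the extraction procedure is
  exactly identifiable and directly testable. This makes no claim to
  a mechanistic hairpin model; it cannot test whether the sigmoid is
  the *right* description of real condensed-phase ssDNA, only that the
  pipeline recovers whatever sigmoid generated the data.
* **Noise.** Gaussian force noise, sd 0.5 pN at 200 Hz (a typical
  instrument magnitude; configurable), seeded; the global RNG state is
  saved and restored, so generation is pure given the seed.

Not emulated: the unzipping sawtooth (sequence-dependent), instrument
drift, bead-geometry artefacts, hysteresis of the condensed phase.
Passing recovery tests therefore demonstrates correctness of the
analysis chain under its own assumptions, not robustness to every
instrumental pathology of real data.

## Numerical choices and degenerate inputs

* WLC inversion: bisection + Newton to ~1e-12 relative; all model
  round trips are tested below 1e-8 relative error over 0.1–40 pN.
* Thick chain: 48 Gauss–Legendre nodes resolve the kernel up to
  `f l/k_BT ≈ 13` (40 pN at `l = 1.32` nm); power iteration to 1e-13
  with warm starts along the force grid.
* Fits reject: non-FEC input, fewer than 10 windowed samples, constant
  force (degenerate), fewer points than free parameters + 1. Windowing
  with no samples raises an explicit "no data in window" error.
* Fraction curves: grid forces outside the measured range are skipped
  with a warning; zero force is excluded (relative extension vanishes).
* Report/curve I/O is plain delimited text with a JSON sidecar — there
  is no de-facto binary standard for tweezers traces, and text keeps
  fixtures reviewable.

## Problem sizes

The shipped tests validate on full-size molecules (13650 bases,
~50 000-sample traces) for the headline recovery checks and on shorter
synthetic constructs (hundreds of nm) for replicate and property
suites; the complete suite runs in about a minute on one core. The
acceptance script uses full-size traces for every recovery target.

## Known limitations

* The thick-chain form is one defensible member of a family of
  published approximants; fitted `Δ` values are comparable across
  studies only when the functional form is stated alongside.
* The sigmoid `x0` is a fit parameter, not literally `n(0)`, for broad
  transitions (see above).
* The effective-contour-length procedure inherits the WLC's validity
  range: below ~50 mM monovalent salt it produces flagged `n > 1`
  values by construction and the sigmoid analysis is not applicable.
* Goodness-of-fit is reported as unweighted R² / residual RMS;
  measurement-error-weighted alternatives are not implemented.
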