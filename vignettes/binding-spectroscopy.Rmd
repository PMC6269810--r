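---
title: "Methods: fluorescence-based protein–ligand binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence-based protein-ligand binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

`specbind` analyses steady-state fluorescence titrations of a protein
with a quenching ligand. This vignette records the models the package
implements, the assumptions behind them, the defaults and units of
every tunable parameter, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
underlying methodology leaves room.

## Quenching models

The titration container (`titration_series()`) always starts with the
quencher-free reference point, which defines `F0`; all fits reduce each
spectrum to one intensity by a configurable readout — the band peak
(default) or the intensity at a fixed wavelength. Intensities should be
corrected for inner-filter attenuation and titrant dilution first;
`correct_inner_filter()` uses the standard half-absorbance form
`F·10^((A_ex+A_em)/2)` (the literature rarely states which variant was
used for any given dataset, and this one is the common default) and
`correct_dilution()` rescales by `(v0 + v_added)/v0`. Both are
multiplicative, hence commute.

**Stern–Volmer.** `F0/F = 1 + Ksv[Q]` forces an intercept of 1, so
`stern_volmer_fit()` estimates `Ksv` by least squares with the
intercept pinned (`Ksv = Σ(y−1)q / Σq²`). The unconstrained regression's
intercept and correlation coefficient are reported separately as
linearity diagnostics — conflating the two would silently absorb
curvature into the intercept. `kq = Ksv/τ0` uses the conventional
biopolymer lifetime `τ0 = 1e-8 s` (overridable). Mechanism
classification is a strict comparison of `kq` (in M⁻¹s⁻¹) against the
diffusion-collision ceiling of `2e10 M⁻¹s⁻¹`: above it, collisional
(dynamic) quenching cannot account for the rate and the call is
`"static"`; at or below it the conservative call is
`"dynamic_possible"` — a boundary value does not prove a static
mechanism. Because titration grids are commonly recorded in mM while
rate constants are reported in M⁻¹s⁻¹, every fit carries its
concentration unit and `classify_mechanism()` refuses non-molar input
rather than guessing (`per_conc_to_per_molar()` makes the conversion
explicit).

**Two regimes.** Modified Stern–Volmer plots of some systems show two
linear stretches, interpreted as two binding-site classes of different
affinity. No standard prescription exists for partitioning the points,
so both `stern_volmer_fit()` and `modified_stern_volmer_fit()` take a
`two_regime` flag and search every contiguous split of the
concentration-ordered points with at least 3 per side, scoring each by
the total squared residual of the two per-side fits and returning the
minimiser. On genuinely two-regime data this beats the single-line fit
strictly; the boundary concentration is reported so the partition is
reproducible.

**Modified Stern–Volmer.** The regression of `F0/(F0−F)` on `1/[Q]`
yields `fa = 1/intercept` and `ka = intercept/slope`. Accessible
fractions above 1 (or nonpositive intercepts) are physically
impossible but do occur in fitted tables; the package returns the raw
parameters with an `unphysical` flag instead of clamping, because a
clamped value would hide the diagnostic signal that the model is
misspecified for the data.

**Double-log.** `log10((F0−F)/F)` on `log10[Q]` gives the binding-site
exponent `n` (slope) and `log10 KA` (intercept). Points with `F = F0`
have no defined ordinate and are dropped with a warning; for a simple
Stern–Volmer law this fit returns `n = 1` and `KA = Ksv` exactly, a
cross-check wired into the test suite.

## Conformation metrics

**REES.** `rees()` differences the emission maxima under 305 nm and
295 nm excitation. Peak positions come from `emission_maximum()`:
3-point parabolic interpolation through the maximal sample and its
neighbours, because integer-nm grids cannot otherwise resolve the ≤3 nm
shifts of interest. Exact intensity ties return the lowest tied
wavelength without interpolation, and a maximum on the grid boundary is
returned flagged rather than extrapolated. `mode = "table"` rounds each
maximum to integer nm *before* differencing, matching how REES tables
are conventionally reported; raw mode keeps sub-nm precision.

**Synchronous slopes.** For scans at fixed offset Δλ = 15 nm (tyrosine)
or 60 nm (tryptophan), `synchronous_slope()` fits a straight line of
`F/F0` against `[Q]`. Real curves may bend; curvature is deliberately
not modelled and is surfaced as the residual RMS, so a user can judge
whether the slope comparison (|slope₆₀| vs |slope₁₅|, which residue
class dominates the quenching) is meaningful.

**CD bookkeeping.** `mean_residue_ellipticity()` implements
`[θ] = 100·θ_obs/(c·l)` with `c` in mol residue cm⁻³ and `l` in cm.
Secondary-structure fractions are *inputs* (from external deconvolution
software), not computed here; `cd_record()` enforces that the six
classes sum to 100 ± 0.5%, and `structure_delta()` reports per-class
changes plus whether they follow the destabilisation pattern (helix and
sheet down, unordered up).

## RLS aggregation onset

The critical induced aggregation concentration is usually read off a
scattering-versus-concentration plot by eye. For reproducibility,
`detect_cciac()` fits a continuous flat-then-linear hinge
(`I = b + m·max(0, [Q]−c)`) by exhaustive search over candidate knots
at and between the observed concentrations, followed by local
optimisation inside the best candidate's bracket with a tolerance
scaled to the bracket width (concentrations can be ~1e-7, so a fixed
absolute tolerance would be useless). The hinge is accepted only if it
beats the flat-only model by an F-ratio of at least 4.0 (configurable);
otherwise "no onset detected" is returned rather than a spurious knot.
The estimator is invariant under positive affine intensity transforms
and under appending flat pre-onset points, and preserves onset ordering
across systems — all property-tested.

## Förster analysis

The overlap integral `J = ∫F ε λ⁴ dλ / ∫F dλ` is evaluated by
trapezoidal sums on the donor grid restricted to the donor–acceptor
overlap interval, with the acceptor linearly interpolated onto it;
wavelengths enter the λ⁴ weight in cm, so `J` emerges in cm³M⁻¹ (the
cleaner of the two volume conventions seen in the literature). The
radius formula is implemented as `R0⁶ = 8.8e-25·K²·n⁻⁴·φ·J` in cm⁶:
dimensional analysis of the standard Förster expression requires the
sixth power even where the prefactor is sometimes printed as if it gave
`R0` directly. Defaults are `K² = 2/3` (isotropic dynamic averaging)
and `n = 1.336` (aqueous buffer); the donor quantum yield `φ` has *no*
default — no universal value is defensible, and published tables that
omit φ cannot be reproduced, which is why the package asserts the
equation identities (`E = 0.5 ⇒ r = R0`, e↔r round trips, J scaling
invariance) rather than any particular tabulated (J, E, R0, r)
quadruple.

## The synthetic generator

`gen_quenching_titration()` produces titrations with the statistical
structure the fits assume: a Gaussian emission band (no line shape is
canonical for protein emission; Gaussian is the simplest with the right
qualitative behaviour) whose center red-shifts linearly with quencher
concentration (matching the small ≤3 nm shifts of interest), scaled per
point by one of four noiseless quenching laws (simple Stern–Volmer,
accessible-fraction, two-regime, Hill/double-log), plus additive
Gaussian intensity noise drawn reproducibly from a private RNG stream
(the global `.Random.seed` is saved and restored). The two-regime
mechanism applies each regime's law on its own side of the split, so
each side is exactly linear in both the Stern–Volmer and modified
Stern–Volmer planes — which is what makes exact split recovery a
meaningful oracle; the price is that the generated `F` can step at the
split when the second constant is smaller than the first.
`gen_rls_series()` produces the flat-then-linear hinge with seeded
noise, and `gen_absorption_spectrum()` flat or Gaussian extinction
traces.

What the generator does **not** emulate: photophysics (lifetimes,
anisotropy, spectral relaxation), instrument artefacts (baseline drift,
lamp flicker, correlated noise, wavelength calibration error),
scattering physics beyond the hinge phenomenology, or inner-filter
effects (generated data are "already corrected"). Passing
recovery tests therefore demonstrate that the estimators are correct
and stable under the assumed noise model — not that real instrument
data meet those assumptions.

A note on magnitudes: reported Stern–Volmer constants of order
1e12 M⁻¹ combined with nM-scale quencher concentrations would imply
enormous `F0/F`, inconsistent with the gentle quenching such titration
figures actually show. The generator makes no attempt to reconcile
this; recovery tests use self-consistent grids chosen so that
`Ksv·[Q]` spans roughly 0–4, the regime where all four linearisations
are numerically well conditioned.

## Problem sizes and stochastic checks

The test and acceptance runs use 10–11 point titrations on ~160-point
wavelength grids, 20-point RLS curves and, for the noise-bias envelope,
200 seeded replicates at 5% intensity noise — sizes representative of
real titration experiments while keeping the full suite in a few
seconds. The bias check reads intensities at the band center rather
than at the per-spectrum maximum: the maximum of a noisy spectrum is a
biased (upward) statistic, and that readout artefact would contaminate
a test whose purpose is to bound the bias of the fitting machinery
itself. Determinism is enforced throughout: the same configuration and
seed reproduce byte-identical series, and `run_analysis()` output is
identical across repeated runs.

## Degenerate inputs and refusals

Constructors and fits refuse, with explicit messages: wavelength grids
that do not cover the band (center ± 3 widths), titrations without a
zero-concentration reference (nothing would define `F0`), nonpositive
intensities in ratio fits, accessible-fraction requests with
`fa·ka[Q]/(1+ka[Q]) ≥ 1` (negative fluorescence), absorption spectra
with negative extinction, RLS knots outside the grid interior, FRET
efficiencies at exactly 0 or 1 (unbounded/zero distance), and missing
quantum yields. Points with `F > F0` (possible under noise) are
excluded from fits with a warning, not silently used.

## Known limitations

- Temperature-dependence experiments, the orthodox way to separate
  static from dynamic quenching, are out of scope; classification rests
  on the `kq` ceiling alone.
- CD secondary-structure deconvolution is not performed; fraction
  tables are trusted inputs.
- The orientation factor is a scalar `K²`; no attempt is made to model
  dipole geometry, and lifetime-based transfer efficiencies are not
  supported.
- Synchronous-scan wavelength axes are reported as scanned; the package
  does not reinterpret synchronous peak positions onto an emission
  axis.
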