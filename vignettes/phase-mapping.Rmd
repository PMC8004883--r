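---
title: "Phase mapping for reproducible pSPR sensing: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase mapping for reproducible pSPR sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psprmap)
```

## The measurement and its reproducibility problem

A Kretschmann-configuration pSPR instrument couples 850 nm light through a
BK7 prism into a thin gold film and reads the *phase* of the reflected
p-polarized beam relative to the s-polarized reference. Near the plasmon
resonance the p-phase sweeps through roughly a radian over a few 10⁻³ RIU of
buffer index change, which is what makes the technique sensitive — and what
makes it irreproducible at a fixed interrogation angle: the local slope of
the phase-vs-index curve depends strongly on the gold thickness (a
nanometre matters) and on the incidence angle (a few hundredths of a degree
matter). Two regions of interest on one chip therefore report different
phase excursions for identical chemistry.

`psprmap` converts each sensor's phasogram into refractive-index units
through a per-sensor mapping function built from physics rather than from an
ad-hoc parametric fit.

## The five-layer model and its observable

`stack_reflectivity()` evaluates the stratified-medium reflection
coefficient with the standard characteristic-matrix method; an independent
interface-by-interface recursion (`stack_reflectivity_recursive()`) is kept
in the package purely as a structural cross-check (they agree to ~1e−12).
Branch choices: complex layer cosines are used throughout and the normal
wave-vector branch is fixed by Im(k_z) ≥ 0, so evanescent and absorbed waves
decay into the stack. The fixed optical constants are BK7 1.51, Cr
3.24+3.49i at 2 nm, Au 0.16+5.34i, wavelength 850 nm.

The modeled observable is the *p−s differential* reflected phase,
baseline-referenced: the interferometer physically interferes p against s
through the analyzer, and baseline referencing makes the pipeline invariant
both to any global phase-sign convention and to the constant s-phase offset.
Phase-vs-index curves are unwrapped by nearest-branch continuation with
automatic grid doubling whenever an adjacent step exceeds π/2.

## The meta-model

The multilayer calculation has no closed form, so each curve (301 samples
over the working window by default) is approximated by three least-squares
cubics on contiguous chunks of equal point count ("similar data chunk
size"). Two reading choices deserve record:

* **Segmentation axis.** Chunks are equal *point counts* along a uniform RI
  grid (hence equal RI spans). Segmenting along the phase axis was measured
  during development and does not improve worst-case fidelity.
* **Joints.** No continuity constraint is imposed in the fit. The domain
  break between adjacent segments is placed at the *crossing* of the two
  fitted cubics when one exists near the chunk boundary — this costs nothing
  in fit quality and makes the piecewise surrogate continuous, hence
  uniquely invertible; when the cubics do not cross there, the midpoint is
  used and the joint gap is monitored (it must stay below twice the maximum
  fit residual). A phase falling inside a residual joint gap inverts to the
  break point, an error bounded by the monitored gap.

Inversion (`invert_phase()`) is cubic root-finding per segment, never a
separately fitted inverse, so forward evaluation and inversion cannot
disagree. Root selection prefers temporal continuity (the previous sample's
index), then the monotone working branch containing the baseline.

**Fidelity limit.** A cubic segment spans ~1e−3 RIU of the calibration
window. Chips near critical coupling (≈48 nm gold here, dip reflectance
~6e−4) have a p−s phase transition *narrower than a segment* (~5e−4 RIU,
>3 rad tall), and no 3×cubic model can follow it at the 0.001 rad noise
floor: measured worst-case |meta − Fresnel| over the 44–48 nm, 66.3–66.5°
family is ~4e−4 rad at 44 nm but ~7e−3 rad at 46 nm and ~5e−2 rad at 48 nm.
The corresponding *mapping* error (phase residual divided by local slope) is
far smaller — ~6e−7, ~8e−6 and ~1.4e−4 RIU respectively — because the
residuals concentrate where the curve is steepest. The package therefore
treats meta-model quality as a property of the *mapping*, and the
acceptance-grade fidelity figure of 1e−3 rad holds only away from critical
coupling. This is a genuine representational limit of the three-cubic
scheme, not a fitting artifact.

## Calibration by Bayesian optimization

`calibrate_chip()` searches (incidence angle, Au thickness, probe thickness,
probe index) inside user bounds (defaults: dip ± 1°, 40–55 nm, 5–10 nm —
a ~22-base-pair aptamer layer at 0.34 nm/bp is ≈7.5 nm — and 1.34–1.45).
Each trial builds the Fresnel curve over the calibration window extended by
10% on both sides ("slightly larger than the experimental data", read
symmetrically), meta-models it, and scores Σ(meta(RIₖ) − Δφₖ)² in rad² over
the five calibration points, the baseline included at equal weight.
Degenerate trials (curves that cannot be unwrapped) receive a finite 1e3
rad² penalty.

No Bayesian-optimization package ships with this environment, so the
surrogate search is implemented here: a seeded Latin-hypercube start,
Gaussian-process regression on log10(SSR) with an SE kernel (length scale
picked by marginal likelihood from a small grid), expected-improvement
proposals, then a Levenberg–Marquardt polish of the incumbent on the
residual vector with Broyden-updated Jacobians, and finally a walk along the
smallest-eigenvector direction of JᵀJ with quick re-polishes. The walk
exploits the defining feature of this problem: single-wavelength data leave
the four parameters non-identifiable along a valley of *equivalent models*,
and the meta-model's anchor-point floor still varies along that valley.
Every objective evaluation counts against the `n_iter` budget, and the full
trial trace is returned (and drawn by `plot_trace()`: x = angle, y = Au
thickness, z = log10 SSR, color = probe index, size = probe thickness, with
a companion CSV so the chart is testable without image comparison).

Identical seeds give identical traces. The acceptance surface is mapping
recovery, not parameter recovery: two seeds' fits on the same calibration
agree through `equivalent_model_check()` to a few 1e−6 RIU although their
parameter vectors differ visibly.

**Convergence limit.** On the noiseless default chip the best achievable
SSR is bounded below by the meta-model's anchor wiggle (global floor
log10 ≈ −6.17, reached in a corner of the bounds; the dominant valley floor
is ≈ −5.93). Within a strict 150-evaluation budget the search typically
lands between −5.5 and −6.1 depending on seed — the same representational
limit as above, now expressed at the calibration anchors.

## The interferometer and GLIA demodulation

`simulate_beating()` generates I(t) = I₀(1 + µ sin ωt)(1 + m cos(Δφₐ sin ωt
− φ)) over integer modulation periods; `lockin_xy()` removes the mean
(an exact high-pass under integer-period sampling — chosen over a causal
filter for bit-reproducible tests) and averages against the Bessel-matched
references cos(Δφₐ sin ωt) and sin(Δφₐ sin ωt). The exact closed forms of
these averages, derived via the Jacobi–Anger expansion, are

    X = (I₀m/2){cosφ [1 + J₀(2d) − 2J₀²(d)] + µ sinφ [J₁(2d) − 2J₀(d)J₁(d)]}
    Y = I₀ µ J₁(d) + (I₀m/2){sinφ [1 − J₀(2d)] + µ cosφ J₁(2d)}

with d the modulation depth. The published forms of these quadratures are
internally inconsistent (coefficients disagree between the quadrature and
arctangent expressions); the package derives its inversion from its own
closed forms and validates it by round-trip: simulate → demodulate →
extract recovers φ to <1e−6 rad over 721 phases and µ up to 0.2, at machine
precision in practice. The I₀µJ₁(d) term in Y is the residual-amplitude-
modulation error that the instrument cancels by tuning the depth to the
first J₁ zero (3.8317 rad); `extract_phase()` deliberately does not correct
it (it would require the unknown intensity scale), which reproduces the
instrument's sensitivity to detuning: dφ̂/dµ is <1e−6 at the null depth and
>1e−3 at d = 3.0. µ is treated as a known configuration constant (default
0); the YVO₄ birefringence is never published and is fixed at ne − no = 0.2,
which together with β = 0.6 nm/mA, L = 1 cm, λ₀ = 852 nm and Δi = 0.369 mA
gives a depth within 0.1% of the null.

## Kinetics

Association ΔS(t) = ΔS_max(1 − e^{−τ(t−t₀)}) and dissociation ΔS(t) =
ΔS₀e^{−k_off(t−t₀)} are both linear in their amplitude, so the fits use
variable projection: the amplitude is profiled out in closed form and the
rate found by a bracketed 1-D search refined by secant-Newton steps on the
projected gradient. This recovers noiseless generating parameters to
machine precision (`stats::nls` raises an error on exactly zero-residual
data, which is why the solver is hand-rolled; no Levenberg–Marquardt
least-squares package is available in this environment). Deterministic
starts: ΔS_max from the last sample, τ from the time to 63.2% of it;
dissociation starts from a log-linear regression. τ is read as a rate
constant in s⁻¹ (the equation form governs; calling it a "half-life" is a
loose usage). `derive_constants()` applies τ = k_on·C + k_off. Note the
published anti-CD9 numbers are mutually inconsistent: k_off/k_on of the
printed rates is 4.09 nM, not the printed K_D of 3.65 nM, and the analyte
molar concentration behind them is not printed; the package back-solves
C = 3.984e−8 M, the value that makes the printed rates coherent.

## The synthetic world

All tests run on generated data. The stated world, frozen before any
acceptance measurement:

| quantity | value | basis |
|---|---|---|
| reference solutions | RI 1.3342, 1.3346, 1.3349, 1.3364 | published calibration series |
| baseline buffer | RI 1.3340 | plain PBS sits just below the +10 mM NaCl reference; not published |
| phase noise | σ = 0.001 rad, i.i.d. Gaussian | the instrument's stated noise floor |
| default chip | 66.4°, 46 nm Au, 7.5 nm probe @ 1.40 | inside the displayed operating regime |
| chip family | 44–48 nm Au, 66.3–66.5° | the displayed thickness/angle sweeps |
| ROI pair offsets | ΔAu = 1.2 nm, Δθ = 0.05° | the published ROI discrepancy |
| reference staircase | 200 s dwell per solution, 1 Hz | typical solution-switching protocol |
| binding course | k_on = 4.28e4 M⁻¹s⁻¹, k_off = 1.75e−4 s⁻¹, C = 3.984e−8 M, ΔRI_max = 5e−4 | published rates; amplitude typical of antibody binding at these RI scales |

What the generator emulates: Fresnel-exact chip responses, additive Gaussian
phase noise, solution staircases and Langmuir binding courses pushed through
each chip's own curve. What it does not emulate: baseline drift, bulk-vs-
surface refractive index decomposition, spike artifacts, flow/mass-transport
limitation, camera shot noise, or wavelength drift of the source. A green
consistency test therefore establishes that *calibration-and-conversion*
removes chip-to-chip optics variation at the stated noise level — not that
the pipeline is robust to drift or transport effects, which are explicit
non-goals.

## Numerical choices

* Angles in degrees at every interface and I/O boundary, radians internally.
* Segment cubics are fitted in the scaled local coordinate
  u = (RI − center)/halfspan; raw powers of RI ≈ 1.334 would be hopelessly
  ill-conditioned.
* `invert_phase()` accepts phases up to a 1e−9-relative tolerance beyond the
  model's phase range and errors beyond that — never silent clipping.
* Baseline re-referencing of measured phasograms uses the mean over the
  first 60 s by default (the protocol establishes baseline with running
  buffer; the window length is a convention).
* Consistency reports resample onto a 512-point regular grid over the
  intersection of the time ranges by linear interpolation.
* log10(SSR) of an exactly zero SSR is floored at −16 for plotting.

## Known limitations

* The three-cubic meta-model cannot follow near-critically coupled chips at
  the noise floor (see above); with such chips the converted consistency
  degrades from ~2e−6 to ~1e−5 RIU on reference staircases. Binding
  courses, which stay within the densely anchored region near baseline,
  remain at a few 1e−6 RIU even for the ROI pair.
* Single wavelength only; no dispersion, no anisotropic or graded layers.
* Parameters returned by calibration are effective, not physical — by the
  non-identifiability argument they must not be interpreted as film
  metrology.
* 1:1 Langmuir kinetics only; no mass-transport or bivalent models.
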