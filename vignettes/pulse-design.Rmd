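---
title: "GIRF-corrected time-optimal design of SMS refocusing pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GIRF-corrected time-optimal design of SMS refocusing pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girfpulse)
```

This vignette is the package's account of its model and of the design
decisions a maintainer would want spelled out.  It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The physical model

### Gradient system as an LTI filter

The demanded slice-selective gradient `Gs(t)` and the field the scanner
actually produces, `G̃s(t)`, are related by a convolution with the
gradient impulse response function, or equivalently in the frequency
domain by `G̃s = Re(F⁻¹ H F Gs)`.  The model captures amplifier
bandwidth, coil dynamics and linear eddy currents; it excludes
nonlinearity, thermal drift, cross-axis terms and higher spatial orders.
`transfer_function` objects tabulate `H(f)` on a uniform frequency axis;
`synthetic_girf()` emulates a measured response with a Butterworth-like
magnitude and a pure delay phase.  Typical measured systems have
half-magnitude cutoffs of a few kHz (`cutoff_frequency()` reports the
interpolated 1/2 point) and delays of tens of microseconds.

Numerical choices, all verified by tests against a direct time-domain
convolution:

* the input is zero-padded to the next power of two at or above twice its
  length before the FFT — the gradient is genuinely off before and after
  the pulse, so zero (not circular) extension is the physical choice and
  suppresses wrap-around of the impulse response;
* `H` is interpolated linearly in its real and imaginary parts onto the
  transform frequencies and set to 0 beyond its tabulated support (the
  measured responses are low-pass);
* Hermitian symmetry is enforced (by averaging `H(f)` with `Conj(H(−f))`
  for two-sided tables) so the realized gradient is exactly real;
* the adjoint of the filter — needed by the chain rule — is filtering
  with `Conj(H)`, verified against the transpose of the dense operator.

### Spin-domain Bloch simulation

Profiles are computed in the spin domain: per spatial position `z` the
Cayley–Klein pair `(a, b)` is propagated through the piecewise-constant
waveform with per-step coefficients built from the effective field
`(B1, z·G̃s + ΔB0/γ̄)`, with relaxation neglected (pulse durations are
milliseconds, tissue relaxation times tens of milliseconds or more).
The perfectly crushed spin-echo observable is `|b(z)|²` with phase
`arg(b²)`; scaled-down use as an excitation pulse is evaluated as the
flip angle `asin(|2ab*|)`.

Two conventions deserve a note.  First, the recursion is initialized
with `a = 1, b = 0` (the unit propagator); an initialization with both
equal to 1 would violate `|a|² + |b|² = 1`.  Second, the rotation-angle
convention carries a leading minus (`φ = −γτ√(r² + (zG̃)²)`), matching
the physical Bloch rotation of magnetization by `−γ|B_eff|τ` about the
effective field; the test suite checks the simulator against an
independent 3×3 rotation-matrix oracle composed exactly that way, to
1e-8 in `|b|²`.  The degenerate step `φ → 0` uses the series limit of
`sin(φ/2)/φ` below `|φ| < 1e-8`.

### Constraints and penalties

Magnitude accuracy is posed pointwise: `|b|² ≤ e_out` out-of-slice and
`1 − |b|² ≤ e_in` in-slice, with transition bands (set by the SLR
prototype's fractional transition width) constrained by neither.  The
in-slice phase is held to within `e_p` of its slice mean, computed as the
argument of the mean unit phasor so the statistic is safe across the
±π branch.  Hardware limits are hard constraints: RF amplitude and slew
rate bound the controls directly (handled by projection), while the
demanded-gradient amplitude `|Gs| ≤ Gmax` is a state constraint handled
by its own penalty term.  The printed form of the amplitude constraint
is one-sided, but the even-exponent penalty is symmetric, so the package
tracks `|Gs|`; for all documented designs the demanded gradient stays
far below the 30 mT/m limit either way.

The objective adds the pulse duration, an RF energy term (amplitudes in
µT there, which keeps the SAR link in natural units), and Lp penalties
of the normalized constraint functions.  The penalty prefactors are
`μ_RF/2`, `μ_G/p`, `μ_out/(2p)`, `μ_in/(2p)` and `μ_p/p` (the spatial
terms also carry the grid spacing `δ`); the per-term breakdown is
reported, so any alternative prefactor convention is a one-line change.
The SAR estimate `SARe = SARcoil_eff · f_p · τ · Σ r²` is tracked, not
penalized directly: exceeding the configured limit (3.2 W/kg head SAR by
default) doubles the RF energy weight at the next adaptation.

## The PINS initialization

The bilevel search needs a feasible starting point.  `build_pins()`
constructs one: `N = ⌈TBWP · spacing/THK⌉` hard RF sub-pulses (spacing
= FOV/MB) interleaved with `N − 1` gradient blips whose zeroth moment
advances the inter-slice precession by exactly one cycle per spacing.
Because RF plays only while the gradient is zero, the on-resonance
profile of the train equals the frequency response of its SLR
beta-polynomial exactly — the initialization is as good as its filter.

Choices, each validated by the profile and duration tests:

* **Ripple convention.**  The sub-pulse takes `d1 = 0.01/4` and
  `d2 = 0.01/2` as crushed-SE *profile* ripples and converts them to
  beta-polynomial ripples with the standard spin-echo relations
  `(d1/4, √d2)`.
* **Prototype filter.**  A weighted least-squares linear-phase lowpass
  (weights ∝ 1/ripple), robust at the small tap counts PINS needs, with
  band edges `(TBWP/2)(1 ∓ w)/N` from the Parks–McClellan transition
  estimate `w = D∞/TBWP`.  `w` is capped at 0.9: for TBWP = 2 the
  requested ripples are infeasible in principle and the cap keeps a
  nonzero flat passband; the capped designs are best-effort and the
  profile tests for strict ripple compliance use feasible TBWPs.
* **Inverse SLR.**  The minimum-phase alpha polynomial comes from a
  cepstral spectral factorization of `1 − |B|²`; the exact backward
  hard-pulse recursion returns the flips.  A real pulse (phases in
  {0, π}) corresponds to a purely *imaginary* beta polynomial under this
  rotation convention, so the linear-phase prototype is multiplied by
  `i` before inversion — a global phase with no effect on `|B|`.
* **Sub-pulse duration.**  All sub-pulses share one duration, set by the
  largest flip at the RF amplitude limit and rounded up to the raster;
  amplitudes then scale to preserve each flip.  (Giving each sub-pulse
  its own minimum duration would shorten the train but also change its
  SAR and peak-amplitude structure; the common-duration convention is
  the one whose durations and SAR the evaluation reproduces.)
* **Blips.**  Minimum-time half-sine lobes under the slew limit,
  sampled on the raster and rescaled to the exact moment, with a
  sine-ramp trapezoid fallback when the half-sine peak would exceed
  Gmax.  Half-sine blips are a touch longer than triangles but gentler
  on the gradient chain — and they are the shape whose total durations
  the duration tests confirm.
* **Even MB.**  The flips alternate in sign, shifting the slice comb by
  half a period so the pattern is symmetric about isocenter.

## The optimizer

The lower level minimizes the penalized cost at fixed duration with a
projected limited-memory BFGS iteration (memory 20) on bound-normalized
controls; real-valued designs (the default, as rapidly varying complex
RF is itself hard to realize) optimize the signed amplitude
`u = r·cos ϑ ∈ [−rmax, rmax]`.  Gradients are exact adjoints: a reverse
sweep over the Cayley–Klein recursion accumulates the profile-term
sensitivities, which are chained through the filter adjoint and the
transposed slew integration; finite-difference agreement to 1e-6
relative is part of the test suite, with and without a GIRF in the loop.

Safeguards that experience with the penalty landscape forced:

* proposed steps are capped at a quarter of the unit control box — an
  early uncapped quasi-Newton step can destroy the pulse structure
  beyond recovery;
* penalty weights adapt every 20th iteration (×2 while a group is
  violated, ÷1.25 once satisfied with a 10% margin, clamped to
  [1e-6, 1e9]); the curvature memory survives these gentle rescalings
  but is cleared on `p` continuation, which changes the objective
  qualitatively;
* the exponent doubles (2 → 4 → … → 32) only once the worst violation is
  below `p_raise_viol` (default 0.01): raising `p` while grossly
  infeasible overflows the Lp terms and stalls the line search;
* on a line-search failure the solver retries with normalized steepest
  descent, and only a repeated failure — a projected stationary point of
  the current penalty — triggers an off-schedule weight adaptation.

The upper level shrinks the interval count by 10% per accepted leg,
warm-starting each solve by *moment-preserving* resampling of the
incumbent: the cumulative RF and gradient integrals are interpolated, so
flip areas and the k-space comb (hence the slice positions) survive the
compression and only the amplitudes grow, to be clipped by projection
where they exceed the limits.  Amplitude-interpolating resampling — the
contract `resample_controls()` keeps as its documented default — dilates
every blip area when the grid shrinks and moves all slices outward,
which reliably stalls the search.  On the first infeasible leg the
search bisects down to one raster sample; because a failed leg proves
only that a *budgeted, local* solve failed, the shrink-bisect cycle then
restarts from the new incumbent and stops when a full cycle brings no
improvement.  Accepted durations are strictly decreasing by
construction, and every accepted design is feasible at `tol_violation`
(1e-3 by default).

## What the synthetic experiments show — and what they do not

The package reproduces the design *mechanism* at desk scale: two slices
across a 60 mm FOV, 256 spatial points, a 12.8 µs raster, and a
synthetic GIRF (3.75 kHz cutoff, 50 µs delay) standing in for a measured
low-pass response.  These sizes keep a full bilevel run in minutes on
one core; the documented full-scale examples (4–5 slices, 6.4 µs raster,
~1000 spatial points) obey the same code paths but each take on the
order of an hour in plain R, and their printed outcomes depend on
lower-level solver internals that this package deliberately approximates
with a first-order projected method.  Synthetic GIRFs capture the
low-pass magnitude and constant group delay of measured systems, not
their mechanical-resonance ripples; a measured table can be supplied as
CSV (`load_girf()`) and used unchanged.  Passing tests therefore show
the correction mechanism and the solver's contracts, not scanner-ready
equivalence for any particular hardware.

## Known limitations

* Relaxation, spatially varying B1, parallel transmit and RF amplifier
  dynamics are out of scope; B0/B1 robustness is evaluated
  (`robustness_sweep()`) but not optimized for.
* The lower-level solver is first-order (projected L-BFGS); it finds
  good feasible designs but not certificates, and the minimum durations
  it reports are upper bounds tied to its iteration budget.
* Cross-axis GIRF terms and field-dynamics beyond the slice axis are not
  modeled.
* The PINS initializer requires the slices (including transition bands)
  not to overlap; very thick slices at high MB are rejected.
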