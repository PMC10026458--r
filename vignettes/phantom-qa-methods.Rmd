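---
title: "Methods: virtual T1/T2 phantom simulation and quality assurance"
author: "phantomqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual T1/T2 phantom simulation and quality assurance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqa)
```

# Scope

`phantomqa` models the computational chain behind a nickel-chloride/agarose
relaxometry phantom for cardiovascular magnetic resonance (CMR) T1 and T2
mapping: designing tube recipes from a relaxivity model, simulating the
acquisitions used to characterize and qualify such a phantom, reconstructing
parameter and field maps, and computing the quality-assurance (QA)
statistics by which a phantom is judged — bias against a spin-echo
reference, coefficients of variation (CoV), long-term reproducibility and
temperature trends. Everything runs on a virtual phantom, so the whole
pipeline is testable without scanner data.

# The recipe model

Agarose concentration chiefly shortens T2 and the paramagnetic Ni²⁺ ion
chiefly shortens T1. Working with relaxation *rates* rather than times, the
model assumes both rates are linear in the ingredient concentrations:

$$R_1 = \tfrac{1000}{T_1\,[\mathrm{ms}]} = r_{1,0} + r_{1,\mathrm{Ni}}\,[\mathrm{Ni}^{2+}] + r_{1,\mathrm{ag}}\,[\mathrm{agarose}]$$

and analogously for $R_2$, with rates in 1/s, Ni²⁺ in mM and agarose in
% w/v. `fit_relaxivity_model()` estimates the six coefficients by ordinary
(unweighted) least squares from a calibration table; `design_recipe()`
inverts the fitted 2×2 slope matrix to obtain the concentrations realizing
a target (T1, T2) pair, rejecting targets whose solution needs a negative
concentration. The forward/inverse pair is an exact linear-algebra round
trip (tested to 1e-9).

Only the pure linear plane is fitted — no Ni–agarose cross terms — and the
residual standard deviations of both rate fits are retained on the model
object so that any inadequacy of the linear assumption stays visible.
Leave-one-out refits (`loo_prediction_errors()`) quantify per-tube
prediction error without silently dropping rows.

**A caveat on the packaged calibration table.** The two concentration
columns of the packaged nine-tube calibration are strongly collinear, and
the fitted nickel-on-R1 coefficient at 1.4 T is −2.6e-4 1/s/mM — an order
of magnitude below the fit's residual SD of 2.5e-3, i.e. statistically
indistinguishable from zero, with a sign that is not a stable feature of
the data (the 1.5 T and 3 T columns give small positive values). The
dominant coefficients land on literature magnitudes, but users should not
interpret the individual cross-coefficients of this particular calibration
mechanistically. The degenerate-design guard raises an error only for an
exactly rank-deficient concentration matrix.

# The virtual phantom

`default_phantom_layout()` places nine 24 mm tubes on a 30 mm grid inside
a 100×100 mm body cross-section; tubes `A`, `B`, `F`, `I` occupy the
corners and the long-T1 tubes sit centrally, mirroring the physical
arrangement that keeps temperature-sensitive tubes away from the bottle
edges. Per-tube truth at 1.5 T and 3 T comes from the packaged calibration
table. The outer matrix fill uses its bench-relaxometer values (T1 850 ms,
T2 140 ms) at both field strengths, the only measurement available for it.

`rasterize_layout()` point-samples the scene: a pixel belongs to a tube iff
its center lies strictly inside the disk. There is no partial-volume
weighting — partial-volume behaviour is explicitly out of scope for a
phantom of this kind — so tube masks are accurate to about half a pixel
and the default 1 mm raster reproduces each 452 mm² tube area within 2%.

## Acquisition simulators

*Reference sequences.* Inversion-recovery gradient echo (11 TIs,
20–2100 ms, TR 10 s) and single-echo spin echo (10 TEs, 10–150 ms,
TR 10 s) are closed-form signal equations,

$$S_{\mathrm{IR}}(TI) = |M_0 (1 - 2e^{-TI/T_1} + e^{-TR/T_1})|,
\qquad
S_{\mathrm{SE}}(TE) = M_0 (1 - e^{-TR/T_1})\, e^{-TE/T_2},$$

evaluated per pixel; the regression tests hold them to 1e-12 against
direct evaluation.

*MOLLI.* The 5(3)3 modified Look-Locker inversion recovery at RR 900 ms
(minimum TI 100 ms; flip angle 35° at 1.5 T, 20° at 3 T) is simulated as
Bloch events on the full magnetization vector, once per compartment: an
ideal inversion, then for each beat a single-shot bSSFP burst — α/2
catalyst, 65 alternating ±α pulses 2.8 ms apart, signal taken at the
k-space-center (middle) pulse, α/2 tip-back — then three recovery beats, a
second inversion and three more beats. The burst drives the magnetization
toward the bSSFP steady state, so the apparent recovery constant T1\* is
shorter than T1; `fit_molli_t1()` applies the Look-Locker correction
T1 = T1\*(B/A − 1).

Two consequences of simulating the transient exactly are worth knowing.
First, at vanishing flip angle the k-center signal retains T2-decayed
memory of the magnetization at the catalyst (the weak pulses cannot
refresh the transverse state), so the samples approach the ideal IR curve
only to within about 1% rather than exactly; the tests encode that bound.
Second, with the default 65-pulse, 2.8 ms readout and gel-like T2 ≈ 45 ms,
corrected MOLLI T1 underestimates truth by roughly 6–11% across
400–1300 ms — consistent with the known short-T2 underestimation of bSSFP
MOLLI — while always exceeding the apparent T1\*. The package treats MOLLI
as a *precision* instrument (its reproducibility is what the QA pipeline
scores), not an accuracy gold standard; the IR-GRE simulator plays that
role.

*T2-prepared bSSFP.* For each preparation time (defaults 0, 25, 55 ms —
typical product values; the choice only scales the sequence-induced bias,
whose sign and ordering are the properties of interest), an ideal T2
preparation scales longitudinal magnetization by $e^{-TE_{prep}/T_2}$
(transverse spoiled), a 10-pulse linear ramp catalyses a 65-pulse
alternating ±70° train with exact free-precession relaxation over the
2.8 ms pulse spacing, the frame signal is the transverse magnitude at the
middle pulse (linear phase-encode ordering), and three R-R intervals of
free recovery precede the next preparation. T1 recovery between the
preparation and the k-space center adds a T1-dependent signal floor, so a
two-parameter exponential fit of the frames overestimates T2 — more
strongly the shorter T1 is. This reproduces the characteristic pattern of
bSSFP T2 mapping against spin echo: a positive bias everywhere, largest
for the short-T1 post-contrast tube. Because the floor is a property of
the readout's *duration*, not only its flip angle, the pure-exponential
limit is reached jointly (small flip angle *and* short train); the
three-parameter offset fit (`model = "3param"`) absorbs the floor under
the default train but is off by default, matching the conventional
two-parameter product fit.

*Field mapping.* Dual-echo gradient echo frames are complex with phase
$2\pi\,\Delta f\,TE$; `compute_b0_map()` recovers off-resonance from the
complex-ratio angle, unambiguous below the aliasing limit $1/(2\Delta TE)$
(400 Hz at the default 2.5 ms spacing). No spatial unwrapping is
performed — a phantom designed for sub-Hz uniformity never needs it — and
aliasing behaviour is documented and tested instead. The double-angle
method acquires long-TR images at 60° and 120° and inverts
$\alpha = \arccos(S_{2\alpha}/2S_\alpha)$; pixels outside the arccos
domain are flagged invalid rather than erroring. Conversion to ppm uses
γ = 42.576 MHz/T; `ppm_report()` rounds to one significant figure for
display only (1 Hz at 3 T → 0.008 ppm), never in stored maps.

*Temperature.* `apply_temperature()` shifts each compartment linearly
about the 22 °C reference with per-compartment slopes constrained to
dT1/dT ≥ 0 and dT2/dT ≤ 0. Default slopes are proportional to the
compartment's reference values — +1.0%/°C for T1, −0.5%/°C for T2 — which
encodes the observation that longer-T1/T2 tubes drift more across the
13.5–38.8 °C range; the proportionality constants are free parameters of
the generator (no published per-tube coefficients exist), and only the
slope *signs* and the ordering of spreads are treated as testable claims.

*Noise.* Magnitude data receive Rician noise (independent complex
Gaussian of SD σ per channel, then magnitude), giving the documented
zero-signal floor σ√(π/2); complex field-mapping data receive additive
complex Gaussian noise. Every simulator is deterministic given
(truth, protocol, seed). Image SNR is defined conventionally on the
reconstructed image — mean in-phantom signal of the brightest frame over
σ — via `noise_for_snr()`.

# Map fitting

All fits are pixel-wise nonlinear least squares solved by variable
projection: for a trial decay constant the linear amplitudes have a
closed-form solution, reducing each model to a one-dimensional
optimization over the rate. A log-spaced coarse grid (80 points,
1–10000 ms), vectorized across pixels, supplies a deterministic global
initialization; Brent refinement then polishes the winning bracket to
~1e-10 relative. On clean data this is equivalent to log-linear
initialization followed by Gauss–Newton, but it is robust to the Rician
floor and needs no per-pixel iteration control. Dense grid-search oracles
in the test suite pin the fitters on small instances.

Magnitude inversion-recovery data are fitted with polarity restoration:
every candidate flip index k (frames 1..k negated, frames ordered by TI)
is fitted and the best residual wins, ties broken toward the smaller
index. Candidates with a physically valid IR shape (A > 0, B > A) are
preferred over raw-residual winners: under noise a spurious no-flip
candidate with B < A can otherwise edge out the true solution while
implying an impossible recovery. Pixels whose Look-Locker ratio B/A ≤ 1
keep their apparent T1\* but are flagged, and pixels with non-positive
signal everywhere are marked unconverged rather than raising errors.
Background pixels are masked out (truth labels when available, otherwise
a signal threshold) and never fitted.

# QA statistics

ROIs are placed at each tube's mask centroid with radius 50% of the tube
radius (25% of the tube area), with optional manual center offsets; an
ROI escaping its tube is an error naming the tube. Statistics use the
arithmetic mean and sample SD (n−1) of converged ROI pixels. The bias
table reports per-tube `mapped − reference` differences in ms and as a
percentage of the reference, plus group summaries (all tubes, corner set
{A, B, F, I}, central set) as the mean absolute difference and that mean
expressed against the group's mean reference. Reproducibility tables use
the baseline as the percent-difference denominator and the two-point
sample-SD CoV; these conventions reproduce the published cells they are
checked against (15/41 → 36.6%, 1/48 → 2.1%, max two-point CoV 1.25%).
Report rounding is half-away-from-zero at the displayed precision
(`round_report()`); stored values are never rounded. `qualify_phantom()`
applies the boundary-inclusive CoV ≤ 2.7% acceptance threshold; the
threshold is adopted as stated for this phantom class rather than
re-derived.

# Numerical and design choices

- **Units.** Times in ms, rates in 1/s (factor 1000), angles in degrees
  at the interfaces and radians internally, frequencies in Hz.
- **Tie-breaks.** Polarity candidates tie toward the smaller flip index;
  group summaries recompute from rows rather than caching.
- **Degenerate inputs.** Collinear calibrations, singular slope
  matrices, infeasible targets, overlapping tubes, non-positive truth,
  mismatched tube ids and inconsistent sidecars all raise typed errors;
  per-pixel pathologies (non-positive signals, arccos domain, undefined
  Look-Locker correction) flag pixels instead.
- **Persistence.** Stacks and maps are NIfTI-1 volumes (frames or layers
  along the third axis; complex data as real/imaginary volume pairs)
  with JSON sidecars carrying protocol, frame parameters, seed and noise
  level — enough to re-run the producing step exactly.
- **Problem sizes.** The test suite and the acceptance script use 2 mm
  rasters (2500 pixels) for noiseless recovery and temperature sweeps and
  the 1 mm raster (10000 pixels, ~112-pixel ROIs) for the noisy
  reproducibility experiment with three seeded repeats; these sizes give
  sub-0.1% recovery and stable CoV estimates while keeping the default
  run fast.

# What the synthetic data does and does not show

The generator reproduces the *structure* of the real experiments:
geometry, sequence timing, relaxation physics of the readouts,
Rician/complex noise, field inhomogeneity maps and temperature scaling.
It does not model partial-volume edges, magnetization transfer, flow,
arrhythmic triggering, T2\*, gradient imperfections, multi-coil
reconstruction or vendor-specific readout details, and the real phantom's
unrealistically high SNR means simulated noise levels are a conservative
stand-in rather than a calibrated match. Passing tests therefore
demonstrate correctness of the computational chain and the qualitative
sequence-physics effects (bias signs and orderings, CoV scales), not
quantitative agreement with any particular scanner.
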