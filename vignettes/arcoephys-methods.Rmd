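---
title: "Models and methods behind arcoephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arcoephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

arcoephys quantifies what makes the vocal-motor projection neurons of the
zebra finch robust nucleus of the arcopallium (RAPNs) fire ultranarrow
action potentials compared with their neighbours in the dorsal intermediate
arcopallium (AId), which drive non-vocal somatic movement. The package
implements the full measurement chain — spike waveform metrics, passive
membrane properties, voltage-clamp current decomposition, SWC morphometry,
in situ hybridization densitometry, and the group statistics — together
with synthetic-data generators (a conductance-based model neuron, a
morphology generator, and an image generator) so that every estimator can
be validated against known ground truth without any recorded data.

This vignette documents the models, the defaults and the numerical choices.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model neuron

A single-compartment Hodgkin–Huxley-style cell with five currents:

$$C \frac{dV}{dt} = -\big(I_{Na} + I_{Klow} + I_{Kv3} + I_{KA} +
I_{leak}\big) + I_{bias} + I_{inj}$$

- transient Na⁺: $g_{Na}\,m^3 h\,(V - 55)$,
- low-threshold delayed rectifier: $g_{Klow}\,n^4\,(V + 90)$,
- high-threshold fast Kv3-type K⁺: $g_{Kv3}\,p^2\,(V + 90)$,
- inactivating A-type K⁺: $g_{KA}\,a^3 b\,(V + 90)$,
- linear leak, plus a constant bias current that sets spontaneous firing.

Each gate follows first-order kinetics toward a Boltzmann steady state
$x_\infty(V) = 1/(1+\exp(-(V-V_{1/2})/k))$ with a bell-shaped
voltage-dependent time constant
$\tau(V) = \tau_{base} + \tau_{amp}/(e^{u} + e^{-u})$,
$u = (V - V_\tau)/\sigma_\tau$. Units are mV, ms, nS, pF, pA throughout
(nS·mV = pA, pA/pF = mV/ms).

No published conductance model exists for these cells, so the model form is
the package's own: the minimal mechanism that reproduces the qualitative
class contrasts (narrow vs broad spikes, Kv3-dependent repolarization,
high-threshold sustained K⁺ current, drug responses). It is a caricature in
the usual single-compartment sense — no dendritic cable, no stochastic
channel gating, no Ca²⁺-dependent currents — and nothing in it was fitted
to recorded traces.

### Presets

`make_preset()` returns the two study conditions:

| parameter | RAPN-like | AId-like | why |
|---|---|---|---|
| capacitance (pF) | 115 | 76 | class-mean passive measurements |
| leak (nS), E_leak (mV) | 5.7, −72 | 4.8, −72 | reciprocal of class-mean input resistance |
| g_Na (nS) | 5200 | 2400 | larger depolarization rates in RAPNs |
| g_Klow (nS) | 500 | 800 | AId relies more on a slow rectifier |
| g_Kv3 (nS) | 3400 | 400 | the central class difference (Kv3.1-rich vs poor) |
| g_KA (nS) | 300 | 350 | both classes show an A-type component |
| bias (pA) | 125 | 110 | spontaneous firing near 10–15 Hz at 24 °C |

Gating parameters are shared except the delayed rectifier: the AId-like
preset uses a slower (Kv2-like) rectifier (τ base 4 ms vs 2 ms), which
accumulates over spike trains and limits sustained firing; without it the
smaller cell would paradoxically out-fire the RAPN-like preset on current
steps. Kv3 activates at V½ = −10 mV with sub-millisecond-to-millisecond
time constants, the high-threshold fast-gating signature; the low-threshold
rectifier at −35 mV.

The Kv3 conductance ratio (8.5:1) is the lever behind every contrast the
pipeline measures: halving/doubling `kv3$g` moves half-width and maximum
repolarization rate monotonically (a property test asserts this).

### Temperature

Gating rates scale by $Q_{10,rates}^{(T-24)/10}$ with default 3.0;
active conductances by $Q_{10,cond}^{(T-24)/10}$ with default 1.5. The
leak is deliberately not temperature-scaled: it stands for the passive
membrane rather than a channel population, and scaling it would
hyperpolarize the cell at 40 °C enough to silence spontaneous firing,
contrary to the biology being emulated (both classes keep firing, faster,
at body temperature).

### Drugs

`drug_preset()` maps the pharmacology onto the conductances:

- **TEA (500 µM)**: blocks 80 % of Kv3 and 50 % of the A-type conductance;
- **4-AP (100 µM)**: blocks 70 % of each;
- **AUT5 (1 µM)**: no block; left-shifts Kv3 activation by 5 mV and divides
  its activation time constant by 1.5 (positive modulation).

The block fractions are free parameters of the synthetic preparation —
sub-millimolar TEA/4-AP sensitivity is a Kv3-family signature, but no
finch-channel dose-response data exist to pin the exact numbers. They are
config-exposed and were chosen once, with the rest of the presets.

### Integration

Exponential Euler for the gates, forward Euler for the voltage, default
`dt = 0.005` ms (stability for the fast Kv3 kinetics at 40 °C, where rates
are ~5.8× faster). Output is recorded at 100 kHz (`dt_out = 0.01` ms), the
nominal acquisition rate of the emulated rig. Divergence (|V| > 500 mV or a
non-finite state) raises an error naming `dt` and the largest |dV/dt| seen.
In voltage-clamp mode the command is imposed exactly (perfect clamp, no
series resistance), gates integrate as usual, and flags emulate the
pharmacological isolation used in the recordings: `na_disabled` silences
Na⁺ (TTX/Cd²⁺), `leak_subtract` removes the leak (P/4-style subtraction).
Simulated clamp currents are larger than the recorded ones because the
real experiments halved the intracellular K⁺ driving force and faced
imperfect space clamp; only directions and ratios are compared.

## Spike detection and waveform metrics

- **Threshold**: first sample at which the centered-difference dV/dt
  reaches 10 V/s on the rise to a peak above 0 mV. dV/dt uses raw samples —
  at 100 kHz the centered difference is stable; a quadratic
  (Savitzky–Golay-type) smoother is available but off by default.
- **Merging**: local maxima sharing a threshold crossing are one event (the
  taller peak wins), so noisy peaks cannot double-count a spike.
- **Half-width**: time between the two crossings of the voltage halfway
  between threshold and peak, with linear interpolation between samples
  (sub-sample precision matters: at 40 °C half-widths are ~0.1 ms, about
  ten samples).
- **Phase-plane rates**: extrema of dV/dt between threshold and the AHP
  window; the repolarization rate is reported as a magnitude.
- **AHP**: minimum voltage from the peak to the next spike's threshold or
  50 ms, whichever comes first. The window end is a package choice (the
  protocol leaves it unstated) and is config-exposed.
- **Amplitude**: peak minus threshold by default. The alternative
  convention (peak minus AHP trough) is computed alongside
  (`amplitude_from_ahp`) because the field uses both; with the default,
  a −55.3 mV threshold and 37.4 mV peak give 92.7 mV.
- **Percent conventions**: `fold_change()` returns post/pre and
  `percent_change()` returns 100·(post−pre)/pre. Both are reported where a
  change is quantified, since "x % larger" is ambiguous between the two in
  parts of the literature.

F-I analysis uses 1 s steps of 0–500 pA in 100 pA increments by default:
rate = spikes within the step / duration; instantaneous frequency =
1/(first interspike interval); steady-state = 1/(last interval); sweeps
with fewer than two spikes yield `NA` frequencies, never zeros.

## Passive properties

`fit_tau()` fits one or two exponentials to the onset-to-peak segment of a
hyperpolarizing step (the window ends at the first extremum of the
smoothed deflection, so slow inward rectification cannot contaminate the
fit), selects the order by corrected AIC, and reports the
amplitude-weighted time constant. Two guards keep the two-exponential fit
identifiable: time constants are bounded above by 3× the fit window, and a
second component carrying under 2 % of the amplitude (or pinned at the
bound) falls back to the single-exponential fit — with 0.2 mV acquisition
noise such components are noise fitting and would otherwise bias the
weighted τ upward. `input_resistance()` is the least-squares V–I slope;
`capacitance_and_area()` applies τ = R·C and converts capacitance to area
with an assumed specific capacitance of 1 µF/cm² (1 pF ↔ 100 µm²), the
textbook value; it is a parameter, not a measurement. Because class means
of τ, R and C come from per-cell averages, τ̄ ≠ R̄·C̄; all recovery checks
run per cell.

## Voltage-clamp metrics

The A-type transient peak is the maximum within 20 ms of step onset
(printed times-to-peak are 4–7 ms); a maximum at the window's end means a
non-peaking current and yields `NA` A-type fields with inactivation ratio
1. The sustained current is read 200 ms after onset as a ±0.5 ms windowed
mean (point sampling vs short window is unstated in the source protocol;
the window buys noise robustness and is configurable). The degree of
inactivation divides the current 8 ms after the transient peak by the peak;
for a planted exponential decay this equals $e^{-8/\tau}$ exactly, which
the tests assert to 4 significant figures. Drug-sensitive currents come
from samplewise subtraction of matched sweeps, which is exact by
construction — a property test recovers a planted 80 % Kv3 block to
machine precision.

## Morphometry

Conventions, in the order the estimators apply them:

- **SWC**: standard 7 columns; one root; spines are type-5 nodes annotated
  in a JSON sidecar as node-id chains (single- or multi-point). An optional
  Z rescale on read restores isotropy after tissue compression.
- **Sholl**: crossings of concentric circles (2D projection, default,
  matching maximum-projection image analysis) or spheres (3D) centered on
  the root, counted exactly by solving the per-segment quadratic; default
  radii 20–200 µm in 20 µm steps. A dense-resampling counter serves as the
  test oracle.
- **Spine density, segment mode**: spines on the first 30 µm of segments
  lying after the second branch point, divided by 30, averaged over up to
  four segments — the classical image-based protocol.
- **Spine density, rolling mode**: a 20-SWC-point window advanced one
  point at a time; the density is the attached-spine count divided by the
  path length *owned* by the window's nodes (half of each adjacent
  inter-node step). Ownership normalization makes the estimator exact for
  uniformly planted spines regardless of node/spine alignment, which the
  acceptance suite exploits (50 spines on 100 µm → 0.5 µm⁻¹ exactly).
  Segments branching off the soma with fewer than 10 spines, and segments
  shorter than 20 µm, are excluded from per-segment averages.
- **Spine geometry**: single-point spines are spheres with a cylindrical
  neck of radius 0.066 µm; the neck length is the attachment-to-head
  distance minus the head radius, floored at zero (the source protocol
  leaves neck length undefined). Multi-point spines use frustum lateral
  areas plus a hemispherical dome on the last point; the attachment end is
  left open. Volumes sum node-sphere volumes in both cases — areas from
  frusta but volumes from spheres is internally inconsistent for
  multi-point chains, but it is implemented as specified by the protocol
  being reproduced.
- **Dendrites**: length sums inter-node distances; area sums lateral
  frustum areas π(r₁+r₂)·slant; volume voxelizes the union of frustum
  bodies (default 0.1 µm voxels) so branch-point overlap is counted once.
  End caps are not voxelized — with them, the estimator could not converge
  to πr²L on a cylinder, the calibration case. Edges leaving the soma are
  truncated at the soma surface and treated as cylinders of the child
  radius; the interior belongs to the soma.
- **Soma**: contours resampled to 20 equally spaced vertices;
  correspondence between adjacent slices by minimizing total inter-vertex
  distance over cyclic shifts and flips; a three-point moving average along
  Z smooths the vertex chains; triangle bands plus the two cap areas give
  the surface, minus πr² per attached dendrite; the volume is the
  signed-tetrahedron sum over the closed triangulated surface. On a 10 µm
  sphere at 0.25 µm slices both land within 3 % of the analytic values,
  with errors decreasing monotonically in slice thickness (the 20-gon
  perimeter deficit, ~1.6 % on area, dominates the residual).
- **Shrinkage**: "≤ 20 % shrinkage" is ambiguous between linear and areal;
  the areal reading (divide areas by 0.8) reproduces the printed adjusted
  totals and is the default; a linear mode (divide by 0.8²) is offered.

The morphology generator plants parametric trees (aspinous trunk, spines at
a set density on all branches past the first branch point, log-normal-ish
head radii) with analytic ground truth for length, area, volume and spine
geometry; generated trees round-trip through the estimators exactly for
length/area and within 2 % for voxelized volume.

## ISH quantification

Mean pixel intensity (0–256 scale) over a 200×200 µm window minus an
adjacent cell-free control window gives the net OD; ratios of net ODs give
expression ratios. Cell counting binarizes at 2.5× the background level,
applies one binary opening then one closing with a 3×3 box (the "standard
binary filters" of the emulated FIJI workflow, delegated to EBImage),
labels 8-connected components, and keeps those of 10–500 px² whose
centroid falls inside the window (centroid containment is the border
tie-break). Chromogenic dark-on-light images are inverted to
signal-positive before thresholding (`invert = TRUE`). The image generator
plants disk-shaped cells over uniform background with optional Gaussian
noise; counting is exact for well-separated disks and matches a flood-fill
oracle on touching ones.

## Statistics

`compare_groups()` implements the selection rule: two-tailed pooled-variance
Student's t if both samples pass Shapiro–Wilk and an F-test of equal
variances at α = 0.05, otherwise Mann–Whitney U; for paired data the
diagnostics run on the differences (paired t vs Wilcoxon signed-rank). The
selection α and tests are configurable; the rule is deterministic given the
data, and its type-I error is calibrated at 0.05 ± 0.02 over 2000 null
simulations in the acceptance suite. Factorial designs use `stats::aov`
with Tukey HSD; fully within-subject two-way designs use a
repeated-measures ANOVA with Greenhouse–Geisser-corrected fractional
degrees of freedom computed from each effect's subject-by-condition
covariance (the F values are checked against `aov` error strata under
compound symmetry).

## What the synthetic data do and do not show

The generators reproduce the *structure* of the study's data — step
protocols at 100 kHz, narrow-vs-broad spike phenotypes, a high-threshold
TEA-sensitive current, planted spines and somata of known geometry, labeled
cells over background — under known ground truth. They do not reproduce
electrode artifacts, imperfect space clamp, liquid-junction offsets (the
recordings were deliberately left uncorrected), bursting, channel noise,
tissue autofluorescence or segmentation ambiguity in real micrographs.
Passing tests therefore establish that the estimators are correct and
well-conditioned, not that they would be unbiased on any particular rig's
recordings.

## Problem sizes

Default analyses use 2 s spontaneous sweeps (first 300 ms discarded as the
settle transient), 1 s current steps at six levels, 200 ms clamp steps, 20
replicates for RC parameter recovery, 0.25 µm soma slices, 0.1 µm voxels on
the calibration cylinder (0.2 µm on full trees), 400×400 px images, and
2000 null datasets for the type-I calibration. These sizes make every
estimate stable to well inside its acceptance tolerance; all are
config-exposed for larger runs.
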