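---
title: "Mapping irritative zones from scalp EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping irritative zones from scalp EEG: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

irritmap localizes the cortical generators of interictal epileptiform
discharges (IEDs) from multichannel scalp EEG and supports the downstream
histological comparison of the identified *irritative zone* (target) with its
contralateral healthy control. This vignette is the package's own account of
the models it implements, the tunable parameters that matter, the choices
made where the design was genuinely open, and what the simulation-based tests
do and do not establish.

## The pipeline at a glance

1. **Forward model** — a lead field maps dipole moments (nA·m) to electrode
   potentials (µV), either by the analytic multi-shell sphere series or by a
   boundary-element model (BEM) on nested triangulated surfaces.
2. **Detection** — threshold detection of transient discharges on the spike
   (15–50 Hz), sharp-wave (5–15 Hz) and broadband streams; event durations
   (FWHM) split the events into spikes (20–70 ms) and sharp-waves
   (70–200 ms).
3. **Classification** — per duration class, the epochs form an
   electrodes × time × samples tensor `V = Σ_f f_e ⊗ f_t ⊗ f_s + E`,
   decomposed by constrained PARAFAC; k-means on the sample signatures
   separates IED subtypes, and a consolidation pass refines the assignment.
4. **Localization** — sLORETA inverts each subtype's mean topography at the
   two-thirds-of-peak latency; the most frequent subtype's peak parcel is the
   target, its mirrored parcel the control, which must be silent for every
   subtype.
5. **Sectioning** — atlas coordinates are rescaled by the shrinkage factor
   `α = L / (a − p)` to cut the histology block.
6. **Histology statistics** — stained-area and object-count quantification,
   then a normality-gated paired test (paired t vs exact Wilcoxon
   signed-rank) per marker.

## Forward models

The **multi-shell sphere** solves the Poisson problem for concentric shells
with an insulating exterior by a Legendre series. Per harmonic degree the
radial coefficients follow from the continuity of potential and normal
current at each interface (a small linear system per degree); the series is
truncated at 100 terms with an early stop once a term contributes less than
1e-12 of the running maximum. At the largest supported eccentricity (0.9 of
the innermost radius) the truncation tail is below 1e-10 relative, which is
what the 1e-6 agreement with the closed-form homogeneous solution requires —
a 60-term default, attractive for speed, cannot reach that tolerance in
worst-case geometry. Units are fixed throughout: mm, S/m, nA·m, µV.

The **closed-form homogeneous-sphere potential** is implemented as a
separate code path (generating-function sums of the Legendre series) and
serves as the independent oracle for the shell code with equal
conductivities.

The **BEM** discretizes the double-layer boundary integral equation with
collocation at mesh vertices and linear interpolation of the surface
potential. Triangle integrals use adaptive midpoint quadrature whose constant
part is corrected to the exact van Oosterom–Strackee triangle solid angle;
the self (vertex-adjacent) lump is fixed by the interior 4π identity, so the
discrete operator is exact on constants. The rank-1 null space of the
exterior Neumann problem (potentials defined up to a constant) is removed by
deflation, and electrodes snap to the nearest scalp vertex (error above 2 mm
aborts). On nested spherical meshes with 2562 vertices per surface the model
agrees with the analytic sphere to a relative difference measure below 0.05
for tangential dipoles up to eccentricity 0.8, and the error falls
monotonically with mesh refinement. No isolated-skull approach is
implemented: the fixture conductivities (0.33 / 0.165 / 0.33 S/m, a mild 2:1
skull contrast) are **configuration, not claimed tissue values** — the
underlying methodology does not state its compartment conductivities.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which everything downstream is validated.

* **Templates** are unit-peak asymmetric bi-Gaussians (fast rise, slower
  decay) whose FWHM equals the nominal duration exactly
  (`FWHM = (σ_rise + σ_decay)·√(2 ln 2)`). The default asymmetry of 8 gives
  the waveform a sharp rising edge. This matters spectrally: a smooth bump
  whose FWHM sits in the 20–70 ms band carries most of its energy *below*
  the 15–50 Hz spike band, so without a fast edge the band streams would
  barely see the events they are named after. Durations outside the class
  band raise an error.
* **Recordings** are sums of `amplitude × lead-field column × template` over
  scheduled events plus background noise: a mixture of white Gaussian and
  AR(1) (coefficient 0.95) components, mixed by `pink_fraction` and scaled so
  that the mean event peak on the best channel over the background SD equals
  the target SNR. Event times keep a global minimum gap (500 ms default,
  enforced across subtypes) so extraction epochs never overlap. All
  randomness derives from one seed; repeated calls are byte-identical.
* **Histology tables** draw six replicate measurements per zone, region and
  marker around `baseline × (1 + effect)` means with a zone-level
  multiplicative random effect shared between the paired regions
  (`zone_sd = 0.15`) and replicate noise (`noise_sd = 0.35` of baseline).
  With these defaults a relative effect of ≈0.3–0.5 corresponds to a paired
  standardized effect d ≈ 1.5–2 at N = 8 zones, the regime in which most
  markers reach significance. Count-type markers are rounded to integers.

What the generator does **not** emulate: muscle/eye artifacts,
non-stationary background, waveform variability within a subtype,
propagation (each subtype is one fixed dipole), co-registration error, or
realistic microscope images (only disc-shaped blobs with Gaussian noise).
Passing tests therefore demonstrate correctness of the algorithms under
controlled conditions, not clinical performance.

## Detection

The detection statistic pools channels: each channel is robust-standardized
(deviation from its median over 1.4826×MAD, falling back to the SD for
mostly-zero noiseless traces), and the across-channel mean square — corrected
by a 1.5 s running-median baseline that tracks slow background power, then
smoothed with a 10 ms Gaussian matched to half the shortest admissible
IED — is thresholded at its median plus `k_sd = 4` robust SDs. Pooling is
essential: at SNR 5 a per-channel threshold leaves single-channel event
peaks at barely 1.0–1.4× the threshold and cannot reach 95% sensitivity at
5% false discoveries, while the coherent multichannel projection stands
several-fold above the pooled noise floor. Candidates within a 300 ms
refractory window merge (largest peak wins); events must be supported by at
least two channels and must also pass the same threshold on the broadband
measurement recording.

Durations are the FWHM of the multichannel envelope
`√(mean-square excess)` — proportional to |waveform| for a single
discharge — with the smoothing kernel removed in quadrature; peak times are
refined on the unsmoothed envelope because smoothing shifts the mode of
asymmetric waveforms. Durations in [20, 70) ms classify as spikes,
[70, 200] ms as sharp-waves (the boundary value belongs to the sharp-wave
band); durations outside [20, 200] ms are discarded. Duplicate detections
across streams (within 30 ms) resolve in favor of the spike stream.

## Classification

Per duration class, epochs (default 300 ms, baseline = mean of the first
20% of the window) are cut from the **broadband** recording: the 5–15 Hz
band preserves little of a 120 ms bump's energy and its ringing corrupts
the downstream latency analysis, so the band streams separate kinds but do
not feed the tensors.

**PARAFAC** is fitted by alternating least squares with per-mode
constraints: orthonormal columns via an orthogonal Procrustes step,
non-negativity via an exact subset-enumeration NNLS on the Gram matrix.
The fit is non-decreasing across iterations (asserted every run); the best
of several seeded restarts is kept. The defaults place **orthogonality on
the spatial mode** and non-negativity on the sample mode. This placement is
a deliberate choice: discharge waveforms of one duration class are nearly
parallel in time, so temporal orthogonality would force the second factor
away from exactly the same-waveform/different-generator structure the
decomposition must separate, and in simulation it collapses subtype
recovery on a large fraction of runs. Distinct cortical generators, by
contrast, project near-orthogonal average-referenced scalp patterns. Both
constraints remain configurable per mode.

**Rank selection** scans F = 1..max and keeps the largest F that passes two
diagnostics computed on unconstrained scan fits (constraint projections
regularize the core and mask over-factoring): CORCONDIA ≥ 80, and
split-half factor stability ≥ 0.6 — each factor must replicate
(spatial × temporal congruence) across models fitted on disjoint halves of
the samples. CORCONDIA is 100 by definition at F = 1, so a smallest-F rule
would be vacuous; and on weak-signal tensors CORCONDIA alone stays high for
ranks whose extra factors are pure noise, which is exactly what the
stability criterion catches (observed stability is bimodal: 0.78–0.92 at
true ranks, ≤ 0.45 above them; 0.6 sits between the modes).

**Clustering** runs k-means on unit-normalized sample-signature rows — a
subtype is a *direction* in atom space, while row norms carry per-event
amplitude and noise that otherwise dominate the Euclidean distance. The gap
statistic decides whether any structure exists at all (the silhouette
cannot prefer k = 1); given structure, the silhouette picks k, capped at
the selected rank (a subtype expresses a dominant atom).

**Consolidation.** Duration estimates near the 70 ms boundary are noisy at
realistic SNR, so some events enter the wrong duration class and are
unreachable by per-class clustering. After the per-stream solution, every
epoch is reassigned to the cluster mean (across both classes) it correlates
with best — one nearest-centroid pass in epoch space, iterated to
stability — and clusters whose mean time courses coincide after
disattenuating by split-half reliability (Spearman–Brown corrected) are
merged as duplicate views of one subtype. Cluster-mean IEDs ("mean value X")
are then simple averages over members.

## Localization and target selection

sLORETA computes the minimum-norm estimate
`j = Gᵀ (G Gᵀ + λH)⁺ v` (H the average-reference operator,
`λ = lambda_rel · trace(G Gᵀ)/n`) and standardizes it by the diagonal
(blocks) of the resolution kernel `S = Gᵀ (G Gᵀ + λH)⁺ G`; free-orientation
sources use the 3×3 block form. Both the lead field and the topography must
be average-referenced (enforced). For noiseless topographies the power
maximum sits exactly at a true single source (verified exhaustively on the
toy source space), and `lambda_rel = 1e-4` is the default. For cluster means
of ~20 noisy events the pipeline uses `lambda_rel = 0.05`: the
standardization *amplifies* noise at low-gain edge sources as λ shrinks
(measured contralateral leakage grows from ~0.08 of peak at λ_rel = 0.1 to
~0.77 at 1e-3), so more regularization — not less — keeps the silence
criterion meaningful while leaving peak parcels unchanged.

The analysis latency is the first rising-phase crossing of two thirds of
the global-field-power peak (across-channel SD per time point), linearly
interpolated and snapped to the nearest sample; the falling phase is
available as an option. Parcel power pools member sources by the mean
(stabler under discretization; max is exposed as an alternative — for
sources on a parcel boundary the mean statistic can prefer the neighboring
parcel). The **target** is the peak parcel of the most frequent subtype
(ties break by peak power), the **control** its contralateral partner
(right ids 1–48 pair with left ids 49–96), and the **silence verdict**
requires every subtype's control-parcel power to stay below
`silence_ratio = 0.2` of that subtype's own peak power. Normalizing by the
subtype's peak rather than its power at the target parcel keeps the
criterion meaningful for subtypes generated far from the target, where both
quantities would otherwise be ratios of numerical noise.

## Sectioning

`shrink_factor(L, a, p) = L / (a − p)` converts the measured specimen
length into the shrinkage factor α; the atlas anterior extent is 5.6 mm in
the coordinate system used, while the posterior extent must be supplied by
the caller (no default is assumed). `atlas_to_specimen()` scales
Bregma-referenced coordinates (anterior positive, origin preserved);
`sectioning_plan()` assembles B2 (anterior cortex → Bregma) and l (Bregma →
block center) with the scaled block limits.

## Histology quantification and statistics

Images are background-subtracted by a morphological top-hat (disc radius 15
px by default), binarized at an intensity quantile (0.95 — the "frequency
threshold" is interpreted as an intensity-quantile threshold), and connected
components under 8-connectivity smaller than `min_object_px` are discarded;
the stained-area fraction and the object count follow. The replicate
measurements (six images per region) are averaged to one value per zone
before pairing: the unit of analysis is the zone. A Shapiro–Wilk test on
the paired differences at α = 0.05 gates between the paired t-test and the
exact Wilcoxon signed-rank test, whose null distribution is built from all
2ⁿ sign assignments (convolution over doubled mid-ranks, so ties are
handled exactly) up to n = 25 and by a tie-corrected,
continuity-corrected normal approximation beyond. Stars follow the usual
convention (* < 0.05, ** < 0.01, *** < 0.001), and no multiple-testing
correction is applied by default — each marker is reported at its nominal
level, matching the reporting convention the package mirrors; Holm
correction is available via `p_adjust`.

## Problem sizes used by the tests

The simulation studies run at desk scale, chosen once: a 3-shell sphere head
at rat dimensions (radii 7.9/8.6/9.2 mm), 32 electrodes on the upper cap,
192 radial sources in 8 mirrored lateral parcels per hemisphere at 6.3 mm,
2-minute recordings at 500 Hz with three IED subtypes (40 and 55 ms spikes,
a 120 ms sharp-wave; 20 events each; SNR 5), BEM meshes of 162–2562
vertices per surface, and 8-zone histology tables with six replicates.
Statistical calibrations use 2000 simulations; the end-to-end study uses 20
seeded recordings.

## Known limitations

* The BEM has no isolated-skull correction; strongly insulating skull
  compartments (realistic 1:20+ contrasts) would need it.
* Subtypes are modeled as single fixed dipoles; extended or propagating
  sources will smear topographies and can shift peak parcels.
* The duration-band split inherits the ambiguity of any width estimate at
  realistic SNR near the 70 ms boundary; the consolidation pass compensates
  within the pipeline but standalone `detect_events()` output retains it.
* The sample-signature clustering assumes subtypes express distinct atoms;
  two generators with both near-identical waveforms *and* strongly
  overlapping topographies are not separable by construction.
* Histology quantification is a contract on synthetic blob images; real
  immunofluorescence (uneven illumination, z-stacks, touching cells) is out
  of scope.
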