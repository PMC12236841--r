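---
title: "Methods: synthetic ground truth, synapse quantification and auditory metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ground truth, synapse quantification and auditory metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaquant)
```

# Scope

`cochleaquant` implements the quantification machinery used in studies of
cochlear synaptopathy and efferent (medial olivocochlear) modulation of
hearing development:

* **counting** of presynaptic ribbons (CtBP2), postsynaptic AMPA-receptor
  patches (GluA2) and their colocalized pairs per inner hair cell (IHC) on
  maximum projections of confocal z-stacks;
* **volumetry** of the same objects in 3D after Richardson–Lucy
  deconvolution, with a 20–2000 voxel size gate;
* **ABR** wave-1 amplitude/latency extraction and threshold detection from
  level-graded averaged waveforms;
* **DPOAE** extraction of the 2f1−f2 distortion product, noise floor and
  threshold;
* the **gated statistical decision tree** (Shapiro–Wilk gate; t-test /
  one-way ANOVA + Holm–Šidák on the parametric branch, Mann–Whitney /
  Kruskal–Wallis + Dunn on the nonparametric branch).

Because raw images and waveforms from such studies are rarely deposited,
every input is also *synthesizable* with planted ground truth, so each stage
of the pipeline can be benchmarked against known answers.

# The synthetic-data generator

## What it emulates

`plant_ground_truth()` builds a row of IHCs (default 10 per field, elliptical
footprints about 8 × 10 µm) and plants a configurable number of synaptic
pairs per cell (default 16) plus unpaired "orphans" at a configurable rate
(default 5% per channel). Real ribbon synapses form a ring around the
basolateral pole of the IHC; the generator reproduces this by placing puncta
on a basal ring at 75–95% of the footprint radius, with slots uniform in
*arc length* (not parametric angle) and small angular jitter. This gives
nearest-neighbour spacings of ~1.2–1.5 µm in the projection plane for
16 synapses/cell — the regime in which projection-based counting is
feasible, as it is in real material. Each receptor punctum is offset from
its ribbon by a synaptic-cleft distance (default 0.3 µm) directed radially
outward with a random axial tilt.

Punctum volumes default to a lognormal with median 0.15 µm³ truncated to
[0.06, 1.2] µm³, inside the 0.04–5 µm³ range a synapse can plausibly occupy.

`render_stack()` rasterizes each punctum as a solid ellipsoid of its planted
volume (axial elongation equal to the PSF anisotropy σ_z/σ_xy), convolves
with a separable 3D Gaussian PSF (defaults σ_xy = 0.2 µm, σ_z = 0.5 µm — a
standard confocal approximation; the acquisition pixel is 0.11 µm, the
z-step 0.2 µm by default with 0.3 µm supported for counting-style stacks;
projection-based counting is insensitive to the z-step), then applies
Poisson shot noise plus Gaussian read noise over a constant background
(defaults: peak photon scale 150, background 10, read σ = 2 — peak SNR ≈ 12,
comfortably above the SNR ≥ 5 regime the counting accuracy statement
assumes). No voxel saturates under default gain.

`simulate_abr_series()` generates per-level epoch sets (default 1024 epochs,
alternating stimulus polarity) containing noise only below the planted
threshold and a sum-of-Gaussians wave template (P1 at 1.5 ms, N1 at 2.1 ms,
then smaller wave-2/3 structure) whose scale grows linearly in dB above
threshold (0.5 µV at threshold + 0.15 µV/dB). An optional stimulus artifact
flips with polarity and cancels in the average. Split-half sub-averages are
polarity-balanced and stored for repeatability testing.

`simulate_ear_canal()` synthesizes f1 and f2 primaries (f2/f1 = 1.2, L2 =
L1 − 10), an optional 2f1−f2 component at a planted level, and white noise
calibrated so that its *measured* floor under the default spectral analysis
equals the requested dB value (Rayleigh-mean algebra for windowed white
noise). `simulate_dpoae_ladder()` plants an emission threshold on the
f2-level axis: no emission below it; at and above it the DP starts 6 dB over
the floor and grows at 1.2 dB/dB.

`simulate_cohort()` draws per-animal metric values from an effect table
(most-specific-match lookup over genotype/arm/age/frequency), normal or
moment-matched lognormal, with optional upper censoring (e.g. thresholds not
measurable above 80 dB SPL).

## What it does not emulate

No optical physics beyond Gaussian blur (no spherical aberration, depth
-dependent PSF, bleaching or chromatic offsets); no cochlear mechanics or
acoustics (the DP is planted phenomenologically, not generated by a
nonlinearity); hair-cell channels are clean ellipses rather than textured
cytoplasm; cell density and synapse spacing are regular compared with real
whole mounts. Passing recovery tests therefore demonstrates that the
*measurement machinery* is unbiased and self-consistent under realistic
noise — not that it would be robust to every staining or acquisition
pathology of real tissue.

# The counting pipeline

Per channel: maximum projection → binarization → 8-connected particle
analysis per IHC region of interest (ROI).

**Thresholding.** Two scale-covariant methods are available and logged with
every run: `robust_background` (median + k·MAD, default k = 4) and `otsu`.
The robust-background method is the default for the sparse puncta channels.
For the *cell* channel used in automatic ROI derivation the default is Otsu:
that image is bimodal with ~50% foreground, where background statistics
(median/MAD) straddle the two modes and become meaningless.

**Colocalization.** The two synaptic-channel projections are multiplied
into a wide-dynamic-range merged image (`multiply_then_binarize`, the
default order; a `binarize_then_multiply` mask intersection is available
behind the same flag). Two numerical details matter:

* the projections are median-background-subtracted before multiplication —
  otherwise the background × signal cross-term lets every single-channel
  punctum survive in the product and inflates the colocalized count;
* the product is binarized at the *product of the single-channel
  above-background thresholds* rather than by a histogram method applied to
  the product itself: the subtracted product image is mostly exact zeros, so
  its MAD is 0 and any background-statistics threshold degenerates. The
  derived threshold is scale-covariant (a global intensity rescale of both
  channels leaves all counts unchanged, which the tests assert).

**ROIs.** Automatic ROI derivation thresholds the cell projection, fills
holes, splits touching cells by watershed on the distance transform, and
discards cells touching the field border. Each ROI is then expanded into its
Voronoi neighbourhood by up to ~1.5 µm beyond the cell mask. This mirrors
the generous hand-drawn ROIs of bench practice: synapses sit at the
basolateral *margin* of the cell, and an ROI clipped exactly at the
footprint boundary systematically loses outward-lying receptor puncta.
Expanded ROIs remain mutually disjoint; particles are assigned to ROIs by
rounded-centroid membership, which is deterministic and tie-free.

**Particles.** 8-connectivity, minimum area 4 px (≈0.05 µm² at 0.11 µm
pixels — below the smallest admissible synapse footprint, so it only rejects
noise specks). Connected-component labelling is implemented in C++ and is
tested for exact agreement with an independent plain-R flood-fill oracle.

# The volumetric pipeline

**Richardson–Lucy.** Standard multiplicative iterations with reflective
boundary handling (avoids edge ringing on small fields), default 10
iterations. With a normalized PSF the scheme conserves flux on
interior-supported images (asserted to 0.1%), is the identity for a delta
PSF, and leaves uniform images fixed.

**Segmentation and the voxel gate.** The deconvolved stack is thresholded
(robust background by default, logged), 26-connected components are
labelled, and components outside 20–2000 voxels are discarded. At the
default 0.11 × 0.11 × 0.2 µm voxel this gate spans 0.0484–4.84 µm³, the
operative form of the 0.04–5 µm³ biological range (the voxel gate, not the
µm³ bounds, is what is enforced). Labels are deterministic — objects are
numbered by the (z, y, x) position of their first voxel. Border-touching
objects are kept but flagged; any object thinner than 2 voxels along an axis
is flagged as below the instrument resolution limit.

**Per-object half-max refinement.** A single global background-statistics
threshold individualizes objects well but sits at a few percent of a
punctum's peak, so raw component volumes are inflated ~3×. Interactive 3D
object counting resolves this by letting the operator adjust the threshold
until measured volumes are sensible; the automated counterpart implemented
here refines each detected object to the voxels above a fixed fraction of
its own peak intensity (above background) before the size gate is applied.
The default fraction 1/3 was calibrated once on the synthetic forward model:
across 0.1–1 µm³ objects at the default PSF and 10 RL iterations it
approximately zeroes the median volume bias (half-max proper, fraction 0.5,
under-measures these sub-PSF-scale objects by ~50% because deconvolution
leaves their profiles peaked rather than flat-topped). The residual
size-dependent bias is tracked, not hidden: the acceptance suite requires
median |relative volume error| ≤ 25%, and measures ~21%.

**Pairing.** Candidate ribbon–receptor pairs that share ≥1 voxel are matched
greedily by descending overlap; remaining objects are matched greedily by
ascending centroid distance up to 1.0 µm. Matching is one-to-one; unmatched
objects are reported as orphans. On default stacks ≥95% of planted pairs are
recovered with no orphan–orphan false pairs beyond occasional coincidences.

# ABR analysis

Averaging is the arithmetic mean over epochs; polarity labels are used only
to keep the split halves balanced (the neural response is polarity
-invariant, while stimulus artifacts flip and cancel — suppressed by ≥40 dB
in the tests). A zero-phase 0.3–3 kHz Butterworth bandpass mirroring the
hardware passband can be applied when raw epochs are supplied.

Wave-1 amplitude is peak-to-peak in a configurable search window (default
1.0–2.5 ms post-onset; the window is a package choice — published protocols
rarely state theirs). The default convention is P1-then-trough (window
maximum minus the following minimum), which reads "difference between the
maximum and minimum peaks" in the way that prevents wave-2 structure from
supplying the peak; a `global` max-minus-min mode is available behind a
flag. Latency is the time of the P1 maximum.

"Lowest level with a repeatable wave 1" is a human visual judgment; it is
formalized here as: a level *responds* when (a) wave-1 amplitude exceeds
3 × the RMS of the pre-stimulus baseline of the average and (b) the two
polarity-balanced split-half sub-averages correlate ≥0.5 inside the wave
window. The threshold is the lowest level such that it *and every higher
tested level* respond; with no responding level the result is censored
(no response at the 80 dB SPL ceiling). Both criteria are configurable and
logged. This rule is monotone: adding a response at a higher level can never
raise the threshold.

# DPOAE analysis

Spectral estimation is a Welch-style average of Hann-windowed segments
(default 3 × 0.5 s, i.e. 2 Hz bins at the 4 µs sampling of the standard
acquisition). Amplitudes are calibrated so a pure tone at a bin centre reads
its time-domain level; between-bin tones scallop by up to ~1.4 dB with the
Hann window, so the standard test frequencies are chosen on-grid (e.g. f2 =
12000 or 22650 Hz put f1, f2 and 2f1−f2 all on 2 Hz and 5 Hz grids). The DP
level is read at the bin nearest 2f1−f2; the noise floor is the mean
amplitude of 5 bins per side with a 1-bin guard, excluding bins near the
primaries; SNR is the ratio of linear amplitudes.

**Threshold rule.** The criterion "lowest f2 level with signal-to-noise
ratio > 1" cannot be applied literally bin-by-bin: a noise-only DP bin
exceeds the mean of its neighbour bins ~46% of the time (Rayleigh
statistics), so the literal first crossing would sit far below any real
emission threshold on every run. The default rule therefore demands the
criterion *sustained* (at the level and all higher levels) and *repeatable*
(SNR > 1 in each Welch segment individually) — the same formalization of
repeatability used for ABR. The literal reading remains available as
`rule = "first"`. The Monte-Carlo recovery tests run the ladder at
fs = 62.5 kHz and 0.6 s recordings (3 × 0.2 s segments, 5 Hz bins) — the
same analysis geometry at a problem size convenient for 100-replicate runs.

# The statistical decision tree

`residual_normality()` applies Shapiro–Wilk to the pooled within-group
residuals; p > 0.05 routes to the parametric branch. Groups with n < 3 or
zero residual variance force the nonparametric branch with a warning.
Routing is then exactly: two groups → t-test (pooled variance) or
Mann–Whitney U; three or more → one-way ANOVA with Holm–Šidák post hoc
contrasts, or Kruskal–Wallis with Dunn's rank contrasts. Dunn z statistics
use tie-corrected pooled-rank variance; both post hoc families use the
step-down Šidák adjustment (adjusted p = 1 − (1 − p)^(m−k+1), monotonicity
enforced), so the two branches are corrected in parallel. Adjusted p-values
always dominate raw ones. Both post hoc procedures are implemented in the
package because no installed package provides them; each is verified against
first-principles arithmetic in the tests.

The *gated* pipeline (gate + routed test) holds its nominal 5% type-I error
on null cohorts — Gaussian and skewed (lognormal) — at n = 10/group within
[0.035, 0.065] over 2000 replicates; the acceptance script recomputes this.

Censored values (e.g. "no response at 80 dB SPL") are excluded from
comparisons with the excluded count reported per comparison — a reporting
rule the package makes explicit because published methods usually do not.

# Determinism and problem sizes

Every generator is a pure function of its configuration and an integer seed
(byte-identical outputs on repeat, asserted in tests); analysis functions
are deterministic, including tie-breaks (label order, centroid rounding,
greedy matching order). The recovery suites use: 20 stacks of 10 IHCs × 16
pairs for counting and volumetry; 100 seeded series/ladders for ABR and
DPOAE threshold recovery; 2000 null cohorts per distribution family for the
type-I calibration. These sizes give Monte-Carlo standard errors well inside
the asserted margins while keeping a full run in minutes on one core.

# Known limitations

* The half-max refinement fraction is calibrated for the default PSF and
  0.1–1 µm³ objects; strongly different optics or much larger objects want
  re-calibration (the forward model makes that a one-liner).
* Projection-based counting saturates when puncta overlap in projection;
  beyond ~20 well-spaced synapses per IHC ring the 2D method undercounts by
  construction, which is a property of the method, not of this
  implementation.
* The DPOAE noise-floor calibration is defined with respect to the default
  analysis window; measuring a recording with a very different segment
  length changes the measured floor (as it does on real hardware).
* The statistical module implements per-frequency comparisons (matching the
  reported layout of such studies); it deliberately omits mixed-effects
  modelling of repeated measures across ages.
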