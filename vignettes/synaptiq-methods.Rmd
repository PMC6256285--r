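---
title: "synaptiq: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synaptiq: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
```

# Scope

`synaptiq` quantifies synaptic biology from two kinds of primary data:
multi-channel 3D fluorescence stacks of immunostained dendrites, and
whole-cell voltage-clamp recordings. It covers the full measurement chain —
preprocessing, 3D puncta segmentation, object-based colocalization,
spine/shaft enrichment, miniature-EPSC detection and kinetics, evoked I/V
rectification, spine ΔF/F₀ transients, and the cohort-based statistical
layer — together with ground-truthed synthetic generators for all of these
inputs, so that every stage can be validated without access to primary
recordings.

All voxel grids use 0-based `(z, y, x)` coordinates with half-open ranges;
physical sizes are micrometres, currents picoamps, potentials millivolts,
sampling rates hertz.

# Synthetic data: what it emulates and what it does not

The generators define the conditions under which the pipeline is tested.

**Dendrite stacks** (`gen_dendrite_stack`). Puncta are rendered as 3D
Gaussians with sigma equal to half the punctum radius, which permits
sub-voxel positioning and a well-defined ground-truth centroid; rendering
is truncated at 3 sigma so noiseless fixtures have compact support. The
optical chain is a Gaussian PSF (default sigma 0.2 µm, i.e. 2 px in-plane
at the default 0.3 × 0.1 × 0.1 µm voxel), then optional Poisson resampling
(shot noise) followed by additive Gaussian read noise — the standard
camera model. Geometry: puncta occupy a shaft tube (lateral spread ±1 µm)
and spine heads 1.1–1.5 µm off the shaft; non-partner puncta keep a
minimum separation of 1 µm so that *programmed* coincidence is the only
source of cross-channel overlap, and coincident partners are jittered at
most one voxel apart (near-but-not-identical colocalization). A request
that cannot be placed at this separation raises an error rather than
silently truncating. Defaults (60 µm → 30 puncta/channel, amplitude 150,
radius 0.35 µm) give post-PSF peak intensities near 43, so Gaussian noise
of SD 5.4 corresponds to a peak SNR of about 8 — a mid-quality confocal
acquisition. Not modeled: optical aberrations, drift, bleaching, uneven
illumination.

**mEPSC traces** (`gen_mepsc_trace`). Events are differences of
exponentials normalized to unit peak, negative-going (inward currents),
with Poisson timing and lognormal amplitudes (median 20 pA), on Gaussian
noise at 20 kHz — the conventional acquisition rate. Event overlap is
possible, as in real recordings; seal instability and slow drift are not
modeled.

**I/V sweep families** (`gen_iv_sweeps`). The voltage dependence of the
evoked AMPAR conductance is a sigmoidal outward block,

$$g(V) = g_0\left(1 - \frac{d}{1 + e^{-(V - V_{1/2})/k}}\right), \qquad
I(V) = g(V)\,(V - V_{rev}),$$

a phenomenological stand-in for the polyamine block of GluA2-lacking
receptors at depolarized potentials. The *true* rectification index is
computed in closed form as the ratio of ordinary-least-squares I/V slopes
on the noiseless model currents below vs above the reversal, with the same
branch rule the analysis uses — for `block_depth = 0` this is exactly 1.
One non-obvious regime: with a *complete* block (`d = 1`,
`V_1/2 = 20 mV`, `k = 10 mV`) the depolarized-branch currents shrink with
further depolarization, so the positive-branch slope is negative and the
slope-ratio RI is negative rather than "very large"; RI grows
monotonically with block depth only while the depolarized branch remains
conductive (up to d ≈ 0.85 for the default parameters). Sweeps place the
EPSC at a 2.5 ms synaptic latency after the stimulus so its peak falls
inside the conventional 3–6 ms post-stimulus measurement band.

**Spine time-lapses** (`gen_spine_timelapse`). Frames every 40–60 s
(values outside that range are rejected), a stable baseline, a plateau of
`transient_pct` above baseline during the stimulus that persists through
the first frame after the stimulus window (solution exchange), and
complete washout. Noise is additive Gaussian as a fraction of baseline.

All generators are bit-reproducible under a fixed seed and return exact
ground truth — nothing inside a generator is estimated.

# Imaging pipeline

**Rolling-ball background subtraction** is implemented as grayscale
opening with a flat disc structuring element of the given radius — the
de-facto ImageJ semantics — applied slice-wise in z and per channel.
The radius is interpreted in pixels (the common convention when none is
stated); the default is 50 px. EBImage performs the morphology; since its
grayscale operators clip to [0, 1], images are normalized by their maximum
and restored. Consequences that tests assert: output never exceeds input,
flat backgrounds vanish, isolated puncta much smaller than the ball are
preserved within 5%, and the operation is idempotent up to small
discretization effects.

**Straightening** resamples the image at 1-px steps along a polyline path
and its local normal with bilinear interpolation. An axis-aligned path
therefore reproduces the corresponding crop exactly, which is the
identity case the tests pin down.

**Deconvolution** is a Richardson–Lucy iteration against a Gaussian PSF
with a boundary-weight correction (the in-bounds kernel mass per voxel),
which keeps total intensity conserved within 1% for interior signal. It is
a stand-in with the same intent as commercial CMLE deconvolution, not a
reproduction of it, and it is **off by default**: all quantitative claims
in the tests are made without deconvolution.

# Puncta segmentation

Segmentation proceeds as: optional unsharp-mask sharpening (Gaussian sigma
1 px, amount 0.6) used for *segmentation geometry only*; thresholding
(voxels ≥ threshold); marker-based 3D watershed on the Gaussian-smoothed
(sigma 1 px) intensity, seeded at its local maxima within the mask
(plateau maxima are consolidated into one marker), flooding in order of
decreasing intensity over the 26-neighbourhood. Watershed can split
touching puncta but never merge threshold-connected components, and the
voxel partition is conserved. All intensity statistics are then measured
on the raw image — sharpening alters intensities, and measuring on the raw
image keeps intensity comparisons valid across conditions. Components
smaller than `min_voxels` (default 4, mirroring the four-pixel rule used
in 2D detection) are discarded.

**Threshold choice.** Thresholds are chosen once per experiment and frozen
across all images and conditions. The default is a robust background
threshold: median + 5 robust SDs, where the SD is the median-to-84.1st-
percentile distance — this stays correct when the background is clipped at
zero, where the MAD collapses. Otsu's method (`threshold_otsu`) is
provided and used as a fallback for noiseless images, but it is *not* the
default: on realistic sparse-puncta stacks the foreground occupies far
less than 1% of voxels and Otsu's between-class criterion splits the
background mode instead, labeling thousands of noise speckles. On the
synthetic study conditions (SNR 8, PSF 2 px) the robust default yields
punctum recall and precision above 0.9 and recovers a programmed
coincidence of 0.5 within ±0.08.

**2D detection** uses the same component labeler on a single slice, where
26-connectivity reduces to 8-connectivity (stated explicitly since only
the 3D connectivity is conventionally specified), with the
four-or-more-adjacent-pixels cluster rule. Densities are reported per
100 µm of dendrite, the field's axis convention, with per-µm available.

**Synaptic punctum selection** retains a detected punctum only if it is
above background in its own and the partner channel, its (padded) bounding
box does not overlap another punctum's box, and its centroid lies within
4 px of the dendrite-marker mask (distance transform of the mask
complement). A Mexican-hat (LoG) enhancement filter is provided for
boxing punctate signal.

# Colocalization and enrichment

A channel-A punctum "overlaps" B when it shares at least one voxel with
any B punctum — the weakest reading of overlap, recorded in the result for
provenance and configurable via `min_shared_voxels`. The fraction is
directional with its own denominator in each direction, and both
directions are always reported. With no A puncta the fraction is missing,
never 0. Triple colocalization chains pairwise intersections. The
overlapping/non-overlapping split of the same punctum set is an exact
partition by construction, so scaffold-positive and scaffold-negative
sites always sum to the whole.

The spine/shaft enrichment ratio integrates background-subtracted
intensity (area-under-curve sum) over user-supplied spine and shaft ROI
sets on a straightened sum projection and reports spine/shaft: 0 means
shaft-exclusive localization, 1 equal contribution. The ratio direction
follows the interpretation that zero marks exclusively shaft-localized
protein (the methods-style phrasing "shaft vs. spine" is ambiguous;
automated spine detection is intentionally out of scope — ROIs are drawn
or supplied by ground truth). Puncta-by-puncta intensity regression is
plain OLS with slope, intercept and r²; a zero-variance predictor is an
error, and n ≥ 3 is required.

# Electrophysiology

**Detection** (`detect_minis`): the trace is median-centred (a DC offset
otherwise produces zero-phase-filter edge transients that look like
events), low-pass filtered at 1 kHz with a 4th-order zero-phase
Butterworth, and the noise SD is estimated robustly as 1.4826 × MAD of the
raw-minus-filtered residual. Deflections beyond 3.5 noise SDs are events;
peaks closer than 5 ms are merged and secondary peaks that walk back to
the same onset are deduplicated, keeping the deepest. The onset is the
10%-of-peak crossing walking back from the peak. On the synthetic study
condition (60 s, 1 Hz, amplitudes ≥ 3.5 × noise SD) recall is ≥ 0.9 at
FDR ≤ 0.1 with onsets matched within ±2 ms. This detector is a documented
substitute for unpublished in-house detection software, not a reproduction
of it.

**Kinetics** (`event_kinetics`): amplitude is baseline minus trough
(reported positive); the baseline is the 2 ms mean immediately before the
onset sample. Rise time is 10→90% by linear interpolation. "Decay time" is
deliberately the single-exponential tau — the convention compatible with
statements about slower GluA2-containing receptor kinetics — fitted from
one onset-to-peak delay *after* the peak (where the rising exponential has
died away; fitting from the peak itself inflates tau by ~3%) over a window
of 5 × the 37%-crossing guess, by Levenberg–Marquardt. The 37%-crossing
time is also reported as a fit-free robustness metric, and a failed fit
yields a missing tau with the event retained. Charge integrates
(baseline − I) from onset to the first return to baseline. On noiseless
round trips amplitude is recovered within 0.5 pA and tau within 2%.

**Rectification** (`rectification_analysis`): each sweep's response is the
baseline-subtracted current; the peak current is the mean over a symmetric
±1.5 ms window about the largest deflection *within the 3–6 ms
post-stimulus band*, clipped to that band (the band-anchored reading of
"averaging within 3–6 ms of peak current"; the plain band average is
selectable via `window_mode = "post_stim"` since the phrase admits both
readings). Because the same template scales linearly across potentials,
any such window yields slopes proportional to the true conductances, and
the RI is recovered exactly on noiseless families. The reversal potential
is interpolated from the I/V zero crossing and the branch split happens
there — not at 0 mV — because the empirical reversal sits near +3 mV under
these recording conditions. RI = negative-branch slope / positive-branch
slope; this orientation (not its reciprocal) makes inwardly rectifying
young-neuron currents give RI > 1. Command potentials are corrected by an
18 mV liquid junction potential (`correct_junction_potential`), the
normalized I/V divides by the magnitude at the most negative potential,
and recordings whose series resistance rises more than 20% are failed by
`qc_series_resistance`.

# Spine ΔF/F₀

F₀ is the mean over all pre-stimulus frames (the baseline window default;
at least 3 frames required, F₀ must be positive). ΔF/F₀ is invariant to
multiplicative gain but *not* to additive offsets, which is why background
subtraction must precede it — a fixture in the tests demonstrates the
offset bias. The transient is read at the first frame at or after the end
of the stimulus window ("immediately post-stimulus", when solution
exchange is complete): a single-frame readout, because a maximum over
noisy frames is biased upward by extreme-value selection (about +4
percentage points at 5% noise). Reversibility is declared when the mean
wash ΔF/F₀ is within 2 baseline SDs of zero — a per-ROI convenience
criterion; population-level reversibility testing belongs to the
statistics layer (paired tests across ROIs).

# Cohort statistics

Cumulative distributions are compared on cohorts built by sampling exactly
`n_per_cell` values from every cell (uniformly, without replacement —
with-replacement is available behind a flag since the sampling scheme is
conventionally unstated), giving each cell equal weight: 12 cells × 50
events = 600. Two cohorts are compared with the two-sample
Kolmogorov–Smirnov test at the stringent α = 0.005 convention; three or
more go through Kruskal–Wallis with Dunn's z-tests on the pooled ranks
(tie-corrected, two-sided, Bonferroni-style multiplication over
comparisons — the "Dunn's correction" of common statistics packages). The
per-cell layer dispatches Wilcoxon matched-pairs (paired), Mann–Whitney
(unpaired) or two-way ANOVA with Šidák-corrected within-genotype
treatment contrasts (factorial), at α = 0.05. Under the null the full
cohort-KS procedure (including the sampling step) holds its nominal
type-I error: 2000 simulated null experiments at n = 600 give a rejection
rate statistically indistinguishable from 0.005.

# Problem sizes and determinism

The test-suite simulations use the study-scale conditions directly: 60 µm
dendrites with 60 puncta per channel for colocalization recovery, 60 s
traces at 20 kHz for detection, 7-potential I/V families, 17-ROI
time-lapses (averaged over three generated experiments for the noisy
recovery check), and 2000 replicates for the type-I error simulation. All
stochastic tests fix their seeds; generator outputs are bit-reproducible
given a seed, and `scripts/acceptance.R` derives every random stream from
its single `--seed` argument.

# Known limitations

- The segmentation threshold procedure of the original imaging software is
  qualitative; the robust default here is a principled stand-in, not a
  claim about any particular historical threshold value.
- The mEPSC detector and the deconvolution step are documented substitutes
  for proprietary/unpublished tools of the same purpose.
- The synthetic optics omit aberrations, drift and bleaching, and the
  synthetic electrophysiology omits biophysical channel kinetics; passing
  recovery tests demonstrates correctness of the measurement chain under
  the stated noise model, not robustness to every artifact of real data.
- Automated spine detection and pixel-correlation colocalization
  (Pearson/Manders) are out of scope by design — colocalization here is
  object-based throughout.
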