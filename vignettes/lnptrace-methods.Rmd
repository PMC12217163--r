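---
title: "Quantifying LNP-mediated endosomal escape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LNP-mediated endosomal escape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnptrace)
```

## The measurement problem

Lipid nanoparticles (LNPs) deliver siRNA and mRNA into cells through the
endosomal system, and the escape of RNA from endosomes into the cytosol is
the rate-limiting step of delivery. Live-cell microscopy can watch this
happen at single-vesicle resolution: a fluorescently labelled RNA cargo is
tracked inside an endosome while a cytosolic damage reporter (galectin-9 or
galectin-8, or the ESCRT component CHMP2A for smaller perturbations) marks
the moment the limiting membrane is breached. The quantities of interest
are cohort statistics over many such damage events:

* the **hit rate** — the fraction of damaged vesicles that carried
  detectable RNA payload before damage;
* the **fast-release fraction** — the fraction of RNA-positive vesicles
  whose RNA intensity drops sharply at damage onset;
* the **release magnitude** — the median fractional intensity drop shortly
  (~10 s) after onset, with a confidence interval;
* the compartment identity of damaged vesicles (early/late endosomal
  **marker positivity**);
* per-cell **foci counts** (damage response over hours) and **uptake**;
* **colocalization** between LNP cargo, lipid, and compartment markers;
* spot sizes (**FWHM**) and the **sub-endosomal geometry** of the damage
  site relative to the LNP, with a random-localization null model.

`lnptrace` implements this measurement chain as reusable, tested functions,
plus a synthetic time-lapse generator with machine-readable ground truth so
that every stage can be verified end to end without any raw data.

## Single-vesicle trace model

A tracked vesicle is measured with a discrete disc ("object mask") of
6 pixels diameter (620 nm at the default 103 nm pixel size) and one z-plane
depth. Per frame the mask is fitted on an integer grid (±3 px laterally,
±1 plane axially by default) to maximize the total in-mask RNA intensity;
ties are resolved toward the smallest displacement from the seed, then
lexicographically, so the measurement is deterministic. The local
background is the median pixel intensity in an annulus 8 px (~825 nm)
outside the mask. The raw trace is corrected as

\[
I_c(t) = I_{\mathrm{mask}}(t) - \langle B \rangle_{11}(t),
\]

where \(\langle B \rangle_{11}\) is an 11-frame centred rolling average of
the background series (truncated at the series edges). Subtracting a
*smoothed* background makes the corrected trace exactly invariant to any
constant offset added to the stack — a property the test suite asserts to
machine precision.

Photobleaching is corrected with a single exponential fitted to pooled
reference traces of event-free vesicles, each normalized to its first
measurement: \(\hat y(t) = e^{-kt}\), applied as multiplication by
\(e^{+kt}\). A negative fitted rate is clamped to zero (no "unbleaching").
Whether the reference traces should be pooled or fitted per-trace was an
open design point; we pool, which weights long traces more and is the
better-conditioned choice at the small reference counts (3–10 traces)
typical of these experiments.

Traces are aligned so that \(t = 0\) is the first frame with detectable
damage-marker recruitment (`t0`). Onset detection itself is an *input* —
in practice onsets of this kind are identified by visual inspection — so
the package takes `t0` from the event table (or the generator's truth). RNA
traces are normalized to mean 1 over a window ~3–60 s before onset;
damage-marker traces to their maximum.

Windows specified in seconds are converted to frames by rounding **toward
including more frames** (nearest bound rounded down, farthest bound
rounded up), because the frame interval varies between experiments
(2.2–3.0 s) and a window must never become empty by rounding.

## Event classification

* **Fast release**: the mean normalized RNA intensity ~2.2–30 s *after*
  onset falls below the pre-onset mean (same window before onset) minus
  one pre-onset standard deviation (sample sd, \(n-1\)). The comparison is
  strict; a post mean exactly at the boundary is not flagged.
* **Hit (detectable payload)**: "detectable" is inherently a visual
  judgment; we implement an auditable surrogate — the pre-onset
  background-corrected mean must exceed `detection_k` (default 3) times
  the robust background noise sd (median over frames of the MAD of the
  annulus pixels). Raising `detection_k` can only lower the hit rate
  (tested as a monotonicity property). The threshold is configurable and
  flagged as a surrogate in the documentation.
* **Release magnitude**: \(1 -\) the normalized level at the frame nearest
  +10 s. The cohort summary is the median with a distribution-free 95% CI
  from binomial order statistics; below 5 events only the point estimate
  is reported.
* **Marker positivity**: compartment-marker intensity is divided by the
  per-cell 90th-percentile marker intensity, modelled as a straight line
  between its values at acquisition start and end (per-cell linear
  normalizer). The vesicle is marker-positive when the mean of five
  measurements centred on onset exceeds 0.5, strictly.
* **Subgrouping**: RNA load terciles use type-1 quantile boundaries with
  ties assigned to the lower group; weak/strong galectin response is a
  median split (no canonical cut exists for "weak" versus "strong"
  recruitment, so the simplest deterministic rule is used and
  documented).

## Channel registration

Alignment is measured on a bead field (100 nm multi-spectral beads imaged
in all channels). Beads are localized as intensity-weighted centroids
laterally and axially; the inter-channel translation is the integer shift
(1-pixel lateral, 1 z-interval axial accuracy) maximizing the number of
bead pairs within a match radius, with ties broken toward the smallest
shift. Residual displacement after translation is regressed on field
position — a straight line in x and in y separately — and applied with
1-pixel accuracy (per-column/per-row rounding). Two details that such
protocols rarely pin down are fixed here: bead matching is
mutual-nearest-neighbour within 5 px, and z gets an integer shift only (no
linear term) — chromatic aberration is modelled laterally only.

Note that when a position-dependent chromatic offset is present, the
fitted integer shift may absorb whole pixels of it (with the line's
intercept compensating); the invariant that matters — and that the tests
assert — is that applying the composite model never increases, and in
practice strongly decreases, the mean residual bead distance.

## Foci analysis

Small bright foci are enhanced by subtracting a median-filtered copy of
the image (kernel 9 px by default, exposed as a
config parameter) and clamping at zero. Detection is
connected-component labelling (8-connectivity) above a per-channel manual
intensity threshold with an inclusive area gate. Counts are divided by the
number of cells in the first frame, and the mean baseline count per cell
is subtracted; slightly negative values are reported as computed, not
clamped. Responses across conditions are normalized to the maximum of the
negative-control series. Colocalization comes in the two object-based
flavours used for these data: foci resized to 5-px discs with any shared
pixel counting, and label-mask overlap where an object colocalizes when
some single partner object covers strictly more than 25% of its area (an
asymmetric measure, deliberately). Where a structure-segmentation
threshold is needed and no manual value exists, a configurable global
method (Otsu by default) stands in for the manual or
maximum-correlation thresholding often used interactively for this step;
the substitution is flagged in the function documentation.

## Spot sizing and sub-endosomal geometry

Isolated LNP spots are sized by nonlinear least squares of a 2D Gaussian
with offset; \( \mathrm{FWHM} = 2\sqrt{2\ln 2}\,\bar\sigma \cdot
\mathrm{pixel\ size} \) holds exactly for every converged fit (asserted in
the tests). Non-convergent fits are flagged and excluded from summaries,
never errors.

For endosomes with membrane-adjacent LNP and damage-marker signal, the
endosome centre of mass is the intensity-weighted centroid of the
endosome-marker channel inside the mask. Up to three local maxima per
channel are found inside the mask (8-neighbourhood maxima above a noise
floor, plateau-safe, non-maximum suppressed), refined to sub-pixel
precision with a background-subtracted 3×3 centroid — necessary because
the magnitude differences of interest (tens of nm) are below the pixel
size. Vectors run from the centre to each maximum. Manual pairing of maxima is the usual
practice; the package replaces it with the assignment
minimizing the total angular difference (exhaustive over at most 3×3
candidates, verified against brute force), keeping the best one or two
pairs. Angular differences are folded to [0°, 180°]; magnitude differences
are (marker radius − LNP radius) in nm, positive when the damage marker
sits outside the LNP.

**The null model.** If damage and LNP maxima were placed independently at
random, one maximum per channel gives a folded angular difference uniform
on [0°, 180°], mean 90°. For endosomes with two maxima per channel the
natural geometry (two LNPs at opposite poles, each with its own damage
site) is two antipodal maxima per channel at independent random rotations;
nearest-angle pairing then yields matched differences
\(\min(\delta, 180° - \delta)\) for a uniform rotation difference
\(\delta\) — uniform on [0°, 90°], mean 45°.
The construction behind the dual-pair null is stated explicitly here,
verified by brute-force enumeration over a fine rotation grid, and
reproduces the 45° expectation. A fully-independent-maxima variant with optimal pairing
would give a smaller mean and is *not* what the 45° figure describes.

## The synthetic-data generator

`simulate_release_experiment()` emulates the widefield release assay:
diffraction-limited spots (isotropic 2D Gaussian per plane, amplitude
weighted by a 1D Gaussian in z), per-vesicle Gaussian random-walk motion
reflected at the field margins, a per-event onset frame, a step drop of
the RNA amplitude at onset for fast-releasing vesicles, a damage-marker
spot appearing at onset, exponential photobleaching, marker-channel spots
tied to a per-cell 90th-percentile reference with a linear time trend, and
camera noise applied last (Poisson shot noise, then additive Gaussian read
noise — the standard sCMOS approximation). `simulate_bead_field()` and
`simulate_endosome_scene()` provide the registration and geometry
substrates with programmed shifts, chromatic lines, and focus angles.

Generator defaults are the assay's acquisition conditions: 2.2 s frame
interval, 103 nm pixels (so the 6-px mask spans 620 nm), 100–200-frame
event acquisitions (default 100), and event statistics in the range
observed for siRNA-LNPs — hit fraction 0.7, fast-release fraction 0.5,
release magnitude 0.25. Camera noise statistics and absolute intensities
are instrument-specific, so background (100 counts), read noise
(2 counts) and spot amplitudes (~600 counts peak) are free parameters,
chosen once to give a realistic single-vesicle signal-to-noise
of roughly 20:1 on the mask mean; configurations whose spot amplitude
falls at or below the noise floor are rejected outright, because
classifier results on such data would be meaningless.

What the generator does **not** emulate: realistic optics (no Airy rings,
no depth-dependent aberration beyond the linear chromatic line), vesicle
fusion/fission and crossing tracks (tracking is out of scope — seed tracks
are inputs), gradual or partial-sustained release kinetics, intracellular
marker heterogeneity beyond the per-cell p90 line, and sample drift.
Passing tests therefore demonstrate the correctness of the *measurement
chain* under the stated model, not robustness to every artefact of real
microscopy data.

## Numerical conventions and problem sizes

* Arrays are indexed `[y, x]`; positions are 1-based pixel centres; frames
  are 1-based — the idiomatic R convention, used consistently in the API.
  Exported CSV tables are 0-based for frames and pixel coordinates, so
  that `time_s = frame * frame_interval_s` holds verbatim in the files and
  cross-language consumers get the familiar convention. Readers convert
  back; the round trip is tested.
* A pixel belongs to a disc when its centre lies within the radius
  (boundary inclusive); all thresholds described as "greater than" are
  strict. Both boundary behaviours are pinned by tests.
* All simulations derive every draw from a single top-level seed;
  identical configuration and seed give byte-identical stacks.
* Cohort analyses render events in independent fields of 4 cells × 5
  events (plus bleach references) at 128×128 px and 60–100 frames, pooling
  events across fields. These sizes put a 300-event cohort at roughly two
  minutes of compute while keeping every vesicle's full background annulus
  inside the field; they are the package's standard benchmark conditions,
  stated here so results are reproducible.

## Known limitations

* `t0` (onset) detection is not implemented; onsets are inputs by design.
* The hit-rate threshold (`detection_k`) is a surrogate for a visual
  judgment; absolute hit rates depend on it, though the monotone
  relationship is tested.
* The chromatic model is lateral and linear only, applied at 1-px
  accuracy; sub-pixel resampling is deliberately out of scope.
* Absolute cohort statistics from real experiments depend on raw imaging
  data; the package verifies its estimators against its own generator's
  ground truth and reproduces the self-contained null-model
  expectations.
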