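# lnptrace

Quantitative analysis of lipid-nanoparticle (LNP) mediated endosomal
escape of RNA from live-cell, multi-channel time-lapse microscopy.

Endosomal escape — the passage of siRNA or mRNA cargo from the endosome
lumen to the cytosol — is the rate-limiting step of LNP delivery. At
single-vesicle resolution it can be watched directly: labelled RNA is
tracked inside an endosome while a cytosolic damage reporter (galectin-9/8
or the ESCRT component CHMP2A) marks the moment the membrane is breached.
`lnptrace` implements the full measurement chain for such experiments:

* **Registration** — bead-based channel alignment (integer shift, 1-px /
  1-z accuracy) plus a linear lateral chromatic-aberration model fitted to
  weighted bead centroids (x and y separately).
* **Trace quantification** — a 6-px (620 nm) object mask fitted per frame
  to the tracked vesicle; median background in an annulus 8 px outside the
  mask, smoothed over 11 frames and subtracted; exponential bleach
  correction fitted to pooled reference vesicles; traces aligned to damage
  onset (*t* = 0) and normalized (RNA: pre-onset mean = 1; damage marker:
  max = 1).
* **Event classification** — hit rate (detectable payload by a k·sigma
  rule over local background noise), fast release (post-onset mean below
  pre-onset mean − 1 sd, windows ~2.2–30 s), release magnitude at ~10 s
  (median with order-statistic 95% CI), endosomal-marker positivity
  (normalized marker intensity > 0.5 of the per-cell 90th-percentile
  reference, linear in time), load/response subgrouping.
* **Foci analysis** — median-filter enhancement, thresholded 8-connected
  detection, per-cell baseline-subtracted counts, uptake intensity,
  control-normalized responses, and object colocalization (5-px resized
  discs; strict >25% area overlap).
* **Geometry** — 2D-Gaussian FWHM spot sizing
  (FWHM = 2√(2 ln 2)·σ), intensity-weighted endosome centres, sub-pixel
  local maxima, minimal-angle pairing of damage-marker and LNP vectors
  with angular (0–180°) and magnitude (nm) differences, and the
  random-localization null (90° for one pair per endosome, 45° for two
  antipodal pairs).
* **Synthetic data** — `simulate_release_experiment()`,
  `simulate_bead_field()` and `simulate_endosome_scene()` generate all of
  the above inputs with machine-readable ground truth (Gaussian spots,
  Poisson + read noise, random-walk motion, step release at onset,
  photobleaching, per-cell marker drift, programmed shifts and chromatic
  offsets), so the whole pipeline is testable without any raw data.

## Worked example

```r
library(lnptrace)

# simulate a release experiment and quantify a 100-event cohort
coh <- run_release_cohort(100, rng_seed = 3,
                          config_args = list(n_frames = 60,
                                             onset_margin_frames = 20))
coh$summary
```

Output (as printed by `analysis/03_quantify_release.R`):

```
Cohort of 100 damage events:
  hit rate 0.72 (truth 0.71)
  fast-release fraction among hits 0.57 (truth 0.58)
  median release magnitude 0.25 (95% CI 0.25-0.26) at ~10 s
```

72% of damaged vesicles carried detectable RNA before damage, 57% of
those showed a fast intensity drop at galectin onset, and the median drop
was 25% of the pre-damage signal ~10 s after onset — each matching the
generator's configured truth (0.7 / 0.58 realized / 0.25) within sampling
error.

The numbered scripts under `analysis/` run the full workflow and write
their tables to `results/`:

| script | what it does |
|---|---|
| `01_simulate_experiment.R` | renders a ground-truth experiment (stack to `scratch/`, truth tables to `results/`) |
| `02_register_channels.R`  | fits and applies the bead alignment model |
| `03_quantify_release.R`   | traces, event classification, marker positivity |
| `04_foci_response.R`      | foci counts per cell, uptake, colocalization |
| `05_subendosomal_geometry.R` | angular/magnitude geometry, FWHM sizing, null model |

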