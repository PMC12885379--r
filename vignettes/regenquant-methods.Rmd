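---
title: "Methods: models, conventions and validation in regenquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and validation in regenquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenquant)
```

regenquant re-implements, as explicit and testable code, the scoring
procedures used to quantify whether regenerating zebrafish DRG central
axons re-enter the spinal cord, and the cellular and behavioral assays
surrounding that question. The original workflows were manual: ImageJ
line profiles and MTrackJ clicks exported to spreadsheets, thresholds
applied by hand, frames scored by eye. Re-implementing them forces every
implicit convention into the open. This vignette records those
conventions, the reasoning behind each genuinely open choice, and what
the synthetic-data validation does and does not establish.

## Coordinate and indexing conventions

All analysis happens in a frame with **+y = dorsal**, units µm; loaders
are responsible for flipping image-convention y (row indices grow
ventrally in images). Frame indices are **1-based** everywhere, because
the assay schedules are stated ordinally ("the 16th frame"). Re-entry
line profiles are parameterized with the **medial end at coordinate 0**;
the orientation must be declared in the file header (`medial_end`), and
a file recorded lateral-first declares `medial_end` equal to the line
length and is flipped on read. There is deliberately no auto-detection:
a mis-oriented profile flips the biological conclusion.

## Re-entry scoring

The peak of each channel is the **global maximum**, not the first local
maximum — the junction profiles are single-peaked, and a global rule is
robust to shoulder noise. Exact ties break toward the medial coordinate.
Sub-sample refinement fits a parabola through the maximum and its two
neighbors; it is disabled when the maximum sits at either end of the
line, where the fit is unconstrained on one side, and the shift is
capped at half the sample spacing. At the 0.25–0.5 µm spacings typical
of these exports, comparing unrefined peaks would quantize the
entered/not-entered decision; refinement removes that artifact without
changing any decision where peaks are separated by at least one sample.

Two degenerate cases are scored conservatively as *not entered*:
coincident peaks, and a flat channel with no locatable peak. Re-entry is
the positive claim; a tie is not evidence for it.

## Invadopodia detection

The detector is deliberately simple, because it is the part of the
pipeline that must match a published manual procedure exactly:
background-subtract (negatives preserved — clamping would bias the mean
threshold), threshold at the arithmetic mean of the analyzed window, and
take maximal runs of **strictly** supra-threshold frames of length ≥ 4.
Strict inequality makes the constant trace yield zero events; ties with
the mean are measure-zero on real data. The threshold is computed on the
background-subtracted series (the order the original description
implies; computing it before subtraction would shift the threshold by
the mean background and is recoverable by passing a zero background).

Durations are run length × interval, pinned by "4 timepoints = 20 min".
At 5-min sampling the printed class bands (transient 20–35, intermediate
40–55, stable 60–70+) tile the attainable durations exactly; for other
intervals the bands are half-open — [20, 40), [40, 60), [60, ∞) — which
preserves every printed edge while leaving no gaps. Runs touching the
trace boundary count: no edge exclusion is stated, and discarding them
would censor exactly the long (stable) events that matter.

An event is **at the DREZ** iff a strict majority of its frames carry
the `at_drez` annotation. The source description says only "occurred
when the growth cone was at the DREZ"; majority is the reading that is
stable for events straddling the arrival frame. The per-event at-DREZ
frame fraction is emitted so the stricter all-frames rule can be
recomputed from saved output.

Basal widths (invadopodia vs filopodia morphology) use **FWHM above the
profile minimum** with linear interpolation at the half-maximum
crossings. The manual measurement's intensity cutoff is unstated; FWHM
is the standard, documented stand-in, and only the wide/narrow ordering
is interpreted.

## Glial migration

All metrics are plain coordinate geometry on tracks; the substantive
choices are bookkeeping. "Total migration" between t0 and t140 is the
Euclidean norm of the displacement — the original subtraction of x,y
pairs does not name a norm — and the dx/dy components are returned
alongside so the dorsal-component reading is equally reproducible. The
140-timepoint window starts at an explicitly supplied extension-onset
frame, never inferred. The dorsal-most nucleus is selected at the
window's first frame and held fixed, matching one-nucleus-per-animal
tracking. Note that 140 timepoints at 5 min span 139 intervals
(~11.6 h); summaries report frame counts, not a single duration claim.

## Calcium synchrony

z-scores use each cell's own mean and **sample (n−1) SD** — the
spreadsheet default in the workflow being reproduced — over the full
24-frame trace by default; a `baseline = "pre_stimulus"` switch
restricts the baseline to frames 1–7, and the choice is recorded in
outputs. The activation threshold is **inclusive** (z ≥ 2.0), pinned by
"2.0 or more"; the same inclusive rule is applied at frame 17+ for the
delayed class even though one passage says ">2.0", since a measured z
landing exactly on 2.0 is practically impossible and a single rule is
cleaner. Cells whose only crossings precede the cold frame are
categorized `none` for the synchrony percentages but flagged
`rt_responder`: the original three categories do not cover them, and the
flag records the ambiguity without guessing. Zero-variance cells are
flagged unanalyzable and excluded from percentage denominators with a
warning.

## Shivering classifier

The original scoring was visual. The replacement rule is explicit so it
can be falsified against the generator: frame f shivers iff the head
step since f−1 is ≥ 0.5 µm **and** the net centroid displacement over a
centered 20-frame (1 s) window is ≤ 5 µm. The conjunction encodes the
definition — head/tail movement *without forward locomotion*. The
thresholds are declared conventions calibrated on the generator (a
shiver bout at amplitude 1 µm sits 2× above the move threshold; a swim
bout at 1 µm/frame displaces the centroid 20 µm per window, 4× the veto
threshold), not inferred measurement values. The denominator is always
exactly 400 frames.

## HCR quantification

Pixels belong to a polygon when their **centers** lie inside
(boundary-center pixels count as inside) — deterministic and equivalent
to rasterized-ROI behavior. The puncta detector Gaussian-smooths at the
punctum scale, thresholds at the masked median plus
`k_sd` × 1.4826 × MAD, takes 3×3 local maxima, and merges maxima closer
than 2σ. The robust baseline is the one genuinely free design choice: a
mean/SD baseline is inflated by the puncta themselves, which would make
the threshold depend on the quantity being counted. Densities are
reported per µm² of polygon area, with the per-pixel-count variant
emitted alongside, since the original "divided by the total area" does
not say which was used. A pre-counted puncta table can bypass detection
entirely, mapping the manual-count workflow directly.

## The synthetic world

The generators emulate the *statistical skeleton* of each assay at its
published geometry — 5-min LifeAct sampling, the 8 µm profile line, the
24 × 5 s calcium schedule with additions before frames 8 and 16, 30
spinal cells per animal, 600-frame/50-ms behavior movies with a
400-frame analysis window, well-separated Gaussian puncta — with planted
ground truth for event spans, peak separations, drifts, responder
classes, shiver frames and puncta centers.

Choices the sources leave open, fixed once here:

* **Noise models.** Gaussian intensity noise on traces and profiles,
  Poisson shot noise on images, Gaussian positional jitter on tracks.
  Conventions, not claims — no noise model is published for any of these
  measurements.
* **GCaMP6s kinetics** are a linear rise (default: peak in the first
  post-stimulus frame) with exponential decay (×0.8/frame). Only
  threshold crossings matter downstream, so the exact shape is free.
  Because a z-score is invariant to positive scaling of the trace, a
  planted "peak amplitude in SD units" cannot be set by scaling;
  the generator instead calibrates the *shape* numerically (uniroot on
  the weight of the kinetic tail plus a small deterministic baseline
  wiggle) so the scored z at the peak frame equals the planted value
  exactly at zero noise. The attainable maximum is (n−1)/√n ≈ 4.7 SD
  for 24 frames; requests beyond it are rejected.
* **Shiver bouts** oscillate the head as a sinusoid with a 4-frame
  period (2 frames per half-cycle); the classifier thresholds amplitude,
  so the waveform is immaterial.
* **HCR puncta** default to σ = 0.15 µm on 0.1 µm pixels, peak 200
  counts on background 10: diffraction-limited spots at typical confocal
  sampling. (Larger spots at low magnification make the signal dominate
  small masks and invalidate any background-median threshold, robust or
  not.)

What a green test establishes: that the scoring rules recover exactly
what was planted, under the stated geometry and noise. What it does not:
anything about segmentation, registration, photobleaching, z-projection
artifacts, or observer variability in the upstream manual steps — none
of which are modeled. The generator's percentages are not predictions of
biological effect sizes.

## Statistics

Fisher's exact two-sided p uses the **probability-ordering rule** (sum
of hypergeometric probabilities ≤ the observed table's, with 1 + 1e-7
relative slack), the convention of mainstream packages and, per the
described workflow, of the original analyses; two-sided Fisher
definitions differ, so this is stated. The implementation is validated
against an independent log-binomial enumeration for *every* 2×2 table
with N ≤ 60. Rank tests use mid-ranks with the normal approximation
(exhaustively checked against a first-principles tie-corrected H on
small inputs); Welch ANOVA follows the Welch–Satterthwaite form, and
Brown–Forsythe ANOVA (the unequal-variance test of means, F* with its
df correction) is implemented directly since no installed package
provides it — for two equal-sized groups both reduce algebraically to
Welch's t², which the tests assert. The chi-squared test is uncorrected
Pearson, matching the closed 2×2 form. All-identical rank inputs return
p = 1 with a warning rather than NaN.

Group compilations of invadopodia durations pool events across traces
within a group — the original compilation unit — while per-trace mean
at-DREZ durations are also reported, deliberately exposing the
pseudo-replication question rather than resolving it.

## Numerical choices and degenerate inputs

* Constant series: no peak (re-entry), zero events (invadopodia, since
  "above" is strict), unanalyzable (calcium), flagged width (basal
  width).
* Empty margins: Fisher p = 1 on a degenerate 2×2; chi-squared errors.
* Zero-variance groups in Welch/Brown–Forsythe are handled by the
  formulas as written and flagged.
* All percentages are exact ratios; no rounding happens inside the
  pipeline.

## Known limitations

* No image-stack processing: profiles, tracks and ROI traces are taken
  as upstream exports, and images are single-plane matrices (the R
  environment provides no TIFF I/O; images serialize as CSV matrices
  with a pixel-size header).
* The shiver classifier is a stand-in for visual scoring; its two
  thresholds are conventions and should be re-calibrated against scored
  video before quantitative use on real tracks.
* The puncta detector is a stand-in for manual counting; under Poisson
  noise it is within ±1 of truth in ≈98 % of seeds at SNR ≈ 60, not
  always.
* The at-DREZ majority rule and the µm² density denominator are
  documented choices among defensible readings; both emit enough
  per-event/per-run detail to recompute the alternatives.
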