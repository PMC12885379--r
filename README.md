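# regenquant

Quantification pipeline for studying the closure of the regenerative
period of zebrafish dorsal root ganglion (DRG) centrally-projecting
axons. After laser axotomy, a DRG central axon can re-invade the spinal
cord only during a narrow developmental window; whether it succeeds is
read out across several live-imaging and fixed-tissue assays. This
package provides tested, scriptable implementations of the
quantification and classification procedures behind those readouts —
originally a collection of manual ImageJ + spreadsheet workflows — plus
a seeded synthetic-data module that fabricates every input with
ground-truth sidecars, so each analysis can be validated against planted
truth without a microscope.

It is intended for labs running regeneration, growth-cone dynamics,
calcium-imaging or behavioral assays of this kind who want the scoring
rules explicit, versioned and testable.

## What it computes

**Re-entry scoring** (`classify_entry`). Along an 8 µm line drawn across
the junction of the regenerating axon tip and the glial limitans, the
axon is *entered* iff its fluorescence peak lies strictly medial of the
boundary-channel peak:

    entered  ⇔  argmax_x A(x) < argmax_x B(x)

with medial ties scored conservatively as *not entered*, and optional
3-point parabolic sub-sample peak refinement.

**Invadopodia detection** (`trace_events`). The growth cone's LifeAct
integrated density F(t), sampled every 5 min, is background subtracted,
thresholded at its own mean over the analyzed window, and scanned for
maximal runs of strictly supra-threshold frames. Runs of ≥ 4 consecutive
timepoints (≥ 20 min) are invadopodia formation events; durations
classify them as transient [20, 40), intermediate [40, 60) or stable
[60, ∞) min. Events are compiled per group, overall and restricted to
frames when the growth cone sat at the dorsal root entry zone (DREZ).

**Glial migration metrics** (`dorsal_offsets`, `total_migration`,
`target_distances`). Per-frame dorsal offsets of growth cone and
dorsal-most glial nucleus relative to the DRG dorsal border over 140
timepoints, endpoint migration distances, and target-plot displacement
components.

**Calcium synchrony** (`summarize_animal`). Each cell's trace is
z-scored against its own mean and sample SD; z ≥ 2.0 is an activation
event. With cold water added just before frame 16 of a 24-frame, 5-s
assay, spinal neurons are *rapid/synchronous* (active at frame 16),
*delayed* (first active ≥ frame 17) or *none*; animals lacking a rapidly
active DRG neuron are excluded.

**Shivering** (`classify_shiver`). A frame counts as shivering when the
head moved ≥ 0.5 µm since the last frame while the body centroid's net
displacement over a centered 1-s window stayed ≤ 5 µm; the percentage is
over the first 400 frames (20 s) after immersion.

**HCR quantification** (`detect_puncta`, `corrected_mean_grey`,
`floorplate_mean`). Puncta-per-area density inside a traced neuron mask,
background-corrected mean grey value of a traced region, and the mean
grey of a 200 µm² floor-plate box.

**Statistics** (`fisher_exact`, `rank_tests`, `variance_tests`,
`paired_t`, `chisq_test`). The group comparisons used across the assays,
with Fisher's exact p computed by probability-ordering enumeration.

## Worked example

```r
library(regenquant)

# score two synthetic age groups for re-entry
g2 <- lapply(1:10, function(s) classify_entry(gen_orth_profiles(
  separation_um = if (s <= 8) -1.5 else 1.5, noise_sd = 0.03, seed = s)$pair))
g5 <- lapply(1:12, function(s) classify_entry(gen_orth_profiles(
  separation_um = 1.0, noise_sd = 0.03, seed = 100 + s)$pair))
young <- summarize_outcomes(g2, "2dpf"); print(young)
old   <- summarize_outcomes(g5, "5dpf"); print(old)
print(compare_outcomes(young, old))
```

```
2dpf: 8/10 entered (80%)
5dpf: 0/12 entered (0%)
Fisher's exact test (two-sided): statistic = Inf, p = 0.0001407 (n = 10, 12)
```

Eight of ten axons with peaks planted medial of the boundary score
*entered* (80 %); none of the twelve lateral ones do; Fisher's exact test
calls the difference significant.

```r
# detect invadopodia in a synthetic LifeAct trace: one transient event
# while navigating, one stable event at the DREZ
tr <- gen_lifeact_trace(trace_spec(
  260, events = list(c(30, 5, 8), c(120, 14, 8)),
  noise_sd = 0.5, drez_arrival_frame = 100, seed = 2))$trace
trace_events(tr)
```

```
  start_frame end_frame n_frames duration_min stability_class
1          30        34        5           25       transient
2         120       133       14           70          stable
  frac_frames_at_drez at_drez
1                   0   FALSE
2                   1    TRUE
```

```r
# calcium synchrony for one animal with a planted 27/2/1 responder mix
ca <- gen_calcium(calcium_spec(calcium_classes(27, 2, 1),
                               noise_sd = 0.3, seed = 5))
s <- summarize_animal(ca$recording, "fish01")
```

`fish01: 90.0% rapid, 6.7% delayed, 3.3% none; included = TRUE` — the
planted mix is recovered exactly (27/30 = 90 %).

## Command line

```sh
regenquant simulate lifeact --spec spec.yaml --seed 4 --out sim/
regenquant invadopodia detect sim/trace.csv --out events.json
regenquant calcium score recording.csv --out synchrony.json
regenquant stats fisher --input table.json
regenquant report study.json events.json synchrony.json
```

(`exec/regenquant` is the launcher; `regenquant_cli()` is callable from R.)

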