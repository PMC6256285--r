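# synaptiq

Quantification stack for synapse-biology experiments in cultured neurons.
The package reimplements, as tested reusable R code, the measurement chain
used to characterize synaptic scaffold proteins and AMPA-receptor function
in dissociated hippocampal cultures:

- **3D puncta segmentation** of fluorescent synaptic clusters in
  straightened dendrites: rolling-ball background subtraction, unsharp
  sharpening, thresholding, marker-based 3D watershed separation, and
  **26-connectivity component labeling**, with per-punctum volume,
  intensity and centroid measured on the raw image.
- **Object-based colocalization**: the fraction of channel-A puncta that
  overlap any channel-B punctum,
  `%A overlap with B = (# overlapping A&B puncta) / (# A puncta)`,
  plus overlap density per 100 µm, overlap intensity/volume, triple
  colocalization, and the exact overlapping/non-overlapping partition.
- **Spine-vs-shaft enrichment**: the ratio of integrated protein intensity
  in spine ROIs to dendritic-shaft punctum ROIs on straightened sum
  projections (0 = shaft-exclusive, 1 = equal contribution), and
  puncta-by-puncta intensity **OLS regression** between channels.
- **Miniature EPSC analysis**: threshold detection of inward synaptic
  currents on low-pass-filtered traces with robust (MAD-based) noise
  estimation; per-event amplitude, 10–90% rise time, single-exponential
  decay tau, and charge; onset-aligned ensemble averages.
- **Rectification index** of evoked AMPAR currents: peak currents averaged
  in the 3–6 ms post-stimulus band across holding potentials
  (liquid-junction corrected, default 18 mV), branch-wise I/V regression
  split at the interpolated reversal, and
  `RI = slope(negative branch) / slope(positive branch)` — RI > 1 marks
  the inward rectification of GluA2-lacking AMPA receptors.
- **Spine ΔF/F₀ transients** for zinc-indicator time-lapses: ROI box
  extraction, baseline-relative ΔF/F₀, the immediately-post-stimulus
  readout, and a washout reversibility check.
- **Cohort statistics**: equal-events-per-cell cohort sampling (e.g. 600
  events from 12 cells), two-sample Kolmogorov–Smirnov at α = 0.005,
  Kruskal–Wallis with Dunn's correction, Wilcoxon/Mann–Whitney, and
  two-way ANOVA with Šidák post hocs.

Because primary recordings for this kind of study are rarely deposited, the
package ships **ground-truthed synthetic generators** for every data type —
two-channel dendrite stacks with programmed coincidence, mEPSC trains,
evoked I/V sweep families under a tunable outward-block model with
closed-form true RI, and spine time-lapses — so every stage of the pipeline
is testable end to end.

## Worked example

```r
library(synaptiq)

# a 60 µm two-channel dendrite with 60 puncta/channel, half coincident
sim <- gen_dendrite_stack(length_um = 60, n_puncta = 60, coincidence = 0.5,
                          amplitude = 150, noise_sd = 5.4,
                          psf_sigma_um = 0.2, seed = 11)
a <- get_channel(sim$stack, "A"); b <- get_channel(sim$stack, "B")
lab_a <- segment_puncta_3d(a, threshold_background(a))
lab_b <- segment_puncta_3d(b, threshold_background(b))
overlap_metrics(lab_a, lab_b, a, b, dendrite_length_um = 60,
                voxel_size = sim$stack$voxel_size)
#> <coloc_result> 30/59 A puncta overlap B (50.8%); 30/58 B with A (51.7%)
```

59 of the 60 programmed channel-A puncta are recovered and the estimated
overlap fraction (50.8%) matches the programmed coincidence of 0.5; the
overlap density is 50 per 100 µm of dendrite.

```r
mini <- gen_mepsc_trace(60, 1, noise_sd_pA = 2, seed = 12)
ev <- analyze_minis(mini$trace)
#> 46 events; median amplitude 25.0 pA, median decay tau 5.0 ms

iv <- gen_iv_sweeps(rectification_model(block_depth = 0.8),
                    seq(-60, 60, 20), noise_sd_pA = 2, seed = 13)
rectification_analysis(iv$sweeps)
#> <iv_analysis> 7 potentials, v_rev ~ 4.68 mV, RI = 17.249 (neg 0.896 / pos 0.052 nS)
```

The detector recovers the 1 Hz event train with the programmed 5 ms decay
tau, and the rectifying model (80% outward block) yields a strongly
rectifying I/V (RI ≫ 1), as expected for GluA2-lacking receptors.

A thin command-line front end over the same functions is installed at
`cli/synaptiq.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/synaptiq.R", package="synaptiq"))')" \
    synth minis --seed 1 --out minis.csv
```

## Documentation

The methods vignette (`vignettes/synaptiq-methods.Rmd`) describes the
models, parameter choices, numerical decisions and limitations; function
reference via `?synaptiq` and the roxygen help pages.
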