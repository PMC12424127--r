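# chemotaxr

Quantitative analysis of micropipette chemotaxis and Ca²⁺ signaling in
human iPSC-derived microglia (iMG), built as a fully synthetic, testable
reimplementation of the assay's analysis chain.

In the assay, a pipette at the centre of the imaging field releases brief
pulses of ADP (50 µM, 0.5 Hz, 20 ms). Microglia sense the gradient through
P2Y₁₂/P2Y₁₃ receptors, migrate toward the tip in a distance-dependent way
(up to ~400 µm), and produce biphasic Ca²⁺ responses — an ER store-release
peak followed by a sustained store-operated Ca²⁺ entry (SOCE) plateau.
`chemotaxr` is for researchers who want to analyse such recordings (or
benchmark an analysis) with every stage reproducible and ground-truthed:

* **Gradient model** — pulsed half-space point source,
  C(r,t) = Σᵢ 2Q (4πD(t−tᵢ))^(−3/2) exp(−r²/4D(t−tᵢ)), converging to the
  stable 1/r steady state Q·rate/(2πDr), with the dye normalization used
  to monitor gradient stability.
* **Synthetic data** — biased persistent random walks (von Mises headings,
  gamma step lengths, clipped-linear distance gain g(r) = max(0, 1−r/400 µm)),
  treatment presets for every experimental condition, two-channel Ca²⁺
  traces, and Gaussian-blob rendering with exact centroid ground truth.
* **Tracking** — trim to the 1–11 min analysis window, thin to ≥15 s
  frames, per-frame percentile background subtraction, Otsu segmentation
  with 8-connected components and intensity-weighted centroids, greedy
  nearest-neighbour linking with deterministic tie-breaks and no gap
  closing, ≥20-consecutive-frame track filter, and a logged curation hook.
* **Migration statistics** per track and per 100 µm radial bin —
  directed-migration efficiency (net radial approach / path length),
  speed (path length / time), line speed to the tip, straightness, burst
  speed, and origin-anchored ensemble MSD, aggregated at the
  experiment level (mean ± s.e.m. over experiments).
* **Ca²⁺ metrics** — ΔR/R₀ (or ΔF/F₀) normalization, amplitude and
  integral over the first 100 s, 10–90 % rise time, and the SOCE rate as
  the ΔF/F₀ regression slope over 10 s after Ca²⁺ re-addition.

## Worked example

```r
library(chemotaxr)

cfg <- default_config(seed = 1)
cfg$cohort$n_cells <- 200
report <- run_scenario("control", cfg, render = TRUE)
pipeline_speeds(report)
#> $mean_speed_um_min
#> [1] 4.925351
#> $burst_speed_um_min
#> [1] 10.24659
#> $n_tracks
#> [1] 155
```

155 of 200 simulated cells survive rendering, tracking and the 20-frame
filter. Their mean speed (total path length over elapsed time) is
≈ 4.9 µm/min and the mean per-track peak frame-to-frame speed is
≈ 10.2 µm/min — the system-level migration and burst speeds of this
preparation. Binned efficiency from the same report
(`report$per_bin`, metric `efficiency`) falls from ≈ 0.67 in the
100–200 µm bin to ≈ 0.01 beyond 400 µm, while speed stays flat across
bins: chemotactic steering rides on distance-independent motility.

The numbered scripts under `analysis/` tell the full story and write all
tables under `results/`:

| script | what it shows |
| --- | --- |
| `01_gradient_field.R` | stable 1/r gradient; normalized profile |
| `02_simulate_and_track.R` | full pipeline on the default cohort |
| `03_migration_metrics.R` | binned efficiency, flower plot |
| `04_calcium_responses.R` | distance-decaying Ca²⁺ metrics; WT vs ORAI1-KO SOCE |
| `05_condition_presets.R` | all 15 condition presets vs control |

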