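---
title: "Quantifying micropipette chemotaxis and Ca2+ signaling in iPSC-derived microglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micropipette chemotaxis and Ca2+ signaling in iPSC-derived microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxr)
```

## The assay and what the package computes

In the micropipette chemotaxis assay, human iPSC-derived microglia (iMG)
are plated at low density and a glass pipette at the centre of the imaging
field releases brief pressure pulses of ADP (50 µM in the pipette, 0.5 Hz,
20 ms per pulse). Microglia sense ADP through P2Y~12~/P2Y~13~ receptors and
migrate up the resulting gradient while producing biphasic cytosolic Ca^2+^
responses: a fast ER store-release peak followed by a sustained
store-operated Ca^2+^ entry (SOCE) plateau. The assay quantifies migration
per cell and aggregates cells into 100 µm radial bins by their distance
from the tip at the start of the analysis window.

`chemotaxr` reimplements this analysis end to end on synthetic data so
every stage is exercisable and testable without imaging hardware:

1. a closed-form model of the pulsed point-source gradient
   (`gradient_source()`, `concentration()`, `normalized_profile()`);
2. a biased persistent random-walk generator with treatment presets
   (`simulate_trajectories()`, `preset()`), plus a two-channel Ca^2+^ trace
   generator (`simulate_calcium()`);
3. synthetic rendering with exact ground truth (`render_frames()`) and the
   tracking chain — trimming/downsampling, background subtraction,
   segmentation, greedy linking, minimum-track-length filtering
   (`trim_and_downsample()`, `track_series()`);
4. the migration statistics (`migration_efficiency()`, `track_speed()`,
   `line_speed_to_tip()`, `straightness()`, `msd()`) with radial binning
   and experiment-level aggregation;
5. ratiometric Ca^2+^ metrics (`ca_amplitude()`, `ca_integral()`,
   `rise_time()`, `soce_rate()`);
6. orchestration (`run_scenario()`, `compare_conditions()`).

## The gradient model

The pipette tip sits just above the coverslip, so each 20 ms puff is
modelled as an instantaneous release of an amount $Q$ into the half-space
above a reflecting plane. Superposing one free-diffusion Green's function
per completed pulse (factor 2 from the image source),

$$C(r,t)=\sum_{t_i<t}\frac{2Q}{\left(4\pi D (t-t_i)\right)^{3/2}}
  \exp\!\left(-\frac{r^2}{4D(t-t_i)}\right),$$

which converges to the continuous-source steady state
$C_\infty(r)=Q\,\nu/(2\pi D r)$ for pulse rate $\nu$. The half-space
geometry is essential: a purely two-dimensional continuous source has no
steady state, which would contradict the stable, consistent gradient the
assay monitors with a tracer dye. At finite time the field follows the
continuous-source transient $C_\infty(r)\,\mathrm{erfc}\!\left(r/2\sqrt{Dt}\right)$,
i.e. the gradient is within ~10 % of its final shape over the cell field
after a few minutes — a *shape* model: since no released amount is
measured, $Q$ is a free scale and all outputs are normalized or
threshold-relative. The default $D$ = 300 µm²/s is the order of magnitude
for small nucleotides in water and is configurable.

The dye-normalization used to monitor gradient stability divides the
time-averaged field by its area-weighted mean over the disk $r \le 50$ µm,
time-averaged 20–30 min after release. Time averages are computed from the
exact per-pulse integral ($\int_0^T$ of the kernel is
$\tfrac{Q}{2\pi D r}\mathrm{erfc}(r/2\sqrt{DT})$) rather than by sampling,
because near the tip the instantaneous field is violently pulsatile and
naive time sampling does not converge. The area weight ($2\pi r\,dr$)
regularises the $1/r$ singularity at the tip.

## The motility model

Cell motion is a biased persistent random walk on the tracking clock
(default $\Delta t$ = 15 s per step). Each step's heading is drawn from a
von Mises distribution whose mean direction and concentration are given by
the resultant of two pulls:

* a persistence pull of fixed magnitude $a_p$ along the previous heading,
  with $a_p$ chosen so that, without bias, the expected cosine of the
  turning angle equals the `persistence` parameter exactly;
* a chemotactic pull of magnitude $\kappa\, g(r)$ toward the tip, with
  $g(r)=\max(0,\,1-r/400\ \mu m)$ a clipped-linear proxy for the local
  attractant level that vanishes at the empirically motivated 400 µm
  sensing limit. Distance stands in for concentration (the field is a
  stationary, monotone function of $r$, so sampling the model field would
  add a parameter without adding behaviour).

Step lengths are gamma distributed. The defaults are a deliberate
calibration, fixed before any acceptance measurement and not revisited:

* `mean_step_speed` = 5 µm/min, so the full simulate–render–track pipeline
  reports the system-level mean migration speed of this preparation;
* `speed_cv` = 0.4, so the mean per-track *maximum* frame-to-frame speed —
  the "peak burst" statistic — is about twice the mean
  ($E[\max \text{ of } \sim 40\ \Gamma \text{ draws}] \approx 2.06 \times$ mean),
  i.e. ~10 µm/min;
* `persistence` = 0.5 and `kappa` = 2 give first-bin directed-migration
  efficiencies around 0.6 that decay to the random-walk level beyond
  400 µm, the qualitative shape of the binned data, while leaving speed
  distance-independent.

One global seed fans out to fixed per-cell substreams, so enlarging a
cohort never perturbs previously generated cells.

## Treatment presets

Each experimental condition is encoded as five dimensionless scalings
applied to the motility and Ca^2+^ models: `kappa_multiplier`,
`speed_multiplier`, `er_peak_scale`, `soce_plateau_scale`, `peak_delay_s`.
The source experiments report per-condition effects only graphically, so
presets assert the *sign* of each effect, never a magnitude: receptor
antagonists and caffeine (and caffeine after store depletion) zero the
chemotactic coupling; store depletion by thapsigargin or CPA zeroes the
ADP-evoked Ca^2+^ response while leaving motility untouched; ORAI1
deletion zeroes only the SOCE plateau; Ca^2+^-free bath removes the
plateau with a modest reduction of coupling; BAPTA/EGTA loading reshapes
and delays the Ca^2+^ response without impairing migration; forskolin
strongly depresses coupling. Conditions whose multipliers equal control
generate *identical* trajectories under common random numbers, which makes
"indistinguishable from control" an exact, not merely statistical,
statement in the packaged contracts.

## Imaging and tracking

`render_frames()` draws each cell as an isotropic Gaussian blob
(σ = 3 px) on a constant background with optional Poisson shot noise, on
the assay geometry: 650 × 650 binned pixels of 1.3 µm (an 845 µm field)
with the tip at the centre. Pixel centres sit at integer coordinates,
origin top-left, x along columns; µm = px × 1.3. The exact centroid table
is returned with the stack, so tracking accuracy is measurable rather than
assumed.

The tracking chain mirrors the assay's workflow: the analysis window opens
1 min after release and lasts 10 min; frames are thinned to the smallest
stride with spacing ≥ 15 s (a 0.3 frames/s acquisition thins 5:1 to
16.7 s); a per-frame scalar background (5th percentile — deterministic and
exactly testable, unlike rolling-ball) is subtracted; frames are
thresholded by Otsu's method; components are labelled with 8-connectivity
and intensity-weighted centroids keep sub-pixel accuracy; linking is
greedy globally-nearest-neighbour with deterministic tie-breaks (ascending
distance, then (y, x) lexicographic), no gap closing — a missed detection
ends a track, which is exactly what a "consecutive acquisitions" inclusion
rule implies — and tracks shorter than 20 frames (5 min) are removed. The
default gate `max_disp` = 3 × mean speed × frame interval accommodates
burst steps without cross-linking neighbours at the assay's plating
density. The manual-curation step is modelled as an explicit, logged
exclusion list (`curate_tracks()`), whose default — exclude nothing — is
the reproducible path.

## Migration statistics

For a track with positions $p_1 \dots p_n$ and radial distances
$r_i = \lVert p_i - \text{tip} \rVert$:

* **efficiency** $= (r_1 - r_n) / \sum_i \lVert p_{i+1}-p_i \rVert$. The
  "distance travelled toward the centre" is read as *net radial approach*,
  which bounds the index in $[-1, 1]$ and makes
  efficiency × speed = line speed an exact identity; the alternative
  positive-radial-steps reading is available via `efficiency_mode`.
* **speed** = path length / elapsed time (µm/min);
* **line speed to tip** $= (r_1-r_n)$ / elapsed (signed);
* **straightness** $= \lVert p_n-p_1 \rVert$ / path length,
  tip-independent. (Whether the assay's "straightness" is this
  net-displacement ratio or a turning-angle statistic is not specified;
  the net-displacement ratio is adopted and documented.)
* **MSD**: ensemble mean of squared displacement *from each track's
  origin* — no sliding-window time averaging, matching the "distance
  traveled from their origin" definition; the overlapping-window variant
  sits behind `time_average = TRUE`. Lags need ≥ 5 contributing cells.

Cells are binned by $r$ at their first analysed frame into half-open
100 µm bins ($[100,200), \dots, [400,500)$), frozen for the whole
analysis; out-of-range cells are reported separately, and stationary
tracks (zero path length) are excluded with a reason code. Aggregation is
two-level — cells within experiment, then across experiment means — so the
reported n is experiments and unequal cell counts cannot tilt the summary.

## Ca^2+^ metrics

Traces are ratios R = GCaMP6f-like / TdTomato-like (ratiometric mode
cancels motion and expression artifacts) or single-dye F. Normalization is
$\Delta R/R_0$ with $R_0$ the pre-stimulus baseline mean (≥ 3 samples
required). Metrics: amplitude (window maximum), integral (signed
trapezoid), both restricted by default to the first 100 s after the
challenge — the guard against ROI drift once cells start moving — and
10–90 % rise time on the rising phase, linearly interpolated, with a
detection threshold of 5 baseline-noise standard deviations. The SOCE rate
is the least-squares slope of $\Delta F/F_0$ over 10 s after Ca^2+^
re-addition; a regression is used instead of the raw endpoint difference
because it is robust to sampling noise (the endpoint estimator sits behind
`method = "endpoint"`). The synthetic response is a unit-peak double
exponential (rise 3 s, decay 15 s) plus a saturating plateau (τ = 20 s),
both scaled by $e^{-r/200\,\mu m}$, so every metric has a closed form to
test against.

## What the generator does and does not emulate

The generator reproduces the features the analysis depends on:
distance-dependent directional bias with a hard sensing range,
distance-independent speed with occasional burst steps, biphasic
distance-decaying Ca^2+^ responses, the acquisition geometry and timing,
shot noise, and the sign of every published condition effect. It does not
emulate: cell morphology (cells are Gaussian blobs — no ramified
processes, so segmentation here is easier than on real microglia),
cell–cell collisions or adhesion, ROI drift and reshaping, photobleaching,
focus drift, shear-stress Ca^2+^ transients at stimulation onset, or
mechanistic IP~3~/SOCE kinetics. Passing tests therefore validate the
*analysis chain* and the internal consistency of the models — not
biological conclusions about real recordings, and preset magnitudes must
not be read as quantitative claims.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and early: the field is singular at r = 0;
non-positive rates, time steps and dispersions are rejected; a
non-positive ratio denominator names the offending frame (the signature of
background over-subtraction). Ties in linking are broken by distance then
(y, x); ties between dye channels are "unassigned" (ratio within 1.2× of
1) and excluded from per-population summaries. Von Mises sampling uses the
Best–Fisher rejection algorithm with a wrapped-normal branch above
κ = 5 × 10^5^; the persistence-to-concentration map uses the standard
Best–Fisher approximation of $A^{-1}$. MSD slopes are fitted with
1/lag² weights because the origin-anchored MSD variance grows as lag².

The packaged analyses use cohorts of 200 cells (rendered pipeline runs)
and 500 cells (preset contracts, trajectory-only), 4 independent
experiment replicates, and 1000-resample bootstraps over experiments —
sizes at which every documented check is stable under reseeding while a
full run completes in well under a minute on a laptop core. Bootstrap
confidence intervals are reported instead of p-values throughout;
between-condition hypothesis testing is deliberately out of scope.

## A worked example

```{r example, eval = FALSE}
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

The numbered scripts under `analysis/` run the same machinery as a
narrative: gradient field (01), simulate + track (02), migration metrics
(03), Ca^2+^ responses and the SOCE protocol (04), and all condition
presets with bootstrap deltas against control (05), each writing its
tables under `results/`.
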