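#!/usr/bin/env Rscript
# Simulate the default iMG cohort under the ADP gradient, render it to a
# synthetic time-lapse stack, and run the full tracking chain (trim to the
# 1-11 min window, background subtraction, segmentation, greedy linking,
# 20-frame minimum length). Writes the tracked positions and, for
# comparison, the simulator's ground truth.

library(chemotaxr)

dir.create("results", showWarnings = FALSE)

cfg <- default_config(seed = 1)
cfg$cohort$n_cells <- 200

report <- run_scenario("control", cfg, render = TRUE,
                       out_dir = "results/control_run")

s <- pipeline_speeds(report)
cat(sprintf("Tracked %d cells surviving the 20-frame filter.\n", s$n_tracks))
cat(sprintf("Mean cell speed: %.2f um/min; mean per-cell burst speed: %.2f um/min.\n",
            s$mean_speed_um_min, s$burst_speed_um_min))
cat("Tables written under results/control_run/ (tracks, per-cell metrics,\n")
cat("per-bin summary, MSD curves, Ca2+ metrics, run log).\n")
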