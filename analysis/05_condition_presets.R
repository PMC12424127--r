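#!/usr/bin/env Rscript
# Every experimental condition as a simulator preset, compared against the
# control run with common random numbers: receptor antagonists and caffeine
# abolish directed migration; store depletion (thapsigargin/CPA), ORAI1
# deletion, chelator loading and Ca2+-free bath leave it essentially
# intact while reshaping the Ca2+ response.

library(chemotaxr)

dir.create("results", showWarnings = FALSE)

cfg <- default_config(seed = 11)
cfg$cohort$n_cells <- 500
cfg$calcium$n_cells_per_bin <- 10

cat("Simulating", length(preset_names()), "conditions x 500 cells...\n")
reports <- lapply(preset_names(), function(p)
  run_scenario(p, cfg, render = FALSE))
names(reports) <- preset_names()

summ <- do.call(rbind, lapply(preset_names(), function(p) {
  r <- reports[[p]]
  near <- r$per_cell$bin == "[100,200)"
  data.frame(preset = p,
             eff_100_200 = mean(r$per_cell$efficiency[near]),
             speed = mean(r$per_cell$speed_um_min),
             ca_amplitude = mean(r$calcium$amplitude),
             ca_integral = mean(r$calcium$integral))
}))
write.csv(summ, "results/preset_summary.csv", row.names = FALSE)

deltas <- do.call(rbind, lapply(setdiff(preset_names(), "control"),
  function(p) {
    d <- compare_conditions(reports[[p]], reports$control,
                            metrics = "efficiency", n_boot = 500, seed = 2)
    cbind(preset = p, d)
  }))
write.csv(deltas, "results/preset_deltas_vs_control.csv", row.names = FALSE)

cat("\nPer-condition summary (first radial bin):\n")
print(summ, row.names = FALSE, digits = 3)
cat("\nSign pattern to note: kappa-null presets (sham, antagonist,\n")
cat("caffeine, tg_caffeine) sit at zero efficiency; Ca2+-pathway\n")
cat("perturbations (thapsigargin, cpa, orai1_ko, bapta, egta_am) keep\n")
cat("control-level efficiency despite collapsed or reshaped Ca2+ signals --\n")
cat("directed migration does not require the Ca2+ response.\n")
cat("Bootstrap deltas vs control: results/preset_deltas_vs_control.csv\n")
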