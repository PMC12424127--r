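#!/usr/bin/env Rscript
# Ratiometric Ca2+ responses along the gradient, and the store-operated
# entry (SOCE) re-addition protocol in wild-type vs ORAI1-KO cells.
#
# The ADP challenge evokes a biphasic cytosolic Ca2+ response: an early
# ER-release peak plus a sustained SOCE plateau, both decaying with the
# cell's distance from the tip. In the re-addition protocol the stimulus is
# given in Ca2+-free bath (isolating the store-release peak) and
# extracellular Ca2+ is restored later; the post-re-addition slope of
# dF/F0 is the SOCE rate, which ORAI1 deletion abolishes.

library(chemotaxr)

dir.create("results", showWarnings = FALSE)

cm <- calcium_model()
bin_mids <- c(150, 250, 350, 450)

# --- distance dependence of the ADP-evoked response -------------------------
traces <- unlist(lapply(bin_mids, function(r) {
  lapply(1:12, function(i)
    simulate_calcium(cm, r_um = r, duration = 260, dt = 1,
                     seed = 7000 + 100 * r + i))
}), recursive = FALSE)
tbl <- calcium_metrics(traces)
by_bin <- aggregate(cbind(amplitude, integral, rise_time_s) ~ bin, tbl, mean)
write.csv(tbl, "results/calcium_per_cell.csv", row.names = FALSE)
write.csv(by_bin, "results/calcium_by_bin.csv", row.names = FALSE)

cat("ADP-evoked Ca2+ metrics by radial bin (first 100 s after challenge):\n")
print(by_bin, row.names = FALSE)
cat("\nAmplitude and integral fall monotonically with distance, mirroring\n")
cat("the dose dependence of receptor activation along the 1/r gradient.\n\n")

# --- SOCE protocol: WT vs ORAI1 KO ------------------------------------------
soce_run <- function(preset_name) {
  tr <- lapply(1:20, function(i)
    simulate_calcium(cm, r_um = 150, duration = 400, dt = 1,
                     seed = 9000 + i, preset = preset(preset_name),
                     readdition_time = 250, ratiometric = FALSE))
  calcium_metrics(tr, readdition_time = 250)
}
wt <- soce_run("control")
ko <- soce_run("orai1_ko")
soce <- data.frame(
  genotype = c("WT", "ORAI1_KO"),
  soce_rate_s = c(mean(wt$soce_rate_s), mean(ko$soce_rate_s)),
  store_peak_amplitude = c(mean(wt$amplitude), mean(ko$amplitude))
)
write.csv(soce, "results/soce_wt_vs_ko.csv", row.names = FALSE)
cat("SOCE re-addition protocol (single-dye, store depleted):\n")
print(soce, row.names = FALSE)
cat("\nORAI1 deletion abolishes the re-addition influx while leaving the\n")
cat("ER store-release peak intact.\n")
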