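#' Default run configuration for the packaged scenario
#'
#' All tunables of the simulate -> render -> track -> metrics chain in one
#' serializable list. Geometry follows the assay: a 650 x 650 px field of
#' 1.3 um binned pixels (845 um on a side) with the pipette tip at the field
#' centre, frames every 15 s, a 10-min analysis window opening 1 min after
#' release, and a 20-frame minimum track length. The default motility preset
#' is calibrated so the full pipeline reports the system-level mean speed
#' (about 5 um/min) and burst speed (about 10 um/min).
#'
#' @param seed Top-level seed; per-stage substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    gradient = list(tip_xy_um = c(650, 650) / 2 * 1.3, pulse_rate_hz = 0.5,
                    pulse_ms = 20, diffusion_um2_s = 300,
                    pipette_conc_uM = 50),
    motility = list(mean_step_speed = 5, speed_cv = 0.4, persistence = 0.5,
                    kappa = 2, sensing_range = 400, dt = 15),
    cohort = list(n_cells = 200, n_experiments = 4, duration_s = 660,
                  r_range = c(100, 500)),
    imaging = list(image_shape = c(650, 650), pixel_size = 1.3,
                   blob_sigma = 3, intensity = 500, background = 100,
                   noise = "poisson"),
    tracking = list(start_after_release = 60, window = 600,
                    target_interval = 15, background_percentile = 0.05,
                    min_area = 9, max_disp = NULL, min_length = 20),
    metrics = list(bin_edges = seq(100, 500, by = 100),
                   efficiency_mode = "net"),
    calcium = list(duration_s = 260, dt = 1, window_s = 100,
                   n_cells_per_bin = 12)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run one full scenario: simulate, render, track, measure
#'
#' Executes the end-to-end chain for one treatment preset: trajectory
#' simulation under the pulsed gradient, synthetic rendering, temporal
#' trimming/downsampling, background subtraction, segmentation, linking and
#' the minimum-track-length filter, then per-track migration metrics, binned
#' MSD curves, experiment-level aggregation, and companion Ca2+ traces with
#' their metric table. Cells are split evenly into `n_experiments`
#' independent replicates (separate seeds) so the aggregation mirrors the
#' assay's experiment-level n. The whole run is reproducible bit for bit
#' from (config, preset, seed).
#'
#' Set `render = FALSE` to skip the imaging stage and measure the simulated
#' trajectories directly (resampled to the tracking interval) — useful for
#' large preset-contract cohorts where imaging is not under test.
#'
#' @param preset_name One of [preset_names()].
#' @param config A [default_config()] list (modify fields as needed).
#' @param render Run the render + track imaging chain (default `TRUE`).
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and a plain-text run log is emitted.
#' @return A list of class `scenario_report`: `config`, `preset`, `tracks`,
#'   `per_cell` (migration metrics), `per_bin` (experiment-level summary),
#'   `msd` (per-bin curves), `calcium` (per-cell Ca2+ metrics),
#'   `calcium_traces`.
#' @export
run_scenario <- function(preset_name = "control", config = default_config(),
                         render = TRUE, out_dir = NULL) {
  pr <- preset(preset_name)
  src <- gradient_source(tip = config$gradient$tip_xy_um,
                         pulse_rate = config$gradient$pulse_rate_hz,
                         pulse_duration = config$gradient$pulse_ms / 1000,
                         diffusion_coefficient = config$gradient$diffusion_um2_s,
                         pipette_concentration = config$gradient$pipette_conc_uM)
  mp <- do.call(motility_params, config$motility)
  co <- config$cohort
  n_exp <- co$n_experiments
  per_exp <- rep(floor(co$n_cells / n_exp), n_exp)
  per_exp[seq_len(co$n_cells - sum(per_exp))] <-
    per_exp[seq_len(co$n_cells - sum(per_exp))] + 1

  all_tracks <- list()
  for (e in seq_len(n_exp)) {
    traj <- simulate_trajectories(mp, src, n_cells = per_exp[e],
                                  duration = co$duration_s,
                                  seed = derive_seed(config$seed, 1000L + e),
                                  preset = pr, r_range = co$r_range)
    if (render) {
      rend <- render_frames(traj,
                            image_shape = config$imaging$image_shape,
                            pixel_size = config$imaging$pixel_size,
                            blob_sigma = config$imaging$blob_sigma,
                            intensity = config$imaging$intensity,
                            background = config$imaging$background,
                            noise = config$imaging$noise,
                            seed = derive_seed(config$seed, 2000L + e))
      series <- trim_and_downsample(rend$series,
                                    config$tracking$start_after_release,
                                    config$tracking$window,
                                    config$tracking$target_interval)
      tr <- track_series(series,
                         max_disp = config$tracking$max_disp,
                         min_length = config$tracking$min_length,
                         min_area = config$tracking$min_area,
                         background_percentile =
                           config$tracking$background_percentile)
    } else {
      tr <- resample_tracks(traj, config$tracking)
    }
    if (nrow(tr) > 0) {
      tr$experiment <- e
      tr$track_id <- paste0("e", e, "_", tr$track_id)
      all_tracks[[e]] <- tr
    }
  }
  tracks <- do.call(rbind, all_tracks)

  tip <- config$gradient$tip_xy_um
  per_cell <- migration_metrics(tracks, tip,
                                edges = config$metrics$bin_edges,
                                efficiency_mode = config$metrics$efficiency_mode)
  per_bin <- aggregate_by_experiment(per_cell)
  msd_bins <- lapply(split(per_cell$track_id, per_cell$bin), function(ids) {
    if (length(ids) < 5) return(NULL) # below the per-lag reporting floor
    msd(tracks[tracks$track_id %in% ids, , drop = FALSE])
  })
  msd_tbl <- do.call(rbind, Map(function(b, m) {
    if (is.null(m) || nrow(m) == 0) return(NULL)
    cbind(bin = b, m)
  }, names(msd_bins), msd_bins))

  cm <- calcium_model()
  ca <- config$calcium
  bin_mids <- config$metrics$bin_edges[-1] - diff(config$metrics$bin_edges) / 2
  traces <- list()
  k <- 0
  for (b in seq_along(bin_mids)) {
    for (j in seq_len(ca$n_cells_per_bin)) {
      k <- k + 1
      traces[[k]] <- simulate_calcium(cm, r_um = bin_mids[b],
                                      duration = ca$duration_s, dt = ca$dt,
                                      seed = derive_seed(config$seed,
                                                         3000L + k),
                                      preset = pr)
    }
  }
  ca_tbl <- calcium_metrics(traces,
                            window = NULL,
                            edges = config$metrics$bin_edges)

  report <- structure(
    list(config = config, preset = preset_name, tracks = tracks,
         per_cell = per_cell, per_bin = per_bin, msd = msd_tbl,
         calcium = ca_tbl, calcium_traces = traces),
    class = "scenario_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Resample simulated trajectories onto the tracking clock without imaging:
# drop positions before the analysis window opens, thin to the target
# interval, apply the minimum-length rule.
resample_tracks <- function(traj, tracking) {
  dt <- attr(traj, "dt")
  stride <- ceiling(tracking$target_interval / dt)
  keep_t <- sort(unique(traj$time_s))
  keep_t <- keep_t[keep_t >= tracking$start_after_release]
  keep_t <- keep_t[seq(1, length(keep_t), by = stride)]
  keep_t <- keep_t[keep_t <= keep_t[1] + tracking$window]
  out <- traj[traj$time_s %in% keep_t, , drop = FALSE]
  names(out)[names(out) == "cell_id"] <- "track_id"
  out <- filter_min_length(out, tracking$min_length)
  class(out) <- c("track_set", "data.frame")
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario_report: preset '%s', %d tracks, %d cells measured\n",
              x$preset, length(unique(x$tracks$track_id)), nrow(x$per_cell)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_cell, file.path(out_dir, "per_cell_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_bin, file.path(out_dir, "per_bin_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$msd))
    utils::write.csv(report$msd, file.path(out_dir, "msd.csv"),
                     row.names = FALSE)
  utils::write.csv(report$calcium, file.path(out_dir, "calcium_metrics.csv"),
                   row.names = FALSE)
  log <- c(sprintf("preset: %s", report$preset),
           sprintf("seed: %d", report$config$seed),
           sprintf("tracks: %d", length(unique(report$tracks$track_id))),
           sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Compare two scenario reports bin by bin
#'
#' Differences (a minus b) of experiment-level bin means for each metric,
#' with seeded bootstrap confidence intervals obtained by resampling
#' experiments. No hypothesis tests are computed.
#'
#' @param report_a,report_b Two [run_scenario()] reports with identical bin
#'   edges.
#' @param metrics Metric columns to compare.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Bootstrap seed.
#' @return Data.frame `bin`, `metric`, `delta`, `ci_lo`, `ci_hi`.
#' @export
compare_conditions <- function(report_a, report_b,
                               metrics = c("efficiency", "speed_um_min"),
                               n_boot = 1000, conf = 0.95, seed = 1) {
  ea <- report_a$config$metrics$bin_edges
  eb <- report_b$config$metrics$bin_edges
  if (!identical(ea, eb)) stop("reports have different bin edges")
  exp_means <- function(per_cell, m, b) {
    sub <- per_cell[per_cell$bin == b & !is.na(per_cell[[m]]), ]
    if (nrow(sub) == 0) return(NULL)
    as.numeric(tapply(sub[[m]], sub$experiment, mean))
  }
  set.seed(derive_seed(seed, 99L))
  combos <- expand.grid(bin = levels(report_a$per_cell$bin),
                        metric = metrics, stringsAsFactors = FALSE)
  alpha <- (1 - conf) / 2
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    b <- combos$bin[i]; m <- combos$metric[i]
    ma <- exp_means(report_a$per_cell, m, b)
    mb <- exp_means(report_b$per_cell, m, b)
    if (is.null(ma) || is.null(mb)) return(NULL)
    boot <- replicate(n_boot, {
      mean(sample(ma, replace = TRUE)) - mean(sample(mb, replace = TRUE))
    })
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    data.frame(bin = b, metric = m, delta = mean(ma) - mean(mb),
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' System-level speeds from a scenario report
#'
#' The two headline numbers of the packaged default scenario: the mean
#' per-track speed (total path length over elapsed time) and the burst speed
#' (mean over tracks of the maximum frame-to-frame speed), both in um/min.
#'
#' @param report A [run_scenario()] report.
#' @return Named list `mean_speed_um_min`, `burst_speed_um_min`, `n_tracks`.
#' @export
pipeline_speeds <- function(report) {
  list(mean_speed_um_min = mean(report$per_cell$speed_um_min),
       burst_speed_um_min = mean(report$per_cell$burst_um_min),
       n_tracks = nrow(report$per_cell))
}
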