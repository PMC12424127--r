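# Per-track migration statistics and their radially binned aggregation.
#
# A "track" here is any data.frame with columns time_s, x_um, y_um, ordered
# in time; track sets carry track_id (or cell_id) to split on.

track_id_col <- function(tracks) {
  if ("track_id" %in% names(tracks)) "track_id"
  else if ("cell_id" %in% names(tracks)) "cell_id"
  else stop("need a track_id or cell_id column")
}

split_tracks <- function(tracks) split(tracks, tracks[[track_id_col(tracks)]])

step_lengths <- function(track) {
  sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
}

#' Total path length of a track
#' @param track Data.frame with `x_um`, `y_um` ordered in time.
#' @return Path length, um.
#' @export
path_length <- function(track) sum(step_lengths(track))

#' Net displacement of a track
#' @inheritParams path_length
#' @return Euclidean distance between first and last position, um.
#' @export
net_displacement <- function(track) {
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

radial_distance <- function(track, tip) {
  sqrt((track$x_um - tip[1])^2 + (track$y_um - tip[2])^2)
}

#' Directed-migration efficiency (chemotactic index)
#'
#' Ratio of the distance travelled toward the centre of the gradient to the
#' total distance covered. "Distance travelled toward the centre" is read as
#' the net radial approach, r(first) - r(last), which bounds the index in
#' \[-1, 1\] and makes `efficiency * speed = line_speed_to_tip` an exact
#' identity; positive values mean net approach. The alternative reading
#' (sum of positive radial step components) is available as
#' `mode = "positive_steps"`.
#'
#' @param track Data.frame with `time_s`, `x_um`, `y_um` (>= 2 rows).
#' @param tip Pipette tip, um (length 2).
#' @param mode `"net"` (default) or `"positive_steps"`.
#' @return Dimensionless efficiency, or `NA` with a `reason` attribute for a
#'   stationary track (zero path length).
#' @export
migration_efficiency <- function(track, tip, mode = c("net", "positive_steps")) {
  mode <- match.arg(mode)
  stopifnot(nrow(track) >= 2)
  pl <- path_length(track)
  if (pl == 0) return(structure(NA_real_, reason = "stationary"))
  r <- radial_distance(track, tip)
  towards <- switch(mode,
                    net = r[1] - r[length(r)],
                    positive_steps = sum(pmax(0, -diff(r))))
  towards / pl
}

#' Cell speed: total path length over elapsed time
#'
#' @inheritParams migration_efficiency
#' @return Speed in um/min.
#' @export
track_speed <- function(track) {
  if (nrow(track) < 2) stop("speed needs at least 2 points")
  elapsed <- track$time_s[nrow(track)] - track$time_s[1]
  if (elapsed <= 0) stop("elapsed time must be > 0")
  path_length(track) / (elapsed / 60)
}

#' Line speed to the tip: mean velocity toward the gradient centre
#'
#' Signed net radial approach over elapsed time; negative values indicate
#' net retreat from the tip.
#'
#' @inheritParams migration_efficiency
#' @return Speed in um/min.
#' @export
line_speed_to_tip <- function(track, tip) {
  if (nrow(track) < 2) stop("line speed needs at least 2 points")
  elapsed <- track$time_s[nrow(track)] - track$time_s[1]
  if (elapsed <= 0) stop("elapsed time must be > 0")
  r <- radial_distance(track, tip)
  (r[1] - r[length(r)]) / (elapsed / 60)
}

#' Straightness: net displacement over path length
#'
#' Tip-independent proxy for how line-like a trajectory is: 1 for straight
#' motion in any direction, 0 for a closed loop.
#'
#' @inheritParams migration_efficiency
#' @return Dimensionless in \[0, 1\], or `NA` (reason `"stationary"`).
#' @export
straightness <- function(track) {
  pl <- path_length(track)
  if (pl == 0) return(structure(NA_real_, reason = "stationary"))
  net_displacement(track) / pl
}

#' Peak frame-to-frame speed of a track
#'
#' Maximum single-step displacement divided by the frame interval — the
#' per-cell "burst" speed.
#'
#' @inheritParams migration_efficiency
#' @return Speed in um/min.
#' @export
burst_speed <- function(track) {
  if (nrow(track) < 2) stop("burst speed needs at least 2 points")
  max(step_lengths(track) / (diff(track$time_s) / 60))
}

#' Assign tracks to 100-um radial bins
#'
#' Bins by the radial distance at each track's first analysed frame into
#' half-open intervals \[e_i, e_(i+1)); distances below the first or at/above
#' the last edge go to `"out_of_range"`. Bin membership is frozen at the
#' first frame — cells do not change bins mid-analysis.
#'
#' @param r0 Initial radial distances, um.
#' @param edges Strictly increasing bin edges, um (default 100..500 by 100).
#' @return Factor with levels like `"[100,200)"` plus `"out_of_range"`.
#' @export
radial_bin <- function(r0, edges = seq(100, 500, by = 100)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  lev <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  idx <- findInterval(r0, edges, rightmost.closed = FALSE)
  out <- rep("out_of_range", length(r0))
  in_range <- idx >= 1 & idx < length(edges)
  out[in_range] <- lev[idx[in_range]]
  factor(out, levels = c(lev, "out_of_range"))
}

#' Per-track migration metrics table
#'
#' Computes efficiency, speed, line speed to the tip, straightness, burst
#' speed, path length, net displacement and initial radius for every track,
#' with its radial bin. Stationary tracks are excluded with a reason code in
#' the `excluded` attribute.
#'
#' @param tracks A track set (`track_id` or `cell_id`, `time_s`, `x_um`,
#'   `y_um`).
#' @param tip Pipette tip, um.
#' @param edges Radial bin edges passed to [radial_bin()].
#' @param efficiency_mode Passed to [migration_efficiency()].
#' @return Data.frame, one row per track: `track_id`, `r0_um`, `bin`,
#'   `efficiency`, `speed_um_min`, `line_speed_um_min`, `straightness`,
#'   `burst_um_min`, `path_length_um`, `net_displacement_um`, `n_frames`
#'   (plus `population`/`experiment` if present in the input).
#' @export
migration_metrics <- function(tracks, tip, edges = seq(100, 500, by = 100),
                              efficiency_mode = "net") {
  parts <- split_tracks(tracks)
  rows <- lapply(parts, function(tr) {
    r0 <- radial_distance(tr[1, ], tip)
    data.frame(
      track_id = tr[[track_id_col(tr)]][1],
      r0_um = r0,
      efficiency = as.numeric(migration_efficiency(tr, tip, efficiency_mode)),
      speed_um_min = track_speed(tr),
      line_speed_um_min = line_speed_to_tip(tr, tip),
      straightness = as.numeric(straightness(tr)),
      burst_um_min = burst_speed(tr),
      path_length_um = path_length(tr),
      net_displacement_um = net_displacement(tr),
      n_frames = nrow(tr),
      population = if ("population" %in% names(tr)) tr$population[1] else NA,
      experiment = if ("experiment" %in% names(tr)) tr$experiment[1] else NA
    )
  })
  out <- do.call(rbind, rows)
  out$bin <- radial_bin(out$r0_um, edges)
  excluded <- out[is.na(out$efficiency), "track_id"]
  res <- out[!is.na(out$efficiency), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- data.frame(track_id = excluded,
                                      reason = rep("stationary",
                                                   length(excluded)))
  res
}

#' Ensemble mean squared displacement from track origins
#'
#' MSD(tau) is the mean over cells of the squared displacement from each
#' track's first analysed position after a lag tau — displacement from the
#' origin, with no sliding-window time averaging (set
#' `time_average = TRUE` for the overlapping-window variant). Lags are
#' multiples of the common frame interval; lags with fewer than `min_cells`
#' contributing tracks are dropped.
#'
#' @param tracks A track set with a uniform frame interval.
#' @param max_lag Largest lag, s (default: longest available).
#' @param min_cells Minimum tracks per reported lag (default 5).
#' @param time_average If `TRUE`, average over all same-lag pairs within each
#'   track instead of origin-anchored displacements.
#' @return Data.frame `lag_s`, `msd_um2`, `sem`, `n`; zero rows (with a
#'   warning) if no track is long enough.
#' @export
msd <- function(tracks, max_lag = NULL, min_cells = 5, time_average = FALSE) {
  parts <- split_tracks(tracks)
  dts <- unlist(lapply(parts, function(tr) diff(tr$time_s)))
  if (length(dts) == 0) {
    warning("no track long enough for any lag")
    return(data.frame(lag_s = numeric(0), msd_um2 = numeric(0),
                      sem = numeric(0), n = integer(0)))
  }
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("msd requires a uniform frame interval across tracks")
  max_steps <- max(vapply(parts, nrow, integer(1))) - 1
  if (!is.null(max_lag)) max_steps <- min(max_steps, floor(max_lag / dt))
  rows <- lapply(seq_len(max_steps), function(k) {
    sq <- unlist(lapply(parts, function(tr) {
      n <- nrow(tr)
      if (n <= k) return(NULL)
      if (time_average) {
        i <- seq_len(n - k)
        mean((tr$x_um[i + k] - tr$x_um[i])^2 + (tr$y_um[i + k] - tr$y_um[i])^2)
      } else {
        (tr$x_um[1 + k] - tr$x_um[1])^2 + (tr$y_um[1 + k] - tr$y_um[1])^2
      }
    }))
    if (length(sq) < min_cells) return(NULL)
    data.frame(lag_s = k * dt, msd_um2 = mean(sq),
               sem = stats::sd(sq) / sqrt(length(sq)), n = length(sq))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no lag reached the minimum number of contributing tracks")
    out <- data.frame(lag_s = numeric(0), msd_um2 = numeric(0),
                      sem = numeric(0), n = integer(0))
  }
  out
}

#' Translate tracks to tip-centred ("flower plot") coordinates
#'
#' Rigid translation putting the pipette tip at the origin; pairwise
#' distances are unchanged and the transform is exactly invertible.
#'
#' @param tracks A track set.
#' @param tip Pipette tip, um.
#' @return The track set with `x_um`, `y_um` translated.
#' @export
flower_transform <- function(tracks, tip) {
  tracks$x_um <- tracks$x_um - tip[1]
  tracks$y_um <- tracks$y_um - tip[2]
  tracks
}

#' Two-level aggregation: cells within experiments, then across experiments
#'
#' For each (bin, metric): first average cells within each independent
#' experiment, then report the mean and s.e.m. across experiment means. The
#' reported n is the number of experiments, not cells, so cell-count
#' imbalance between experiments does not bias the summary. With a single
#' experiment the s.e.m. is reported as `NA`.
#'
#' @param per_cell Output of [migration_metrics()] (or any per-cell table)
#'   with columns `bin`, `experiment` and the metrics in `metrics`.
#' @param metrics Character vector of metric column names.
#' @return Data.frame `bin`, `metric`, `mean`, `sem`, `n_experiments`,
#'   `n_cells`.
#' @export
aggregate_by_experiment <- function(per_cell,
                                    metrics = c("efficiency", "speed_um_min",
                                                "line_speed_um_min",
                                                "straightness")) {
  stopifnot(all(c("bin", "experiment") %in% names(per_cell)),
            all(metrics %in% names(per_cell)))
  combos <- expand.grid(bin = levels(per_cell$bin), metric = metrics,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    b <- combos$bin[i]; m <- combos$metric[i]
    sub <- per_cell[per_cell$bin == b & !is.na(per_cell[[m]]), ]
    if (nrow(sub) == 0) return(NULL)
    em <- tapply(sub[[m]], sub$experiment, mean)
    data.frame(bin = b, metric = m, mean = mean(em),
               sem = if (length(em) > 1) stats::sd(em) / sqrt(length(em))
                     else NA_real_,
               n_experiments = length(em), n_cells = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
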