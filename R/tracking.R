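#' Trim a series to the analysis window and downsample in time
#'
#' Reproduces the assay's temporal curation: starting
#' `start_after_release` seconds after chemoattractant release, keep a
#' `window`-second stretch and thin frames to the smallest stride whose
#' resulting interval is at least `target_interval` (extra frames are
#' removed; nothing is interpolated). With the default 0.3 frames/s raw rate
#' and a 15 s target this keeps every 5th frame (16.67 s apart).
#'
#' @param series A [frame_series()].
#' @param start_after_release Seconds after release at which the analysis
#'   window opens (default 60 s).
#' @param window Window length, s (default 600 s). If it extends past the
#'   end of the series it is truncated with a warning.
#' @param target_interval Desired inter-frame interval, s (default 15;
#'   must be >= the native interval).
#' @return A trimmed, downsampled [frame_series()].
#' @export
trim_and_downsample <- function(series, start_after_release = 60,
                                window = 600, target_interval = 15) {
  stopifnot(inherits(series, "frame_series"))
  if (target_interval < series$frame_interval)
    stop("target_interval must be >= the native frame interval")
  times <- frame_times(series)
  t_start <- series$t0_offset + start_after_release
  first <- which(times >= t_start)[1]
  if (is.na(first)) stop("analysis window starts after the series ends")
  stride <- ceiling(target_interval / series$frame_interval)
  idx <- seq(first, length(times), by = stride)
  t_end <- times[first] + window
  if (max(times) < t_end) {
    warning("analysis window extends past the series end; truncating")
  }
  idx <- idx[times[idx] <= t_end]
  frame_series(series$frames[idx],
               frame_interval = stride * series$frame_interval,
               pixel_size = series$pixel_size,
               t0_offset = series$t0_offset - times[first],
               channel = series$channel)
}

#' Subtract a scalar background from every frame
#'
#' The per-frame background is estimated as a low percentile of the frame's
#' pixel values (default 5th percentile, a mode-equivalent for images
#' dominated by background) and subtracted, clipping at zero. A percentile
#' estimator is used in preference to rolling-ball filtering because it is
#' deterministic and exactly testable.
#'
#' @param series A [frame_series()].
#' @param percentile Background percentile in \[0, 1) (default 0.05).
#' @return The background-subtracted [frame_series()].
#' @export
subtract_background <- function(series, percentile = 0.05) {
  stopifnot(inherits(series, "frame_series"))
  series$frames <- lapply(series$frames, function(m) {
    b <- stats::quantile(m, percentile, names = FALSE)
    pmax(m - b, 0)
  })
  series
}

# Merge 4-connected labels that touch diagonally, giving 8-connectivity.
# Union-find over the label adjacency induced by the two diagonal shifts.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left neighbours
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  # compact to consecutive ids for stable downstream bookkeeping
  map <- integer(n); map[sort(unique(root))] <- seq_along(unique(root))
  lab[lab > 0] <- map[root[lab[lab > 0]]]
  lab
}

#' Segment one frame into cell centroids
#'
#' Global threshold (Otsu's bimodal split by default, via EBImage), 8-connected
#' component labelling, removal of components smaller than `min_area`, and
#' intensity-weighted centroids of the surviving components.
#'
#' @param image Numeric matrix (row = y, column = x), non-negative.
#' @param min_area Minimum component area in px^2 (default 9).
#' @param threshold `"otsu"` or a numeric threshold in image units.
#' @return A data.frame with zero-based pixel coordinates `x_px`, `y_px`,
#'   plus `area` and `total_intensity`; zero rows for an all-background
#'   frame.
#' @export
segment_frame <- function(image, min_area = 9, threshold = "otsu") {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("image must be non-negative")
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area = numeric(0), total_intensity = numeric(0))
  mx <- max(image)
  if (mx <= 0) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1)) * mx
  } else {
    as.numeric(threshold)
  }
  mask <- image > thr
  if (!any(mask)) return(empty)
  lab <- merge_diagonal_labels(EBImage::bwlabel(mask))
  idx <- which(lab > 0)
  ids <- lab[idx]
  w <- image[idx]
  rows0 <- (idx - 1) %% nrow(image)        # zero-based row (y)
  cols0 <- (idx - 1) %/% nrow(image)       # zero-based col (x)
  area <- tabulate(ids)
  wt <- tapply(w, ids, sum)
  xw <- tapply(w * cols0, ids, sum)
  yw <- tapply(w * rows0, ids, sum)
  keep <- area >= min_area
  out <- data.frame(x_px = (xw / wt)[keep], y_px = (yw / wt)[keep],
                    area = area[keep], total_intensity = as.numeric(wt)[keep])
  rownames(out) <- NULL
  out[order(out$y_px, out$x_px), , drop = FALSE]
}

#' Detect cells in every frame of a series
#'
#' Applies [segment_frame()] to each frame and stamps frame index, time and
#' micrometre coordinates.
#'
#' @param series A [frame_series()] (background-subtracted).
#' @inheritParams segment_frame
#' @return A data.frame with columns `frame`, `time_s`, `x_px`, `y_px`,
#'   `x_um`, `y_um`, `area`, `total_intensity`.
#' @export
detect_cells <- function(series, min_area = 9, threshold = "otsu") {
  stopifnot(inherits(series, "frame_series"))
  # times are reported on the release clock (t0_offset is the release time
  # relative to the first frame, so it is negative after trimming)
  times <- frame_times(series) - series$t0_offset
  out <- lapply(seq_along(series$frames), function(f) {
    d <- segment_frame(series$frames[[f]], min_area, threshold)
    if (nrow(d) == 0) return(NULL)
    cbind(frame = f, time_s = times[f], d,
          x_um = d$x_px * series$pixel_size,
          y_um = d$y_px * series$pixel_size)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), time_s = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      area = numeric(0), total_intensity = numeric(0),
                      x_um = numeric(0), y_um = numeric(0))
  rownames(out) <- NULL
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-neighbour assignment between consecutive frames:
#' candidate (track, detection) pairs within `max_disp` are taken in order of
#' ascending distance (ties broken by the track's last (y, x), then the
#' detection's (y, x), lexicographically), each detection and each track used
#' at most once. Unmatched detections start new tracks; unmatched tracks
#' terminate — there is no gap closing, so a missed detection ends a track,
#' matching the "consecutive acquisitions" track-length rule. Tracks shorter
#' than `min_length` positions are then removed.
#'
#' @param detections Output of [detect_cells()] (needs `frame`, `time_s`,
#'   `x_um`, `y_um`).
#' @param max_disp Maximum frame-to-frame displacement, um (> 0).
#' @param min_length Minimum surviving track length in frames (default 20).
#' @return A data.frame of class `track_set` with columns `track_id`,
#'   `frame`, `time_s`, `x_um`, `y_um`; attribute `linking` records the
#'   parameters used.
#' @export
link_tracks <- function(detections, max_disp, min_length = 20) {
  if (max_disp <= 0) stop("max_disp must be > 0")
  if (min_length < 2) stop("min_length must be >= 2")
  cols <- c("frame", "time_s", "x_um", "y_um")
  stopifnot(all(cols %in% names(detections)))
  empty <- structure(
    data.frame(track_id = integer(0), frame = integer(0), time_s = numeric(0),
               x_um = numeric(0), y_um = numeric(0)),
    class = c("track_set", "data.frame"),
    linking = list(max_disp = max_disp, min_length = min_length))
  if (nrow(detections) == 0) return(empty)

  frames <- sort(unique(detections$frame))
  next_id <- 0L
  rows <- vector("list", length(frames))
  active <- NULL # data.frame: track_id, x_um, y_um (position at prev frame)
  prev_frame <- NA_integer_
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- detections[detections$frame == f, cols]
    det <- det[order(det$y_um, det$x_um), , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(det))
    if (!is.null(active) && nrow(active) > 0 && !is.na(prev_frame) &&
        f == prev_frame + 1L) {
      dx <- outer(active$x_um, det$x_um, "-")
      dy <- outer(active$y_um, det$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        o <- order(dist[cand], active$y_um[cand[, 1]], active$x_um[cand[, 1]],
                   det$y_um[cand[, 2]], det$x_um[cand[, 2]])
        cand <- cand[o, , drop = FALSE]
        used_tr <- logical(nrow(active)); used_de <- logical(nrow(det))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_tr[i] && !used_de[j]) {
            used_tr[i] <- TRUE; used_de[j] <- TRUE
            assigned[j] <- active$track_id[i]
          }
        }
      }
    }
    new <- which(is.na(assigned))
    if (length(new) > 0) {
      assigned[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    rows[[fi]] <- data.frame(track_id = assigned, frame = det$frame,
                             time_s = det$time_s,
                             x_um = det$x_um, y_um = det$y_um)
    active <- data.frame(track_id = assigned, x_um = det$x_um,
                         y_um = det$y_um)
    prev_frame <- f
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  attr(out, "linking") <- list(max_disp = max_disp, min_length = min_length)
  filter_min_length(out, min_length)
}

#' Remove tracks shorter than a minimum number of frames
#'
#' The assay's inclusion rule: only cells tracked for at least `min_length`
#' consecutive acquisitions enter the analysis. Idempotent.
#'
#' @param tracks A `track_set` (or any data.frame with `track_id`).
#' @param min_length Minimum number of positions (default 20).
#' @return The filtered track set, attributes preserved.
#' @export
filter_min_length <- function(tracks, min_length = 20) {
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_length]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("linking", "curation")) attr(out, a) <- attr(tracks, a)
  class(out) <- class(tracks)
  out
}

#' Manual-curation hook: exclude tracks by id
#'
#' Stands in for the assay's manual removal of false-positive traces as an
#' explicit, logged exclusion list; excluding nothing is the default and the
#' reproducible path.
#'
#' @param tracks A `track_set`.
#' @param exclude Track ids to drop (default none).
#' @return The curated track set; attribute `curation` records the list.
#' @export
curate_tracks <- function(tracks, exclude = integer(0)) {
  out <- tracks[!(tracks$track_id %in% exclude), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "linking") <- attr(tracks, "linking")
  attr(out, "curation") <- list(excluded = exclude)
  class(out) <- class(tracks)
  out
}

#' Assign each track to a dye population
#'
#' For dual-population experiments in which two cell lines carry spectrally
#' distinct dyes in the same dish: each track is labelled by the channel with
#' the higher track-median intensity. Tracks whose median intensity ratio is
#' within `ambiguity` of 1 are labelled `"unassigned"` and excluded from
#' per-population summaries.
#'
#' @param tracks A `track_set`.
#' @param series_a,series_b The two channel [frame_series()] objects
#'   (aligned with the tracked frames).
#' @param labels Length-2 population labels.
#' @param ambiguity Ratio band treated as ambiguous (default 1.2).
#' @param radius_px Half-width of the square sampling patch around each
#'   position.
#' @return `tracks` with a `population` column added.
#' @export
assign_population <- function(tracks, series_a, series_b,
                              labels = c("population_A", "population_B"),
                              ambiguity = 1.2, radius_px = 2) {
  stopifnot(inherits(series_a, "frame_series"), inherits(series_b, "frame_series"))
  sample_int <- function(series, frame, x_um, y_um) {
    img <- series$frames[[frame]]
    x <- round(x_um / series$pixel_size); y <- round(y_um / series$pixel_size)
    rows <- pmax(0, y - radius_px):pmin(nrow(img) - 1, y + radius_px)
    cols <- pmax(0, x - radius_px):pmin(ncol(img) - 1, x + radius_px)
    mean(img[rows + 1, cols + 1])
  }
  ids <- unique(tracks$track_id)
  pop <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    ia <- mapply(sample_int, frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um,
                 MoreArgs = list(series = series_a))
    ib <- mapply(sample_int, frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um,
                 MoreArgs = list(series = series_b))
    ma <- stats::median(ia); mb <- stats::median(ib)
    if (mb <= 0 && ma <= 0) return("unassigned")
    ratio <- if (mb <= 0) Inf else ma / mb
    if (ratio >= ambiguity) labels[1]
    else if (ratio <= 1 / ambiguity) labels[2]
    else "unassigned"
  }, character(1))
  tracks$population <- pop[match(tracks$track_id, ids)]
  tracks
}

#' Full detection-to-tracks chain on a frame series
#'
#' Convenience composition of [subtract_background()], [detect_cells()],
#' [link_tracks()] and [curate_tracks()].
#'
#' @param series A [frame_series()].
#' @param max_disp Maximum frame-to-frame displacement, um. The default,
#'   `3 * 5 um/min * frame_interval`, covers burst steps without
#'   cross-linking neighbours at the assay's plating density.
#' @param min_length Minimum track length, frames.
#' @param min_area Minimum component area, px^2.
#' @param background_percentile Passed to [subtract_background()].
#' @param exclude Curation exclusion list.
#' @return A `track_set`.
#' @export
track_series <- function(series, max_disp = NULL, min_length = 20,
                         min_area = 9, background_percentile = 0.05,
                         exclude = integer(0)) {
  if (is.null(max_disp)) max_disp <- 3 * 5 / 60 * series$frame_interval
  series <- subtract_background(series, background_percentile)
  det <- detect_cells(series, min_area = min_area)
  tr <- link_tracks(det, max_disp = max_disp, min_length = min_length)
  curate_tracks(tr, exclude)
}
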