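#' Time-lapse frame series
#'
#' Minimal container for a single-channel time-lapse stack: an ordered list
#' of identically sized frames (numeric matrices, row = y, column = x) with
#' the acquisition interval, pixel size and the time of chemoattractant
#' release relative to the first frame.
#'
#' Pixel coordinates are zero-based with the origin at the top-left pixel
#' centre, x along columns and y along rows; micrometre coordinates are
#' pixel coordinates times `pixel_size`, and the pipette tip is specified in
#' micrometres in the same frame.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_interval Seconds between frames (> 0).
#' @param pixel_size Micrometres per (binned) pixel; default 1.3.
#' @param t0_offset Time of chemoattractant release relative to the first
#'   frame, s (release at first frame by default).
#' @param channel Channel label.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_interval, pixel_size = 1.3,
                         t0_offset = 0, channel = "ch1") {
  stopifnot(is.list(frames), length(frames) >= 1, frame_interval > 0,
            pixel_size > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, t0_offset = t0_offset,
                 channel = channel),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_series: %d frames of %dx%d px, %.3g s/frame, %.3g um/px (%s)\n",
              length(x$frames), d[1], d[2], x$frame_interval, x$pixel_size,
              x$channel))
  invisible(x)
}

# Frame acquisition times (s), first frame at 0.
frame_times <- function(series) {
  (seq_along(series$frames) - 1) * series$frame_interval
}

#' Render trajectories to a synthetic fluorescence stack
#'
#' Draws each cell as an isotropic Gaussian blob on a constant background,
#' with optional Poisson shot noise, at the assay's default geometry
#' (650 x 650 binned pixels of 1.3 um, a field of 845 um on a side). Cells
#' whose centroid leaves the field are clipped from both the image and the
#' ground truth for that frame (not wrapped). One frame is rendered per
#' trajectory time point.
#'
#' @param tracks A `trajectory_set` from [simulate_trajectories()].
#' @param image_shape Integer length-2, field size in pixels (rows, cols).
#' @param pixel_size um per pixel.
#' @param blob_sigma Blob standard deviation, px (> 0).
#' @param intensity Peak blob amplitude above background (photon counts).
#' @param background Constant background level.
#' @param noise `"poisson"` for shot noise, `"none"` for a noiseless render.
#' @param seed Integer seed (used only when noise is applied).
#' @return A list with `series` (a [frame_series()]) and `truth`, the exact
#'   per-frame centroid table (`frame`, `time_s`, `cell_id`, `x_um`, `y_um`,
#'   `x_px`, `y_px`) restricted to visible cells.
#' @export
render_frames <- function(tracks, image_shape = c(650, 650), pixel_size = 1.3,
                          blob_sigma = 3, intensity = 500, background = 100,
                          noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(inherits(tracks, "data.frame"),
            all(c("cell_id", "time_s", "x_um", "y_um") %in% names(tracks)))
  if (blob_sigma <= 0) stop("blob_sigma must be > 0")
  nr <- image_shape[1]; nc <- image_shape[2]
  times <- sort(unique(tracks$time_s))
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  pad <- ceiling(4 * blob_sigma)

  if (noise == "poisson") set.seed(derive_seed(seed, 0L))
  frames <- vector("list", length(times))
  truth <- vector("list", length(times))
  for (f in seq_along(times)) {
    sub <- tracks[tracks$time_s == times[f], , drop = FALSE]
    x_px <- sub$x_um / pixel_size
    y_px <- sub$y_um / pixel_size
    vis <- x_px >= 0 & x_px <= nc - 1 & y_px >= 0 & y_px <= nr - 1
    img <- matrix(background, nr, nc)
    for (j in which(vis)) {
      c0 <- max(0, floor(x_px[j]) - pad); c1 <- min(nc - 1, ceiling(x_px[j]) + pad)
      r0 <- max(0, floor(y_px[j]) - pad); r1 <- min(nr - 1, ceiling(y_px[j]) + pad)
      cols <- c0:c1; rows <- r0:r1
      gx <- exp(-(cols - x_px[j])^2 / (2 * blob_sigma^2))
      gy <- exp(-(rows - y_px[j])^2 / (2 * blob_sigma^2))
      img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
        intensity * outer(gy, gx)
    }
    if (noise == "poisson") {
      img <- matrix(stats::rpois(nr * nc, lambda = img), nr, nc)
    }
    frames[[f]] <- img
    truth[[f]] <- data.frame(frame = f, time_s = times[f],
                             cell_id = sub$cell_id[vis],
                             x_um = sub$x_um[vis], y_um = sub$y_um[vis],
                             x_px = x_px[vis], y_px = y_px[vis])
  }
  list(series = frame_series(frames, frame_interval = dt,
                             pixel_size = pixel_size),
       truth = do.call(rbind, truth))
}

#' Write / read a frame series as multi-page TIFF
#'
#' Frames are scaled to 16-bit on write; metadata (interval, pixel size) is
#' not stored in the file and must be supplied on read.
#'
#' @param series A [frame_series()].
#' @param path Output .tif path.
#' @param max_value Full-scale value mapped to 16-bit white.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(series, path, max_value = 65535) {
  imgs <- lapply(series$frames, function(m) pmin(pmax(m / max_value, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @param frame_interval,pixel_size,t0_offset,channel Metadata for the
#'   reconstructed [frame_series()].
#' @export
read_frames_tiff <- function(path, frame_interval, pixel_size = 1.3,
                             t0_offset = 0, channel = "ch1",
                             max_value = 65535) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) m * max_value)
  frame_series(frames, frame_interval, pixel_size, t0_offset, channel)
}
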