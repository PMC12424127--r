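# Imaging chain: temporal trimming/downsampling, background subtraction,
# segmentation, greedy linking, the minimum-length filter, curation and
# population assignment.

const_series <- function(value, n_frames, shape = c(40, 40),
                         frame_interval = 10 / 3) {
  frame_series(replicate(n_frames, matrix(value, shape[1], shape[2]),
                         simplify = FALSE), frame_interval)
}

test_that("downsampling a 0.3 fps series to 15 s keeps every 5th frame", {
  s <- const_series(1, 200) # 3.333 s/frame, release at frame 1
  out <- trim_and_downsample(s, start_after_release = 60, window = 600,
                             target_interval = 15)
  expect_equal(out$frame_interval, 5 * 10 / 3) # ceil(15/3.333) = 5 -> 16.67 s
  # 600 s window at 16.67 s stride: floor(600/16.67) + 1 = 37 frames
  expect_equal(length(out$frames), 37)
  expect_lte(length(out$frames), 41) # never more than the 15 s-budget count
})

test_that("downsampling at the native interval is the identity on the window", {
  s <- const_series(1, 50, frame_interval = 15)
  out <- trim_and_downsample(s, start_after_release = 60, window = 600,
                             target_interval = 15)
  expect_equal(out$frame_interval, 15)
  expect_equal(length(out$frames), 41) # frames at 60, 75, ..., 660 s
  expect_error(trim_and_downsample(s, target_interval = 5), "native")
})

test_that("a window past the series end truncates with a warning", {
  s <- const_series(1, 20, frame_interval = 15) # 285 s of data
  expect_warning(out <- trim_and_downsample(s, 60, 600, 15), "truncat")
  expect_equal(length(out$frames), 16)
})

test_that("background subtraction removes a constant offset exactly", {
  s <- const_series(7.5, 3)
  out <- subtract_background(s)
  expect_true(all(vapply(out$frames, function(m) all(m == 0), logical(1))))
  # blob on constant background: peak reduced by exactly the background
  img <- matrix(20, 50, 50)
  img[25, 25] <- 520
  s2 <- frame_series(list(img), 15)
  out2 <- subtract_background(s2)
  expect_equal(max(out2$frames[[1]]), 500)
})

test_that("residual background is near zero on noisy synthetic frames", {
  set.seed(42)
  imgs <- replicate(20, matrix(rpois(2500, 100), 50, 50), simplify = FALSE)
  out <- subtract_background(frame_series(imgs, 15))
  resid <- vapply(out$frames, mean, numeric(1))
  # 5th-percentile estimator sits ~1.6 sd below the mean of Poisson(100)
  expect_true(all(resid > 0 & resid < 100 * 0.25))
})

test_that("segmentation: blank frames, area filter and 8-connectivity", {
  expect_equal(nrow(segment_frame(matrix(0, 30, 30))), 0)
  # a blob smaller than min_area is discarded
  img <- matrix(0, 30, 30); img[10, 10] <- 100
  expect_equal(nrow(segment_frame(img, min_area = 9)), 0)
  expect_equal(nrow(segment_frame(img, min_area = 1)), 1)
  # two diagonally touching pixels are one 8-connected component
  img2 <- matrix(0, 30, 30); img2[10, 10] <- 100; img2[11, 11] <- 100
  expect_equal(nrow(segment_frame(img2, min_area = 1)), 1)
})

test_that("intensity-weighted centroids are exact on a known blob", {
  img <- matrix(0, 21, 21)
  img[10, 11] <- 30; img[10, 12] <- 10 # x weights: 10,11 (0-based cols)
  det <- segment_frame(img, min_area = 1, threshold = 1)
  expect_equal(det$x_px, (30 * 10 + 10 * 11) / 40)
  expect_equal(det$y_px, 9)
})

# Straight-line detection streams for linking tests.
line_detections <- function(x0, y0, vx, n, frames = seq_len(n)) {
  data.frame(frame = frames, time_s = (frames - 1) * 15,
             x_um = x0 + vx * (seq_len(n) - 1), y_um = y0)
}

test_that("two well-separated cells link into two clean tracks", {
  det <- rbind(line_detections(0, 0, 2, 30), line_detections(0, 200, 2, 30))
  tr <- link_tracks(det, max_disp = 5, min_length = 20)
  expect_equal(length(unique(tr$track_id)), 2)
  for (d in split(tr, tr$track_id)) {
    expect_equal(length(unique(d$y_um)), 1) # no identity switches
    expect_equal(nrow(d), 30)
  }
})

test_that("minimum-length filter keeps exactly the tracks with >= 20 frames", {
  lens <- c(10, 19, 20, 25, 40)
  det <- do.call(rbind, lapply(seq_along(lens), function(i) {
    line_detections(0, 300 * i, 1, lens[i])
  }))
  tr <- link_tracks(det, max_disp = 5, min_length = 20)
  expect_equal(length(unique(tr$track_id)), 3)
  expect_setequal(as.numeric(table(tr$track_id)), c(20, 25, 40))
  # idempotence
  expect_identical(filter_min_length(tr, 20), tr)
})

test_that("a pair gap beyond max_disp starts a new track", {
  det <- line_detections(0, 0, 2, 50)
  det$x_um[26:50] <- det$x_um[26:50] + 100 # teleport mid-stream
  tr <- link_tracks(det, max_disp = 5, min_length = 20)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(7)
  det <- do.call(rbind, lapply(1:6, function(i) {
    line_detections(runif(1, 0, 500), runif(1, 0, 500), rnorm(1), 25)
  }))
  shuffled <- det[sample(nrow(det)), ]
  canon <- function(tr) {
    tr <- tr[order(tr$frame, tr$y_um, tr$x_um), c("frame", "x_um", "y_um")]
    rownames(tr) <- NULL
    tr
  }
  a <- link_tracks(det, 5, 20)
  b <- link_tracks(shuffled, 5, 20)
  expect_equal(canon(a), canon(b))
  expect_equal(length(unique(a$track_id)), length(unique(b$track_id)))
})

test_that("empty detections give an empty track set", {
  tr <- link_tracks(data.frame(frame = integer(0), time_s = numeric(0),
                               x_um = numeric(0), y_um = numeric(0)),
                    max_disp = 5)
  expect_s3_class(tr, "track_set")
  expect_equal(nrow(tr), 0)
})

test_that("curation hook drops listed tracks and logs the exclusion", {
  det <- rbind(line_detections(0, 0, 2, 25), line_detections(0, 200, 2, 25))
  tr <- link_tracks(det, 5, 20)
  ids <- unique(tr$track_id)
  kept <- curate_tracks(tr, exclude = ids[1])
  expect_equal(unique(kept$track_id), ids[2])
  expect_equal(attr(kept, "curation")$excluded, ids[1])
  expect_identical(nrow(curate_tracks(tr)), nrow(tr)) # default: exclude none
})

test_that("population assignment follows the brighter channel, ties are
           unassigned", {
  mk <- function(a_level, b_level) {
    tr <- make_track(rep(65, 25), rep(65, 25))
    tr$frame <- seq_len(25)
    a <- frame_series(replicate(25, matrix(a_level, 100, 100),
                                simplify = FALSE), 15)
    b <- frame_series(replicate(25, matrix(b_level, 100, 100),
                                simplify = FALSE), 15)
    unique(assign_population(tr, a, b)$population)
  }
  expect_equal(mk(100, 5), "population_A")
  expect_equal(mk(5, 100), "population_B")
  expect_equal(mk(50, 50), "unassigned")
})

test_that("a 1:1 dual-dye dish is recovered near 50/50", {
  src <- centre_source()
  mp <- motility_params(kappa = 0)
  wt <- simulate_trajectories(mp, src, 20, 300, seed = 41,
                              r_range = c(100, 350), population = "WT")
  ko <- simulate_trajectories(mp, src, 20, 300, seed = 42,
                              r_range = c(100, 350), population = "KO")
  ko$cell_id <- ko$cell_id + 100
  both <- rbind(wt, ko)
  green <- render_frames(wt, noise = "none")$series
  orange <- render_frames(ko, noise = "none")$series
  tr <- both
  names(tr)[names(tr) == "cell_id"] <- "track_id"
  tr$frame <- match(tr$time_s, sort(unique(tr$time_s)))
  lab <- assign_population(tr, green, orange)
  per_track <- tapply(lab$population, lab$track_id, unique)
  expect_equal(sum(per_track == "population_A"), 20)
  expect_equal(sum(per_track == "population_B"), 20)
})
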