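# Per-track migration statistics against hand-computed and brute-force
# oracles, plus binning, the flower transform and hierarchical aggregation.

test_that("efficiency: radial approach, mixed path, closed loop", {
  tip <- c(0, 0)
  expect_equal(migration_efficiency(radial_track(tip, 300, 100), tip), 1.0)
  # hand-computed: (0,300) -> (0,200) -> (100,200)
  tr <- make_track(c(0, 0, 100), c(300, 200, 200))
  expect_equal(migration_efficiency(tr, tip),
               (300 - sqrt(100^2 + 200^2)) / 200, tolerance = 1e-12)
  expect_equal(round(migration_efficiency(tr, tip), 3), 0.382)
  loop <- make_track(c(0, 50, 50, 0, 0), c(100, 100, 150, 150, 100))
  expect_equal(migration_efficiency(loop, tip), 0)
  # stationary track is excluded with a reason code
  still <- make_track(c(5, 5), c(5, 5))
  expect_true(is.na(migration_efficiency(still, tip)))
  expect_equal(attr(migration_efficiency(still, tip), "reason"), "stationary")
})

test_that("positive-steps efficiency mode counts only approaching segments", {
  tip <- c(0, 0)
  # out-and-back along a radius: net mode 0, positive-steps mode 0.5
  tr <- make_track(c(200, 100, 200), c(0, 0, 0))
  expect_equal(migration_efficiency(tr, tip, mode = "net"), 0)
  expect_equal(migration_efficiency(tr, tip, mode = "positive_steps"), 0.5)
})

test_that("speed is path length over elapsed time, regardless of shape", {
  straight <- make_track(c(0, 100), c(0, 0), t = c(0, 600))
  expect_equal(track_speed(straight), 10)
  zigzag <- make_track(c(0, 50, 0, 50, 0), c(0, 0, 0, 0, 0),
                       t = seq(0, 600, length.out = 5))
  expect_equal(track_speed(zigzag), 20)
  expect_error(track_speed(make_track(1, 1, t = 0)))
})

test_that("line speed to the tip: radial, tangential, and the exact identity
           with efficiency x speed", {
  tip <- c(0, 0)
  expect_equal(line_speed_to_tip(radial_track(tip, 300, 100), tip), 20)
  arc <- make_track(100 * cos(seq(0, pi / 2, length.out = 10)),
                    100 * sin(seq(0, pi / 2, length.out = 10)),
                    t = seq(0, 600, length.out = 10))
  expect_equal(line_speed_to_tip(arc, tip), 0, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    tr <- random_track(15)
    tip2 <- runif(2, -50, 50)
    expect_equal(migration_efficiency(tr, tip2) * track_speed(tr),
                 line_speed_to_tip(tr, tip2), tolerance = 1e-12)
  }
})

test_that("straightness: line, loop, right angle", {
  expect_equal(straightness(make_track(c(0, 30, 60), c(0, 40, 80))), 1.0)
  loop <- make_track(c(0, 50, 50, 0, 0), c(0, 0, 50, 50, 0))
  expect_equal(straightness(loop), 0)
  elbow <- make_track(c(0, 100, 100), c(0, 0, 100))
  expect_equal(straightness(elbow), sqrt(2) * 100 / 200, tolerance = 1e-12)
})

test_that("speed, path length and efficiency match brute-force oracles", {
  set.seed(99)
  tip <- c(10, -20)
  for (i in 1:25) {
    tr <- random_track(sample(5:30, 1))
    expect_equal(path_length(tr), oracle_path_length(tr), tolerance = 1e-12)
    expect_equal(track_speed(tr), oracle_speed(tr), tolerance = 1e-12)
    expect_equal(migration_efficiency(tr, tip), oracle_efficiency(tr, tip),
                 tolerance = 1e-12)
  }
})

test_that("MSD: ballistic exactness, single step, and the min-cells rule", {
  tip <- c(0, 0)
  v <- 6 # um/min
  tracks <- do.call(rbind, lapply(1:6, function(i) {
    radial_track(tip, 400, 400 - v * 10, n = 41, total_min = 10,
                 angle = i, id = i)
  }))
  m <- msd(tracks)
  expect_equal(m$msd_um2, (v / 60)^2 * m$lag_s^2, tolerance = 1e-9)
  expect_true(all(m$n == 6))
  # single two-point track: MSD at one lag equals that squared step
  two <- make_track(c(0, 3), c(0, 4))
  m2 <- msd(two, min_cells = 1)
  expect_equal(m2$msd_um2, 25)
  expect_equal(nrow(m2), 1)
  # below the contributing-track floor nothing is reported
  expect_warning(empty <- msd(two, min_cells = 5), "minimum number")
  expect_equal(nrow(empty), 0)
})

test_that("time-averaged MSD variant uses overlapping windows", {
  tr <- make_track(c(0, 1, 3), c(0, 0, 0))
  anchored <- msd(tr, min_cells = 1)
  sliding <- msd(tr, min_cells = 1, time_average = TRUE)
  expect_equal(anchored$msd_um2[1], 1) # origin step only
  expect_equal(sliding$msd_um2[1], mean(c(1, 4))) # both unit-lag pairs
})

test_that("radial bins are half-open with an out-of-range group", {
  b <- radial_bin(c(150, 200, 80, 500, 499.9))
  expect_equal(as.character(b),
               c("[100,200)", "[200,300)", "out_of_range", "out_of_range",
                 "[400,500)"))
  expect_error(radial_bin(100, edges = c(100, 100, 300)))
})

test_that("flower transform is a rigid, invertible translation", {
  tip <- c(422.5, 422.5)
  tr <- random_track(10)
  ft <- flower_transform(tr, tip)
  tip_track <- flower_transform(make_track(tip[1], tip[2], t = 0), tip)
  expect_equal(c(tip_track$x_um, tip_track$y_um), c(0, 0))
  expect_equal(as.numeric(dist(cbind(ft$x_um, ft$y_um))),
               as.numeric(dist(cbind(tr$x_um, tr$y_um))))
  back <- flower_transform(ft, -tip)
  expect_equal(back, tr)
})

test_that("metrics are invariant under joint rigid motion; straightness and
           speed ignore the tip entirely", {
  set.seed(5)
  tr <- random_track(20)
  tip <- c(30, 40)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(120, -60)
  xy <- cbind(tr$x_um, tr$y_um) %*% t(R)
  tr2 <- make_track(xy[, 1] + shift[1], xy[, 2] + shift[2])
  tip2 <- as.numeric(R %*% tip + shift)
  expect_equal(migration_efficiency(tr2, tip2), migration_efficiency(tr, tip),
               tolerance = 1e-10)
  expect_equal(line_speed_to_tip(tr2, tip2), line_speed_to_tip(tr, tip),
               tolerance = 1e-10)
  expect_equal(track_speed(tr2), track_speed(tr), tolerance = 1e-10)
  expect_equal(straightness(tr2), straightness(tr), tolerance = 1e-10)
  expect_equal(track_speed(tr), track_speed(tr)) # tip plays no role
  expect_equal(straightness(tr2), straightness(make_track(xy[, 1], xy[, 2])))
})

test_that("experiment-level aggregation and its edge cases", {
  per_cell <- data.frame(
    bin = factor("[100,200)", levels = c("[100,200)", "out_of_range")),
    experiment = c(1, 1, 1, 2),
    efficiency = c(0.2, 0.2, 0.2, 0.4),
    speed_um_min = 5, line_speed_um_min = 1, straightness = 0.5)
  out <- aggregate_by_experiment(per_cell)
  eff <- out[out$metric == "efficiency", ]
  # experiment means 0.2 and 0.4 -> mean 0.3, sem 0.1; imbalance (3 vs 1
  # cells) does not tilt the experiment-level mean
  expect_equal(eff$mean, 0.3)
  expect_equal(eff$sem, 0.1)
  expect_equal(eff$n_experiments, 2)
  expect_equal(eff$n_cells, 4)
  one <- aggregate_by_experiment(per_cell[4, ])
  expect_true(is.na(one$sem[one$metric == "efficiency"]))
})

test_that("migration_metrics excludes stationary tracks with a reason", {
  tracks <- rbind(make_track(c(200, 210, 220), c(0, 0, 0), id = 1L),
                  make_track(c(150, 150, 150), c(0, 0, 0), id = 2L))
  pc <- migration_metrics(tracks, tip = c(0, 0))
  expect_equal(pc$track_id, 1)
  expect_equal(attr(pc, "excluded")$track_id, 2)
  expect_equal(attr(pc, "excluded")$reason, "stationary")
})
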