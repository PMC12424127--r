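# Ratiometric Ca2+ metrics: ratio, baseline normalization, amplitude,
# integral, rise time and the SOCE rate, against closed forms and
# root-finding oracles.

ramp_trace <- function(slope = 0.05, onset = 30, duration = 100, dt = 0.5) {
  t <- seq(0, duration, by = dt)
  v <- 1 + pmax(0, t - onset) * slope
  normalize_trace(t, v, onset)
}

test_that("ratio is elementwise division with ratiometric invariance", {
  G <- c(1, 2, 3.5); T_ch <- c(2, 2, 7)
  expect_equal(compute_ratio(G, T_ch), G / T_ch)
  expect_equal(compute_ratio(G, G), rep(1, 3))
  expect_equal(compute_ratio(3.7 * G, 3.7 * T_ch), compute_ratio(G, T_ch))
  expect_error(compute_ratio(c(1, 2), c(1, 0, 2)), "length")
  expect_error(compute_ratio(c(1, 2, 3), c(1, 0, 2)), "frame\\(s\\) 2")
})

test_that("normalization: constant trace, known peak, baseline guards", {
  t <- 0:100
  expect_equal(normalize_trace(t, rep(2.4, 101), onset = 50)$values,
               rep(0, 101))
  v <- rep(1, 101); v[70] <- 1.5
  nt <- normalize_trace(t, v, onset = 50)
  expect_equal(max(nt$values), 0.5)
  expect_equal(nt$R0, 1)
  expect_error(normalize_trace(t[1:4], v[1:4], onset = 2), "3 baseline")
  expect_error(normalize_trace(t, v - 1, onset = 50), "R0")
})

test_that("noisy baseline normalizes to zero mean within standard error", {
  set.seed(12)
  ok <- 0
  for (i in 1:30) {
    t <- 0:199
    v <- 2 * (1 + rnorm(200, 0, 0.03))
    nt <- normalize_trace(t, v, onset = 100)
    pre <- nt$values[t < 100]
    ok <- ok + (abs(mean(pre)) < 3 * sd(pre) / sqrt(length(pre)))
  }
  expect_gte(ok, 28) # ~3 s.e. band should cover essentially always
})

test_that("amplitude: flat zero trace, window restriction", {
  flat <- normalize_trace(0:200, rep(1, 201), onset = 60)
  expect_equal(ca_amplitude(flat), 0)
  # amplitude in the 100 s window never exceeds the global maximum
  t <- 0:300
  v <- 1 + 0.8 * exp(-(t - 250)^2 / 50) + 0.3 * exp(-(t - 100)^2 / 100)
  nt <- normalize_trace(t, v, onset = 60)
  expect_lte(ca_amplitude(nt), max(nt$values))
  expect_equal(ca_amplitude(nt, window = c(0, 300)), max(nt$values))
})

test_that("integral: rectangular pulse area, zero trace, linearity", {
  dt <- 0.01
  t <- seq(0, 200, by = dt)
  v <- 1 + 0.5 * (t >= 100 & t < 120)
  nt <- normalize_trace(t, v, onset = 60)
  expect_equal(ca_integral(nt), 10, tolerance = 2 * dt) # edge discretization
  zero <- normalize_trace(0:200, rep(1, 201), onset = 60)
  expect_equal(ca_integral(zero), 0)
  nt2 <- nt; nt2$values <- 3 * nt$values
  expect_equal(ca_integral(nt2), 3 * ca_integral(nt), tolerance = 1e-12)
})

test_that("rise time: linear ramp gives the 10-90% answer, steps are fast,
           sub-threshold traces are reason-coded", {
  # ramp from 0 to peak over 10 s: 10-90% spans 8 s
  t <- seq(0, 160, by = 0.01)
  v <- 1 + 0.5 * pmin(1, pmax(0, (t - 60) / 10))
  nt <- normalize_trace(t, v, onset = 60)
  expect_equal(rise_time(nt), 8, tolerance = 0.01)
  # one-sample step: rise time bounded by one frame interval
  ts <- 0:160
  vs <- ifelse(ts < 80, 1, 1.6)
  nts <- normalize_trace(ts, vs, onset = 60)
  expect_lte(rise_time(nts), 1)
  # flat noisy trace below 5 sd of baseline noise -> NA with reason
  set.seed(3)
  vn <- 1 + rnorm(161, 0, 0.01)
  ntn <- normalize_trace(ts, vn, onset = 60)
  rt <- rise_time(ntn)
  expect_true(is.na(rt))
  expect_equal(attr(rt, "reason"), "sub_threshold")
})

test_that("rise time of a double exponential matches a root-finding oracle", {
  cm <- calcium_model(noise_sd = 0, plateau_amp_at_0 = 0)
  tr <- simulate_calcium(cm, r_um = 0, duration = 200, dt = 0.002, seed = 1)
  nt <- normalize_trace(tr$time_s, compute_ratio(tr$G, tr$T),
                        onset = cm$stimulus_onset)
  measured <- rise_time(nt)
  # oracle: invert the continuous double exponential with uniroot
  h <- function(t) {
    (exp(-t / cm$peak_decay_tau) - exp(-t / cm$peak_rise_tau))
  }
  t_star <- cm$peak_rise_tau * cm$peak_decay_tau /
    (cm$peak_decay_tau - cm$peak_rise_tau) *
    log(cm$peak_decay_tau / cm$peak_rise_tau)
  peak <- h(t_star)
  t10 <- uniroot(function(t) h(t) - 0.1 * peak, c(1e-9, t_star),
                 tol = 1e-10)$root
  t90 <- uniroot(function(t) h(t) - 0.9 * peak, c(1e-9, t_star),
                 tol = 1e-10)$root
  expect_equal(measured, t90 - t10, tolerance = 0.01)
})

test_that("SOCE rate: ramp slope, flat trace, and estimator modes", {
  nt <- ramp_trace(slope = 0.05, onset = 30)
  expect_equal(soce_rate(nt, readdition_time = 30), 0.05, tolerance = 1e-9)
  expect_equal(soce_rate(nt, readdition_time = 30, method = "endpoint"),
               0.05, tolerance = 1e-9)
  flat <- normalize_trace(0:100, rep(1, 101), onset = 50)
  expect_equal(soce_rate(flat, readdition_time = 60), 0)
  expect_error(soce_rate(flat, readdition_time = 99.5), "3 samples")
})

test_that("SOCE regression slope recovers the truth within its own CI", {
  true_slope <- 0.04
  covered <- 0
  set.seed(2024)
  for (i in 1:100) {
    t <- seq(0, 60, by = 0.5)
    v <- 1 + pmax(0, t - 40) * true_slope + rnorm(length(t), 0, 0.01)
    nt <- normalize_trace(t, v, onset = 40)
    sel <- t >= 40 & t <= 50
    fit <- lm(nt$values[sel] ~ t[sel])
    ci <- confint(fit)[2, ]
    covered <- covered + (ci[1] <= true_slope && true_slope <= ci[2])
  }
  # nominal 95% coverage; 85 allows ~3 binomial sd of slack
  expect_gte(covered, 85)
})

test_that("end-to-end: metrics on the emitted channels match the generator's
           ground-truth signal within noise", {
  cm <- calcium_model(noise_sd = 0.02)
  tr <- simulate_calcium(cm, r_um = 100, duration = 260, dt = 1, seed = 77)
  nt <- normalize_trace(tr$time_s, compute_ratio(tr$G, tr$T),
                        onset = cm$stimulus_onset)
  truth <- attr(tr, "truth")
  sel <- tr$time_s >= cm$stimulus_onset &
    tr$time_s <= cm$stimulus_onset + 100
  true_amp <- max(truth[sel])
  true_int <- sum(diff(tr$time_s[sel]) *
                    (truth[sel][-1] + truth[sel][-sum(sel)]) / 2)
  expect_equal(ca_amplitude(nt), true_amp, tolerance = 0.1)
  expect_equal(ca_integral(nt), true_int, tolerance = 0.1)
})

test_that("calcium_metrics assembles the per-cell table with bins", {
  cm <- calcium_model()
  traces <- lapply(c(150, 250), function(r)
    simulate_calcium(cm, r, duration = 260, dt = 1, seed = r))
  tbl <- calcium_metrics(traces)
  expect_equal(nrow(tbl), 2)
  expect_equal(as.character(tbl$bin), c("[100,200)", "[200,300)"))
  expect_true(all(c("amplitude", "integral", "rise_time_s") %in% names(tbl)))
  expect_gt(tbl$amplitude[1], tbl$amplitude[2]) # distance decay
})
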