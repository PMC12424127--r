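# Shared fixtures and independent brute-force oracles used across tests.

# A track data.frame from coordinate vectors (times default to 15 s frames).
make_track <- function(x, y, t = (seq_along(x) - 1) * 15, id = 1L) {
  data.frame(track_id = id, time_s = t, x_um = x, y_um = y)
}

# Brute-force per-segment oracles, written as plain loops so they stay
# independent of the vectorised implementation.
oracle_path_length <- function(track) {
  s <- 0
  for (i in 2:nrow(track)) {
    s <- s + sqrt((track$x_um[i] - track$x_um[i - 1])^2 +
                    (track$y_um[i] - track$y_um[i - 1])^2)
  }
  s
}

oracle_speed <- function(track) {
  oracle_path_length(track) /
    ((track$time_s[nrow(track)] - track$time_s[1]) / 60)
}

oracle_efficiency <- function(track, tip) {
  r <- function(i) sqrt((track$x_um[i] - tip[1])^2 + (track$y_um[i] - tip[2])^2)
  (r(1) - r(nrow(track))) / oracle_path_length(track)
}

# Random jagged track for oracle-equivalence checks.
random_track <- function(n = 20, id = 1L) {
  make_track(cumsum(stats::rnorm(n, sd = 5)), cumsum(stats::rnorm(n, sd = 5)),
             id = id)
}

# Purely radial approach toward `tip` at constant speed (um/min).
radial_track <- function(tip, r_start, r_end, n = 21, total_min = 10,
                         angle = pi / 3, id = 1L) {
  r <- seq(r_start, r_end, length.out = n)
  make_track(tip[1] + r * cos(angle), tip[2] + r * sin(angle),
             t = seq(0, total_min * 60, length.out = n), id = id)
}

# erfc via the normal CDF (for the continuous-source transient).
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Default-geometry source with the tip at the field centre.
centre_source <- function() gradient_source(tip = c(650, 650) / 2 * 1.3)
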