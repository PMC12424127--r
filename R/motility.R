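# Biased persistent random walk machinery.
#
# Headings are drawn from a von Mises distribution whose mean direction and
# concentration come from the resultant of two pull vectors: one along the
# previous heading (persistence) and one toward the pipette tip (chemotactic
# bias). With no bias the mean cosine of the turning angle equals the
# `persistence` parameter exactly; with overwhelming bias the walk becomes
# ballistic toward the tip.

# Inverse of A(k) = I1(k)/I0(k): concentration giving mean resultant rho.
# Best & Fisher (1981) approximation, standard in circular statistics.
vm_concentration <- function(rho) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(0)
  if (rho < 0.53) {
    2 * rho + rho^3 + 5 * rho^5 / 6
  } else if (rho < 0.85) {
    -0.4 + 1.39 * rho + 0.43 / (1 - rho)
  } else {
    1 / (rho^3 - 4 * rho^2 + 3 * rho)
  }
}

# Draw n angles from von Mises(mu, kappa); Best & Fisher rejection sampler.
# kappa = 0 falls back to the uniform circle. Uses the session RNG stream.
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) { # wrapped-normal regime; sd < 0.0015 rad
    return((mu + stats::rnorm(n, 0, sqrt(1 / kappa)) + pi) %% (2 * pi) - pi)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  (mu + out + pi) %% (2 * pi) - pi
}

#' Motility parameters of the persistent random-walk generator
#'
#' @param mean_step_speed Mean instantaneous speed, um/min. The default 5
#'   um/min is calibrated so the full simulate-render-track pipeline reports
#'   the system-level microglial migration speed.
#' @param speed_cv Coefficient of variation of per-step speed (gamma step
#'   lengths; 0 = constant steps). The default 0.4 sets the burstiness so the
#'   mean per-track peak frame-to-frame speed is about twice the mean speed.
#' @param persistence Directional correlation between successive steps,
#'   in \[0, 1): the expected cosine of the turning angle for an unbiased
#'   walk.
#' @param kappa Chemotactic sensitivity (>= 0): weight of the radial pull
#'   toward the tip at r = 0. 0 gives an unbiased persistent random walk.
#' @param sensing_range Radial distance (um) beyond which the bias is zero;
#'   default 400 um, the distance beyond which cells in the assay move as an
#'   unbiased random walk.
#' @param dt Time step, s.
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(mean_step_speed = 5, speed_cv = 0.4,
                            persistence = 0.5, kappa = 2,
                            sensing_range = 400, dt = 15) {
  if (mean_step_speed < 0 || speed_cv < 0 || kappa < 0 || sensing_range <= 0)
    stop("motility parameters must be non-negative (sensing_range > 0)")
  if (persistence < 0 || persistence >= 1)
    stop("persistence must be in [0, 1)")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(mean_step_speed = mean_step_speed, speed_cv = speed_cv,
                 persistence = persistence, kappa = kappa,
                 sensing_range = sensing_range, dt = dt),
            class = "motility_params")
}

# Radial bias gain: clipped-linear proxy for the local attractant level,
# 1 at the tip, 0 at and beyond the sensing range.
bias_gain <- function(r, sensing_range) pmax(0, 1 - r / sensing_range)

#' Treatment presets emulating the assay's experimental conditions
#'
#' Each preset is a set of dimensionless scalings applied on top of
#' [motility_params()] and [calcium_model()], encoding the qualitative sign
#' of each condition's effect on directed migration and on the two phases of
#' the Ca2+ response (ER-store release peak, sustained store-operated entry).
#' Magnitudes are qualitative: the source experiments report per-condition
#' effects only graphically, so presets assert direction, not size.
#'
#' Available presets: `control`, `sham` (vehicle, no attractant coupling),
#' `antagonist` (P2Y12 + P2Y13 receptor blockade), `atp_gamma_s`
#' (non-hydrolyzable ATP analog), `ca_free` (nominally Ca2+-free bath +
#' EGTA), `ca_10mM` (supraphysiological bath Ca2+), `bapta_20`, `bapta_5`,
#' `egta_am` (intracellular chelator loading), `orai1_ko` (CRISPR deletion of
#' the CRAC channel pore), `thapsigargin`, `cpa` (SERCA blockade, ER store
#' depletion), `caffeine`, `tg_caffeine` (caffeine after store depletion),
#' `forskolin` (adenylate-cyclase activation).
#'
#' @param name Preset name (see Details), or use the constructor arguments
#'   directly via [treatment_preset()].
#' @return An object of class `treatment_preset`.
#' @export
preset <- function(name) {
  tbl <- preset_table()
  if (!name %in% names(tbl)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tbl), collapse = ", "))
  }
  tbl[[name]]
}

#' @rdname preset
#' @param kappa_multiplier,speed_multiplier Scalings of chemotactic
#'   sensitivity and mean step speed.
#' @param er_peak_scale,soce_plateau_scale Scalings of the ER-release peak
#'   and of the sustained store-operated plateau of the Ca2+ response.
#' @param peak_delay_s Delay added to the Ca2+ response onset, s.
#' @export
treatment_preset <- function(name = "custom",
                             kappa_multiplier = 1, speed_multiplier = 1,
                             er_peak_scale = 1, soce_plateau_scale = 1,
                             peak_delay_s = 0) {
  stopifnot(kappa_multiplier >= 0, speed_multiplier >= 0,
            er_peak_scale >= 0, soce_plateau_scale >= 0, peak_delay_s >= 0)
  structure(list(name = name,
                 kappa_multiplier = kappa_multiplier,
                 speed_multiplier = speed_multiplier,
                 er_peak_scale = er_peak_scale,
                 soce_plateau_scale = soce_plateau_scale,
                 peak_delay_s = peak_delay_s),
            class = "treatment_preset")
}

preset_table <- function() {
  p <- treatment_preset
  list(
    control      = p("control"),
    sham         = p("sham", kappa_multiplier = 0, er_peak_scale = 0,
                     soce_plateau_scale = 0),
    antagonist   = p("antagonist", kappa_multiplier = 0,
                     speed_multiplier = 0.6, er_peak_scale = 0,
                     soce_plateau_scale = 0),
    atp_gamma_s  = p("atp_gamma_s", kappa_multiplier = 0.85,
                     er_peak_scale = 0.6, soce_plateau_scale = 0.3),
    ca_free      = p("ca_free", kappa_multiplier = 0.85,
                     soce_plateau_scale = 0),
    ca_10mM      = p("ca_10mM"),
    bapta_20     = p("bapta_20", er_peak_scale = 0.4,
                     soce_plateau_scale = 0.4, peak_delay_s = 10),
    bapta_5      = p("bapta_5", er_peak_scale = 0.6,
                     soce_plateau_scale = 0.6, peak_delay_s = 5),
    egta_am      = p("egta_am", speed_multiplier = 0.8, er_peak_scale = 0.5),
    orai1_ko     = p("orai1_ko", soce_plateau_scale = 0),
    thapsigargin = p("thapsigargin", er_peak_scale = 0,
                     soce_plateau_scale = 0),
    cpa          = p("cpa", er_peak_scale = 0, soce_plateau_scale = 0),
    caffeine     = p("caffeine", kappa_multiplier = 0,
                     speed_multiplier = 0.7, er_peak_scale = 0.3,
                     soce_plateau_scale = 0.3),
    tg_caffeine  = p("tg_caffeine", kappa_multiplier = 0,
                     speed_multiplier = 0.7, er_peak_scale = 0,
                     soce_plateau_scale = 0),
    forskolin    = p("forskolin", kappa_multiplier = 0.15,
                     er_peak_scale = 0.5, soce_plateau_scale = 0.5)
  )
}

#' Names of the packaged treatment presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(preset_table())

# Deterministic 32-bit sub-seed for cell / stage substreams.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483629)
}

#' Simulate biased persistent random-walk trajectories
#'
#' Generates 2-D cell trajectories under the pulsed-gradient geometry. At
#' each step a heading is drawn from a von Mises distribution whose resultant
#' combines a persistence pull along the previous heading with a radial pull
#' of weight `kappa * kappa_multiplier * g(r)` toward the tip, where
#' `g(r) = max(0, 1 - r / sensing_range)` is a clipped-linear proxy for the
#' local attractant concentration. Step lengths are gamma-distributed with
#' mean `mean_step_speed * speed_multiplier * dt`.
#'
#' One global seed fans out to fixed per-cell substreams, so increasing
#' `n_cells` extends the ensemble without perturbing earlier cells.
#'
#' @param params A [motility_params()].
#' @param source A [gradient_source()] (supplies the tip position).
#' @param n_cells Number of cells.
#' @param duration Track duration, s (first position at t = 0).
#' @param seed Integer seed (reproducibility contract: identical inputs give
#'   identical output).
#' @param preset A [treatment_preset()]; default control.
#' @param r_range Length-2 annulus (um) over which initial positions are
#'   drawn uniformly by area, centred on the tip.
#' @param min_separation Optional minimum initial separation (um), enforced
#'   by sequential rejection — used for well-separated tracking benchmarks.
#' @param population Population label stored with each cell.
#' @return A data.frame of class `trajectory_set` with columns `cell_id`,
#'   `population`, `time_s`, `x_um`, `y_um`.
#' @export
simulate_trajectories <- function(params, source, n_cells, duration, seed,
                                  preset = chemotaxr::preset("control"),
                                  r_range = c(100, 500),
                                  min_separation = NULL,
                                  population = "A") {
  stopifnot(inherits(params, "motility_params"),
            inherits(source, "gradient_source"),
            inherits(preset, "treatment_preset"))
  if (n_cells <= 0) stop("n_cells must be > 0")
  if (duration < params$dt) stop("duration must be >= dt")
  if (missing(seed)) stop("a seed is required for reproducibility")

  n_steps <- floor(duration / params$dt)
  times <- seq(0, by = params$dt, length.out = n_steps + 1)
  kappa_eff <- params$kappa * preset$kappa_multiplier
  mean_step <- params$mean_step_speed * preset$speed_multiplier *
    params$dt / 60 # um per step
  a_p <- vm_concentration(params$persistence)

  # initial positions: per-cell substream, or joint rejection sampling when a
  # minimum separation is requested (sequential, so earlier cells are stable)
  starts <- matrix(NA_real_, n_cells, 2)
  if (is.null(min_separation)) {
    for (i in seq_len(n_cells)) {
      set.seed(derive_seed(seed, i))
      starts[i, ] <- draw_start(source$tip, r_range)
    }
  } else {
    set.seed(derive_seed(seed, 0L))
    for (i in seq_len(n_cells)) {
      repeat {
        cand <- draw_start(source$tip, r_range)
        if (i == 1) { starts[i, ] <- cand; break }
        d2 <- min((starts[seq_len(i - 1), 1] - cand[1])^2 +
                    (starts[seq_len(i - 1), 2] - cand[2])^2)
        if (d2 >= min_separation^2) { starts[i, ] <- cand; break }
      }
    }
  }

  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(derive_seed(seed, i) %% 2147483629L + 1L)
    pos <- matrix(NA_real_, n_steps + 1, 2)
    pos[1, ] <- starts[i, ]
    heading <- NA_real_
    for (s in seq_len(n_steps)) {
      rel <- source$tip - pos[s, ]
      r <- sqrt(sum(rel^2))
      b <- kappa_eff * bias_gain(r, params$sensing_range)
      w <- c(0, 0)
      if (!is.na(heading) && a_p > 0) w <- w + a_p * c(cos(heading), sin(heading))
      if (b > 0 && r > 0) w <- w + b * rel / r
      k_dir <- sqrt(sum(w^2))
      mu <- if (k_dir > 0) atan2(w[2], w[1]) else 0
      th <- rvonmises(1, mu, k_dir)
      len <- if (params$speed_cv == 0) mean_step else
        stats::rgamma(1, shape = 1 / params$speed_cv^2,
                      scale = mean_step * params$speed_cv^2)
      pos[s + 1, ] <- pos[s, ] + len * c(cos(th), sin(th))
      heading <- th
    }
    out[[i]] <- data.frame(cell_id = i, population = population,
                           time_s = times, x_um = pos[, 1], y_um = pos[, 2])
  }
  res <- do.call(rbind, out)
  class(res) <- c("trajectory_set", "data.frame")
  attr(res, "dt") <- params$dt
  attr(res, "tip") <- source$tip
  attr(res, "preset") <- preset$name
  res
}

draw_start <- function(tip, r_range) {
  r <- sqrt(stats::runif(1, r_range[1]^2, r_range[2]^2))
  phi <- stats::runif(1, 0, 2 * pi)
  tip + r * c(cos(phi), sin(phi))
}
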