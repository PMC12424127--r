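#' Parametric model of the biphasic microglial Ca2+ response
#'
#' Describes the cytosolic Ca2+ response to a purinergic challenge as the sum
#' of two phases riding on a constant baseline ratio: an early, transient
#' ER-store-release peak (a difference of exponentials, normalised so its
#' maximum equals the nominal amplitude) and a sustained store-operated entry
#' (SOCE) plateau (a saturating rise). Both amplitudes decay exponentially
#' with the cell's distance from the gradient origin, reproducing the
#' distance- (hence dose-) dependence of the measured responses.
#'
#' @param baseline_R0 Resting fluorescence ratio (GCaMP6f/TdTomato-like).
#' @param peak_amp_at_0 Peak delta-R/R0 for a cell at the tip.
#' @param peak_decay_length Exponential decay length of response amplitude
#'   with radial distance, um.
#' @param peak_rise_tau,peak_decay_tau Rise and decay time constants of the
#'   store-release peak, s (decay > rise).
#' @param plateau_amp_at_0 Sustained-plateau delta-R/R0 for a cell at the tip.
#' @param plateau_tau Time constant of the plateau's saturating rise, s.
#' @param noise_sd Multiplicative Gaussian noise s.d. per channel sample.
#' @param stimulus_onset Time of the chemoattractant challenge, s.
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(baseline_R0 = 1, peak_amp_at_0 = 1.5,
                          peak_decay_length = 200,
                          peak_rise_tau = 3, peak_decay_tau = 15,
                          plateau_amp_at_0 = 0.4, plateau_tau = 20,
                          noise_sd = 0.02, stimulus_onset = 60) {
  stopifnot(baseline_R0 > 0, peak_amp_at_0 >= 0, peak_decay_length > 0,
            peak_rise_tau > 0, peak_decay_tau > peak_rise_tau,
            plateau_amp_at_0 >= 0, plateau_tau > 0, noise_sd >= 0,
            stimulus_onset >= 0)
  structure(as.list(environment()), class = "calcium_model")
}

# Unit-peak double exponential: h(t) = (e^{-t/td} - e^{-t/tr}) / h_max,
# h_max attained at t* = tr*td/(td-tr) * log(td/tr).
double_exp_unit <- function(t, tau_r, tau_d) {
  t_star <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  h_max <- exp(-t_star / tau_d) - exp(-t_star / tau_r)
  ifelse(t <= 0, 0, (exp(-t / tau_d) - exp(-t / tau_r)) / h_max)
}

# Time of the double-exponential maximum after onset.
double_exp_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Simulate a two-channel (or single-dye) Ca2+ trace
#'
#' Builds the noise-free delta-R/R0 signal from [calcium_model()] for a cell
#' at radial distance `r_um`, applies the preset's phase scalings and onset
#' delay, and emits raw fluorescence channels so the full ratiometric
#' pipeline (ratio, baseline normalization, metrics) is exercised end to end:
#' the denominator is a constant plus noise, the numerator is the true ratio
#' times that constant, plus its own noise.
#'
#' In the standard protocol the plateau follows the stimulus. If
#' `readdition_time` is given, the trace instead follows the Ca2+
#' re-addition protocol used to isolate SOCE: the store-release peak occurs
#' at the stimulus (in a Ca2+-free bath) and the plateau phase is keyed to
#' the re-addition of extracellular Ca2+.
#'
#' @param model A [calcium_model()].
#' @param r_um Radial distance of the cell from the gradient origin, um.
#' @param duration Trace duration, s.
#' @param dt Sampling interval, s.
#' @param seed Integer seed.
#' @param preset A [treatment_preset()].
#' @param readdition_time Optional time (s) of extracellular Ca2+
#'   re-addition (SOCE protocol).
#' @param ratiometric If `FALSE`, emit a single-dye trace (column `F`
#'   instead of `G`/`T`), as with a synthetic indicator.
#' @return A data.frame of class `ratio_trace` with columns `time_s` and
#'   `G`, `T` (ratiometric) or `F` (single-dye); attributes `stimulus_onset`,
#'   `r_um`, `condition`, `truth` (the noise-free delta-R/R0 signal).
#' @export
simulate_calcium <- function(model, r_um, duration, dt, seed,
                             preset = chemotaxr::preset("control"),
                             readdition_time = NULL,
                             ratiometric = TRUE) {
  stopifnot(inherits(model, "calcium_model"),
            inherits(preset, "treatment_preset"), r_um >= 0)
  if (dt <= 0) stop("dt must be > 0")
  if (duration <= model$stimulus_onset)
    stop("duration must exceed stimulus_onset")
  if (missing(seed)) stop("a seed is required for reproducibility")

  times <- seq(0, duration, by = dt)
  decay <- exp(-r_um / model$peak_decay_length)
  onset <- model$stimulus_onset + preset$peak_delay_s
  peak_amp <- model$peak_amp_at_0 * decay * preset$er_peak_scale
  plat_amp <- model$plateau_amp_at_0 * decay * preset$soce_plateau_scale
  plat_t0 <- if (is.null(readdition_time)) onset else readdition_time

  signal <- peak_amp * double_exp_unit(times - onset,
                                       model$peak_rise_tau,
                                       model$peak_decay_tau) +
    plat_amp * ifelse(times <= plat_t0, 0,
                      1 - exp(-(times - plat_t0) / model$plateau_tau))

  set.seed(derive_seed(seed, as.integer(round(r_um)) + 1L))
  n <- length(times)
  R_true <- 1 + signal # ratio relative to baseline; R0 = baseline_R0
  if (ratiometric) {
    T0 <- 1000
    T_ch <- T0 * (1 + stats::rnorm(n, 0, model$noise_sd))
    G_ch <- model$baseline_R0 * R_true * T0 *
      (1 + stats::rnorm(n, 0, model$noise_sd))
    out <- data.frame(time_s = times, G = G_ch, T = T_ch)
  } else {
    F0 <- 1000 * model$baseline_R0
    out <- data.frame(time_s = times,
                      F = F0 * R_true * (1 + stats::rnorm(n, 0, model$noise_sd)))
  }
  class(out) <- c("ratio_trace", "data.frame")
  attr(out, "stimulus_onset") <- model$stimulus_onset
  attr(out, "r_um") <- r_um
  attr(out, "condition") <- preset$name
  attr(out, "truth") <- signal
  out
}
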