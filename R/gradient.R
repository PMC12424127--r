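#' Pulsed micropipette point source
#'
#' Describes the chemoattractant source used in the micropipette assay: a
#' glass pipette whose tip sits just above the coverslip and releases short
#' pressure pulses of solution (ADP plus tracking dye) into the bath. Each
#' pulse is far shorter than any analysis timestep, so it is modelled as an
#' instantaneous release of amount `release_per_pulse` that then diffuses in
#' the half-space above the coverslip. The field is diffusion-only; convective
#' ejection at the tip is ignored.
#'
#' `release_per_pulse` is a free scale: no absolute dye/attractant amount is
#' measured in this assay, and every downstream use of the field is either
#' normalized or threshold-relative, so concentrations are reported in
#' arbitrary units proportional to micromolar.
#'
#' @param tip Numeric length-2, pipette tip position in micrometres.
#' @param pulse_rate Pulses per second (default 0.5 Hz).
#' @param pulse_duration Pulse duration in seconds (default 0.02 s); must be
#'   positive but does not enter the instantaneous-release model beyond
#'   validation.
#' @param release_per_pulse Amount released per pulse (arbitrary units).
#' @param diffusion_coefficient Diffusion coefficient D in um^2/s. The default
#'   300 um^2/s is the order of magnitude for small nucleotides in water.
#' @param pipette_concentration Concentration in the pipette solution, uM
#'   (default 50, ADP). Informational; the released amount is the free scale.
#' @return An object of class `gradient_source`.
#' @examples
#' src <- gradient_source()
#' concentration(src, r = 100, t = 600)
#' @export
gradient_source <- function(tip = c(0, 0),
                            pulse_rate = 0.5,
                            pulse_duration = 0.02,
                            release_per_pulse = 1,
                            diffusion_coefficient = 300,
                            pipette_concentration = 50) {
  stopifnot(length(tip) == 2, is.finite(tip))
  if (pulse_rate <= 0) stop("pulse_rate must be > 0")
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (diffusion_coefficient <= 0) stop("diffusion_coefficient must be > 0")
  if (release_per_pulse <= 0) stop("release_per_pulse must be > 0")
  structure(
    list(
      tip = as.numeric(tip),
      pulse_rate = pulse_rate,
      pulse_duration = pulse_duration,
      release_per_pulse = release_per_pulse,
      diffusion_coefficient = diffusion_coefficient,
      pipette_concentration = pipette_concentration
    ),
    class = "gradient_source"
  )
}

#' @export
print.gradient_source <- function(x, ...) {
  cat(sprintf(
    "Pulsed point source at (%.1f, %.1f) um: %.2g Hz x %.3g s pulses, D = %g um^2/s\n",
    x$tip[1], x$tip[2], x$pulse_rate, x$pulse_duration, x$diffusion_coefficient
  ))
  invisible(x)
}

#' Concentration of the pulsed point-source field
#'
#' Superposes instantaneous point-source solutions for the diffusion equation
#' in the half-space above the coverslip, one per completed pulse. With the
#' tip at the reflecting coverslip plane, the image source doubles the
#' free-space Green's function:
#'
#' \deqn{C(r, t) = \sum_{t_i < t} \frac{2\,Q}{(4 \pi D (t - t_i))^{3/2}}
#'   \exp\!\left(-\frac{r^2}{4 D (t - t_i)}\right)}
#'
#' Pulses occur at times 0, 1/rate, 2/rate, ... (first pulse at t = 0). As
#' t grows the sum converges to the continuous-source steady state
#' Q rate / (2 pi D r), which decays as 1/r — the stable gradient shape the
#' assay relies on.
#'
#' @param source A [gradient_source()].
#' @param r Radial distance(s) from the tip, um; must be > 0 (the source
#'   point itself is singular).
#' @param t Time since the first pulse, s (scalar, >= 0).
#' @return Concentration in arbitrary units, one value per element of `r`.
#' @export
concentration <- function(source, r, t) {
  stopifnot(inherits(source, "gradient_source"), length(t) == 1, t >= 0)
  if (any(r <= 0)) stop("r must be > 0: the source point is singular")
  D <- source$diffusion_coefficient
  Q <- source$release_per_pulse
  n_pulses <- floor(t * source$pulse_rate) + 1L # pulses at 0, 1/rate, ...
  tau <- t - (seq_len(n_pulses) - 1L) / source$pulse_rate # time since pulse
  tau <- tau[tau > 0]
  if (length(tau) == 0) return(rep(0, length(r)))
  vapply(r, function(ri) {
    sum(2 * Q / (4 * pi * D * tau)^1.5 * exp(-ri^2 / (4 * D * tau)))
  }, numeric(1))
}

#' Steady-state concentration of a continuously emitting point source
#'
#' Half-space steady state C(r) = Q rate / (2 pi D r), the t -> Inf limit of
#' [concentration()].
#'
#' @inheritParams concentration
#' @return Concentration in the same arbitrary units as [concentration()].
#' @export
steady_state_concentration <- function(source, r) {
  if (any(r <= 0)) stop("r must be > 0")
  source$release_per_pulse * source$pulse_rate /
    (2 * pi * source$diffusion_coefficient * r)
}

#' Time-averaged concentration of the pulsed field
#'
#' Exact time average of [concentration()] over a window, computed per pulse
#' from the closed-form time integral of the half-space kernel,
#' \deqn{\int_0^T \frac{2Q}{(4\pi D\tau)^{3/2}} e^{-r^2/(4D\tau)} d\tau
#'   = \frac{Q}{2\pi D r}\,\mathrm{erfc}\!\left(\frac{r}{2\sqrt{DT}}\right),}
#' which stays accurate arbitrarily close to the tip where the instantaneous
#' field is violently pulsatile and naive time sampling fails.
#'
#' @inheritParams concentration
#' @param window Length-2 averaging window, s.
#' @return Mean concentration over the window, one value per element of `r`.
#' @export
time_averaged_concentration <- function(source, r, window) {
  stopifnot(window[2] > window[1], window[1] >= 0)
  if (any(r <= 0)) stop("r must be > 0")
  D <- source$diffusion_coefficient
  Q <- source$release_per_pulse
  a <- window[1]; b <- window[2]
  n_pulses <- floor(b * source$pulse_rate) + 1L
  ti <- (seq_len(n_pulses) - 1L) / source$pulse_rate
  ti <- ti[ti < b]
  if (length(ti) == 0) return(rep(0, length(r)))
  erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
  vapply(r, function(ri) {
    upper <- erfc(ri / (2 * sqrt(D * (b - ti))))
    lo_t <- pmax(a, ti) - ti
    lower <- ifelse(lo_t > 0, erfc(ri / (2 * sqrt(D * lo_t))), 0)
    Q / (2 * pi * D * ri) * sum(upper - lower) / (b - a)
  }, numeric(1))
}

#' Reference intensity for gradient-profile normalization
#'
#' Mean concentration within `ref_radius` of the tip, time-averaged over
#' `ref_window`. The spatial mean is area-weighted over the disk r <=
#' ref_radius (the weight 2 pi r regularises the 1/r singularity at the tip),
#' mirroring the experimental normalization of dye fluorescence to the mean
#' intensity measured within 50 um of the tip 20-30 min after release.
#'
#' @param source A [gradient_source()].
#' @param ref_radius Disk radius, um (default 50).
#' @param ref_window Length-2 time window in seconds (default 1200-1800 s,
#'   i.e. 20-30 min).
#' @param n_r Number of radial quadrature points.
#' @return Scalar reference concentration (arbitrary units).
#' @export
reference_intensity <- function(source, ref_radius = 50,
                                ref_window = c(1200, 1800), n_r = 200) {
  stopifnot(ref_window[2] > ref_window[1], ref_radius > 0)
  # midpoint rule in r with area weight 2*pi*r / (pi*R^2)
  dr <- ref_radius / n_r
  rs <- (seq_len(n_r) - 0.5) * dr
  w <- 2 * rs * dr / ref_radius^2
  sum(w * time_averaged_concentration(source, rs, ref_window))
}

#' Normalized radial gradient profile
#'
#' Time-averages the concentration field at each radius over `t_window` and
#' divides by the [reference_intensity()] (mean within `ref_radius` of the
#' tip over `ref_window`). Because the same released amount Q multiplies both
#' numerator and denominator, the profile is invariant to the free release
#' scale — the ratiometric trick used to monitor gradient stability with a
#' tracer dye.
#'
#' @inheritParams reference_intensity
#' @param radii Radii at which to evaluate, um (> 0).
#' @param t_window Length-2 evaluation window, s.
#' @return A data.frame with columns `radius_um` and `norm_intensity`.
#' @export
normalized_profile <- function(source, radii, t_window,
                               ref_radius = 50, ref_window = c(1200, 1800)) {
  stopifnot(t_window[2] > t_window[1])
  if (any(radii <= 0)) stop("radii must be > 0")
  ref <- reference_intensity(source, ref_radius, ref_window)
  if (ref <= 0) stop("reference average is 0: gradient never established")
  prof <- time_averaged_concentration(source, radii, t_window)
  data.frame(radius_um = radii, norm_intensity = prof / ref)
}
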