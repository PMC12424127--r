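# Ratiometric and single-dye Ca2+ metrics: delta-R/R0 normalization,
# amplitude and integral over the first 100 s, 10-90% rise time, and the
# store-operated entry (SOCE) rate after Ca2+ re-addition.

#' Pointwise fluorescence ratio of the two indicator channels
#'
#' @param G Numerator channel (Ca2+-sensitive, GCaMP6f-like).
#' @param T_ch Denominator channel (Ca2+-insensitive, TdTomato-like); must be
#'   strictly positive after background subtraction.
#' @return Numeric vector `G / T_ch`.
#' @export
compute_ratio <- function(G, T_ch) {
  if (length(G) != length(T_ch)) stop("channels must have the same length")
  bad <- which(T_ch <= 0)
  if (length(bad) > 0) {
    stop("denominator channel <= 0 at frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": background over-subtraction?")
  }
  G / T_ch
}

#' Baseline-normalize a ratio (or single-dye) trace
#'
#' Computes delta-R/R0 = (R - R0)/R0, where R0 is the mean over the
#' pre-stimulus baseline window (by default everything before `onset`).
#'
#' @param times Sample times, s (strictly increasing).
#' @param values Ratio R (or fluorescence F) series.
#' @param onset Stimulus onset, s.
#' @param baseline_window Optional length-2 window for the baseline mean;
#'   default `c(min(times), onset)`. At least 3 samples are required.
#' @return An object of class `normalized_trace`: list with `times`,
#'   `values` (delta-R/R0), `R0`, `onset`, `baseline_sd` (s.d. of the
#'   normalized baseline residuals).
#' @export
normalize_trace <- function(times, values, onset, baseline_window = NULL) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  if (is.null(baseline_window)) baseline_window <- c(min(times), onset)
  in_base <- times >= baseline_window[1] & times < baseline_window[2]
  if (sum(in_base) < 3) stop("need at least 3 baseline samples before onset")
  R0 <- mean(values[in_base])
  if (R0 <= 0) stop("baseline R0 must be > 0")
  norm <- (values - R0) / R0
  structure(list(times = times, values = norm, R0 = R0, onset = onset,
                 baseline_sd = stats::sd(norm[in_base])),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("normalized_trace: %d samples, R0 = %.4g, onset = %g s\n",
              length(x$times), x$R0, x$onset))
  invisible(x)
}

default_ca_window <- function(trace, window) {
  if (is.null(window)) window <- c(trace$onset, trace$onset + 100)
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (!any(sel)) stop("analysis window contains no samples")
  sel
}

#' Ca2+ amplitude: maximum delta-R/R0 in the response window
#'
#' Proxy for the maximum cation load. The default window is the first 100 s
#' after the challenge — the guard against ROI drift as cells start moving.
#'
#' @param trace A [normalize_trace()] result.
#' @param window Length-2 window, s; default `onset + c(0, 100)`.
#' @return Dimensionless amplitude.
#' @export
ca_amplitude <- function(trace, window = NULL) {
  sel <- default_ca_window(trace, window)
  max(trace$values[sel])
}

#' Ca2+ integral: area under delta-R/R0 over the response window
#'
#' Index of overall cation load; trapezoidal rule, signed (negative
#' excursions subtract).
#'
#' @inheritParams ca_amplitude
#' @return Integral in dimensionless * s.
#' @export
ca_integral <- function(trace, window = NULL) {
  sel <- default_ca_window(trace, window)
  t <- trace$times[sel]; v <- trace$values[sel]
  if (length(t) < 2) stop("integral needs at least 2 samples in the window")
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

#' 10-90% rise time of the Ca2+ response
#'
#' Time between the first upward crossings of 10% and 90% of the window peak
#' on the rising phase, linearly interpolated between samples. Traces whose
#' peak does not exceed `threshold_sd` baseline noise standard deviations are
#' reported as `NA` with reason `"sub_threshold"`.
#'
#' @inheritParams ca_amplitude
#' @param threshold_sd Detection threshold in baseline-noise s.d. units
#'   (default 5).
#' @return Rise time, s, or `NA` with a `reason` attribute.
#' @export
rise_time <- function(trace, window = NULL, threshold_sd = 5) {
  sel <- default_ca_window(trace, window)
  t <- trace$times[sel]; v <- trace$values[sel]
  peak <- max(v)
  noise <- trace$baseline_sd
  if (is.na(noise)) noise <- 0
  if (peak <= threshold_sd * noise)
    return(structure(NA_real_, reason = "sub_threshold"))
  cross <- function(level) {
    above <- which(v >= level)
    if (length(above) == 0) return(NA_real_)
    i <- above[1]
    if (i == 1) return(t[1])
    t[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
  }
  t10 <- cross(0.1 * peak); t90 <- cross(0.9 * peak)
  t90 - t10
}

#' Store-operated Ca2+ entry (SOCE) rate
#'
#' Rate of rise of delta-F/F0 after re-addition of extracellular Ca2+ to
#' store-depleted cells, as delta-F/delta-t over a 10 s window. Implemented
#' as the least-squares slope of the trace against time over the window
#' (robust to sampling noise); `method = "endpoint"` gives the raw
#' endpoint difference divided by the window length.
#'
#' @param trace A [normalize_trace()] result (single-dye delta-F/F0).
#' @param readdition_time Time of Ca2+ re-addition, s.
#' @param window_s Window length after re-addition, s (default 10).
#' @param method `"regression"` (default) or `"endpoint"`.
#' @return Rate in s^-1.
#' @export
soce_rate <- function(trace, readdition_time, window_s = 10,
                      method = c("regression", "endpoint")) {
  method <- match.arg(method)
  sel <- trace$times >= readdition_time &
    trace$times <= readdition_time + window_s
  if (sum(sel) < 3) stop("need at least 3 samples in the SOCE window")
  t <- trace$times[sel]; v <- trace$values[sel]
  if (method == "regression") {
    unname(stats::coef(stats::lm(v ~ t))[2])
  } else {
    (v[length(v)] - v[1]) / (t[length(t)] - t[1])
  }
}

#' Per-cell Ca2+ metric table for a set of traces
#'
#' Runs the ratio -> normalize -> metrics chain on each trace and collects
#' amplitude, integral, rise time (and SOCE rate when a re-addition time is
#' given) with the cell's distance bin.
#'
#' @param traces List of `ratio_trace` objects from [simulate_calcium()] (or
#'   data.frames with `time_s` plus `G`/`T` or `F` and attributes
#'   `stimulus_onset`, `r_um`, `condition`).
#' @param window Analysis window passed to the metrics (default first 100 s
#'   after onset).
#' @param readdition_time Optional Ca2+ re-addition time, s; enables
#'   `soce_rate` and the post-re-addition integral.
#' @param edges Radial bin edges.
#' @return Data.frame with one row per trace: `r0_um`, `bin`, `condition`,
#'   `amplitude`, `integral`, `rise_time_s`, and with re-addition
#'   `soce_rate_s` and `soce_integral`.
#' @export
calcium_metrics <- function(traces, window = NULL, readdition_time = NULL,
                            edges = seq(100, 500, by = 100)) {
  rows <- lapply(traces, function(tr) {
    onset <- attr(tr, "stimulus_onset")
    R <- if ("F" %in% names(tr)) tr$F else compute_ratio(tr$G, tr$T)
    nt <- normalize_trace(tr$time_s, R, onset)
    out <- data.frame(
      r0_um = attr(tr, "r_um"),
      condition = attr(tr, "condition"),
      amplitude = ca_amplitude(nt, window),
      integral = ca_integral(nt, window),
      rise_time_s = as.numeric(rise_time(nt, window))
    )
    if (!is.null(readdition_time)) {
      out$soce_rate_s <- soce_rate(nt, readdition_time)
      out$soce_integral <- ca_integral(nt, c(readdition_time,
                                             max(nt$times)))
    }
    out
  })
  out <- do.call(rbind, rows)
  out$bin <- radial_bin(out$r0_um, edges)
  rownames(out) <- NULL
  out
}
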