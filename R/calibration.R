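#' Construct a stopped-flow fluorescence trace
#'
#' A raw stopped-flow recording: time in seconds and fluorescence in
#' arbitrary units, with a reference value `F0` (fluorescence at t = 0)
#' used for normalisation. Intracellular carboxyfluorescein self-quenches
#' as the cell shrinks and the dye concentrates, so fluorescence tracks
#' cell volume after calibration.
#'
#' @param times Strictly increasing time vector, s.
#' @param f Fluorescence values (finite), same length as `times`.
#' @param f0 Reference fluorescence at t = 0; defaults to `f[1]`.
#' @return A data frame of class `fluorescence_trace` with columns
#'   `time_s`, `f` and attribute `f0`.
#' @export
fluorescence_trace <- function(times, f, f0 = f[1]) {
  stopifnot(length(times) == length(f), length(times) >= 2L)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (!all(is.finite(f))) stop("fluorescence values must be finite")
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be finite and > 0")
  structure(data.frame(time_s = as.numeric(times), f = as.numeric(f)),
            f0 = f0, class = c("fluorescence_trace", "data.frame"))
}

#' @export
#' @rdname fluorescence_trace
#' @param trace A `fluorescence_trace`.
trace_f0 <- function(trace) attr(trace, "f0")

#' Subtract a photobleaching baseline from a shock trace
#'
#' The baseline trace records the same cell suspension mixed with an
#' isosmotic solution, so its only time dependence is fluorophore
#' bleaching. Subtracting the baseline drift, `F - (F_base - F0_base)`,
#' removes the bleaching component from the shock trace while preserving
#' the trace's own F0 normalisation. The baseline is linearly interpolated
#' onto the trace's time grid.
#'
#' @param trace Shock `fluorescence_trace`.
#' @param baseline Isosmotic `fluorescence_trace` recording bleaching only.
#' @return A corrected `fluorescence_trace` on `trace`'s grid.
#' @export
subtract_baseline <- function(trace, baseline) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(baseline, "fluorescence_trace"))
  if (min(baseline$time_s) > min(trace$time_s) + 1e-9 ||
      max(baseline$time_s) < max(trace$time_s) - 1e-9) {
    stop("alignment error: baseline does not cover the trace's time range")
  }
  drift <- stats::approx(baseline$time_s, baseline$f, xout = trace$time_s,
                         rule = 2)$y - trace_f0(baseline)
  fluorescence_trace(trace$time_s, trace$f - drift, f0 = trace_f0(trace))
}

#' Fit the linear volume calibration on an impermeant-shock trace
#'
#' Converts normalised fluorescence to relative volume via
#' `v_rel = a * F/F0 + b`. The two calibration constants are pinned by the
#' known endpoints of a sorbitol (impermeant) shock: the cell starts at
#' `v_rel = 1` and settles at the Boyle-van't Hoff equilibrium volume
#' determined by the shock tonicity and the osmotically inactive fraction.
#' Since `F0` is defined as the fluorescence at t = 0, the initial point
#' is anchored at `F(0)/F0 = 1` exactly; `F_inf/F0` is estimated as the
#' 10%-trimmed mean of the last 5% of samples. Averaging the earliest
#' samples instead would bias the initial estimate by O(window/tau) on a
#' shrinking trace and propagate directly into the permeability.
#'
#' @param trace Baseline-corrected impermeant-shock `fluorescence_trace`
#'   that has reached equilibrium.
#' @param shock The [shock_protocol()] of the sorbitol shock.
#' @param geom The [cell_geometry()].
#' @param edge_frac Fraction of samples used for each endpoint estimate.
#' @return A `calibration_fit` list with slope `a`, intercept `b`, and the
#'   endpoint volumes used.
#' @export
fit_calibration <- function(trace, shock, geom, edge_frac = 0.05) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(shock, "shock_protocol"),
            inherits(geom, "cell_geometry"))
  if (shock$permeant_gradient != 0) {
    stop("calibration requires an impermeant (sorbitol-only) shock trace")
  }
  n <- nrow(trace)
  k <- max(2L, ceiling(edge_frac * n))
  fn <- trace$f / trace_f0(trace)
  f_start <- 1  # F0 is the t = 0 reference by construction
  f_end <- mean(fn[seq.int(n - k + 1L, n)], trim = 0.1)

  amplitude <- diff(range(fn))
  if (abs(f_end - f_start) < max(1e-12, 0.1 * amplitude)) {
    stop("degenerate calibration: trace amplitude below the noise floor")
  }
  v_final <- equilibrium_volume(shock$tonicity, geom$beta, permeant = FALSE)
  if (abs(v_final - 1) < 1e-12) {
    stop("degenerate calibration: tonicity 1 gives no volume change")
  }
  # solve a*f_start + b = 1 ; a*f_end + b = v_final
  a <- (v_final - 1) / (f_end - f_start)
  b <- 1 - a * f_start
  structure(list(a = a, b = b, v_initial = 1, v_final = v_final,
                 f_start = f_start, f_end = f_end),
            class = "calibration_fit")
}

#' Apply a fitted calibration to a fluorescence trace
#'
#' Sorbitol-derived calibrations are applied unchanged to the paired
#' glycerol-shock trace recorded under the same tonicity and temperature.
#'
#' @param trace A baseline-corrected `fluorescence_trace`.
#' @param cal A `calibration_fit` from [fit_calibration()].
#' @return A `volume_trace` data frame (`time_s`, `v_rel`).
#' @export
apply_calibration <- function(trace, cal) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(cal, "calibration_fit"))
  out <- data.frame(time_s = trace$time_s,
                    v_rel = cal$a * trace$f / trace_f0(trace) + cal$b)
  class(out) <- c("volume_trace", "data.frame")
  out
}
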