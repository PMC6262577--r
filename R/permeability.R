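#' @keywords internal
trace_sse <- function(trace, geom, perm, shock) {
  sim <- simulate_volume_response(geom, perm, shock, times = trace$time_s)
  sum((trace$v_rel - sim$v_rel)^2)
}

fit_one_permeability <- function(trace, geom, shock, bracket, objective) {
  if (stats::sd(trace$v_rel) < 1e-6) {
    stop("non-identifiable: trace carries no volume signal")
  }
  lb <- log10(bracket[1]); ub <- log10(bracket[2])
  opt <- stats::optimize(function(lp) objective(10^lp, trace),
                         interval = c(lb, ub), tol = 1e-6)
  value <- 10^opt$minimum
  boundary <- opt$minimum < lb + 1e-3 || opt$minimum > ub - 1e-3
  list(value = value, sse = opt$objective, boundary = boundary)
}

new_permeability_estimate <- function(fits, kind) {
  values <- vapply(fits, `[[`, numeric(1), "value")
  s <- summarize_mean_sem(values)
  structure(list(
    value = s$mean,
    stderr = if (is.na(s$sem)) 0 else s$sem,
    n_traces = length(values),
    per_trace = values,
    residual_sse = sum(vapply(fits, `[[`, numeric(1), "sse")),
    boundary_warning = any(vapply(fits, `[[`, logical(1), "boundary")),
    kind = kind
  ), class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  unit <- "cm/s"
  cat(sprintf("%s permeability: %.4g +/- %.2g %s (n = %d traces, SSE = %.3g)\n",
              if (x$kind == "water") "Water" else "Solute",
              x$value, x$stderr, unit, x$n_traces, x$residual_sse))
  if (isTRUE(x$boundary_warning)) {
    cat("warning: optimizer touched the search bracket boundary\n")
  }
  invisible(x)
}

#' Estimate osmotic water permeability (Pf) from impermeant-shock traces
#'
#' Each calibrated relative-volume trace from a sorbitol shock is fitted
#' to the forward kinetic model ([simulate_volume_response()]) by
#' minimising the sum of squared residuals over Pf alone (the solute
#' permeability is held at 0), using a bounded one-dimensional search on
#' log10(Pf) over `bracket`. Per-trace estimates are aggregated as mean
#' +/- SEM across traces.
#'
#' @param traces A `volume_trace` or list of them.
#' @param geom [cell_geometry()].
#' @param shock [shock_protocol()] with `permeant_gradient = 0`.
#' @param bracket Search interval for Pf, cm/s.
#' @return A `permeability_estimate` (fields `value`, `stderr`,
#'   `n_traces`, `per_trace`, `residual_sse`, `boundary_warning`).
#' @export
estimate_pf <- function(traces, geom, shock, bracket = c(1e-6, 1e-1)) {
  traces <- as_trace_list(traces)
  stopifnot(inherits(geom, "cell_geometry"), inherits(shock, "shock_protocol"))
  if (shock$permeant_gradient != 0) {
    stop("Pf is estimated from impermeant shocks (permeant_gradient = 0)")
  }
  obj <- function(pf, trace) {
    trace_sse(trace, geom, permeability_params(pf = pf, pgly = 0), shock)
  }
  fits <- lapply(traces, fit_one_permeability,
                 geom = geom, shock = shock, bracket = bracket,
                 objective = obj)
  new_permeability_estimate(fits, kind = "water")
}

#' Estimate solute (glycerol) permeability from permeant-shock traces
#'
#' Second stage of the paired-shock protocol: each glycerol-shock volume
#' trace is fitted over PGly with the water permeability frozen at the
#' value obtained from the paired sorbitol shock.
#'
#' @inheritParams estimate_pf
#' @param shock [shock_protocol()] with `permeant_gradient > 0`.
#' @param pf_fixed Water permeability, cm/s, from the paired sorbitol fit.
#' @param bracket Search interval for PGly, cm/s.
#' @return A `permeability_estimate` with `kind = "solute"`.
#' @export
estimate_pgly <- function(traces, geom, shock, pf_fixed,
                          bracket = c(1e-9, 1e-3)) {
  traces <- as_trace_list(traces)
  stopifnot(inherits(geom, "cell_geometry"), inherits(shock, "shock_protocol"))
  if (shock$permeant_gradient <= 0) {
    stop("PGly is estimated from permeant shocks (permeant_gradient > 0)")
  }
  if (!is.numeric(pf_fixed) || pf_fixed < 0) stop("pf_fixed must be >= 0")
  obj <- function(pgly, trace) {
    trace_sse(trace, geom, permeability_params(pf = pf_fixed, pgly = pgly),
              shock)
  }
  fits <- lapply(traces, fit_one_permeability,
                 geom = geom, shock = shock, bracket = bracket,
                 objective = obj)
  new_permeability_estimate(fits, kind = "solute")
}

as_trace_list <- function(traces) {
  if (inherits(traces, "volume_trace")) traces <- list(traces)
  if (!length(traces)) stop("at least one trace is required")
  lapply(traces, function(tr) {
    stopifnot(is.data.frame(tr), all(c("time_s", "v_rel") %in% names(tr)))
    tr
  })
}

#' Percent inhibition of a permeability estimate
#'
#' @param p_control,p_treated `permeability_estimate` objects (or bare
#'   numbers) for untreated and inhibitor-treated cells.
#' @return Percent inhibition, `100 * (1 - treated/control)`.
#' @examples
#' percent_inhibition(10, 1.6)  # 84
#' @export
percent_inhibition <- function(p_control, p_treated) {
  pc <- if (inherits(p_control, "permeability_estimate")) p_control$value else p_control
  pt <- if (inherits(p_treated, "permeability_estimate")) p_treated$value else p_treated
  if (pc == 0) stop("control permeability is zero; inhibition undefined")
  100 * (1 - pt / pc)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector.
#' @return List with `mean`, `sem` (NA for a single value) and `n`.
#' @export
summarize_mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("insufficient data: empty input")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Unpaired two-sample Student's t-test (pooled variance)
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p` and `df`.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("insufficient data: need n >= 2 per group")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}
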