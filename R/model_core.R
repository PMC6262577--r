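#' Simulate the relative cell-volume response to a hyperosmotic shock
#'
#' Forward kinetic model of stopped-flow volume kinetics with one
#' impermeant and optionally one permeant solute. The state is the cell
#' volume `V` and the internal moles of permeant solute `Ng`:
#'
#' \deqn{dV/dt   = -P_f A \bar{v}_w (C_{out} - C_{in})}
#' \deqn{dN_g/dt =  P_{gly} A (C_{out,g} - N_g / (V - \beta V_0))}
#'
#' with total internal osmolarity `C_in = (Ns + Ng)/(V - beta*V0)` computed
#' over the osmotically active volume, and the impermeant internal osmole
#' count fixed by isotonic equilibrium, `Ns = iso_osm * V0 * (1 - beta)`.
#' The external bath is treated as infinite (constant concentrations after
#' mixing): total external osmolarity `tonicity * iso_osm`, of which
#' `permeant_gradient` is the permeant species. Reflection coefficients are
#' 1 for both solutes. Osmolarities are supplied in osmol/L and converted
#' internally to mol/cm^3; lengths are cm, times s.
#'
#' Integration uses [deSolve::lsoda()] with rtol 1e-8 and atol 1e-10,
#' reported on the requested time grid.
#'
#' @param geom A [cell_geometry()].
#' @param perm A [permeability_params()].
#' @param shock A [shock_protocol()].
#' @param t_end End of the simulated interval, s.
#' @param n_points Number of grid points on `[0, t_end]`.
#' @param times Optional explicit time grid starting at 0 (overrides
#'   `t_end`/`n_points`).
#' @param full Logical; if `TRUE`, also return internal state columns
#'   (`v_cm3`, `ng_mol`, `c_in_osmolar`).
#'
#' @return A data frame of class `volume_trace` with columns `time_s` and
#'   `v_rel` (relative volume V/V0, starting at 1).
#' @examples
#' geom <- cell_geometry()
#' tr <- simulate_volume_response(geom, permeability_params(pf = 4.38e-4),
#'                                shock_protocol(1.25), t_end = 30)
#' tail(tr$v_rel, 1)  # ~ 0.9, the Boyle-van't Hoff equilibrium
#' @export
simulate_volume_response <- function(geom, perm, shock,
                                     t_end = 40, n_points = 400,
                                     times = NULL, full = FALSE) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(perm, "permeability_params"),
            inherits(shock, "shock_protocol"))
  if (is.null(times)) {
    if (t_end <= 0) stop("t_end must be > 0")
    times <- seq(0, t_end, length.out = n_points)
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("time grid must start at 0 and be strictly increasing")
  }
  if (shock$permeant_gradient >
      (shock$tonicity - 1) * geom$iso_osm + 1e-12) {
    stop("permeant_gradient exceeds the imposed osmotic gradient")
  }

  v0 <- geom$v0
  beta <- geom$beta
  # state is dimensionless: x = V/V0, g = Ng/(iso_mol * V0)
  av <- geom$area / v0            # surface-to-volume ratio, 1/cm
  iso_mol <- geom$iso_osm / 1000  # osmol/L -> mol/cm^3
  lam <- shock$tonicity
  grad_g <- shock$permeant_gradient / geom$iso_osm  # in units of iso_mol
  pf <- perm$pf
  pgly <- perm$pgly
  vw <- geom$vw

  rhs <- function(t, y, parms) {
    act <- y[1] - beta                   # osmotically active volume / V0
    c_in <- ((1 - beta) + y[2]) / act    # total internal conc / iso_mol
    c_in_g <- y[2] / act
    list(c(
      -pf * av * vw * iso_mol * (lam - c_in),
      pgly * av * (grad_g - c_in_g)
    ))
  }

  sol <- deSolve::lsoda(c(x = 1, g = 0), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (!all(is.finite(sol)) || nrow(sol) < length(times)) {
    stop(sprintf(
      "integration failure for pf=%.3g, pgly=%.3g, tonicity=%.3g: non-finite state",
      pf, pgly, shock$tonicity))
  }
  x <- sol[, "x"]
  if (any(x <= beta)) {
    stop(sprintf(
      "integration failure for pf=%.3g, pgly=%.3g: volume reached the inactive fraction",
      pf, pgly))
  }
  out <- data.frame(time_s = times, v_rel = x)
  if (full) {
    out$v_cm3 <- x * v0
    out$ng_mol <- sol[, "g"] * iso_mol * v0
    out$c_in_osmolar <- geom$iso_osm * ((1 - beta) + sol[, "g"]) / (x - beta)
  }
  class(out) <- c("volume_trace", "data.frame")
  out
}
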