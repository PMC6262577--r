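#' Cell geometry for an osmotic-shock experiment
#'
#' Describes the physical setup of a spherical cell used in stopped-flow
#' volume kinetics: its radius, the osmotically inactive volume fraction
#' (solids and bound water that do not participate in shrink/swell), the
#' partial molar volume of water, and the isotonic external osmolarity the
#' cell is equilibrated in before the shock.
#'
#' @param radius Cell radius in cm. Default 2.5e-4 cm (a typical yeast
#'   spheroplast of ~5 um diameter).
#' @param beta Osmotically inactive fraction of the initial cell volume,
#'   in `[0, 1)`. Default 0.5.
#' @param vw Partial molar volume of water in cm^3/mol. Default 18.
#' @param iso_osm Isotonic external osmolarity in osmol/L. Default 1.4
#'   (cells equilibrated in 1.4 mol/L sorbitol).
#'
#' @return A `cell_geometry` object with derived fields `v0` (initial
#'   volume, cm^3) and `area` (surface area, cm^2).
#' @examples
#' geom <- cell_geometry()
#' geom$v0 / geom$area  # radius/3
#' @export
cell_geometry <- function(radius = 2.5e-4, beta = 0.5, vw = 18,
                          iso_osm = 1.4) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("radius must be > 0")
  if (!is.numeric(beta) || beta < 0 || beta >= 1) {
    stop("beta must lie in [0, 1)")
  }
  if (vw <= 0) stop("vw must be > 0")
  if (iso_osm <= 0) stop("iso_osm must be > 0")
  structure(list(
    radius = radius, beta = beta, vw = vw, iso_osm = iso_osm,
    v0 = (4 / 3) * pi * radius^3,
    area = 4 * pi * radius^2
  ), class = "cell_geometry")
}

#' Hyperosmotic shock protocol
#'
#' A shock is described by its tonicity Lambda = (osm_out at equilibrium) /
#' (osm_out before mixing) and by how much of the imposed gradient is a
#' permeant solute (e.g. glycerol). A sorbitol-only shock has
#' `permeant_gradient = 0`.
#'
#' @param tonicity Dimensionless tonicity Lambda >= 1.
#' @param permeant_gradient Osmolarity of permeant solute added externally,
#'   osmol/L; 0 for a fully impermeant shock.
#' @param temperature Bath temperature in K. Default 296.15 (23 C).
#' @return A `shock_protocol` object.
#' @examples
#' shock_protocol(tonicity = 1.25)                       # sorbitol shock
#' shock_protocol(tonicity = 1.25, permeant_gradient = 0.35)  # glycerol
#' @export
shock_protocol <- function(tonicity = 1.25, permeant_gradient = 0,
                           temperature = 296.15) {
  if (!is.numeric(tonicity) || length(tonicity) != 1L || !is.finite(tonicity)) {
    stop("tonicity must be a finite number")
  }
  if (tonicity < 1) {
    stop("unsupported protocol: tonicity < 1 (hypoosmotic shocks not modelled)")
  }
  if (permeant_gradient < 0) stop("permeant_gradient must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0 K")
  structure(list(
    tonicity = tonicity,
    permeant_gradient = permeant_gradient,
    temperature = temperature
  ), class = "shock_protocol")
}

#' Membrane permeability parameters
#'
#' @param pf Osmotic water permeability, cm/s.
#' @param pgly Permeant-solute (glycerol) permeability, cm/s.
#' @return A `permeability_params` object.
#' @export
permeability_params <- function(pf = 0, pgly = 0) {
  if (pf < 0 || pgly < 0) stop("permeabilities must be >= 0")
  structure(list(pf = pf, pgly = pgly), class = "permeability_params")
}

#' Equilibrium relative volume after a hyperosmotic shock
#'
#' Closed-form endpoint of the volume response. For an impermeant shock the
#' cell behaves as an ideal osmometer and settles at the Boyle-van't Hoff
#' volume `(1 - beta)/tonicity + beta`. When the gradient is imposed by a
#' permeant solute alone, the solute equilibrates across the membrane and
#' water follows, so the volume returns to 1.
#'
#' @param tonicity Tonicity Lambda >= 1.
#' @param beta Osmotically inactive volume fraction in `[0, 1)`.
#' @param permeant Logical; `TRUE` if the osmotic gradient is carried by a
#'   permeant solute only.
#' @return Relative equilibrium volume V/V0 (dimensionless).
#' @examples
#' equilibrium_volume(1.25, 0.5)        # 0.9
#' equilibrium_volume(1.25, 0.5, TRUE)  # 1
#' @export
equilibrium_volume <- function(tonicity, beta, permeant = FALSE) {
  if (tonicity < 1) stop("unsupported protocol: tonicity < 1")
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  if (isTRUE(permeant)) return(1)
  (1 - beta) / tonicity + beta
}
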