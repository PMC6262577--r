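#' Hill model for pH-dependent permeability
#'
#' Permeability rises sigmoidally with pH from `p_min` (acid-blocked
#' channel) to `p_max` (fully open), half-maximal at `pka`:
#' `p(pH) = p_min + (p_max - p_min) * 10^(n*(pH - pKa)) / (1 + 10^(n*(pH - pKa)))`.
#'
#' @param ph pH values.
#' @param pka Midpoint, pH units.
#' @param n_hill Hill coefficient (> 0).
#' @param p_max,p_min Plateau permeabilities, cm/s.
#' @return Permeability at `ph`.
#' @export
hill_ph <- function(ph, pka, n_hill, p_max, p_min = 0) {
  r <- 10^(n_hill * (ph - pka))
  p_min + (p_max - p_min) * r / (1 + r)
}

#' Fit the Hill pH-dependence of permeability and estimate pKa
#'
#' Least-squares fit of [hill_ph()] to permeability measured across a pH
#' range, via [minpack.lm::nlsLM()]. Starting values: plateaus from the
#' data range, pKa from the pH at which the response crosses its midpoint,
#' Hill coefficient 1. `n_hill` is bounded in (0, 10]; `p_min` is bounded
#' below by 0 rather than pinned to a control level, since channels can
#' retain residual permeability on the acid side.
#'
#' @param ph pH values (>= 4 distinct values spanning the transition).
#' @param p Permeabilities, cm/s (replicates allowed: repeat `ph` entries).
#' @return A `hill_fit` list: `pka`, `n_hill`, `p_max`, `p_min`,
#'   `covariance`, `stderr` (named), `r_squared`, and the `fit` object.
#' @export
fit_hill_ph <- function(ph, p) {
  stopifnot(length(ph) == length(p), all(is.finite(ph)), all(is.finite(p)))
  if (length(unique(ph)) < 4L) {
    stop("need >= 4 distinct pH points spanning the transition")
  }
  rng <- range(p)
  if (diff(rng) < 1e-12 * max(abs(rng), 1)) {
    stop("non-identifiable: flat permeability across the pH range")
  }
  # midpoint crossing for the pKa start value
  mid <- mean(rng)
  ord <- order(ph)
  start_pka <- stats::approx(p[ord], ph[ord], xout = mid, ties = mean)$y
  if (is.na(start_pka)) start_pka <- stats::median(ph)

  dat <- data.frame(ph = ph, p = p)
  fit <- minpack.lm::nlsLM(
    p ~ hill_ph(ph, pka, n_hill, p_max, p_min),
    data = dat,
    start = list(pka = start_pka, n_hill = 1,
                 p_max = rng[2], p_min = max(rng[1], 0)),
    # the acid plateau may vanish; a hair of slack below 0 keeps the
    # optimizer off the bound (estimates in [-eps, 0) are clamped to 0)
    lower = c(pka = min(ph) - 5, n_hill = 1e-3, p_max = 0,
              p_min = -0.01 * rng[2]),
    upper = c(pka = max(ph) + 5, n_hill = 10, p_max = Inf, p_min = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  cf[["p_min"]] <- max(cf[["p_min"]], 0)
  if (cf[["pka"]] < min(ph) || cf[["pka"]] > max(ph)) {
    warning("pKa lies outside the sampled pH range (extrapolation)")
  }
  res <- stats::resid(fit)
  structure(list(
    pka = cf[["pka"]], n_hill = cf[["n_hill"]],
    p_max = cf[["p_max"]], p_min = cf[["p_min"]],
    covariance = stats::vcov(fit),
    stderr = sqrt(diag(stats::vcov(fit))),
    r_squared = 1 - sum(res^2) / sum((p - mean(p))^2),
    fit = fit
  ), class = "hill_fit")
}

#' Arrhenius activation energy from a permeability-temperature series
#'
#' Ordinary least squares of `ln(p)` on `1/T`; the activation energy is
#' `Ea = -slope * R` with R = 1.9872e-3 kcal/(mol K). A low Ea
#' (< ~5-10 kcal/mol) signals channel-mediated transport; high Ea signals
#' diffusion across the lipid bilayer.
#'
#' @param temps_k Absolute temperatures, K (>= 3 values).
#' @param p Permeabilities, cm/s (all > 0).
#' @return An `arrhenius_fit` list: `ea` (kcal/mol), `ea_stderr`,
#'   `ln_prefactor`, `r_gas`, `r_squared`, `fit`.
#' @export
fit_arrhenius <- function(temps_k, p) {
  stopifnot(length(temps_k) == length(p))
  if (length(unique(temps_k)) < 2L) stop("need >= 2 distinct temperatures")
  if (any(p <= 0)) stop("all permeabilities must be > 0 for the log transform")
  if (any(temps_k <= 0)) stop("temperatures must be in K")
  r_gas <- 1.9872e-3  # kcal / (mol K)
  inv_t <- 1 / temps_k
  fit <- stats::lm(log(p) ~ inv_t)
  slope <- stats::coef(fit)[["inv_t"]]
  sm <- suppressWarnings(summary(fit))  # zero-residual fits warn in summary()
  structure(list(
    ea = -slope * r_gas,
    ea_stderr = sm$coefficients["inv_t", "Std. Error"] * r_gas,
    ln_prefactor = stats::coef(fit)[["(Intercept)"]],
    r_gas = r_gas,
    r_squared = sm$r.squared,
    fit = fit
  ), class = "arrhenius_fit")
}

#' Four-parameter logistic dose-response model
#'
#' `p(c) = p_bottom + (p_top - p_bottom) / (1 + (c/ic50)^hill_slope)`.
#'
#' @param conc Inhibitor concentrations.
#' @param ic50 Half-maximal inhibitory concentration (> 0).
#' @param hill_slope Slope factor.
#' @param p_top,p_bottom Uninhibited and fully inhibited permeability.
#' @return Permeability at `conc`.
#' @export
logistic_dose <- function(conc, ic50, hill_slope, p_top, p_bottom = 0) {
  p_bottom + (p_top - p_bottom) / (1 + (conc / ic50)^hill_slope)
}

#' Fit a dose-response inhibition curve and estimate IC50
#'
#' Least-squares fit of the four-parameter logistic [logistic_dose()] to
#' permeability measured across inhibitor doses, via
#' [minpack.lm::nlsLM()]. IC50 is reported on the concentration scale of
#' the input.
#'
#' @param conc Doses (umol/L), >= 4 including a 0/near-0 and a saturating
#'   dose; replicates as repeated entries.
#' @param p Permeabilities, cm/s.
#' @param fix_bottom Optional value at which to pin `p_bottom` (e.g. 0).
#' @return A `dose_response_fit` list: `ic50`, `hill_slope`, `p_top`,
#'   `p_bottom`, `stderr`, `r_squared`, `fit`.
#' @export
fit_dose_response <- function(conc, p, fix_bottom = NULL) {
  stopifnot(length(conc) == length(p), all(conc >= 0), all(is.finite(p)))
  if (length(unique(conc)) < 4L) stop("need >= 4 distinct doses")
  pos <- sort(unique(conc[conc > 0]))
  start_ic50 <- stats::median(pos)
  dat <- data.frame(conc = conc, p = p)
  top0 <- max(p); bot0 <- max(min(p), 0)
  if (is.null(fix_bottom)) {
    fit <- minpack.lm::nlsLM(
      p ~ logistic_dose(conc, ic50, hill_slope, p_top, p_bottom),
      data = dat,
      start = list(ic50 = start_ic50, hill_slope = 1,
                   p_top = top0, p_bottom = bot0),
      # slack below 0 as in fit_hill_ph; clamped afterwards
      lower = c(ic50 = min(pos) / 100, hill_slope = 1e-3, p_top = 0,
                p_bottom = -0.01 * top0),
      upper = c(ic50 = max(pos) * 100, hill_slope = 10, p_top = Inf,
                p_bottom = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      p ~ logistic_dose(conc, ic50, hill_slope, p_top, fix_bottom),
      data = dat,
      start = list(ic50 = start_ic50, hill_slope = 1, p_top = top0),
      lower = c(ic50 = min(pos) / 100, hill_slope = 1e-3, p_top = 0),
      upper = c(ic50 = max(pos) * 100, hill_slope = 10, p_top = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((p - mean(p))^2)
  if (r2 < 0.5) warning(sprintf("poor dose-response fit (R^2 = %.2f)", r2))
  structure(list(
    ic50 = cf[["ic50"]], hill_slope = cf[["hill_slope"]],
    p_top = cf[["p_top"]],
    p_bottom = if (is.null(fix_bottom)) max(cf[["p_bottom"]], 0) else fix_bottom,
    stderr = sqrt(diag(stats::vcov(fit))),
    r_squared = r2,
    fit = fit
  ), class = "dose_response_fit")
}

#' Relative membrane expression from fluorescence line profiles
#'
#' For each intensity profile drawn across a cell membrane, the background
#' intensity measured along an equal path is averaged and subtracted from
#' the profile's peak, and the difference is divided by the peak:
#' `rme = (max(profile) - mean(background)) / max(profile)`. Per-line
#' values are aggregated as mean +/- SEM.
#'
#' @param line_profiles List of numeric intensity vectors (one per line).
#' @param backgrounds List of background intensity vectors, paired with
#'   `line_profiles`.
#' @return An `rme_result` list: `rme`, `sem`, `n_profiles`, `per_line`.
#' @export
relative_membrane_expression <- function(line_profiles, backgrounds) {
  if (is.numeric(line_profiles)) line_profiles <- list(line_profiles)
  if (is.numeric(backgrounds)) backgrounds <- list(backgrounds)
  if (!length(line_profiles)) stop("insufficient data: no profiles")
  if (length(backgrounds) != length(line_profiles)) {
    stop("each profile needs a paired background")
  }
  per_line <- mapply(function(prof, bg) {
    peak <- max(prof)
    if (peak <= 0) stop("degenerate profile: non-positive peak intensity")
    (peak - mean(bg)) / peak
  }, line_profiles, backgrounds)
  s <- summarize_mean_sem(per_line)
  structure(list(rme = s$mean, sem = if (is.na(s$sem)) 0 else s$sem,
                 n_profiles = s$n, per_line = per_line),
            class = "rme_result")
}
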