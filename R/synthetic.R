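#' Specification for the seeded synthetic-data generators
#'
#' Controls every generator in the package: the RNG seed, the measurement
#' noise (Gaussian, multiplicative on signal amplitude), the number of
#' replicates, and the photobleaching drift rate of the fluorophore.
#' Identical specs reproduce identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd_frac Noise SD as a fraction of signal amplitude (>= 0).
#' @param n_replicates Number of replicate runs/measurements (>= 1).
#' @param bleach_rate Photobleaching rate constant, 1/s (exponential
#'   decay of the fluorophore). Default 1/30.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(seed = 1L, noise_sd_frac = 0.01,
                           n_replicates = 1L, bleach_rate = 1 / 30) {
  stopifnot(noise_sd_frac >= 0, n_replicates >= 1L, bleach_rate >= 0)
  structure(list(seed = as.integer(seed), noise_sd_frac = noise_sd_frac,
                 n_replicates = as.integer(n_replicates),
                 bleach_rate = bleach_rate),
            class = "generator_spec")
}

#' Ground truth attached to a generated object
#'
#' @param x A generator output.
#' @return The embedded ground-truth parameter list.
#' @export
generator_truth <- function(x) attr(x, "truth")

# fluorescence from relative volume under the linear calibration
# v = a * F/F0 + b  =>  F = F0 * (v - b)/a; self-quenching makes F rise
# on shrinkage, so a < 0.
volume_to_fluorescence <- function(v_rel, a, b, f0) f0 * (v_rel - b) / a

#' Generate paired sorbitol/glycerol stopped-flow runs with ground truth
#'
#' Emulates the paired-shock stopped-flow protocol: for each replicate
#' run, the forward model produces the sorbitol (impermeant) and glycerol
#' (permeant) relative-volume responses, which are mapped to fluorescence
#' by inverting a run-specific linear calibration (slope `a` drawn
#' uniformly in `[-0.7, -0.3]`, intercept `b = 1 - a` so that F(0) = F0;
#' negative slope encodes self-quenching: fluorescence rises as the cell
#' shrinks). An additive exponential photobleaching drift
#' `F0*(exp(-bleach_rate*t) - 1)` and Gaussian noise (SD =
#' `noise_sd_frac` x signal amplitude) are added; each run carries an
#' isosmotic baseline trace holding drift and noise only.
#'
#' @param geom [cell_geometry()].
#' @param perm [permeability_params()] ground truth (pf, pgly).
#' @param shock [shock_protocol()] of the glycerol shock
#'   (`permeant_gradient > 0`); the paired sorbitol shock uses the same
#'   tonicity with a zero permeant gradient.
#' @param spec [generator_spec()]; `n_replicates` sets the number of runs.
#' @param t_end,n_points Acquisition window (s) and samples per trace (default 60 s, long enough for both shock types to equilibrate).
#' @return A list of runs, each with elements `sorbitol`, `glycerol`
#'   (each a list `shock`/`baseline` of [fluorescence_trace()]s) and
#'   `truth` (pf, pgly, a, b, v_rel ground-truth traces); the full truth
#'   is also attached as an attribute.
#' @export
generate_stopped_flow_pair <- function(geom, perm, shock,
                                       spec = generator_spec(),
                                       t_end = 60, n_points = 400) {
  stopifnot(inherits(spec, "generator_spec"))
  if (shock$permeant_gradient <= 0) {
    stop("shock must carry a permeant gradient; the sorbitol pair is derived")
  }
  set.seed(spec$seed)
  shock_sorb <- shock_protocol(shock$tonicity, 0, shock$temperature)
  v_sorb <- simulate_volume_response(
    geom, permeability_params(pf = perm$pf, pgly = 0), shock_sorb,
    t_end = t_end, n_points = n_points)
  v_gly <- simulate_volume_response(
    geom, perm, shock, t_end = t_end, n_points = n_points)
  times <- v_sorb$time_s
  f0 <- 100
  drift <- f0 * (exp(-spec$bleach_rate * times) - 1)

  runs <- lapply(seq_len(spec$n_replicates), function(i) {
    a <- stats::runif(1, -0.7, -0.3)
    b <- 1 - a
    make_trace <- function(v_rel) {
      f_signal <- volume_to_fluorescence(v_rel, a, b, f0)
      amp <- diff(range(f_signal))
      noise_sd <- spec$noise_sd_frac * amp
      f <- f_signal + drift + stats::rnorm(length(times), 0, noise_sd)
      fluorescence_trace(times, f, f0 = f0)
    }
    make_baseline <- function(amp_ref) {
      noise_sd <- spec$noise_sd_frac * amp_ref
      fluorescence_trace(
        times, f0 + drift + stats::rnorm(length(times), 0, noise_sd),
        f0 = f0)
    }
    amp_sorb <- diff(range(volume_to_fluorescence(v_sorb$v_rel, a, b, f0)))
    amp_gly <- diff(range(volume_to_fluorescence(v_gly$v_rel, a, b, f0)))
    list(
      sorbitol = list(shock = make_trace(v_sorb$v_rel),
                      baseline = make_baseline(amp_sorb)),
      glycerol = list(shock = make_trace(v_gly$v_rel),
                      baseline = make_baseline(amp_gly)),
      truth = list(pf = perm$pf, pgly = perm$pgly, a = a, b = b, f0 = f0)
    )
  })
  attr(runs, "truth") <- list(
    pf = perm$pf, pgly = perm$pgly,
    v_rel_sorbitol = v_sorb, v_rel_glycerol = v_gly,
    geom = geom, shock = shock, spec = spec)
  runs
}

add_mult_noise <- function(values, noise_sd_frac) {
  values * (1 + stats::rnorm(length(values), 0, noise_sd_frac))
}

#' Generate a synthetic permeability-vs-pH series from the Hill model
#'
#' @param truth List with `pka`, `n_hill`, `p_max`, `p_min`.
#' @param ph_grid pH values.
#' @param spec [generator_spec()] (`n_replicates` measurements per pH;
#'   multiplicative Gaussian noise).
#' @return Data frame `ph`, `p`, `replicate` with the truth attached.
#' @export
generate_ph_series <- function(truth, ph_grid = seq(5, 7.5, by = 0.5),
                               spec = generator_spec(noise_sd_frac = 0.05,
                                                     n_replicates = 4L)) {
  stopifnot(inherits(spec, "generator_spec"), length(ph_grid) >= 2L)
  set.seed(spec$seed)
  model_p <- hill_ph(ph_grid, truth$pka, truth$n_hill, truth$p_max,
                     truth$p_min)
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    data.frame(ph = ph_grid,
               p = add_mult_noise(model_p, spec$noise_sd_frac),
               replicate = r)
  }))
  attr(out, "truth") <- c(truth, list(spec = spec))
  out
}

#' Generate a synthetic permeability-vs-temperature (Arrhenius) series
#'
#' `ln p` is linear in `1/T` with slope `-Ea/R`; `p_ref` anchors the
#' curve at `t_ref_c`.
#'
#' @param truth List with `ea` (kcal/mol), `p_ref` (cm/s at `t_ref_c`)
#'   and optionally `t_ref_c` (default 23).
#' @param temps_c Temperatures in Celsius.
#' @param spec [generator_spec()].
#' @return Data frame `temp_C`, `p`, `replicate` with truth attached.
#' @export
generate_arrhenius_series <- function(truth,
                                      temps_c = c(7, 15, 23, 30, 38),
                                      spec = generator_spec(
                                        noise_sd_frac = 0.03,
                                        n_replicates = 3L)) {
  stopifnot(inherits(spec, "generator_spec"), length(temps_c) >= 2L)
  set.seed(spec$seed)
  r_gas <- 1.9872e-3
  t_ref <- (if (is.null(truth$t_ref_c)) 23 else truth$t_ref_c) + 273.15
  temps_k <- temps_c + 273.15
  model_p <- truth$p_ref * exp(-(truth$ea / r_gas) * (1 / temps_k - 1 / t_ref))
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    data.frame(temp_C = temps_c,
               p = add_mult_noise(model_p, spec$noise_sd_frac),
               replicate = r)
  }))
  attr(out, "truth") <- c(truth, list(spec = spec))
  out
}

#' Generate a synthetic dose-response inhibition series
#'
#' @param truth List with `ic50`, `hill_slope`, `p_top`, `p_bottom`.
#' @param doses Inhibitor concentrations (umol/L), including 0 and a
#'   saturating dose.
#' @param spec [generator_spec()].
#' @return Data frame `conc_uM`, `p`, `replicate` with truth attached.
#' @export
generate_dose_response <- function(truth,
                                   doses = c(0, 2, 5, 10, 20, 50, 100),
                                   spec = generator_spec(
                                     noise_sd_frac = 0.05,
                                     n_replicates = 3L)) {
  stopifnot(inherits(spec, "generator_spec"), length(doses) >= 4L)
  set.seed(spec$seed)
  model_p <- logistic_dose(doses, truth$ic50, truth$hill_slope,
                           truth$p_top, truth$p_bottom)
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    data.frame(conc_uM = doses,
               p = add_mult_noise(model_p, spec$noise_sd_frac),
               replicate = r)
  }))
  attr(out, "truth") <- c(truth, list(spec = spec))
  out
}

#' Generate synthetic membrane line profiles for RME analysis
#'
#' Each profile is a Gaussian membrane peak of known height on a flat
#' background; each background path holds the background level only.
#'
#' @param peak Peak intensity above zero.
#' @param background_level Mean background intensity.
#' @param n_lines Number of profile lines.
#' @param n_points Samples per line.
#' @param spec [generator_spec()].
#' @return List with `profiles`, `backgrounds` and the ground-truth `rme`
#'   attached (`(peak - background_level)/peak`, exact at zero noise).
#' @export
generate_line_profiles <- function(peak = 200, background_level = 50,
                                   n_lines = 3L, n_points = 51L,
                                   spec = generator_spec(noise_sd_frac = 0)) {
  set.seed(spec$seed)
  xs <- seq(-1, 1, length.out = n_points)
  shape <- exp(-xs^2 / (2 * 0.15^2))
  noise_sd <- spec$noise_sd_frac * peak
  profiles <- lapply(seq_len(n_lines), function(i) {
    background_level + (peak - background_level) * shape +
      stats::rnorm(n_points, 0, noise_sd)
  })
  backgrounds <- lapply(seq_len(n_lines), function(i) {
    background_level + stats::rnorm(n_points, 0, noise_sd)
  })
  out <- list(profiles = profiles, backgrounds = backgrounds)
  attr(out, "truth") <- list(rme = (peak - background_level) / peak,
                             peak = peak,
                             background_level = background_level)
  out
}

#' Generate a scripted channel trajectory with known crossing counts
#'
#' Builds a toy MD coordinate stream realising exactly the planned number
#' of directional channel passages, plus non-crossing decoys that
#' exercise the exclusion logic: molecules that enter the slab and return
#' to their entry side, molecules crossing the slab outside all monomer
#' cylinders (bilayer path), and reflected random walkers confined
#' laterally outside the cylinders. Crossing paths run monotonically in z
#' through a monomer axis (cycled across monomers) with lateral Gaussian
#' jitter small relative to `radius_cut` and z jitter small relative to
#' the per-frame step, so region membership is preserved. Trajectories
#' are fixtures for the counting logic, not physical simulations.
#'
#' @param n_water,n_glycerol Molecule counts per kind.
#' @param planned List with integer fields `water_down`, `water_up`,
#'   `glycerol_down`, `glycerol_up` (defaults 0).
#' @param region [channel_region()].
#' @param n_frames Frames in the stream.
#' @param dt_ps Frame spacing, ps.
#' @param spec [generator_spec()].
#' @return A [trajectory()] with the plan attached as truth.
#' @export
generate_channel_trajectory <- function(n_water, n_glycerol = 0L,
                                        planned = list(),
                                        region = default_channel_region(),
                                        n_frames = 120L, dt_ps = 10,
                                        spec = generator_spec()) {
  stopifnot(inherits(region, "channel_region"), n_frames >= 10L)
  plan <- list(water_down = 0L, water_up = 0L,
               glycerol_down = 0L, glycerol_up = 0L)
  plan[names(planned)] <- lapply(planned, as.integer)
  if (plan$water_down + plan$water_up > n_water ||
      plan$glycerol_down + plan$glycerol_up > n_glycerol) {
    stop("infeasible plan: more crossings than molecules")
  }
  set.seed(spec$seed)

  z_top <- region$z_hi + 10
  z_bot <- region$z_lo - 10
  step <- (z_top - z_bot) / (n_frames - 1)
  z_jit <- min(0.1, step / 5)
  lat_jit <- min(0.5, region$radius_cut / 6)
  axes <- region$axes
  far <- max(abs(unlist(axes))) + region$radius_cut + 8

  mol_paths <- list()
  mol_counter <- 0L
  add_mol <- function(kind, x, y, z) {
    mol_counter <<- mol_counter + 1L
    mol_paths[[mol_counter]] <<- data.frame(
      frame = seq_len(n_frames) - 1L, mol_id = mol_counter, kind = kind,
      x = x, y = y, z = z)
  }
  crosser <- function(kind, direction, idx) {
    ax <- axes[(idx - 1L) %% nrow(axes) + 1L, ]
    z <- seq(z_top, z_bot, length.out = n_frames)
    if (direction == "up") z <- rev(z)
    add_mol(kind,
            ax$x + stats::rnorm(n_frames, 0, lat_jit),
            ax$y + stats::rnorm(n_frames, 0, lat_jit),
            z + stats::rnorm(n_frames, 0, z_jit))
  }
  returner <- function(kind, idx) {
    ax <- axes[(idx - 1L) %% nrow(axes) + 1L, ]
    mid <- (region$z_lo + region$z_hi) / 2
    half <- ceiling(n_frames / 2)
    z <- c(seq(z_top, mid, length.out = half),
           seq(mid, z_top, length.out = n_frames - half + 1L)[-1])
    add_mol(kind,
            ax$x + stats::rnorm(n_frames, 0, lat_jit),
            ax$y + stats::rnorm(n_frames, 0, lat_jit),
            z + stats::rnorm(n_frames, 0, z_jit))
  }
  bilayer <- function(kind) {
    z <- seq(z_top, z_bot, length.out = n_frames)
    add_mol(kind,
            far + stats::rnorm(n_frames, 0, lat_jit),
            far + stats::rnorm(n_frames, 0, lat_jit),
            z + stats::rnorm(n_frames, 0, z_jit))
  }
  walker <- function(kind) {
    z <- numeric(n_frames)
    z[1] <- stats::runif(1, z_bot, z_top)
    steps <- stats::rnorm(n_frames - 1L, 0, 1.5)
    for (i in 2:n_frames) {
      zi <- z[i - 1L] + steps[i - 1L]
      if (zi > z_top) zi <- 2 * z_top - zi
      if (zi < z_bot) zi <- 2 * z_bot - zi
      z[i] <- zi
    }
    add_mol(kind,
            far + stats::rnorm(n_frames, 0, 1),
            -far + stats::rnorm(n_frames, 0, 1),
            z)
  }

  build_kind <- function(kind, n_mol, n_down, n_up) {
    i <- 0L
    for (k in seq_len(n_down)) { i <- i + 1L; crosser(kind, "down", i) }
    for (k in seq_len(n_up)) { i <- i + 1L; crosser(kind, "up", i) }
    n_rest <- n_mol - n_down - n_up
    if (n_rest > 0L) {
      roles <- rep(c("returner", "bilayer", "walker"), length.out = n_rest)
      for (r in roles) {
        i <- i + 1L
        switch(r,
               returner = returner(kind, i),
               bilayer = bilayer(kind),
               walker = walker(kind))
      }
    }
  }
  build_kind("water", n_water, plan$water_down, plan$water_up)
  if (n_glycerol > 0L) {
    build_kind("glycerol", n_glycerol, plan$glycerol_down, plan$glycerol_up)
  }

  traj <- trajectory(do.call(rbind, mol_paths), dt_ps = dt_ps)
  attr(traj, "truth") <- c(plan, list(spec = spec))
  traj
}

#' Default tetrameric channel region used by the toy generator
#'
#' Four monomer axes at (+/-10, +/-10) Angstrom, slab z in [-15, 15],
#' lateral cut-off 6 Angstrom.
#' @return A [channel_region()].
#' @export
default_channel_region <- function() {
  channel_region(data.frame(x = c(10, 10, -10, -10),
                            y = c(10, -10, 10, -10)),
                 z_lo = -15, z_hi = 15, radius_cut = 6)
}

#' Load the shipped scenario presets
#'
#' Named parameter sets for the study conditions (hAQP7 at pH 7.4 and pH
#' 5.0, control cells, Auphen-treated cells, and the gating-curve truths)
#' stored as YAML with the package.
#'
#' @return Nested list of scenario parameters.
#' @export
load_scenarios <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "aqpflux",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}
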