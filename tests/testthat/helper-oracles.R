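# Independent oracles used to cross-check the package implementations.
# These re-derive the computations from first principles and deliberately
# share no code with the package internals.

default_geom <- function() cell_geometry(radius = 2.5e-4, beta = 0.5,
                                         vw = 18, iso_osm = 1.4)

# Fixed-step classical RK4 integration of the shrink/swell equations,
# written in dimensional form (V in cm^3, Ng in mol).
rk4_volume_oracle <- function(geom, pf, pgly, tonicity, permeant_gradient,
                              t_end, n_steps = 5000) {
  v0 <- (4 / 3) * pi * geom$radius^3
  area <- 4 * pi * geom$radius^2
  beta_v0 <- geom$beta * v0
  c_out <- tonicity * geom$iso_osm / 1000
  c_out_g <- permeant_gradient / 1000
  ns <- (geom$iso_osm / 1000) * (v0 - beta_v0)

  deriv <- function(state) {
    v_act <- state[1] - beta_v0
    c_in <- (ns + state[2]) / v_act
    c(-pf * area * geom$vw * (c_out - c_in),
      pgly * area * (c_out_g - state[2] / v_act))
  }
  h <- t_end / n_steps
  state <- c(v0, 0)
  times <- numeric(n_steps + 1)
  v_rel <- numeric(n_steps + 1)
  v_rel[1] <- 1
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    times[i + 1] <- i * h
    v_rel[i + 1] <- state[1] / v0
  }
  data.frame(time_s = times, v_rel = v_rel)
}

# time at which a shrinking trace first reaches a given volume,
# by linear interpolation between the bracketing samples
crossing_time <- function(trace, v_target) {
  i <- which(trace$v_rel <= v_target)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  v1 <- trace$v_rel[i - 1L]; v2 <- trace$v_rel[i]
  t1 <- trace$time_s[i - 1L]; t2 <- trace$time_s[i]
  t1 + (v_target - v1) * (t2 - t1) / (v2 - v1)
}

# Brute-force directional passage count for one molecule: label frames
# above/inside/below, collapse into maximal runs, and scan for
# outside -> inside-run -> opposite-outside subsequences with lateral
# containment (any monomer cylinder) on every inside frame.
passage_oracle_one <- function(x, y, z, region) {
  lab <- ifelse(z > region$z_hi, "A", ifelse(z < region$z_lo, "B", "I"))
  inside_ok <- rep(FALSE, length(z))
  for (i in seq_len(nrow(region$axes))) {
    inside_ok <- inside_ok |
      ((x - region$axes$x[i])^2 + (y - region$axes$y[i])^2 <=
         region$radius_cut^2)
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  down <- 0L; up <- 0L
  for (j in seq_along(r$values)) {
    if (r$values[j] == "I") {
      if (j == 1L || j == length(r$values)) next
      a <- r$values[j - 1L]; b <- r$values[j + 1L]
      if (a == b) next
      if (!all(inside_ok[starts[j]:ends[j]])) next
      if (a == "A") down <- down + 1L else up <- up + 1L
    } else if (j > 1L && r$values[j - 1L] != "I" &&
               r$values[j] != r$values[j - 1L]) {
      # direct jump across the slab, lateral check skipped
      if (r$values[j - 1L] == "A") down <- down + 1L else up <- up + 1L
    }
  }
  c(down = down, up = up)
}

passage_oracle <- function(traj, region, kind = "water") {
  fr <- traj$frames[traj$frames$kind == kind, , drop = FALSE]
  fr <- fr[order(fr$mol_id, fr$frame), , drop = FALSE]
  total <- c(down = 0L, up = 0L)
  for (path in split(fr, fr$mol_id)) {
    total <- total + passage_oracle_one(path$x, path$y, path$z, region)
  }
  total
}

# Grid search over (pKa, n) with the plateaus profiled out by a
# closed-form 2x2 linear solve (the Hill model is linear in p_min, p_max
# given pKa and n).
hill_grid_oracle <- function(ph, p, pka_range, n_range,
                             pka_step = 0.002, n_step = 0.02) {
  best <- c(sse = Inf, pka = NA, n = NA)
  for (pka in seq(pka_range[1], pka_range[2], by = pka_step)) {
    for (n in seq(n_range[1], n_range[2], by = n_step)) {
      w <- 10^(n * (ph - pka)); w <- w / (1 + w)
      x1 <- 1 - w
      # normal equations for p = p_min*x1 + p_max*w
      s11 <- sum(x1 * x1); s12 <- sum(x1 * w); s22 <- sum(w * w)
      b1 <- sum(x1 * p); b2 <- sum(w * p)
      det <- s11 * s22 - s12^2
      if (det < 1e-12) next
      p_min <- (b1 * s22 - b2 * s12) / det
      p_max <- (b2 * s11 - b1 * s12) / det
      sse <- sum((p - (p_min * x1 + p_max * w))^2)
      if (sse < best["sse"]) best <- c(sse = sse, pka = pka, n = n)
    }
  }
  best
}

# random-walk trajectory builder for the path-oracle property test
random_walk_trajectory <- function(n_mol, n_frames, region, seed) {
  set.seed(seed)
  paths <- lapply(seq_len(n_mol), function(m) {
    start_axis <- region$axes[sample.int(nrow(region$axes), 1L), ]
    x0 <- start_axis$x + stats::runif(1, -12, 12)
    y0 <- start_axis$y + stats::runif(1, -12, 12)
    z0 <- stats::runif(1, region$z_lo - 20, region$z_hi + 20)
    data.frame(
      frame = seq_len(n_frames) - 1L, mol_id = m, kind = "water",
      x = x0 + cumsum(stats::rnorm(n_frames, 0, 1.5)),
      y = y0 + cumsum(stats::rnorm(n_frames, 0, 1.5)),
      z = z0 + cumsum(stats::rnorm(n_frames, 0, 3)))
  })
  trajectory(do.call(rbind, paths), dt_ps = 10)
}
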