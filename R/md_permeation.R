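#' Channel region for crossing analysis
#'
#' Defines the membrane slab (`z_lo`, `z_hi`, from pore-radius data) and
#' one axis point per monomer in the membrane plane. A molecule inside the
#' slab is attributed to the channel path only while it stays within
#' `radius_cut` of at least one monomer axis; molecules traversing the
#' slab further out are counted as bilayer path and excluded.
#'
#' @param axes Data frame or matrix with columns `x`, `y` (one row per
#'   monomer axis, Angstrom).
#' @param z_lo,z_hi Lower/upper slab bounds, Angstrom (`z_lo < z_hi`).
#' @param radius_cut Lateral cut-off radius around each axis, Angstrom.
#' @return A `channel_region` object.
#' @export
channel_region <- function(axes, z_lo, z_hi, radius_cut = 6) {
  axes <- as.data.frame(axes)
  stopifnot(all(c("x", "y") %in% names(axes)), nrow(axes) >= 1L)
  if (!(z_lo < z_hi)) stop("z_lo must be < z_hi")
  if (radius_cut <= 0) stop("radius_cut must be > 0")
  structure(list(axes = axes[, c("x", "y")], z_lo = z_lo, z_hi = z_hi,
                 radius_cut = radius_cut),
            class = "channel_region")
}

#' Build an MD coordinate stream from per-frame records
#'
#' @param frames Data frame with columns `frame` (integer, uniform
#'   spacing), `mol_id`, `kind` ("water"/"glycerol"), `x`, `y`, `z`
#'   (Angstrom). Each molecule appears at most once per frame.
#' @param dt_ps Time between frames, ps.
#' @return A `trajectory` object.
#' @export
trajectory <- function(frames, dt_ps) {
  frames <- as.data.frame(frames)
  need <- c("frame", "mol_id", "kind", "x", "y", "z")
  stopifnot(all(need %in% names(frames)))
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || !is.finite(dt_ps) ||
      dt_ps <= 0) {
    stop("invalid trajectory: dt_ps must be a positive number")
  }
  if (!all(is.finite(frames$x) & is.finite(frames$y) & is.finite(frames$z))) {
    stop("invalid trajectory: non-finite coordinates")
  }
  if (anyDuplicated(frames[, c("frame", "mol_id")])) {
    stop("invalid trajectory: molecule repeated within a frame")
  }
  structure(list(frames = frames, dt_ps = dt_ps,
                 n_frames = length(unique(frames$frame))),
            class = "trajectory")
}

# Label each z against the slab: 1 above, 0 inside, -1 below
slab_side <- function(z, region) {
  ifelse(z > region$z_hi, 1L, ifelse(z < region$z_lo, -1L, 0L))
}

# For inside frames: index of the monomer axis within radius_cut (nearest),
# or NA when outside all cylinders (bilayer path).
nearest_axis <- function(x, y, region) {
  d2 <- sapply(seq_len(nrow(region$axes)), function(i) {
    (x - region$axes$x[i])^2 + (y - region$axes$y[i])^2
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = length(x))
  idx <- max.col(-d2, ties.method = "first")
  ok <- d2[cbind(seq_along(idx), idx)] <= region$radius_cut^2
  ifelse(ok, idx, NA_integer_)
}

# Directional passages for one molecule's ordered path. State machine over
# the side sequence: arm on an outside frame; while armed, traverse inside
# frames (checking lateral containment); count on reaching the opposite
# side, reset on returning to the entry side. A direct jump across the
# slab in one step counts with the lateral check skipped.
count_molecule_passages <- function(side, axis_idx, n_axes) {
  down <- integer(n_axes); up <- integer(n_axes)
  entry <- 0L          # -1/+1 when armed, 0 when not
  clean <- TRUE        # all inside frames so far within a cylinder
  axes_seen <- integer(0)
  for (i in seq_along(side)) {
    s <- side[i]
    if (s == 0L) {
      if (entry != 0L) {
        if (is.na(axis_idx[i])) clean <- FALSE
        else axes_seen <- c(axes_seen, axis_idx[i])
      }
      next
    }
    if (entry == 0L) {
      entry <- s
    } else if (s == entry) {          # re-exit on the entry side: reset
      clean <- TRUE; axes_seen <- integer(0)
    } else {                          # reached the opposite side
      if (clean) {
        ax <- if (length(axes_seen)) {
          as.integer(names(which.max(table(axes_seen))))
        } else 1L                      # single-frame jump: lateral unchecked
        if (entry == 1L) down[ax] <- down[ax] + 1L else up[ax] <- up[ax] + 1L
      }
      entry <- s; clean <- TRUE; axes_seen <- integer(0)
    }
  }
  list(down = down, up = up)
}

#' Count complete directional channel crossings in an MD trajectory
#'
#' Per molecule, a three-region state machine (above / inside / below the
#' membrane slab) registers a passage when the molecule enters the slab
#' from one z-side and exits on the opposite side, provided every inside
#' frame lies within `radius_cut` of a monomer axis. Excursions that
#' return to the entry side reset the state; molecules travelling through
#' the slab outside all monomer cylinders are excluded as bilayer paths.
#' The transport rate is `k_o = total crossings / simulation length`.
#'
#' Periodic-boundary unwrapping is the caller's responsibility; paths with
#' per-frame |dz| jumps larger than the slab height (beyond the adjacent
#' outside regions) trigger a wrap warning.
#'
#' @param traj A [trajectory()].
#' @param region A [channel_region()].
#' @param kind Molecule kind to count, `"water"` or `"glycerol"`.
#' @return A `crossing_result` list: `down`, `up` (per-monomer vectors),
#'   `total_down`, `total_up`, `total`, `sim_length_s`, `k_o`.
#' @export
count_crossings <- function(traj, region, kind = c("water", "glycerol")) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "channel_region"))
  kind <- match.arg(kind)
  fr <- traj$frames[traj$frames$kind == kind, , drop = FALSE]
  n_axes <- nrow(region$axes)
  down <- integer(n_axes); up <- integer(n_axes)
  slab_h <- region$z_hi - region$z_lo
  if (nrow(fr)) {
    fr <- fr[order(fr$mol_id, fr$frame), , drop = FALSE]
    for (path in split(fr, fr$mol_id)) {
      if (nrow(path) < 2L) next
      if (any(abs(diff(path$z)) >= slab_h)) {
        warning("per-frame z jump exceeds slab height: unwrap coordinates?")
      }
      side <- slab_side(path$z, region)
      axis_idx <- nearest_axis(path$x, path$y, region)
      res <- count_molecule_passages(side, axis_idx, n_axes)
      down <- down + res$down
      up <- up + res$up
    }
  }
  sim_length_s <- traj$dt_ps * traj$n_frames * 1e-12
  total <- sum(down) + sum(up)
  structure(list(down = down, up = up,
                 total_down = sum(down), total_up = sum(up),
                 total = total,
                 sim_length_s = sim_length_s,
                 k_o = total / sim_length_s,
                 kind = kind),
            class = "crossing_result")
}

#' Single-file water diffusion constant from the transport rate
#'
#' Einstein-relation estimate for single-file water in a channel:
#' `D_w = k_o * z^2 / 2`, with `z` the average distance between two
#' adjacent water molecules in the single-file region, converted from
#' Angstrom to cm.
#'
#' @param k_o Transport rate, complete crossings per second (>= 0), or a
#'   `crossing_result`.
#' @param z_spacing Average single-file water-water spacing, Angstrom.
#' @return A `diffusion_estimate` list: `d_w` (cm^2/s), `k_o`,
#'   `z_spacing`.
#' @examples
#' water_diffusion_constant(2e9, 2.8)$d_w  # 7.84e-7 cm^2/s
#' @export
water_diffusion_constant <- function(k_o, z_spacing) {
  if (inherits(k_o, "crossing_result")) k_o <- k_o$k_o
  if (k_o < 0) stop("k_o must be >= 0")
  if (z_spacing <= 0) stop("z_spacing must be > 0")
  z_cm <- z_spacing * 1e-8
  structure(list(d_w = k_o * z_cm^2 / 2, k_o = k_o, z_spacing = z_spacing),
            class = "diffusion_estimate")
}

#' Mean and SEM of molecules crossing per simulation
#'
#' @param results List of `crossing_result` objects (one per simulation),
#'   or a numeric vector of per-simulation totals.
#' @return List with `mean`, `sem` (NA for a single simulation) and `n`.
#' @export
glycerol_passage_summary <- function(results) {
  if (inherits(results, "crossing_result")) results <- list(results)
  totals <- if (is.numeric(results)) results else {
    vapply(results, function(r) {
      stopifnot(inherits(r, "crossing_result")); r$total
    }, numeric(1))
  }
  summarize_mean_sem(totals)
}

#' Average pore-radius profiles across monomers/simulations
#'
#' Profiles are interpolated onto the first profile's z grid when grids
#' differ, then averaged pointwise with SEM.
#'
#' @param profiles List of data frames with columns `z_A`, `radius_A`.
#' @return Data frame `z_A`, `radius_A` (mean), `sem`, `n`.
#' @export
average_pore_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  profiles <- lapply(profiles, function(p) {
    p <- as.data.frame(p)
    stopifnot(all(c("z_A", "radius_A") %in% names(p)))
    if (any(p$radius_A < 0)) stop("pore radii must be >= 0")
    p[order(p$z_A), ]
  })
  grid <- profiles[[1]]$z_A
  mat <- vapply(profiles, function(p) {
    if (length(p$z_A) == length(grid) && all(p$z_A == grid)) return(p$radius_A)
    if (min(p$z_A) > min(grid) || max(p$z_A) < max(grid)) {
      stop("alignment error: profile does not cover the reference z grid")
    }
    stats::approx(p$z_A, p$radius_A, xout = grid)$y
  }, numeric(length(grid)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(grid))
  n <- ncol(mat)
  data.frame(
    z_A = grid,
    radius_A = rowMeans(mat),
    sem = if (n >= 2L) apply(mat, 1L, stats::sd) / sqrt(n) else 0,
    n = n
  )
}
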