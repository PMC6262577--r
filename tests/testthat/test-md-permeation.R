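region4 <- default_channel_region()

# single-monomer region used for hand-built paths
region1 <- channel_region(data.frame(x = 0, y = 0), z_lo = -10, z_hi = 10,
                          radius_cut = 5)

path_df <- function(mol_id, kind, x, y, z) {
  data.frame(frame = seq_along(z) - 1L, mol_id = mol_id, kind = kind,
             x = x, y = y, z = z)
}

test_that("a hand-built three-molecule trajectory counts one downward passage", {
  zs <- seq(15, -15, length.out = 11)
  clean <- path_df(1, "water", rep(0, 11), rep(0, 11), zs)          # crosses
  back <- path_df(2, "water", rep(0, 11), rep(0, 11),
                  c(15, 10, 5, 0, -5, 0, 5, 10, 15, 15, 15))        # returns
  outside <- path_df(3, "water", rep(8, 11), rep(0, 11), zs)        # bilayer
  traj <- trajectory(rbind(clean, back, outside), dt_ps = 10)
  res <- count_crossings(traj, region1, "water")
  expect_equal(res$total_down, 1)
  expect_equal(res$total_up, 0)
  expect_equal(res$k_o, 1 / (10 * 11 * 1e-12))
})

test_that("static or absent molecules give zero counts", {
  static <- path_df(1, "water", rep(0, 5), rep(0, 5), rep(20, 5))
  traj <- trajectory(static, dt_ps = 10)
  res <- count_crossings(traj, region1, "water")
  expect_equal(res$total, 0)
  expect_equal(count_crossings(traj, region1, "glycerol")$total, 0)
})

test_that("reversing the frame order swaps downward and upward counts", {
  traj <- generate_channel_trajectory(
    n_water = 12, planned = list(water_down = 3, water_up = 2),
    spec = generator_spec(seed = 31))
  fwd <- count_crossings(traj, region4, "water")
  rev_frames <- traj$frames
  rev_frames$frame <- max(rev_frames$frame) - rev_frames$frame
  bwd <- count_crossings(trajectory(rev_frames, traj$dt_ps), region4, "water")
  expect_equal(fwd$total_down, 3)
  expect_equal(fwd$total_up, 2)
  expect_equal(bwd$total_down, fwd$total_up)
  expect_equal(bwd$total_up, fwd$total_down)
})

test_that("the state machine matches a brute-force path oracle on random walks", {
  mismatches <- 0L
  for (s in 1:100) {
    traj <- random_walk_trajectory(n_mol = 20, n_frames = 200,
                                   region = region4, seed = 5000 + s)
    res <- count_crossings(traj, region4, "water")
    oracle <- passage_oracle(traj, region4, "water")
    if (res$total_down != oracle["down"] || res$total_up != oracle["up"]) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("single-frame slab jumps count with the lateral check skipped", {
  jumpy <- path_df(1, "water", rep(20, 4), rep(20, 4), c(12, 11, -11, -12))
  traj <- trajectory(jumpy, dt_ps = 10)
  res <- suppressWarnings(count_crossings(traj, region1, "water"))
  expect_equal(res$total_down, 1)
})

test_that("the diffusion constant follows D_w = k_o z^2 / 2", {
  expect_equal(water_diffusion_constant(0, 2.8)$d_w, 0)
  est <- water_diffusion_constant(2e9, 2.8)
  expect_equal(est$d_w, 7.84e-7, tolerance = 1e-12)
  # quadratic scaling in the spacing
  expect_equal(water_diffusion_constant(2e9, 5.6)$d_w / est$d_w, 4)
  # identity holds bit-for-bit against a crossing result
  traj <- generate_channel_trajectory(
    n_water = 6, planned = list(water_down = 2),
    spec = generator_spec(seed = 17))
  res <- count_crossings(traj, region4, "water")
  est2 <- water_diffusion_constant(res, 2.8)
  expect_identical(est2$d_w, res$k_o * (2.8e-8)^2 / 2)
  expect_error(water_diffusion_constant(-1, 2.8), "k_o")
  expect_error(water_diffusion_constant(1, 0), "z_spacing")
})

test_that("passage summaries aggregate totals across simulations", {
  single <- glycerol_passage_summary(3)
  expect_equal(single$mean, 3)
  expect_true(is.na(single$sem))
  five <- glycerol_passage_summary(c(2, 3, 2, 4, 3))
  expect_equal(five$mean, 2.8)
  expect_equal(five$sem, sd(c(2, 3, 2, 4, 3)) / sqrt(5))
  zeros <- glycerol_passage_summary(c(0, 0, 0))
  expect_equal(zeros$mean, 0)
  expect_equal(zeros$sem, 0)
  expect_error(glycerol_passage_summary(list()), "insufficient|at least")
})

test_that("pore profiles average pointwise with SEM", {
  z <- seq(-20, 20, by = 5)
  p1 <- data.frame(z_A = z, radius_A = 2 + 0.05 * abs(z))
  ident <- average_pore_profile(list(p1, p1, p1))
  expect_equal(ident$radius_A, p1$radius_A)
  expect_equal(ident$sem, rep(0, length(z)))

  p2 <- data.frame(z_A = z, radius_A = p1$radius_A + 1)
  two <- average_pore_profile(list(p1, p2))
  expect_equal(two$radius_A, p1$radius_A + 0.5)

  # interpolation path cross-checked against manual resampling
  zq <- c(-20, -10, 0, 10, 20)
  p3 <- data.frame(z_A = zq, radius_A = c(3, 2.2, 1.5, 2.0, 3.1))
  mixed <- average_pore_profile(list(p1, p3))
  manual <- approx(p3$z_A, p3$radius_A, xout = z)$y
  expect_equal(mixed$radius_A, (p1$radius_A + manual) / 2)
  p_short <- data.frame(z_A = c(-5, 0, 5), radius_A = c(2, 2, 2))
  expect_error(average_pore_profile(list(p1, p_short)), "alignment")
})

test_that("trajectory CSV round-trips and requires the dt header", {
  traj <- generate_channel_trajectory(
    n_water = 4, planned = list(water_down = 1),
    spec = generator_spec(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$dt_ps, traj$dt_ps)
  expect_equal(count_crossings(back, region4, "water")$total_down, 1)

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(traj$frames, bad, row.names = FALSE)
  expect_error(read_trajectory_csv(bad), "dt_ps")
})
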