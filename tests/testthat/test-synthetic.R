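test_that("generators are pure functions of spec and parameters", {
  geom <- default_geom()
  shock <- shock_protocol(1.25, 0.35)
  spec <- generator_spec(seed = 123, noise_sd_frac = 0.01, n_replicates = 2L)
  r1 <- generate_stopped_flow_pair(geom, permeability_params(4e-4, 1e-5),
                                   shock, spec)
  r2 <- generate_stopped_flow_pair(geom, permeability_params(4e-4, 1e-5),
                                   shock, spec)
  expect_identical(r1, r2)

  s1 <- generate_ph_series(list(pka = 5.88, n_hill = 1, p_max = 4e-4,
                                p_min = 0),
                           spec = generator_spec(seed = 4))
  s2 <- generate_ph_series(list(pka = 5.88, n_hill = 1, p_max = 4e-4,
                                p_min = 0),
                           spec = generator_spec(seed = 4))
  expect_identical(s1, s2)

  t1 <- generate_channel_trajectory(n_water = 10,
                                    planned = list(water_down = 2),
                                    spec = generator_spec(seed = 8))
  t2 <- generate_channel_trajectory(n_water = 10,
                                    planned = list(water_down = 2),
                                    spec = generator_spec(seed = 8))
  expect_identical(t1, t2)
})

test_that("every generator embeds its ground truth", {
  prof <- generate_line_profiles()
  expect_true(is.numeric(generator_truth(prof)$rme))
  series <- generate_dose_response(list(ic50 = 12.95, hill_slope = 1,
                                        p_top = 1.3e-5, p_bottom = 1e-6))
  expect_equal(generator_truth(series)$ic50, 12.95)
  traj <- generate_channel_trajectory(n_water = 6,
                                      planned = list(water_up = 1),
                                      spec = generator_spec(seed = 3))
  expect_equal(generator_truth(traj)$water_up, 1L)
})

test_that("noiseless gating series are recovered by the fits to 1e-6", {
  truth_h <- list(pka = 5.88, n_hill = 1, p_max = 4.38e-4, p_min = 2e-5)
  ph <- generate_ph_series(truth_h,
                           spec = generator_spec(seed = 1, noise_sd_frac = 0))
  expect_equal(fit_hill_ph(ph$ph, ph$p)$pka, truth_h$pka, tolerance = 1e-6)

  truth_a <- list(ea = 10.55, p_ref = 1.31e-5)
  ar <- generate_arrhenius_series(truth_a,
                                  spec = generator_spec(seed = 1,
                                                        noise_sd_frac = 0))
  expect_equal(fit_arrhenius(ar$temp_C + 273.15, ar$p)$ea, truth_a$ea,
               tolerance = 1e-6)

  truth_d <- list(ic50 = 12.95, hill_slope = 1, p_top = 1.31e-5,
                  p_bottom = 2.1e-6)
  dr <- generate_dose_response(truth_d,
                               spec = generator_spec(seed = 1,
                                                     noise_sd_frac = 0))
  expect_equal(fit_dose_response(dr$conc_uM, dr$p)$ic50, truth_d$ic50,
               tolerance = 1e-6)
})

test_that("scripted trajectories realise exactly the planned crossings", {
  region <- default_channel_region()
  traj <- generate_channel_trajectory(
    n_water = 15, n_glycerol = 8,
    planned = list(water_down = 2, water_up = 1, glycerol_down = 1),
    spec = generator_spec(seed = 12))
  rw <- count_crossings(traj, region, "water")
  rg <- count_crossings(traj, region, "glycerol")
  expect_equal(c(rw$total_down, rw$total_up), c(2, 1))
  expect_equal(c(rg$total_down, rg$total_up), c(1, 0))
  # conservation: passages never exceed the molecules scripted to make them
  expect_lte(rw$total, 15)
  expect_lte(rg$total, 8)
  # agreement with the independent path oracle on the scripted paths
  expect_equal(unname(passage_oracle(traj, region, "water")), c(2L, 1L))

  quiet <- generate_channel_trajectory(
    n_water = 50, planned = list(), spec = generator_spec(seed = 13))
  expect_equal(count_crossings(quiet, region, "water")$total, 0)

  expect_error(
    generate_channel_trajectory(n_water = 1,
                                planned = list(water_down = 2),
                                spec = generator_spec(seed = 1)),
    "infeasible")
})

test_that("pKa tolerance is met in at least 95% of generator seeds", {
  truth <- list(pka = 5.88, n_hill = 1, p_max = 4.38e-4, p_min = 2e-5)
  hits <- vapply(1:100, function(s) {
    series <- generate_ph_series(
      truth, ph_grid = seq(5, 7.5, by = 0.5),
      spec = generator_spec(seed = s, noise_sd_frac = 0.05,
                            n_replicates = 4L))
    fit <- try(fit_hill_ph(series$ph, series$p), silent = TRUE)
    !inherits(fit, "try-error") && abs(fit$pka - truth$pka) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the shipped scenario presets load and carry the study conditions", {
  sc <- load_scenarios()
  expect_equal(sc$stopped_flow$haqp7_ph74$pf, 4.38e-4)
  expect_equal(sc$stopped_flow$control$pf, 2.91e-4)
  expect_equal(sc$gating$ic50_auphen, 12.95)
  expect_equal(sc$shock$tonicity, 1.25)
})
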