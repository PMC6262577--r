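test_that("noiseless Hill data are recovered exactly", {
  ph <- seq(5, 7.5, by = 0.25)
  p <- hill_ph(ph, pka = 6.0, n_hill = 1, p_max = 4.4e-4, p_min = 2e-5)
  fit <- fit_hill_ph(ph, p)
  expect_equal(fit$pka, 6.0, tolerance = 1e-6)
  expect_equal(fit$n_hill, 1, tolerance = 1e-6)
  expect_equal(fit$p_max, 4.4e-4, tolerance = 1e-6)
  # midpoint identity
  expect_equal(hill_ph(fit$pka, fit$pka, fit$n_hill, fit$p_max, fit$p_min),
               (fit$p_max + fit$p_min) / 2)
})

test_that("the Hill fit matches a dense grid-search oracle", {
  series <- generate_ph_series(
    list(pka = 5.88, n_hill = 1, p_max = 4.38e-4, p_min = 2e-5),
    ph_grid = seq(5, 7.5, by = 0.5),
    spec = generator_spec(seed = 21, noise_sd_frac = 0.05,
                          n_replicates = 4L))
  fit <- fit_hill_ph(series$ph, series$p)
  coarse <- hill_grid_oracle(series$ph, series$p,
                             pka_range = c(5.5, 6.3), n_range = c(0.5, 2),
                             pka_step = 0.005, n_step = 0.025)
  fine <- hill_grid_oracle(series$ph, series$p,
                           pka_range = coarse["pka"] + c(-0.01, 0.01),
                           n_range = coarse["n"] + c(-0.05, 0.05),
                           pka_step = 2e-4, n_step = 2e-3)
  expect_equal(fit$pka, unname(fine["pka"]), tolerance = 1e-3)
})

test_that("shifting the pH axis shifts pKa by exactly the shift", {
  series <- generate_ph_series(
    list(pka = 5.88, n_hill = 1, p_max = 4.38e-4, p_min = 2e-5),
    spec = generator_spec(seed = 5, noise_sd_frac = 0.05, n_replicates = 4L))
  f0 <- fit_hill_ph(series$ph, series$p)
  f1 <- fit_hill_ph(series$ph + 1, series$p)
  expect_equal(f1$pka - f0$pka, 1, tolerance = 1e-6)
  expect_equal(f1$n_hill, f0$n_hill, tolerance = 1e-6)
})

test_that("flat pH data are non-identifiable", {
  expect_error(fit_hill_ph(seq(5, 7.5, by = 0.5), rep(3e-4, 6)),
               "non-identifiable")
  expect_error(fit_hill_ph(c(5, 6), c(1e-4, 2e-4)), "4 distinct")
})

test_that("two-point Arrhenius data give the exact activation energy", {
  r_gas <- 1.9872e-3
  temps <- c(280, 310)
  p <- 1e-3 * exp(-10 / (r_gas * temps))
  fit <- fit_arrhenius(temps, p)
  expect_equal(fit$ea, 10, tolerance = 1e-9)
})

test_that("the Arrhenius slope matches closed-form OLS", {
  series <- generate_arrhenius_series(
    list(ea = 10.55, p_ref = 1.31e-5),
    spec = generator_spec(seed = 9, noise_sd_frac = 0.03, n_replicates = 3L))
  fit <- fit_arrhenius(series$temp_C + 273.15, series$p)
  x <- 1 / (series$temp_C + 273.15)
  y <- log(series$p)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$ea, -slope_hand * 1.9872e-3, tolerance = 1e-12)
})

test_that("Ea is invariant to rescaling all permeabilities", {
  temps <- c(280, 288, 296, 303, 311)
  p <- 2e-4 * exp(-9.16 / (1.9872e-3 * temps))
  f1 <- fit_arrhenius(temps, p)
  f2 <- fit_arrhenius(temps, 100 * p)
  expect_equal(f1$ea, f2$ea, tolerance = 1e-12)
  expect_equal(f2$ln_prefactor - f1$ln_prefactor, log(100), tolerance = 1e-9)
  expect_error(fit_arrhenius(temps, c(-1, p[-1])), "> 0")
})

test_that("noiseless dose-response data are recovered exactly", {
  doses <- c(0, 2, 5, 10, 20, 50, 100)
  p <- logistic_dose(doses, ic50 = 10, hill_slope = 1, p_top = 1.3e-5,
                     p_bottom = 1e-6)
  fit <- fit_dose_response(doses, p)
  expect_equal(fit$ic50, 10, tolerance = 1e-6)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-6)
  # the model midpoint identity holds for any fit
  expect_equal(logistic_dose(fit$ic50, fit$ic50, fit$hill_slope, fit$p_top,
                             fit$p_bottom),
               (fit$p_top + fit$p_bottom) / 2)
})

test_that("pinning the bottom plateau reduces to the simpler logistic", {
  doses <- c(0, 1, 3, 10, 30, 100)
  p <- logistic_dose(doses, ic50 = 12, hill_slope = 1, p_top = 1e-5,
                     p_bottom = 0)
  free <- fit_dose_response(doses, p)
  pinned <- fit_dose_response(doses, p, fix_bottom = 0)
  expect_equal(pinned$ic50, 12, tolerance = 1e-6)
  expect_equal(free$ic50, pinned$ic50, tolerance = 1e-4)
})

test_that("RME follows the background-corrected peak formula", {
  expect_equal(relative_membrane_expression(list(c(0, 100, 0)),
                                            list(c(0, 0, 0)))$rme, 1)
  res <- relative_membrane_expression(list(c(10, 200, 30)), list(rep(50, 3)))
  expect_equal(res$rme, 0.75)
  expect_error(relative_membrane_expression(list(c(-5, 0)), list(c(0, 0))),
               "degenerate")
  prof <- generate_line_profiles(peak = 180, background_level = 45,
                                 n_lines = 3)
  out <- relative_membrane_expression(prof$profiles, prof$backgrounds)
  expect_equal(out$rme, generator_truth(prof)$rme, tolerance = 1e-12)
  expect_equal(out$n_profiles, 3)
})
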