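test_that("dilution series reproduces the two-fold ladder with blank", {
  s <- dilution_series()
  expect_equal(s, c(8, 4, 2, 1, 0.5, 0.25, 0.125, 0))
  expect_equal(8 / 2^6, 0.125)
  expect_equal(dilution_series(include_blank = FALSE),
               c(8, 4, 2, 1, 0.5, 0.25, 0.125))
})

test_that("Stokes settling velocity and sedimentation mass balance", {
  sc <- culture_scenario("sedimentation", concentration = 8)
  expect_equal(stokes_velocity(sc), (2 / 9) * 100 * 9.81 * (2.5e-6)^2 / 1e-3)
  expect_equal(stokes_velocity(sc), 1.36e-6, tolerance = 0.01)

  t <- seq(0, 12, by = 0.1)
  tr <- sedimentation_trajectory(sc, t)
  expect_true(all(diff(tr$areal_biovolume) >= 0))
  # plateau equals concentration x column height / cell mass density
  expect_equal(max(tr$areal_biovolume),
               8 * sc$column_height / sc$cell$rho, tolerance = 1e-12)
  # plateau reached at about H / v_s (~1.1 h with defaults), within 2 h
  t_plateau <- sc$column_height / stokes_velocity(sc) / 3600
  expect_lt(t_plateau, 2)
  expect_equal(tr$areal_biovolume[t >= t_plateau][1], max(tr$areal_biovolume),
               tolerance = 1e-9)

  tr0 <- sedimentation_trajectory(
    culture_scenario("sedimentation", concentration = 0), t)
  expect_true(all(tr0$areal_biovolume == 0))
  expect_error(culture_scenario("sedimentation", concentration = 1,
                                column_height = 0),
               class = "configuration_error")
})

test_that("growth trajectory: lag, doubling algebra and nutrient-set plateau", {
  # exponential limit: one doubling exactly 90 min after the lag ends
  sc <- culture_scenario("proliferation", od_start = 0.2, glucose = Inf,
                         doubling_time = 90, lag = 5)
  tr <- growth_trajectory(sc, c(0, 5, 6.5, 8))
  od <- attr(tr, "od")
  expect_equal(od[1], 0.2)
  expect_equal(od[2], 0.2)           # still in lag
  expect_equal(od[3], 0.4)           # lag + 90 min
  expect_equal(od[4], 0.8)           # two doublings

  # plateau increment scales with glucose: 10.00 vs 0.16 g/L is x62.5
  t <- seq(0, 400, by = 1)
  hi <- attr(growth_trajectory(
    culture_scenario("proliferation", od_start = 0.2, glucose = 10), t), "od")
  lo <- attr(growth_trajectory(
    culture_scenario("proliferation", od_start = 0.2, glucose = 0.16), t), "od")
  expect_equal((max(hi) - 0.2) / (max(lo) - 0.2), 62.5, tolerance = 1e-6)
  expect_true(all(diff(hi) >= 0))

  # halving od_start delays a fixed pre-saturation threshold by one doubling
  t <- seq(0, 30, by = 0.005)
  odA <- attr(growth_trajectory(
    culture_scenario("proliferation", od_start = 0.4, glucose = Inf), t), "od")
  odB <- attr(growth_trajectory(
    culture_scenario("proliferation", od_start = 0.2, glucose = Inf), t), "od")
  thr <- 3
  delay <- t[which(odB >= thr)[1]] - t[which(odA >= thr)[1]]
  expect_equal(delay, 1.5, tolerance = 0.01)

  expect_error(culture_scenario("proliferation", od_start = 0.2, glucose = 10,
                                doubling_time = -1),
               class = "domain_error")
})

test_that("effective cell layer obeys the mixing bounds and thickness rule", {
  cell <- reference_material("yeast_cell", thickness = 1e-6, k = 0.40)
  med <- reference_material("water", semi_infinite = TRUE)

  expect_null(layer_from_biomass(0, 0.64, cell, med))

  full <- layer_from_biomass(1e-5, 1, cell, med)
  expect_equal(full$k, cell$k)
  expect_equal(full$thickness, 1e-5)

  half <- layer_from_biomass(1e-5, 0.5, cell, med)
  expect_equal(half$thickness, 2e-5)
  ser <- layer_from_biomass(1e-5, 0.5, cell, med, mixing = "series")
  par <- layer_from_biomass(1e-5, 0.5, cell, med, mixing = "parallel")
  # Maxwell-Eucken lies strictly between the series and parallel bounds
  expect_gt(half$k, ser$k)
  expect_lt(half$k, par$k)
  expect_gt(half$k, cell$k)
  expect_lt(half$k, med$k)

  expect_error(layer_from_biomass(1e-5, 0, cell, med),
               class = "configuration_error")
})

test_that("generated experiments follow the onset convention and are seed-reproducible", {
  sc <- culture_scenario("sedimentation", concentration = 0)
  pr <- pulse_protocol(total_duration = 610)
  e1 <- generate_experiment(sc, sensor_spec(), pr, seed = 4)
  expect_length(e1, 10)
  expect_equal(vapply(e1, `[[`, numeric(1), "onset"), seq(0, 549, by = 61))

  e2 <- generate_experiment(sc, sensor_spec(), pr, seed = 4)
  expect_identical(
    lapply(e1, `[[`, "voltage"),
    lapply(e2, `[[`, "voltage")
  )
  e3 <- generate_experiment(sc, sensor_spec(), pr, seed = 5)
  expect_false(identical(e1[[1]]$voltage, e3[[1]]$voltage))

  # static water control: percent change stays at noise level
  ser <- slope_series(e1)
  expect_lt(max(abs(ser$pct_change)), 3)
  expect_equal(ser$pct_change[1], 0)
})

test_that("endpoint percent change increases with concentration across the upper dilutions", {
  # noisy generation, one seed; upper dilutions where the separation is well
  # above the first-pulse normalization noise
  pr <- pulse_protocol(total_duration = 1.5 * 3600)
  ends <- vapply(c(1, 2, 4, 8), function(conc) {
    e <- generate_experiment(
      culture_scenario("sedimentation", concentration = conc),
      sensor_spec(), pr, seed = 21)
    mean(tail(slope_series(e)$pct_change, 10))
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
})

test_that("calibration-mode endpoints are drawn from the ground-truth line", {
  pts <- calibration_endpoints(dilution_series(), replicates = 200,
                               noise_sd = 0.25, seed = 2)
  expect_equal(nrow(pts), 8 * 200)
  by_conc <- tapply(pts$endpoint_pct, pts$concentration, mean)
  conc <- as.numeric(names(by_conc))
  # 200 replicates at sd 0.25 -> standard error ~0.018 per mean
  expect_lt(max(abs(unname(by_conc) - (0.7806 * conc - 0.2194))), 0.06)
  pts0 <- calibration_endpoints(c(0, 8), replicates = 1, noise_sd = 0, seed = 1)
  expect_equal(pts0$endpoint_pct, c(-0.2194, 6.0254))
})
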