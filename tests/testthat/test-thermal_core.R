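test_that("effusivity is sqrt(k rho cp) and rejects invalid materials", {
  water <- material_layer("water", 0.60, 998, 4182, semi_infinite = TRUE)
  expect_equal(effusivity(water), sqrt(0.60 * 998 * 4182))
  expect_equal(effusivity(water), 1582.5, tolerance = 1e-3)

  poly <- reference_material("polyimide", thickness = 40e-6)
  expect_equal(effusivity(poly), 431, tolerance = 1e-3)

  # e -> 0 as k -> 0
  ks <- 10^seq(-1, -6, by = -1)
  es <- vapply(ks, function(k)
    effusivity(material_layer("x", k, 998, 4182, 1e-3)), numeric(1))
  expect_true(all(diff(es) < 0))
  # e scales as sqrt(k)
  expect_equal(es[length(es)] / es[1], sqrt(1e-6 / 1e-1), tolerance = 1e-9)

  expect_error(material_layer("bad", -1, 998, 4182, 1e-3),
               class = "invalid_material")
  expect_error(effusivity(list(k = 0, rho = 998, cp = 4182)),
               class = "invalid_material")
})

test_that("probing depth follows the 2*sqrt(a t) convention", {
  a <- 7.75e-8  # polyimide k/(rho cp)
  # inverting depth = 40 um gives t ~ 5.2 ms
  t40 <- (40e-6 / 2)^2 / a
  expect_equal(probing_depth(a, t40), 40e-6, tolerance = 1e-12)
  expect_equal(t40, 5.2e-3, tolerance = 0.01)

  expect_identical(probing_depth(a, 0), 0)
  # quadrupling t doubles the depth
  t <- c(0.01, 0.04, 0.16)
  d <- probing_depth(a, t)
  expect_equal(d[2] / d[1], 2, tolerance = 1e-12)
  expect_equal(d[3] / d[2], 2, tolerance = 1e-12)
  expect_error(probing_depth(a, -1), class = "domain_error")
})

test_that("closed-form semi-infinite response is linear in sqrt(t) with slope 2q/(e sqrt(pi))", {
  e <- 1582.5
  q <- 0.5 / 81e-6
  t <- seq(0.002, 1, by = 0.002)
  dT <- analytic_semiinfinite(e, q, t)
  fit <- sqrt_time_regression(t, dT, regression_window())
  expect_equal(fit$slope, 2 * q / (e * sqrt(pi)), tolerance = 1e-12)
  expect_equal(fit$slope, 4.40, tolerance = 1e-3)
  expect_equal(fit$r2, 1)
  expect_identical(analytic_semiinfinite(e, q, 0), 0)
  # doubling e halves dT everywhere
  expect_equal(analytic_semiinfinite(2 * e, q, t), dT / 2, tolerance = 1e-12)
})

test_that("finite-difference solver matches the semi-infinite oracle within 2%", {
  water <- reference_material("water", semi_infinite = TRUE)
  st <- layer_stack(above = list(water), below = list(water),
                    heater_areal_heat_capacity = 0, heater_area = 81e-6,
                    below_boundary = "semi_infinite")
  cv <- simulate_step_response(st, power = 0.5, duration = 1, sample_rate = 500)
  # symmetric stack: each half-space receives half the flux
  q_half <- 0.5 / 81e-6 / 2
  keep <- cv$t >= 0.0256 & cv$t <= 0.3136
  expected <- analytic_semiinfinite(effusivity(water), q_half, cv$t[keep])
  expect_lt(max(abs(cv$dT[keep] / expected - 1)), 0.02)
  slope_fd <- sqrt_time_regression(cv$t, cv$dT)$slope
  slope_th <- 2 * q_half / (effusivity(water) * sqrt(pi))
  expect_lt(abs(slope_fd / slope_th - 1), 0.02)
})

test_that("solver conserves energy and returns zero response to zero power", {
  st <- default_sensor_stack()
  cv <- simulate_step_response(st, power = 0.5, duration = 0.5)
  expect_lt(abs(attr(cv, "energy_balance")), 1e-10)
  expect_true(all(cv$dT >= 0))
  expect_true(all(diff(cv$dT) > 0))  # monotone heating under constant power

  cv0 <- simulate_step_response(st, power = 0, duration = 0.1)
  expect_true(all(cv0$dT == 0))
})

test_that("an insulating interlayer steepens the sqrt(t)-window slope", {
  st0 <- default_sensor_stack()
  film <- material_layer("film", k = 0.4, rho = 1100, cp = 3500,
                         thickness = 20e-6)
  st1 <- default_sensor_stack(cell_layer = film)
  s0 <- sqrt_time_regression(
    simulate_step_response(st0, 0.5, 1)$t,
    simulate_step_response(st0, 0.5, 1)$dT)$slope
  cv1 <- simulate_step_response(st1, 0.5, 1)
  s1 <- sqrt_time_regression(cv1$t, cv1$dT)$slope
  expect_gt(s1, s0)
})

test_that("window slope is monotone in layer thickness and conductivity", {
  slope_of <- function(thick_um, k = 0.45) {
    lay <- if (thick_um > 0)
      material_layer("cells", k, 1100, 3500, thickness = thick_um * 1e-6)
    cv <- simulate_step_response(default_sensor_stack(cell_layer = lay), 0.5, 1)
    sqrt_time_regression(cv$t, cv$dT)$slope
  }
  s_thick <- vapply(c(0, 10, 30, 60), slope_of, numeric(1))
  expect_true(all(diff(s_thick) > 0))
  s_k <- vapply(c(0.35, 0.45, 0.55), function(k) slope_of(30, k), numeric(1))
  expect_true(all(diff(s_k) < 0))
})

test_that("window slope is approximately affine in thickness over the working band", {
  # response to a thin film is convex at small thickness (film diffusion
  # time ~ d^2/a); over 40-100 um it is affine within 5% of the secant
  slope_of <- function(thick_um) {
    lay <- material_layer("cells", 0.50, 1063, 3746, thickness = thick_um * 1e-6)
    cv <- simulate_step_response(default_sensor_stack(cell_layer = lay), 0.5, 1)
    sqrt_time_regression(cv$t, cv$dT)$slope
  }
  th <- c(40, 55, 70, 85, 100)
  s <- vapply(th, slope_of, numeric(1))
  sec <- s[1] + (s[length(s)] - s[1]) * (th - th[1]) / (th[length(th)] - th[1])
  expect_lt(max(abs(s / sec - 1)), 0.05)
})

test_that("halving the grid steps changes the window slope by < 0.5%", {
  lay <- material_layer("cells", 0.5, 1100, 3500, thickness = 30e-6)
  st <- default_sensor_stack(cell_layer = lay)
  s1 <- sqrt_time_regression(
    simulate_step_response(st, 0.5, 1)$t,
    simulate_step_response(st, 0.5, 1)$dT)$slope
  fine <- grid_opts(film_dx = 5e-7, first_dx = 1e-6, substeps = 8L,
                    first_substeps = 64L)
  cvf <- simulate_step_response(st, 0.5, 1, opts = fine)
  s2 <- sqrt_time_regression(cvf$t, cvf$dT)$slope
  expect_lt(abs(s2 / s1 - 1), 0.005)
})

test_that("stack validity and solver configuration errors are raised", {
  water <- reference_material("water", semi_infinite = TRUE)
  poly <- reference_material("polyimide", thickness = 40e-6)
  expect_error(layer_stack(above = list(poly)), class = "invalid_stack")
  expect_error(layer_stack(above = list(water, poly)), class = "invalid_stack")
  expect_error(layer_stack(above = list(water), below = list(water)),
               class = "invalid_stack")
  st <- default_sensor_stack()
  expect_error(simulate_step_response(st, -1, 1), class = "configuration_error")
  expect_error(simulate_step_response(st, 0.5, 1,
                                      opts = grid_opts(domain_depth = 1e-4)),
               class = "configuration_error")
})
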