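test_that("calibration fit recovers an exact line and inverts it", {
  conc <- dilution_series()
  pct <- 0.7806 * conc - 0.2194
  fit <- fit_calibration(conc, pct)
  expect_equal(fit$slope, 0.7806, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.2194, tolerance = 1e-9)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)

  expect_equal(0.7806 * 8 - 0.2194, 6.0254)
  pred <- predict_concentration(fit, 6.0254)
  expect_equal(pred$concentration, 8, tolerance = 1e-9)
  expect_equal(predict_concentration(fit, -0.2194)$concentration, 0,
               tolerance = 1e-9)

  # round trip: predict then evaluate forward
  y <- 3.3
  x <- predict_concentration(fit, y)$concentration
  expect_equal(fit$slope * x + fit$intercept, y, tolerance = 1e-12)

  expect_error(fit_calibration(rep(2, 5), rnorm(5)), class = "fit_error")
})

test_that("calibration recovery from noisy endpoints is within 3 standard errors", {
  # seeded Monte-Carlo over several replicate draws
  for (s in c(7, 17, 27)) {
    pts <- calibration_endpoints(dilution_series(), replicates = 4,
                                 noise_sd = 0.25, seed = s)
    fit <- fit_calibration(pts$concentration, pts$endpoint_pct)
    expect_lt(abs(fit$slope - 0.7806), 3 * fit$slope_se)
    expect_equal(fit$inverse_prediction_sd, fit$residual_sd / abs(fit$slope))
  }
})

test_that("growth fit recovers an exact logistic and flags flat series", {
  t <- seq(0, 18, by = 301 / 3600)
  y <- 5 / (1 + exp(-(log(2) / 1.5) * (t - 10)))
  fit <- fit_growth(data.frame(t_h = t, pct_change = y))
  expect_true(fit$converged)
  expect_equal(fit$doubling_time, 90, tolerance = 1e-6)
  expect_equal(fit$rate * fit$doubling_time / 60, log(2), tolerance = 1e-9)

  # lag-floored input: floor recovered along with the rate
  yf <- 5 / (1 + exp(-(log(2) / 1.5) * (pmax(t, 5) - 10)))
  fitf <- fit_growth(data.frame(t_h = t, pct_change = yf))
  expect_equal(fitf$doubling_time, 90, tolerance = 1e-4)
  expect_equal(fitf$lag_estimate, 5, tolerance = 0.05)

  flat <- data.frame(t_h = t, pct_change = rnorm(length(t), 0, 0.1))
  ff <- fit_growth(flat)
  expect_false(ff$converged)
  expect_true(is.na(ff$doubling_time))
})

test_that("growth fit recovers the generator's own trajectory family exactly", {
  sc <- culture_scenario("proliferation", od_start = 0.2, glucose = 10)
  t <- seq(0, 18, by = 301 / 3600)
  od <- attr(growth_trajectory(sc, t), "od")
  fit <- fit_growth(data.frame(t_h = t, pct_change = 2 * (od - od[1])))
  expect_equal(fit$doubling_time, 90, tolerance = 0.01)
  expect_equal(fit$lag_estimate, 5, tolerance = 0.1)
})

test_that("end-to-end doubling-time recovery lands in the model's accuracy band", {
  # the thermal rendering is mildly convex in layer thickness, which inflates
  # the apparent rate by ~10% on top of noise scatter; the estimate must stay
  # within 25% of truth and below it only moderately
  tds <- vapply(c(3, 5), function(s) {
    fit <- fit_growth(slope_series(fx_proliferation(seed = s)))
    expect_true(fit$converged)
    fit$doubling_time
  }, numeric(1))
  expect_true(all(abs(tds / 90 - 1) < 0.25))
})

test_that("composing the fit with the sensor response removes the rendering bias", {
  resp <- fx_response()
  # response curve: monotone, convex at the low end, bare sensor at ratio 1
  expect_equal(resp$curve$ratio[1], 1)
  expect_true(all(diff(resp$curve$ratio) > 0))
  # convex at the low end: per-micrometre gain grows from the first
  # segment into the mid band (it flattens again at very thick layers)
  gain <- diff(resp$curve$ratio) / diff(resp$curve$thickness)
  mid <- which.min(abs(resp$curve$thickness - 60e-6))
  expect_gt(gain[mid] / gain[1], 1.2)

  sc <- culture_scenario("proliferation", od_start = 0.2, glucose = 10)
  th0 <- sc$od_start * sc$od_to_biovolume / sc$packing_fraction
  ser <- slope_series(fx_proliferation(seed = 13, noise_sd = 0))

  plain <- fit_growth(ser)
  anchored <- fit_growth(ser, response = resp, th0 = th0)
  free <- fit_growth(ser, response = resp)
  # the proportionality assumption inflates the apparent rate...
  expect_lt(plain$doubling_time, 85)
  # ...the composed fits recover the ground truth
  expect_equal(anchored$doubling_time, 90, tolerance = 0.01)
  expect_equal(free$doubling_time, 90, tolerance = 0.01)
  expect_equal(anchored$lag_estimate, 5, tolerance = 0.05)
  expect_equal(anchored$th0 + anchored$dth,
               (sc$od_start + sc$yield * sc$glucose) * sc$od_to_biovolume /
                 sc$packing_fraction,
               tolerance = 0.05)
})

test_that("doubling the inoculum advances the fitted midpoint by about one doubling time", {
  f1 <- fit_growth(slope_series(fx_proliferation(seed = 13, noise_sd = 0,
                                                 od_start = 0.2)))
  f2 <- fit_growth(slope_series(fx_proliferation(seed = 13, noise_sd = 0,
                                                 od_start = 0.4)))
  shift_h <- f1$t_mid - f2$t_mid
  expect_equal(shift_h, 1.5, tolerance = 0.25)
  # equal nutrients: amplitudes within 5%
  expect_lt(abs(f1$amplitude / f2$amplitude - 1), 0.05)
})

test_that("phase segmentation finds lag, exponential window and stationary phase", {
  set.seed(99)
  t <- seq(0, 18, by = 301 / 3600)
  y <- 6 / (1 + exp(-1.2 * (pmax(t, 5) - 9))) + rnorm(length(t), 0, 0.1)
  ser <- structure(data.frame(pulse_index = seq_along(t) - 1L, t_h = t,
                              slope = 1, intercept = 0, r2 = 1, pct_change = y),
                   class = c("slope_series", "data.frame"))
  seg <- phase_segmentation(ser)
  expect_true(seg$has_growth)
  expect_true(seg$has_stationary)
  # first persistent rise above baseline + 3 sd lands just after the lag
  expect_gt(seg$lag_end, 4.9)
  expect_lt(seg$lag_end, 7.5)
  expect_gt(seg$stationary_start, seg$lag_end)
  expect_lt(seg$stationary_start, max(t))
  expect_equal(seg$exp_window, c(seg$lag_end, seg$stationary_start))

  flat <- ser; flat$pct_change <- rnorm(length(t), 0, 0.1)
  segf <- phase_segmentation(flat)
  expect_false(segf$has_growth)
  expect_true(is.na(segf$lag_end))
})
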