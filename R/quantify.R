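#' Fit the endpoint-versus-concentration calibration line
#'
#' Ordinary least squares of endpoint percent change on suspension
#' concentration (linear abscissa, mg/mL). The inverse-prediction
#' uncertainty is reported by the delta-method convention
#' `residual_sd / |slope|`, in mg/mL.
#'
#' @param concentration Concentrations, mg/mL.
#' @param endpoint_pct Endpoint percent-change values.
#' @return An object of class `calibration_fit`: `slope` (% per mg/mL),
#'   `intercept` (%), `residual_sd` (%), `inverse_prediction_sd` (mg/mL),
#'   `slope_se`, `n_points`, and the underlying `lm` fit.
#' @examples
#' pts <- calibration_endpoints(dilution_series(), seed = 7)
#' fit_calibration(pts$concentration, pts$endpoint_pct)
#' @export
fit_calibration <- function(concentration, endpoint_pct) {
  if (length(concentration) != length(endpoint_pct)) {
    stop_tp("concentration and endpoint_pct must have equal length", "fit_error")
  }
  if (length(unique(concentration)) < 2) {
    stop_tp("need >= 2 distinct concentrations to fit a line", "fit_error")
  }
  fit <- lm(endpoint_pct ~ concentration)
  cf <- coef(fit)
  # suppressed: R warns on an (legitimate) exactly collinear perfect fit
  s <- suppressWarnings(summary(fit))
  residual_sd <- s$sigma
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 residual_sd = residual_sd,
                 inverse_prediction_sd = residual_sd / abs(unname(cf[2])),
                 slope_se = unname(s$coefficients[2, 2]),
                 n_points = length(concentration), lm = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> pct = %.4f * conc %+.4f  (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("  residual sd %.3g %%, inverse-prediction sd %.3g mg/mL\n",
              x$residual_sd, x$inverse_prediction_sd))
  invisible(x)
}

#' Predict a concentration from an endpoint percent change
#'
#' Inverse prediction through the calibration line:
#' `conc = (pct - intercept) / slope`, with the fit's delta-method
#' uncertainty attached.
#'
#' @param fit A [fit_calibration()] result.
#' @param endpoint_pct Observed endpoint percent change (vectorised).
#' @return data.frame with `concentration` (mg/mL) and `sd` (mg/mL).
#' @export
predict_concentration <- function(fit, endpoint_pct) {
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop_tp("calibration slope is zero; concentration not identifiable",
            "non_identifiable")
  }
  data.frame(concentration = (endpoint_pct - fit$intercept) / fit$slope,
             sd = fit$inverse_prediction_sd)
}

# logistic in time, optionally floored at a lag time: before t_lag the curve
# holds the value the logistic takes at t_lag (cells adapting, no net growth)
logistic4 <- function(t, baseline, amplitude, t_mid, rate, t_lag = -Inf) {
  te <- pmax(t, t_lag)
  baseline + amplitude / (1 + exp(-rate * (te - t_mid)))
}

#' Fit a logistic growth curve to a percent-change slope series
#'
#' Proliferation runs show lag, exponential and stationary phases; the
#' percent change in slope is treated as proportional to the areal biomass
#' (approximately valid while the cell layer stays within the solver's
#' affine response band), and a lag-floored logistic
#' `pct(t) = baseline + amplitude / (1 + exp(-rate * (max(t, t_lag) -
#' t_mid)))` is fitted by bounded Levenberg-Marquardt least squares from a
#' small multi-start grid. The floor at `t_lag` matches the lag phase, where
#' the population holds its inoculum level before exponential growth; a
#' plain 4-parameter logistic (no floor) systematically overestimates the
#' rate on such series because its left tail cannot stay flat. The
#' exponential-phase doubling time follows from the rate as
#' `60 * ln(2) / rate` minutes, and `lag_estimate` is the fitted floor time.
#'
#' Treating percent change as proportional to biomass is exact only where
#' the sensor's slope-versus-thickness response is affine; at small layer
#' thickness the response is convex, which inflates the apparent rate.
#' Passing a [slope_response()] as `response` removes this bias: the fit
#' then composes the logistic biomass model with the tabulated response,
#' `pct(t) = 100 * (R(th(t)) / R(th(0)) - 1)` with
#' `th(t) = th0 + dth / (1 + exp(-rate * (max(t, t_lag) - t_mid)))`,
#' and estimates the layer thicknesses alongside the kinetics.
#'
#' @param series A `slope_series` (or data.frame with `t_h`, `pct_change`).
#' @param floor_lag Fit the lag floor (default). `FALSE` fits the plain
#'   4-parameter logistic.
#' @param response Optional [slope_response()] for the physics-informed
#'   (response-composed) fit.
#' @param th0 Optional known baseline layer thickness, m, for the
#'   response-composed fit (the inoculum's settled layer is experiment
#'   metadata); `NULL` estimates it from the series, at the cost of a
#'   noticeably wider rate uncertainty.
#' @return An object of class `growth_fit`: `baseline`, `amplitude` (%),
#'   `t_mid` (h), `rate` (h^-1), `doubling_time` (min), `lag_estimate` (h),
#'   `residual_sd`, `converged`. A flat series returns `converged = FALSE`
#'   with `NA` parameters rather than an error. Response-composed fits also
#'   carry `th0` and `dth` (baseline layer thickness and its increment, m).
#' @export
fit_growth <- function(series, floor_lag = TRUE, response = NULL, th0 = NULL) {
  if (!is.null(response)) {
    return(fit_growth_response(series, response, th0_fixed = th0))
  }
  t <- series$t_h
  y <- series$pct_change
  if (length(t) < 5) stop_tp("need >= 5 slope datapoints", "fit_error")

  not_converged <- function() {
    structure(list(baseline = NA_real_, amplitude = NA_real_, t_mid = NA_real_,
                   rate = NA_real_, doubling_time = NA_real_,
                   lag_estimate = NA_real_, residual_sd = sd(y),
                   converged = FALSE),
              class = "growth_fit")
  }

  # initialize from a running-median smooth so single noisy pulses cannot
  # misplace the half-range crossing
  ys <- if (length(y) >= 9) stats::runmed(y, 9) else y
  nb <- max(3L, ceiling(0.1 * length(y)))
  base0 <- median(ys[seq_len(nb)])
  rng <- max(ys) - base0
  noise0 <- sd(head(y, nb))
  if (!is.finite(rng) || rng <= 4 * max(noise0, .Machine$double.eps)) {
    return(not_converged())  # flat series: no rise to fit
  }
  half <- base0 + rng / 2
  i <- which(ys >= half)[1]
  t_mid0 <- t[i]
  # secant rate around the half-crossing
  rate0 <- if (i > 1 && t[i] > t[i - 1]) {
    dydt <- (ys[i] - ys[i - 1]) / (t[i] - t[i - 1])
    max(4 * dydt / rng, 0.05)
  } else 0.5
  lag0 <- t[which(ys > base0 + 0.05 * rng)[1]] %||% min(t)

  one_fit <- function(start) {
    tryCatch({
      fit <- if (floor_lag) {
        minpack.lm::nlsLM(
          y ~ logistic4(t, baseline, amplitude, t_mid, rate, t_lag),
          start = start,
          lower = c(baseline = -Inf, amplitude = 0, t_mid = min(t),
                    rate = 1e-3, t_lag = min(t)),
          upper = c(baseline = Inf, amplitude = Inf, t_mid = max(t) * 2,
                    rate = 100, t_lag = max(t)),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          y ~ logistic4(t, baseline, amplitude, t_mid, rate),
          start = start[c("baseline", "amplitude", "t_mid", "rate")],
          lower = c(baseline = -Inf, amplitude = 0, t_mid = min(t), rate = 1e-3),
          upper = c(baseline = Inf, amplitude = Inf, t_mid = max(t) * 2, rate = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
      list(fit = fit, sse = sum(residuals(fit)^2))
    }, error = function(e) NULL)
  }
  # small deterministic multi-start: rate and lag are the parameters whose
  # basins matter
  starts <- list()
  for (rf in c(0.5, 1, 2)) for (lf in unique(c(lag0, min(t)))) {
    starts[[length(starts) + 1L]] <-
      list(baseline = base0, amplitude = rng, t_mid = t_mid0,
           rate = rate0 * rf, t_lag = lf)
  }
  fits <- Filter(Negate(is.null), lapply(starts, one_fit))
  if (length(fits) == 0) return(not_converged())
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]$fit
  p <- as.list(coef(best))
  structure(list(baseline = p$baseline, amplitude = p$amplitude,
                 t_mid = p$t_mid, rate = p$rate,
                 doubling_time = 60 * log(2) / p$rate,
                 lag_estimate = if (floor_lag) p$t_lag else
                   p$t_mid - log(19) / p$rate,
                 residual_sd = sd(residuals(best)), converged = TRUE),
            class = "growth_fit")
}

# Physics-informed growth fit: logistic layer growth composed with the
# sensor's slope-vs-thickness response curve. A free additive offset absorbs
# the noise of the first-pulse normalization (the whole percent-change
# series shares the baseline pulse's noise draw as a common shift); without
# it that correlated offset leaks into the kinetic parameters.
# When the inoculum layer thickness th0 is known, the logistic is anchored
# through it (the population equals the inoculum when the lag ends), which
# removes the midpoint as a free parameter.
fit_growth_response <- function(series, response, th0_fixed = NULL) {
  t <- series$t_h
  y <- series$pct_change
  if (length(t) < 6) stop_tp("need >= 6 slope datapoints", "fit_error")
  th_max <- max(response$curve$thickness)
  R <- response$ratio_fun
  fixed <- !is.null(th0_fixed)

  not_conv <- function() structure(
    list(baseline = NA_real_, amplitude = NA_real_, t_mid = NA_real_,
         rate = NA_real_, doubling_time = NA_real_, lag_estimate = NA_real_,
         th0 = NA_real_, dth = NA_real_, residual_sd = sd(y),
         converged = FALSE),
    class = "growth_fit")

  # anchored family: th(t) = THK / (1 + exp(-r (max(t, lag) - t_mid))) with
  # t_mid tied by th(lag) = th0
  model_anchored <- function(t, THK, r, lag, c0) {
    t_mid <- lag + log(pmax(THK / th0_fixed - 1, 1e-9)) / r
    th <- pmin(THK / (1 + exp(-r * (pmax(t, lag) - t_mid))), th_max)
    c0 + 100 * (R(th) / R(th0_fixed) - 1)
  }
  # free family: baseline thickness and increment both estimated
  model_free <- function(t, th0, dth, t_mid, rate, t_lag, c0) {
    th <- pmin(th0 + dth / (1 + exp(-rate * (pmax(t, t_lag) - t_mid))), th_max)
    c0 + 100 * (R(th) / R(th0) - 1)
  }

  ys <- if (length(y) >= 9) stats::runmed(y, 9) else y
  nb <- max(3L, ceiling(0.1 * length(y)))
  base0 <- median(ys[seq_len(nb)])
  rng <- max(ys) - base0
  noise0 <- sd(head(y, nb))
  if (!is.finite(rng) || rng <= 4 * max(noise0, .Machine$double.eps)) {
    return(not_conv())
  }
  i <- which(ys >= base0 + rng / 2)[1]
  t_mid0 <- t[i]
  lag0 <- t[which(ys > base0 + 0.05 * rng)[1]] %||% min(t)
  th_end0 <- response$thickness_fun(
    min(max(1 + rng / 100, 1), max(response$curve$ratio)))

  one_fit <- function(r0, l0) {
    tryCatch({
      fit <- if (fixed) {
        minpack.lm::nlsLM(
          y ~ model_anchored(t, THK, r, lag, c0),
          start = list(THK = max(th_end0, 2.5 * th0_fixed), r = r0,
                       lag = l0, c0 = 0),
          lower = c(THK = 1.1 * th0_fixed, r = 1e-3, lag = min(t), c0 = -Inf),
          upper = c(THK = th_max, r = 100, lag = max(t), c0 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          y ~ model_free(t, th0, dth, t_mid, rate, t_lag, c0),
          start = list(th0 = 5e-6, dth = max(th_end0 - 5e-6, 1e-6),
                       t_mid = t_mid0, rate = r0, t_lag = l0, c0 = 0),
          lower = c(th0 = 0, dth = 1e-7, t_mid = min(t), rate = 1e-3,
                    t_lag = min(t), c0 = -Inf),
          upper = c(th0 = 0.5 * th_max, dth = th_max, t_mid = 2 * max(t),
                    rate = 100, t_lag = max(t), c0 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
      list(fit = fit, sse = sum(residuals(fit)^2))
    }, error = function(e) NULL)
  }

  lag_grid <- unique(c(lag0, min(t) + c(0.15, 0.35) * diff(range(t))))
  fits <- list()
  for (r0 in c(0.25, 0.5, 1)) for (l0 in lag_grid) {
    fits[[length(fits) + 1L]] <- one_fit(r0, l0)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(not_conv())
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  p <- as.list(coef(best$fit))
  if (fixed) {
    p$th0 <- th0_fixed
    p$dth <- p$THK - th0_fixed
    p$rate <- p$r
    p$t_lag <- p$lag
    p$t_mid <- p$lag + log(max(p$THK / th0_fixed - 1, 1e-9)) / p$r
  }
  structure(list(baseline = p$c0,
                 amplitude = 100 * (R(pmin(p$th0 + p$dth, th_max)) / R(p$th0) - 1),
                 t_mid = p$t_mid, rate = p$rate,
                 doubling_time = 60 * log(2) / p$rate,
                 lag_estimate = p$t_lag, th0 = p$th0, dth = p$dth,
                 residual_sd = sd(residuals(best$fit)), converged = TRUE),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<growth_fit> not converged (flat or unfit series)\n")
    return(invisible(x))
  }
  cat(sprintf("<growth_fit> amplitude %.3g %%, t_mid %.3g h, rate %.3g 1/h\n",
              x$amplitude, x$t_mid, x$rate))
  cat(sprintf("  doubling time %.1f min, lag estimate %.2f h, residual sd %.3g %%\n",
              x$doubling_time, x$lag_estimate, x$residual_sd))
  invisible(x)
}

#' Segment a proliferation series into lag, exponential and stationary phases
#'
#' Heuristic segmentation on the percent-change series: the baseline level
#' and noise are estimated from the earliest pulses; the lag ends at the
#' first time the series exceeds `baseline + 3 * noise_sd` (and stays up),
#' and the stationary phase starts at [plateau_time()]. The exponential
#' window lies between the two. Phases that are absent are flagged rather
#' than raising an error.
#'
#' @param series A `slope_series`.
#' @param baseline_fraction Early fraction of the series used for the
#'   baseline level and noise estimate.
#' @param plateau_tolerance Tolerance handed to [plateau_time()], percentage
#'   points; defaults to `3 * noise_sd`.
#' @return List with `lag_end` (h or `NA`), `exp_window` (length-2 vector or
#'   `NA`), `stationary_start` (h or `NA`), and logical flags
#'   `has_growth`, `has_stationary`.
#' @export
phase_segmentation <- function(series, baseline_fraction = 0.1,
                               plateau_tolerance = NULL) {
  n <- nrow(series)
  nb <- max(3L, ceiling(baseline_fraction * n))
  base_level <- median(series$pct_change[seq_len(nb)])
  base_sd <- max(sd(series$pct_change[seq_len(nb)]), 1e-12)
  thresh <- base_level + 3 * base_sd

  above <- series$pct_change > thresh
  # require the exceedance to persist (not a lone noise spike)
  persist <- above & c(above[-1], TRUE)
  lag_end <- if (any(persist)) series$t_h[which(persist)[1]] else NA_real_
  has_growth <- !is.na(lag_end)

  stationary_start <- NA_real_
  if (has_growth) {
    tol <- plateau_tolerance %||% (3 * base_sd)
    stationary_start <- suppressWarnings(plateau_time(series, tolerance_pct = tol))
    if (!is.na(stationary_start) && stationary_start <= lag_end) {
      stationary_start <- NA_real_
    }
  }
  list(lag_end = lag_end,
       exp_window = if (has_growth && !is.na(stationary_start))
         c(lag_end, stationary_start) else NA,
       stationary_start = stationary_start,
       has_growth = has_growth,
       has_stationary = has_growth && !is.na(stationary_start))
}
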