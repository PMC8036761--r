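#' Regression window in sqrt-time
#'
#' The read-out statistic is the slope of the transient against `sqrt(t)`
#' inside a fixed early window. The defaults, 0.16 to 0.56 s^1/2 (25.6 ms to
#' 313.6 ms), start once the pulse has penetrated the 40 um substrate and end
#' before the far field dominates; membership is a closed interval on sample
#' timestamps, so at 500 Hz (samples at 2 ms, 4 ms, ...) 144 samples fall
#' inside.
#'
#' @param start_sqrt,end_sqrt Window bounds in sqrt-seconds.
#' @return An object of class `regression_window`.
#' @examples
#' regression_window()            # [0.16, 0.56] s^1/2
#' sqrt(c(0.0256, 0.3136))        # the same bounds, from the pulse times
#' @export
regression_window <- function(start_sqrt = 0.16, end_sqrt = 0.56) {
  if (!(start_sqrt > 0 && end_sqrt > start_sqrt)) {
    stop_tp("need 0 < start_sqrt < end_sqrt", "window_error")
  }
  structure(list(start_sqrt = start_sqrt, end_sqrt = end_sqrt),
            class = "regression_window")
}

#' Convert a raw voltage pulse record to a temperature transient
#'
#' 4-wire inversion: `R(t) = V(t) / I`, then the resistance-thermometry
#' relation gives `dT(t) = (R(t)/r_ref - 1) / alpha`. Exact inverse of the
#' synthesis model in the noiseless case.
#'
#' @param record A [pulse_record()].
#' @param spec The [sensor_spec] the record was measured with.
#' @return A `transient_curve` (data.frame `t`, `dT`).
#' @export
voltage_to_temperature <- function(record, spec) {
  if (is.null(record$current) || !is.finite(record$current) || record$current <= 0) {
    stop_tp("pulse record needs a positive drive current", "invalid_record")
  }
  r <- record$voltage / record$current
  dT <- (r / spec$r_ref - 1) / spec$alpha
  structure(data.frame(t = record$t_rel, dT = dT),
            class = c("transient_curve", "data.frame"))
}

#' Ordinary least squares of a transient against sqrt(time)
#'
#' Regresses the signal (temperature or voltage) on `sqrt(t)` over the
#' samples whose `sqrt(t)` falls inside the closed window. Sample timestamps
#' exactly on a bound are included (up to floating-point tolerance).
#'
#' @param t Sample times, s.
#' @param y Signal at those times (K or V).
#' @param window A [regression_window()].
#' @return List with `slope` (per sqrt-second), `intercept`, `r2` and `n`
#'   (in-window sample count). A perfectly fit (including constant) signal
#'   has `r2 = 1`.
#' @export
sqrt_time_regression <- function(t, y, window = regression_window()) {
  st <- sqrt(t)
  eps <- 1e-12
  keep <- st >= window$start_sqrt - eps & st <= window$end_sqrt + eps
  n <- sum(keep)
  if (n < 3) {
    stop_tp(sprintf("only %d samples inside the sqrt-time window [%g, %g]; need >= 3",
                    n, window$start_sqrt, window$end_sqrt), "window_error")
  }
  x <- st[keep]; yy <- y[keep]
  xm <- mean(x); ym <- mean(yy)
  sxx <- sum((x - xm)^2)
  sxy <- sum((x - xm) * (yy - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  ss_tot <- sum((yy - ym)^2)
  ss_res <- sum((yy - intercept - slope * x)^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else
    as.numeric(ss_res <= eps)
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}

#' Per-pulse slope series with percent change against the first pulse
#'
#' Runs the sqrt-time regression on every pulse of an experiment and
#' normalizes the slopes to the first pulse:
#' `pct_change_i = 100 * (slope_i - slope_0) / slope_0`. The first entry is
#' exactly zero. Normalizing to the sensor's own first pulse cancels
#' unit-to-unit differences in the cold resistance, so series from sensors
#' with different `r_ref` are directly comparable.
#'
#' @param records A `pulse_experiment` or list of [pulse_record()]s.
#' @param spec The [sensor_spec] (needed for `domain = "temperature"`; for an
#'   experiment generated by [generate_experiment()] it defaults to the one
#'   stored in the object).
#' @param window A [regression_window()].
#' @param domain Regress on `"temperature"` transients (default; physically
#'   interpretable slope units K s^-1/2) or raw `"voltage"` (V s^-1/2). The
#'   two give identical percent-change series because the voltage is an
#'   affine function of the temperature rise.
#' @param baseline `"first"` (the first pulse, the default) or `"mean:k"`
#'   (mean slope of the first k pulses, for noise robustness).
#' @return A `slope_series` data.frame: `pulse_index`, `t_h` (onset, hours),
#'   `slope`, `intercept`, `r2`, `pct_change`; attribute `unit` records the
#'   slope unit. Pulses with non-finite samples are dropped with a warning.
#' @export
slope_series <- function(records, spec = attr(records, "spec"),
                         window = regression_window(),
                         domain = c("temperature", "voltage"),
                         baseline = "first") {
  domain <- match.arg(domain)
  if (length(records) < 1) stop_tp("need at least one pulse", "invalid_record")
  if (domain == "temperature" && is.null(spec)) {
    stop_tp("temperature domain needs a sensor_spec", "invalid_record")
  }
  rows <- lapply(records, function(rec) {
    if (any(!is.finite(rec$voltage))) return(NULL)
    if (domain == "temperature") {
      curve <- voltage_to_temperature(rec, spec)
      fit <- sqrt_time_regression(curve$t, curve$dT, window)
    } else {
      fit <- sqrt_time_regression(rec$t_rel, rec$voltage, window)
    }
    data.frame(pulse_index = rec$pulse_index, t_h = rec$onset / 3600,
               slope = fit$slope, intercept = fit$intercept, r2 = fit$r2)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("dropped %d degenerate pulse(s) with non-finite samples", dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop_tp("no usable pulses", "invalid_record")

  k <- if (identical(baseline, "first")) 1L else {
    if (!grepl("^mean:[0-9]+$", baseline)) {
      stop_tp("baseline must be 'first' or 'mean:k'", "configuration_error")
    }
    min(as.integer(sub("^mean:", "", baseline)), nrow(out))
  }
  s0 <- mean(out$slope[seq_len(k)])
  if (s0 == 0) stop_tp("baseline slope is zero; percent change undefined", "normalization_error")
  out$pct_change <- 100 * (out$slope - s0) / s0
  if (identical(baseline, "first")) out$pct_change[1] <- 0
  class(out) <- c("slope_series", "data.frame")
  attr(out, "unit") <- if (domain == "temperature") "K/sqrt(s)" else "V/sqrt(s)"
  attr(out, "window") <- window
  attr(out, "baseline") <- baseline
  rownames(out) <- NULL
  out
}

#' @export
plot.slope_series <- function(x, ...) {
  graphics::plot(x$t_h, x$pct_change, type = "l",
                 xlab = "time [h]", ylab = "slope change [%]", ...)
  invisible(x)
}

#' Endpoint statistic of a slope series
#'
#' Mean and standard deviation of the percent change over a time window,
#' by default 2 h to 12 h — after sedimentation is complete and before the
#' end of a standard run — giving the endpoint value regressed against
#' concentration in calibration.
#'
#' @param series A `slope_series`.
#' @param t_from,t_to Window bounds, h.
#' @return List with `mean`, `sd` (0 for a single point) and `n`.
#' @export
endpoint_statistic <- function(series, t_from = 2, t_to = 12) {
  keep <- series$t_h >= t_from & series$t_h <= t_to
  if (!any(keep)) {
    stop_tp(sprintf("no slope datapoints inside [%g, %g] h", t_from, t_to),
            "window_error")
  }
  v <- series$pct_change[keep]
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v))
}

#' Time at which a slope series settles onto its plateau
#'
#' First time after which every subsequent percent-change value stays within
#' `tolerance_pct` of the plateau level (the mean over the trailing
#' `tail_fraction` of the series).
#'
#' @param series A `slope_series`.
#' @param tolerance_pct Allowed deviation from the plateau level, percentage
#'   points.
#' @param tail_fraction Trailing fraction used to estimate the plateau level.
#' @return Plateau onset time in hours, or `NA` (with a warning) if the
#'   series never settles within tolerance.
#' @export
plateau_time <- function(series, tolerance_pct = 0.5, tail_fraction = 0.25) {
  n <- nrow(series)
  level <- mean(tail(series$pct_change, max(1L, ceiling(tail_fraction * n))))
  ok <- abs(series$pct_change - level) <= tolerance_pct
  # first index from which all later values stay inside the band
  settled <- rev(cumprod(rev(ok))) > 0
  if (!any(settled)) {
    warning("series never settles within tolerance; no plateau")
    return(NA_real_)
  }
  series$t_h[which(settled)[1]]
}
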