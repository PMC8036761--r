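#' Electrical/thermal description of one foil-heater sensor
#'
#' Captures the resistance-thermometry constants of the planar copper
#' meander: reference resistance `r_ref` at temperature `t_ref` and the
#' temperature coefficient of resistance `alpha`, so that
#' `R(T) = r_ref * (1 + alpha * (T - t_ref))`. Typical as-built sensors have
#' `r_ref` between 7 and 10 ohm at 20 degC and `alpha = 3.818e-3 K^-1`
#' (copper).
#'
#' @param r_ref Resistance at `t_ref`, ohm (> 0).
#' @param t_ref Reference (ambient) temperature, K. Default 293.15 (20 degC);
#'   cooling intervals are assumed to restore the sensor to `t_ref` exactly.
#' @param alpha Temperature coefficient of resistance, K^-1 (> 0).
#' @param heater_area Heated area, m^2.
#' @param stack A [layer_stack]; defaults to [default_sensor_stack()].
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(r_ref = 8, t_ref = 293.15, alpha = 3.818e-3,
                        heater_area = 81e-6, stack = NULL) {
  if (r_ref <= 0) stop_tp("r_ref must be positive", "invalid_sensor")
  if (alpha <= 0) stop_tp("alpha must be positive", "invalid_sensor")
  if (heater_area <= 0) stop_tp("heater_area must be positive", "invalid_sensor")
  if (is.null(stack)) stack <- default_sensor_stack(heater_area = heater_area)
  structure(list(r_ref = r_ref, t_ref = t_ref, alpha = alpha,
                 heater_area = heater_area, stack = stack),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> Rref = %.3g ohm @ %.5g K, alpha = %.4g 1/K, area = %.3g mm2\n",
              x$r_ref, x$t_ref, x$alpha, x$heater_area * 1e6))
  invisible(x)
}

#' Pulse protocol: power, timing and sampling of the heat pulses
#'
#' One slope datapoint takes `pulse_duration + cooling_time` seconds. The
#' defaults follow the sedimentation protocol (0.5 W, 1 s pulse, 60 s
#' cooling, 500 Hz sampling); proliferation runs stretch the cooling to
#' 300 s, since a ~90 min doubling time is amply sampled at one pulse per
#' 5 minutes.
#'
#' @param power Pulse power, W.
#' @param pulse_duration Heating time per pulse, s.
#' @param cooling_time Cool-down between pulses, s (sensor returns to
#'   ambient).
#' @param sample_rate Voltage sampling rate during heating, Hz.
#' @param total_duration Experiment length, s. Alternatively give `n_pulses`.
#'   Defaults to a 12 h run when neither is given.
#' @param n_pulses Number of pulses (converted to a total duration).
#' @return An object of class `pulse_protocol`.
#' @examples
#' pulse_protocol(total_duration = 610)   # 10 pulses, one per 61 s
#' @export
pulse_protocol <- function(power = 0.5, pulse_duration = 1, cooling_time = 60,
                           sample_rate = 500, total_duration = NULL,
                           n_pulses = NULL) {
  vals <- c(power = power, pulse_duration = pulse_duration,
            cooling_time = cooling_time, sample_rate = sample_rate)
  if (any(vals <= 0)) stop_tp("all protocol fields must be positive", "invalid_protocol")
  period <- pulse_duration + cooling_time
  if (is.null(total_duration)) {
    total_duration <- if (is.null(n_pulses)) 12 * 3600 else
      (n_pulses - 1) * period + pulse_duration
  }
  if (total_duration < pulse_duration) {
    stop_tp("total_duration shorter than one pulse", "invalid_protocol")
  }
  structure(list(power = power, pulse_duration = pulse_duration,
                 cooling_time = cooling_time, sample_rate = sample_rate,
                 total_duration = total_duration),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> %.3g W, %.3g s pulse + %.3g s cooling @ %g Hz; %d pulses in %.5g s\n",
              x$power, x$pulse_duration, x$cooling_time, x$sample_rate,
              length(pulse_onsets(x)), x$total_duration))
  invisible(x)
}

#' Pulse onset times of a protocol
#'
#' Pulses start at `k * (pulse_duration + cooling_time)` for
#' `k = 0, 1, ...` while the pulse still fits inside `total_duration`.
#'
#' @param protocol A [pulse_protocol].
#' @return Numeric vector of onset times, s.
#' @export
pulse_onsets <- function(protocol) {
  period <- protocol$pulse_duration + protocol$cooling_time
  k_max <- floor((protocol$total_duration - protocol$pulse_duration) / period)
  (0:k_max) * period
}

#' Resistance of the sensor at a given temperature
#'
#' Linear resistance thermometry: `R = r_ref * (1 + alpha * (T - t_ref))`.
#'
#' @param spec A [sensor_spec].
#' @param temperature Sensor temperature, K (vectorised).
#' @return Resistance, ohm.
#' @export
resistance_from_temperature <- function(spec, temperature) {
  spec$r_ref * (1 + spec$alpha * (temperature - spec$t_ref))
}

#' Temperature of the sensor from its measured resistance
#'
#' Exact algebraic inverse of [resistance_from_temperature()].
#'
#' @param spec A [sensor_spec].
#' @param resistance Measured resistance, ohm (vectorised, > 0).
#' @return Temperature, K.
#' @export
temperature_from_resistance <- function(spec, resistance) {
  if (any(resistance <= 0)) stop_tp("resistance must be positive", "domain_error")
  spec$t_ref + (resistance / spec$r_ref - 1) / spec$alpha
}

#' Drive current delivering a nominal power into a sensor
#'
#' Pulses must deposit the same power in every sensor despite unit-to-unit
#' spread in the cold resistance, so the source current is computed from the
#' initial resistance: `I = sqrt(power / r_init)`.
#'
#' @param r_init Initial (ambient) sensor resistance, ohm.
#' @param power Requested pulse power, W (>= 0).
#' @return Drive current, A.
#' @examples
#' drive_current_for_power(8, 0.5)   # 0.25 A
#' @export
drive_current_for_power <- function(r_init, power) {
  if (r_init <= 0) stop_tp("r_init must be positive", "domain_error")
  if (power < 0) stop_tp("power must be >= 0", "domain_error")
  sqrt(power / r_init)
}

#' One recorded heat pulse
#'
#' Container for a single 4-wire pulse record: the constant drive current and
#' the uniformly sampled voltage transient, relative to the pulse onset.
#'
#' @param pulse_index Integer index, 0-based, within the experiment.
#' @param onset Pulse onset, s since experiment start.
#' @param current Drive current, A.
#' @param t_rel Sample times relative to onset, s (uniform).
#' @param voltage Sampled voltages, V.
#' @return An object of class `pulse_record`.
#' @export
pulse_record <- function(pulse_index, onset, current, t_rel, voltage) {
  if (length(t_rel) != length(voltage)) {
    stop_tp("t_rel and voltage must have equal length", "invalid_record")
  }
  structure(list(pulse_index = as.integer(pulse_index), onset = onset,
                 current = current, t_rel = as.numeric(t_rel),
                 voltage = as.numeric(voltage)),
            class = "pulse_record")
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("<pulse_record> #%d @ %.5g s, I = %.4g A, %d samples (%.4g..%.4g V)\n",
              x$pulse_index, x$onset, x$current, length(x$t_rel),
              min(x$voltage), max(x$voltage)))
  invisible(x)
}

#' Synthesize a 4-wire voltage record from a thermal transient
#'
#' Forward electrical model: the drive current through the
#' temperature-dependent resistance gives
#' `V(t) = I * r_ref * (1 + alpha * dT(t))` (the sensor starts each pulse at
#' ambient `t_ref`), plus additive white Gaussian voltage noise.
#'
#' @param spec A [sensor_spec].
#' @param curve A `transient_curve` from [simulate_step_response()].
#' @param current Drive current, A.
#' @param noise_sd Voltage noise standard deviation, V. Default 2e-4 (0.2 mV).
#' @param seed Optional integer seed for the noise draw; the record is then
#'   fully deterministic.
#' @param quantization Optional ADC step, V; voltages are rounded to
#'   multiples of it after the noise is added. 0 (default) disables it.
#' @param pulse_index,onset Metadata stored in the record.
#' @return A [pulse_record()].
#' @export
synthesize_pulse <- function(spec, curve, current, noise_sd = 2e-4, seed = NULL,
                             quantization = 0, pulse_index = 0L, onset = 0) {
  if (noise_sd < 0) stop_tp("noise_sd must be >= 0", "domain_error")
  if (quantization < 0) stop_tp("quantization must be >= 0", "domain_error")
  mean_v <- current * resistance_from_temperature(spec, spec$t_ref + curve$dT)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(length(mean_v), 0, noise_sd) else 0
  v <- mean_v + noise
  if (quantization > 0) v <- round(v / quantization) * quantization
  pulse_record(pulse_index, onset, current, curve$t, v)
}
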