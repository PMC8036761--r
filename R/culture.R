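#' Two-fold dilution series of the sedimentation stock
#'
#' The sedimentation study conditions: a stock suspension diluted two-fold
#' `n_dilutions` times, plus a pure-water blank as the static control.
#'
#' @param stock Stock concentration, mg/mL. Default 8.
#' @param n_dilutions Number of two-fold dilution steps. Default 6
#'   (8, 4, 2, 1, 0.5, 0.25, 0.125 mg/mL).
#' @param include_blank Append the 0 mg/mL water control.
#' @return Numeric vector of concentrations, mg/mL, decreasing.
#' @export
dilution_series <- function(stock = 8, n_dilutions = 6, include_blank = TRUE) {
  s <- stock / 2^(0:n_dilutions)
  if (include_blank) s <- c(s, 0)
  s
}

#' Describe a synthetic culture scenario
#'
#' Ground-truth biology for the generator, in one of two modes:
#' \describe{
#'   \item{sedimentation}{a fixed inoculum of non-growing cells (dry yeast in
#'     water, no nutrients) settles by Stokes drag onto the sensor;
#'     `concentration` (mg/mL) and the liquid `column_height` set the total
#'     deposit.}
#'   \item{proliferation}{a yeast culture with lag, exponential and
#'     stationary phases; `od_start` (OD600) and `glucose` (g/L, the
#'     fermentable carbon source) set the start point and the carrying
#'     capacity `K = od_start + yield * glucose`.}
#' }
#' Biomass is expressed as areal biovolume (m^3 of cells per m^2 of sensor);
#' OD600 maps to it through the single conversion constant
#' `od_to_biovolume`. Absolute conversions are configuration, not claims —
#' only ratios and orderings carry meaning downstream.
#'
#' @param mode `"sedimentation"` or `"proliferation"`.
#' @param concentration Cell suspension concentration, mg/mL (sedimentation).
#' @param od_start Starting optical density, OD600 units (proliferation).
#' @param glucose Glucose content of the medium, g/L (proliferation).
#' @param column_height Liquid column height over the sensor, m. Defaults:
#'   1.5 mL in a 19 mm tube (~5.3 mm) for sedimentation, 10 mL (~35 mm) for
#'   proliferation.
#' @param cell_radius Cell radius, m (Stokes settling).
#' @param excess_density Cell-minus-medium density difference, kg m^-3.
#' @param viscosity Medium dynamic viscosity, Pa s.
#' @param cell [material_layer] properties of the packed cell interior.
#' @param medium Semi-infinite [material_layer] of the culture liquid.
#' @param lag Lag phase before exponential growth, h.
#' @param doubling_time Exponential-phase doubling time, min.
#' @param yield Biomass yield, OD600 units per g/L of glucose.
#' @param packing_fraction Volume fraction of cells inside the settled
#'   layer, in (0, 1].
#' @param od_to_biovolume Areal biovolume per OD600 unit of culture, m^3
#'   m^-2. The default 1.2e-5 follows from the column mass balance (an OD600
#'   unit is roughly 6.5e-4 cell volume fraction; times the ~35 mm column
#'   that is ~2.3e-5 m^3 m^-2 fully settled) scaled by ~0.5 for incomplete
#'   settling during growth; an effective constant, not a claim.
#' @return An object of class `culture_scenario`.
#' @export
culture_scenario <- function(mode = c("sedimentation", "proliferation"),
                             concentration = NULL, od_start = NULL,
                             glucose = NULL, column_height = NULL,
                             cell_radius = 2.5e-6, excess_density = 100,
                             viscosity = 1e-3,
                             cell = reference_material("yeast_cell", thickness = 1e-6),
                             medium = reference_material("water", semi_infinite = TRUE),
                             lag = 5, doubling_time = 90, yield = 0.5,
                             packing_fraction = 0.64,
                             od_to_biovolume = 1.2e-5) {
  mode <- match.arg(mode)
  if (mode == "sedimentation") {
    if (is.null(concentration) || concentration < 0) {
      stop_tp("sedimentation scenario needs concentration >= 0 (mg/mL)", "invalid_scenario")
    }
    column_height <- column_height %||% (1.5e-6 / (pi * (19e-3 / 2)^2))
  } else {
    if (is.null(od_start) || od_start <= 0) {
      stop_tp("proliferation scenario needs od_start > 0", "invalid_scenario")
    }
    if (is.null(glucose) || glucose < 0) {
      stop_tp("proliferation scenario needs glucose >= 0 (g/L)", "invalid_scenario")
    }
    if (doubling_time <= 0) stop_tp("doubling_time must be positive", "domain_error")
    column_height <- column_height %||% (10e-6 / (pi * (19e-3 / 2)^2))
  }
  if (column_height <= 0) stop_tp("column_height must be positive", "configuration_error")
  if (packing_fraction <= 0 || packing_fraction > 1) {
    stop_tp("packing_fraction must be in (0, 1]", "configuration_error")
  }
  structure(list(mode = mode, concentration = concentration,
                 od_start = od_start, glucose = glucose,
                 column_height = column_height, cell_radius = cell_radius,
                 excess_density = excess_density, viscosity = viscosity,
                 cell = cell, medium = medium, lag = lag,
                 doubling_time = doubling_time, yield = yield,
                 packing_fraction = packing_fraction,
                 od_to_biovolume = od_to_biovolume),
            class = "culture_scenario")
}

#' @export
print.culture_scenario <- function(x, ...) {
  if (x$mode == "sedimentation") {
    cat(sprintf("<culture_scenario> sedimentation: %.4g mg/mL over %.3g mm column\n",
                x$concentration, x$column_height * 1e3))
  } else {
    cat(sprintf("<culture_scenario> proliferation: OD600 %.3g, %.4g g/L glucose, lag %.3g h, Td %.3g min\n",
                x$od_start, x$glucose, x$lag, x$doubling_time))
  }
  invisible(x)
}

#' Stokes settling velocity of a single cell
#'
#' `v_s = (2/9) * excess_density * g * radius^2 / viscosity`.
#'
#' @param scenario A [culture_scenario] (its `cell_radius`, `excess_density`
#'   and `viscosity` fields are used).
#' @return Settling velocity, m s^-1.
#' @export
stokes_velocity <- function(scenario) {
  (2 / 9) * scenario$excess_density * 9.81 * scenario$cell_radius^2 /
    scenario$viscosity
}

#' Sedimentation trajectory: areal biovolume settled over time
#'
#' A uniform suspension of depth `column_height` settles at the Stokes
#' velocity; the fraction deposited on the sensor by time `t` is
#' `min(1, v_s * t / H)`, and the total deposit is set by mass balance
#' (concentration x column height / cell mass density). The trajectory
#' plateaus once the whole column has cleared, at `t = H / v_s`.
#'
#' @param scenario A sedimentation [culture_scenario].
#' @param t_grid Times, h.
#' @return A `biomass_trajectory`: data.frame with `t` (h) and
#'   `areal_biovolume` (m^3 m^-2).
#' @export
sedimentation_trajectory <- function(scenario, t_grid) {
  if (scenario$mode != "sedimentation") {
    stop_tp("scenario mode must be 'sedimentation'", "invalid_scenario")
  }
  v_s <- stokes_velocity(scenario)
  frac <- pmin(1, v_s * (t_grid * 3600) / scenario$column_height)
  # concentration mg/mL == kg/m^3; deposit volume per area by mass balance
  total <- scenario$concentration * scenario$column_height / scenario$cell$rho
  structure(data.frame(t = t_grid, areal_biovolume = total * frac),
            class = c("biomass_trajectory", "data.frame"))
}

#' Growth trajectory: lag + logistic proliferation
#'
#' The population holds at `od_start` for `lag` hours (cells settle on the
#' sensor and adapt), then grows logistically with exponential-phase rate
#' `r = ln(2) / doubling_time` toward the nutrient-set carrying capacity
#' `K = od_start + yield * glucose`; once glucose is exhausted the culture
#' is stationary and the trajectory is flat. OD600 is converted to areal
#' biovolume with the scenario's `od_to_biovolume` constant.
#'
#' @param scenario A proliferation [culture_scenario].
#' @param t_grid Times, h.
#' @return A `biomass_trajectory` (columns `t` h, `areal_biovolume` m^3 m^-2)
#'   with attribute `od` holding the OD600 trajectory.
#' @export
growth_trajectory <- function(scenario, t_grid) {
  if (scenario$mode != "proliferation") {
    stop_tp("scenario mode must be 'proliferation'", "invalid_scenario")
  }
  if (scenario$doubling_time <= 0) stop_tp("doubling_time must be positive", "domain_error")
  n0 <- scenario$od_start
  K <- n0 + scenario$yield * scenario$glucose
  r <- log(2) / (scenario$doubling_time / 60)  # per hour
  te <- pmax(0, t_grid - scenario$lag)
  od <- if (is.finite(K)) {
    K / (1 + ((K - n0) / n0) * exp(-r * te))
  } else {
    n0 * 2^(te * 60 / scenario$doubling_time)
  }
  out <- data.frame(t = t_grid, areal_biovolume = scenario$od_to_biovolume * od)
  class(out) <- c("biomass_trajectory", "data.frame")
  attr(out, "od") <- od
  out
}

#' Effective cell layer from a settled biovolume
#'
#' Cells pack on the sensor at volume fraction `packing_fraction` with medium
#' filling the voids, so the layer thickness is
#' `areal_biovolume / packing_fraction` and its conductivity follows the
#' Maxwell-Eucken effective-medium rule with the medium as the continuous
#' phase (series and parallel mixing are available as sensitivity bounds).
#' Density and volumetric heat capacity mix linearly in volume.
#'
#' @param areal_biovolume Settled cell volume per sensor area, m^3 m^-2.
#' @param packing_fraction Cell volume fraction in the layer, (0, 1].
#' @param cell [material_layer] properties of the cell phase.
#' @param medium [material_layer] properties of the medium phase.
#' @param mixing `"maxwell_eucken"` (default), `"series"` or `"parallel"`.
#' @return A finite [material_layer], or `NULL` for zero biovolume (no
#'   layer; the stack is unchanged).
#' @export
layer_from_biomass <- function(areal_biovolume, packing_fraction,
                               cell = reference_material("yeast_cell", thickness = 1e-6),
                               medium = reference_material("water", semi_infinite = TRUE),
                               mixing = c("maxwell_eucken", "series", "parallel")) {
  mixing <- match.arg(mixing)
  if (packing_fraction <= 0 || packing_fraction > 1) {
    stop_tp("packing_fraction must be in (0, 1]", "configuration_error")
  }
  if (areal_biovolume < 0) stop_tp("areal_biovolume must be >= 0", "domain_error")
  if (areal_biovolume == 0) return(NULL)
  phi <- packing_fraction
  km <- medium$k; kc <- cell$k
  k_eff <- switch(mixing,
    maxwell_eucken = km * (2 * km + kc - 2 * phi * (km - kc)) /
                     (2 * km + kc + phi * (km - kc)),
    series = 1 / (phi / kc + (1 - phi) / km),
    parallel = phi * kc + (1 - phi) * km
  )
  rho_eff <- phi * cell$rho + (1 - phi) * medium$rho
  rhocp_eff <- phi * cell$rho * cell$cp + (1 - phi) * medium$rho * medium$cp
  material_layer("cell_layer", k = k_eff, rho = rho_eff,
                 cp = rhocp_eff / rho_eff,
                 thickness = areal_biovolume / packing_fraction)
}

# insert a finite cell layer between heater and the rest of the above side
with_cell_layer <- function(stack, layer) {
  if (is.null(layer)) return(stack)
  layer_stack(above = c(list(layer), stack$above), below = stack$below,
              heater_areal_heat_capacity = stack$heater_areal_heat_capacity,
              heater_area = stack$heater_area,
              below_boundary = stack$below_boundary)
}

#' Generate a full synthetic pulse experiment
#'
#' Composes the pipeline end-to-end: the scenario's biomass trajectory is
#' evaluated at every pulse onset, mapped to an effective cell layer,
#' inserted into the sensor stack, the thermal step response is solved, and
#' a noisy 4-wire voltage record is synthesized per pulse. The drive current
#' is computed once from the sensor's ambient resistance so every sensor
#' receives the same nominal power.
#'
#' @param scenario A [culture_scenario].
#' @param spec A [sensor_spec].
#' @param protocol A [pulse_protocol].
#' @param seed Top-level integer seed; the voltage-noise stream is derived
#'   from it, so the full dataset is reproducible.
#' @param noise_sd Voltage noise sd, V. Default 2e-4.
#' @param opts Solver [grid_opts()].
#' @return A `pulse_experiment`: list of [pulse_record()]s with the
#'   scenario, protocol, spec and ground-truth trajectory attached as
#'   attributes.
#' @export
generate_experiment <- function(scenario, spec, protocol, seed = 1,
                                noise_sd = 2e-4, opts = grid_opts()) {
  if (protocol$total_duration < protocol$pulse_duration) {
    stop_tp("protocol period shorter than pulse duration", "configuration_error")
  }
  onsets <- pulse_onsets(protocol)
  t_h <- onsets / 3600
  traj <- switch(scenario$mode,
    sedimentation = sedimentation_trajectory(scenario, t_h),
    proliferation = growth_trajectory(scenario, t_h)
  )
  current <- drive_current_for_power(spec$r_ref, protocol$power)
  set.seed(substream_seed(seed, "noise"))
  records <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    layer <- layer_from_biomass(traj$areal_biovolume[i],
                                scenario$packing_fraction,
                                cell = scenario$cell, medium = scenario$medium)
    stack_i <- with_cell_layer(spec$stack, layer)
    curve <- simulate_step_response(stack_i, protocol$power,
                                    protocol$pulse_duration,
                                    protocol$sample_rate, opts = opts)
    records[[i]] <- synthesize_pulse(spec, curve, current, noise_sd = noise_sd,
                                     pulse_index = i - 1L, onset = onsets[i])
  }
  structure(records, class = "pulse_experiment", scenario = scenario,
            protocol = protocol, spec = spec, trajectory = traj, seed = seed)
}

#' @export
print.pulse_experiment <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("<pulse_experiment> %d pulses (%.3g W, %.3g s @ %g Hz), period %.4g s\n",
              length(x), p$power, p$pulse_duration, p$sample_rate,
              p$pulse_duration + p$cooling_time))
  invisible(x)
}

#' Draw calibration endpoints directly from the linear sensor response
#'
#' Calibration-mode generator: bypasses the thermal physics and draws final
#' percent-change endpoints straight from the package's ground-truth linear
#' response of endpoint percent change to suspension concentration,
#' `pct = slope * concentration + intercept`, plus Gaussian noise. Used to
#' exercise calibration fitting and inverse prediction independently of
#' assumed cell thermal properties.
#'
#' @param concentrations Concentrations, mg/mL (e.g. [dilution_series()]).
#' @param replicates Replicate endpoints per concentration.
#' @param noise_sd Endpoint noise sd, percentage points.
#' @param seed Integer seed.
#' @param slope,intercept Ground-truth response line; defaults 0.7806 %
#'   per mg/mL and -0.2194 %.
#' @return data.frame with columns `concentration` and `endpoint_pct`.
#' @export
calibration_endpoints <- function(concentrations, replicates = 4,
                                  noise_sd = 0.25, seed = 1,
                                  slope = 0.7806, intercept = -0.2194) {
  if (noise_sd < 0) stop_tp("noise_sd must be >= 0", "domain_error")
  set.seed(substream_seed(seed, "calibration"))
  conc <- rep(concentrations, each = replicates)
  data.frame(
    concentration = conc,
    endpoint_pct = slope * conc + intercept + rnorm(length(conc), 0, noise_sd)
  )
}
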