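#' Write raw pulse records to CSV
#'
#' Serializes a pulse experiment to the raw-pulse table: one row per sample,
#' columns `pulse_index`, `onset_s`, `current_A`, `t_rel_s`, `voltage_V`,
#' sorted by pulse then sample time. Numbers are written with full
#' round-tripping precision (well beyond 9 significant digits).
#'
#' @param records A `pulse_experiment` or list of [pulse_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_pulses <- function(records, path) {
  tabs <- lapply(records, function(r) {
    data.table::data.table(pulse_index = r$pulse_index, onset_s = r$onset,
                           current_A = r$current, t_rel_s = r$t_rel,
                           voltage_V = r$voltage)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

raw_pulse_columns <- c("pulse_index", "onset_s", "current_A", "t_rel_s", "voltage_V")

#' Read raw pulse records from CSV
#'
#' Reads and validates the raw-pulse table written by [write_raw_pulses()]:
#' all five columns must be present, rows must be sorted and unique on
#' (`pulse_index`, `t_rel_s`), and the drive current must be constant within
#' each pulse. Violations raise a schema error naming the first offending
#' row.
#'
#' @param path CSV path.
#' @return A `pulse_experiment` (possibly empty list for a header-only file).
#' @export
read_raw_pulses <- function(path) {
  dt <- data.table::fread(path)
  missing_cols <- setdiff(raw_pulse_columns, names(dt))
  if (length(missing_cols)) {
    stop_tp(paste0("raw pulse file missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (nrow(dt) == 0) return(structure(list(), class = "pulse_experiment"))

  if (nrow(dt) > 1) {
    dpi <- diff(dt$pulse_index)
    bad <- which(dpi < 0 | (dpi == 0 & diff(dt$t_rel_s) <= 0))
    if (length(bad)) {
      stop_tp(sprintf("raw pulse rows not sorted by (pulse_index, t_rel_s); first offence at row %d",
                      bad[1] + 1L), "schema_error")
    }
  }
  dup <- which(duplicated(dt[, c("pulse_index", "t_rel_s")]))
  if (length(dup)) {
    stop_tp(sprintf("duplicate (pulse_index, t_rel_s) at row %d", dup[1]), "schema_error")
  }
  records <- lapply(split(dt, by = "pulse_index", sorted = TRUE), function(p) {
    if (length(unique(p$current_A)) != 1L) {
      stop_tp(sprintf("pulse %d: current varies within the pulse", p$pulse_index[1]),
              "schema_error")
    }
    if (length(unique(p$onset_s)) != 1L) {
      stop_tp(sprintf("pulse %d: onset varies within the pulse", p$pulse_index[1]),
              "schema_error")
    }
    pulse_record(p$pulse_index[1], p$onset_s[1], p$current_A[1],
                 p$t_rel_s, p$voltage_V)
  })
  structure(unname(records), class = "pulse_experiment")
}

#' Write / read a slope series CSV
#'
#' Columns `pulse_index`, `t_h`, `slope`, `intercept`, `r2`, `pct_change`.
#'
#' @param series A `slope_series`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `slope_series` (read).
#' @export
write_slope_series <- function(series, path) {
  data.table::fwrite(as.data.frame(series)[, c("pulse_index", "t_h", "slope",
                                               "intercept", "r2", "pct_change")],
                     path)
  invisible(path)
}

#' @rdname write_slope_series
#' @export
read_slope_series <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("pulse_index", "t_h", "slope", "intercept", "r2", "pct_change")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop_tp(paste0("slope series file missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "schema_error")
  }
  class(dt) <- c("slope_series", "data.frame")
  dt
}

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop_tp(sprintf("unknown key(s) in %s: %s", where,
                    paste(unknown, collapse = ", ")), "config_error")
  }
}

material_from_config <- function(blk, name, default) {
  if (is.null(blk)) return(default)
  check_keys(blk, c("k_W_mK", "rho_kg_m3", "cp_J_kgK", "thickness_m"),
             paste0("materials$", name))
  material_layer(name,
                 k = blk$k_W_mK %||% default$k,
                 rho = blk$rho_kg_m3 %||% default$rho,
                 cp = blk$cp_J_kgK %||% default$cp,
                 thickness = blk$thickness_m %||%
                   (if (default$semi_infinite) NA_real_ else default$thickness),
                 semi_infinite = default$semi_infinite)
}

#' Read an experiment configuration file
#'
#' Parses a YAML experiment description into the package's objects. Keys
#' carry explicit units in their names to prevent unit drift (for example
#' `pulse_duration_s`, `alpha_per_K`); unknown keys are rejected. See
#' `system.file("extdata", "demo_sedimentation.yaml", package =
#' "thermopulse")` for the full schema.
#'
#' @param path YAML file path.
#' @return List with `spec` ([sensor_spec]), `protocol` ([pulse_protocol]),
#'   `scenario` ([culture_scenario]), `analysis` (window, domain, baseline,
#'   endpoint window), `noise_sd` (V) and `seed`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("seed", "noise_sd_V", "sensor", "protocol", "scenario",
                    "materials", "analysis"), "config")

  mats <- cfg$materials %||% list()
  check_keys(mats, c("medium", "substrate", "cell"), "materials")
  medium <- material_from_config(mats$medium, "medium",
                                 reference_material("water", semi_infinite = TRUE))
  substrate <- material_from_config(mats$substrate, "substrate",
                                    reference_material("polyimide", thickness = 40e-6))
  cell <- material_from_config(mats$cell, "cell",
                               reference_material("yeast_cell", thickness = 1e-6))

  sn <- cfg$sensor %||% list()
  check_keys(sn, c("r_ref_ohm", "t_ref_K", "alpha_per_K", "heater_area_m2",
                   "heater_areal_heat_capacity_J_m2K"), "sensor")
  area <- sn$heater_area_m2 %||% 81e-6
  stack <- default_sensor_stack(
    medium = medium, substrate = substrate,
    heater_areal_heat_capacity = sn$heater_areal_heat_capacity_J_m2K %||% 51.7,
    heater_area = area)
  spec <- sensor_spec(r_ref = sn$r_ref_ohm %||% 8,
                      t_ref = sn$t_ref_K %||% 293.15,
                      alpha = sn$alpha_per_K %||% 3.818e-3,
                      heater_area = area, stack = stack)

  pr <- cfg$protocol %||% list()
  check_keys(pr, c("power_W", "pulse_duration_s", "cooling_time_s",
                   "sample_rate_Hz", "total_duration_s", "n_pulses"), "protocol")
  protocol <- pulse_protocol(power = pr$power_W %||% 0.5,
                             pulse_duration = pr$pulse_duration_s %||% 1,
                             cooling_time = pr$cooling_time_s %||% 60,
                             sample_rate = pr$sample_rate_Hz %||% 500,
                             total_duration = pr$total_duration_s,
                             n_pulses = pr$n_pulses)

  sc <- cfg$scenario %||% list()
  check_keys(sc, c("mode", "concentration_mg_mL", "od_start", "glucose_g_L",
                   "column_height_m", "cell_radius_m", "excess_density_kg_m3",
                   "viscosity_Pa_s", "lag_h", "doubling_time_min",
                   "yield_od_per_gL", "packing_fraction",
                   "od_to_biovolume_m3_m2"), "scenario")
  scenario <- culture_scenario(
    mode = sc$mode %||% "sedimentation",
    concentration = sc$concentration_mg_mL,
    od_start = sc$od_start, glucose = sc$glucose_g_L,
    column_height = sc$column_height_m,
    cell_radius = sc$cell_radius_m %||% 2.5e-6,
    excess_density = sc$excess_density_kg_m3 %||% 100,
    viscosity = sc$viscosity_Pa_s %||% 1e-3,
    cell = cell, medium = medium,
    lag = sc$lag_h %||% 5,
    doubling_time = sc$doubling_time_min %||% 90,
    yield = sc$yield_od_per_gL %||% 0.5,
    packing_fraction = sc$packing_fraction %||% 0.64,
    od_to_biovolume = sc$od_to_biovolume_m3_m2 %||% 1.2e-5)

  an <- cfg$analysis %||% list()
  check_keys(an, c("window_sqrt_s", "domain", "baseline",
                   "endpoint_from_h", "endpoint_to_h"), "analysis")
  w <- an$window_sqrt_s %||% c(0.16, 0.56)
  analysis <- list(window = regression_window(w[1], w[2]),
                   domain = an$domain %||% "temperature",
                   baseline = an$baseline %||% "first",
                   endpoint_from = an$endpoint_from_h %||% 2,
                   endpoint_to = an$endpoint_to_h %||% 12)

  list(spec = spec, protocol = protocol, scenario = scenario,
       analysis = analysis, noise_sd = cfg$noise_sd_V %||% 2e-4,
       seed = cfg$seed %||% 1)
}
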