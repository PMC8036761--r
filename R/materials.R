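#' Define a homogeneous material layer
#'
#' A `material_layer` carries the bulk thermal properties of one slab in the
#' one-dimensional sensor stack: thermal conductivity `k`, density `rho` and
#' specific heat capacity `cp`, plus a thickness. A terminal layer may be
#' declared semi-infinite (its far boundary never influences the transient on
#' the pulse timescale), in which case the thickness is ignored.
#'
#' @param name Layer label (free text, used in diagnostics).
#' @param k Thermal conductivity, W m^-1 K^-1. Must be positive.
#' @param rho Density, kg m^-3. Must be positive.
#' @param cp Specific heat capacity, J kg^-1 K^-1. Must be positive.
#' @param thickness Layer thickness in metres. Required (and positive) unless
#'   `semi_infinite = TRUE`.
#' @param semi_infinite Logical; `TRUE` marks a terminal half-space.
#' @return An object of class `material_layer`.
#' @examples
#' water <- material_layer("water", k = 0.60, rho = 998, cp = 4182,
#'                         semi_infinite = TRUE)
#' effusivity(water)
#' @export
material_layer <- function(name, k, rho, cp, thickness = NA_real_,
                           semi_infinite = FALSE) {
  for (v in c("k", "rho", "cp")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop_tp(sprintf("material '%s': '%s' must be a positive finite number", name, v),
              "invalid_material")
    }
  }
  if (!isTRUE(semi_infinite)) {
    if (!is.numeric(thickness) || !is.finite(thickness) || thickness <= 0) {
      stop_tp(sprintf("material '%s': finite layer needs thickness > 0", name),
              "invalid_material")
    }
  } else {
    thickness <- Inf
  }
  structure(
    list(name = as.character(name), k = as.numeric(k), rho = as.numeric(rho),
         cp = as.numeric(cp), thickness = as.numeric(thickness),
         semi_infinite = isTRUE(semi_infinite)),
    class = "material_layer"
  )
}

#' @export
print.material_layer <- function(x, ...) {
  thick <- if (x$semi_infinite) "semi-infinite" else
    sprintf("%.4g um", x$thickness * 1e6)
  cat(sprintf("<material_layer> %s: k = %.3g W/mK, rho = %.4g kg/m3, cp = %.4g J/kgK, %s\n",
              x$name, x$k, x$rho, x$cp, thick))
  invisible(x)
}

#' Thermal effusivity of a material
#'
#' Effusivity `e = sqrt(k * rho * cp)` (units W s^1/2 m^-2 K^-1) governs the
#' surface temperature rise of a semi-infinite medium under constant heat
#' flux: the larger the effusivity of the material in contact with the
#' heater, the flatter the transient.
#'
#' @param layer A [material_layer], or a list with elements `k`, `rho`, `cp`.
#' @return Thermal effusivity, W s^1/2 m^-2 K^-1.
#' @examples
#' effusivity(material_layer("water", 0.60, 998, 4182, semi_infinite = TRUE))
#' @export
effusivity <- function(layer) {
  if (!all(c("k", "rho", "cp") %in% names(layer))) {
    stop_tp("effusivity() needs a material with k, rho and cp", "invalid_material")
  }
  if (any(vapply(layer[c("k", "rho", "cp")], function(x) x <= 0, logical(1)))) {
    stop_tp("effusivity(): k, rho and cp must all be positive", "invalid_material")
  }
  sqrt(layer$k * layer$rho * layer$cp)
}

#' Thermal diffusivity of a material
#'
#' `a = k / (rho * cp)`, m^2 s^-1: how fast a thermal disturbance penetrates.
#'
#' @inheritParams effusivity
#' @return Thermal diffusivity, m^2 s^-1.
#' @export
thermal_diffusivity <- function(layer) {
  layer$k / (layer$rho * layer$cp)
}

#' Probing depth of a heat pulse
#'
#' Characteristic depth sensed by a pulse of duration `t` in a material of
#' diffusivity `a`, using the common transient-plane-source rule of thumb
#' `depth = 2 * sqrt(a * t)`. This is a convention, used here for regression
#' window selection guidance, not a sharp physical cutoff.
#'
#' @param diffusivity Thermal diffusivity, m^2 s^-1 (positive).
#' @param t Time since pulse onset, s (non-negative; vectorised).
#' @return Probing depth in metres, same length as `t`.
#' @examples
#' probing_depth(7.75e-8, 0.0052)  # ~40 um into polyimide after ~5 ms
#' @export
probing_depth <- function(diffusivity, t) {
  if (!is.numeric(diffusivity) || diffusivity <= 0) {
    stop_tp("diffusivity must be positive", "domain_error")
  }
  if (any(t < 0)) stop_tp("t must be non-negative", "domain_error")
  2 * sqrt(diffusivity * t)
}

#' Closed-form heater temperature over a semi-infinite medium
#'
#' Constant heat flux `q_flux` deposited at the surface of a homogeneous
#' semi-infinite half-space of effusivity `e` raises the surface temperature
#' by `dT(t) = (2 * q_flux / e) * sqrt(t / pi)`: linear in `sqrt(t)` with
#' slope `2 * q_flux / (e * sqrt(pi))`. Serves as the analytic oracle for the
#' finite-difference solver.
#'
#' @param e Thermal effusivity of the half-space, W s^1/2 m^-2 K^-1.
#' @param q_flux Heat flux into the half-space, W m^-2.
#' @param t Time since flux onset, s (vectorised).
#' @return Temperature rise dT in kelvin, same length as `t`.
#' @examples
#' # 0.5 W over 81 mm^2 into water: slope ~ 4.40 K s^-1/2
#' analytic_semiinfinite(1582.5, 0.5 / 81e-6, c(0.0256, 0.3136))
#' @export
analytic_semiinfinite <- function(e, q_flux, t) {
  if (e <= 0) stop_tp("effusivity must be positive", "domain_error")
  if (any(t < 0)) stop_tp("t must be non-negative", "domain_error")
  (2 * q_flux / e) * sqrt(t / pi)
}

#' Reference materials for the default sensor build
#'
#' Room-temperature property sets used throughout the package defaults:
#' liquid water (standing in for dilute aqueous culture medium), the polyimide
#' foil substrate, and a nominal yeast-cell interior. The cell properties are
#' configuration defaults inside literature-plausible ranges, not measured
#' claims; what matters downstream is that cell conductivity is below that of
#' the medium, so a settling or growing cell layer insulates the heater.
#'
#' @param name One of `"water"`, `"polyimide"`, `"yeast_cell"`.
#' @param ... Overrides passed to [material_layer()] (e.g. `thickness`).
#' @return A [material_layer].
#' @export
reference_material <- function(name = c("water", "polyimide", "yeast_cell"), ...) {
  name <- match.arg(name)
  props <- switch(name,
    water      = list(k = 0.60, rho = 998,  cp = 4182),
    polyimide  = list(k = 0.12, rho = 1420, cp = 1090),
    yeast_cell = list(k = 0.45, rho = 1100, cp = 3500)
  )
  args <- modifyList(c(list(name = name), props), list(...))
  do.call(material_layer, args)
}
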