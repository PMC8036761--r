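#' Assemble the layered stack around the planar heater
#'
#' The sensor is modelled one-dimensionally through the plane of the meander:
#' a lumped heater node (areal heat capacity `heater_areal_heat_capacity`)
#' sandwiched between an ordered sequence of layers running upward toward the
#' culture (`above`, last layer semi-infinite medium) and downward through
#' the substrate (`below`, terminated either adiabatically -- the backplate
#' cut-out -- or by a semi-infinite backing).
#'
#' @param above List of [material_layer]s from the heater plane toward the
#'   medium; the last must be semi-infinite.
#' @param below List of [material_layer]s from the heater plane downward.
#'   May be empty only if `below_boundary = "adiabatic"` and at least one
#'   side carries material.
#' @param heater_areal_heat_capacity Areal heat capacity of the heater node,
#'   J m^-2 K^-1. Default 51.7 (15 um copper, volumetric heat capacity
#'   3.45e6 J m^-3 K^-1).
#' @param heater_area Heated area, m^2. Default 81e-6 (9 mm x 9 mm meander
#'   footprint treated as a uniform planar source).
#' @param below_boundary `"adiabatic"` (zero flux behind the last below
#'   layer) or `"semi_infinite"` (last below layer is a half-space).
#' @return An object of class `layer_stack`.
#' @examples
#' st <- default_sensor_stack()
#' st
#' @export
layer_stack <- function(above, below = list(),
                        heater_areal_heat_capacity = 51.7,
                        heater_area = 81e-6,
                        below_boundary = c("adiabatic", "semi_infinite")) {
  below_boundary <- match.arg(below_boundary)
  check_side <- function(layers, side, semi_terminal) {
    if (length(layers) == 0L) return(invisible())
    ok <- vapply(layers, inherits, logical(1), "material_layer")
    if (!all(ok)) stop_tp(sprintf("all '%s' layers must be material_layer objects", side),
                          "invalid_stack")
    si <- vapply(layers, function(l) l$semi_infinite, logical(1))
    if (semi_terminal) {
      if (!si[length(si)]) {
        stop_tp(sprintf("last '%s' layer must be semi-infinite", side), "invalid_stack")
      }
      if (any(si[-length(si)])) {
        stop_tp(sprintf("only the terminal '%s' layer may be semi-infinite", side),
                "invalid_stack")
      }
    } else if (any(si)) {
      stop_tp(sprintf("'%s' side is adiabatic-terminated; no layer may be semi-infinite", side),
              "invalid_stack")
    }
  }
  if (length(above) == 0L) stop_tp("'above' needs at least the medium half-space", "invalid_stack")
  check_side(above, "above", semi_terminal = TRUE)
  check_side(below, "below", semi_terminal = below_boundary == "semi_infinite")
  if (below_boundary == "semi_infinite" && length(below) == 0L) {
    stop_tp("semi-infinite below boundary needs at least one below layer", "invalid_stack")
  }
  if (heater_areal_heat_capacity < 0) {
    stop_tp("heater_areal_heat_capacity must be >= 0", "invalid_stack")
  }
  if (heater_area <= 0) stop_tp("heater_area must be positive", "invalid_stack")
  structure(
    list(above = above, below = below,
         heater_areal_heat_capacity = heater_areal_heat_capacity,
         heater_area = heater_area, below_boundary = below_boundary),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> heater: C_A = %.3g J/m2K over %.3g mm2 (%s backside)\n",
              x$heater_areal_heat_capacity, x$heater_area * 1e6, x$below_boundary))
  cat("  above (heater -> medium):\n")
  for (l in x$above) cat("   -", format_layer(l), "\n")
  if (length(x$below)) {
    cat("  below (heater -> backside):\n")
    for (l in x$below) cat("   -", format_layer(l), "\n")
  }
  invisible(x)
}

format_layer <- function(l) {
  thick <- if (l$semi_infinite) "semi-inf" else sprintf("%.4g um", l$thickness * 1e6)
  sprintf("%s (k=%.3g, %s)", l$name, l$k, thick)
}

#' Default sensor stack: polyimide foil under a liquid culture
#'
#' Builds the stack for the default foil-heater build: a 40 um polyimide
#' substrate backed by an adiabatic plane (the backplate cut-out that limits
#' energy loss to the environment) below the heater, and optionally a thin
#' cell layer followed by semi-infinite medium above it.
#'
#' @param cell_layer Optional finite [material_layer] inserted between heater
#'   and medium (e.g. from [layer_from_biomass()]); `NULL` or a zero-thickness
#'   layer leaves the stack unchanged.
#' @param medium Semi-infinite [material_layer] for the culture liquid.
#' @param substrate Finite [material_layer] for the foil substrate.
#' @param ... Passed on to [layer_stack()].
#' @return A `layer_stack`.
#' @export
default_sensor_stack <- function(cell_layer = NULL,
                                 medium = reference_material("water", semi_infinite = TRUE),
                                 substrate = reference_material("polyimide", thickness = 40e-6),
                                 ...) {
  above <- list(medium)
  if (!is.null(cell_layer) && is.finite(cell_layer$thickness) && cell_layer$thickness > 0) {
    above <- c(list(cell_layer), above)
  }
  layer_stack(above = above, below = list(substrate), ...)
}
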