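#' Forward response curve: window slope versus cell-layer thickness
#'
#' Tabulates, with the package's own solver, the sqrt-time window slope of
#' the sensor as a function of the effective cell-layer thickness, and
#' returns it with monotone spline interpolants. The response is convex at
#' small thickness (a film of thickness `d` has internal diffusion time
#' `d^2/a`, so a thin film perturbs mostly the intercept of the transient,
#' not its slope) and becomes affine once the film fills a noticeable part
#' of the window's probing depth. Quantification steps that assume slope
#' change proportional to biomass are therefore biased at small loads;
#' passing this curve to [fit_growth()] removes that bias by fitting the
#' composed model instead.
#'
#' @param spec A [sensor_spec] (supplies the base stack and heated area).
#' @param cell,medium [material_layer] properties of the two phases of the
#'   cell layer.
#' @param packing_fraction Cell volume fraction in the layer.
#' @param thicknesses Layer thickness grid, m; refined at the convex low
#'   end by default, reaching 200 um.
#' @param power,duration,sample_rate Pulse parameters for the tabulation;
#'   defaults match the standard protocol.
#' @param window [regression_window()] used for the slopes.
#' @param opts Solver [grid_opts()].
#' @return An object of class `slope_response`: data.frame `curve`
#'   (`thickness` m, `slope` K s^-1/2, `ratio` slope relative to the bare
#'   sensor), plus interpolants `ratio_fun(thickness)` and
#'   `thickness_fun(ratio)`.
#' @export
slope_response <- function(spec = sensor_spec(),
                           cell = reference_material("yeast_cell", thickness = 1e-6),
                           medium = reference_material("water", semi_infinite = TRUE),
                           packing_fraction = 0.64,
                           thicknesses = c(0, 2, 4, 6, 9, 12, 16, 20, 26, 33,
                                           41, 50, 62, 76, 92, 110, 130, 155,
                                           180, 200) * 1e-6,
                           power = 0.5, duration = 1, sample_rate = 500,
                           window = regression_window(), opts = grid_opts()) {
  thicknesses <- sort(unique(thicknesses))
  if (thicknesses[1] != 0) thicknesses <- c(0, thicknesses)
  slopes <- vapply(thicknesses, function(th) {
    lay <- layer_from_biomass(th * packing_fraction, packing_fraction,
                              cell = cell, medium = medium)
    cv <- simulate_step_response(with_cell_layer(spec$stack, lay), power,
                                 duration, sample_rate, opts = opts)
    sqrt_time_regression(cv$t, cv$dT, window)$slope
  }, numeric(1))
  ratio <- slopes / slopes[1]
  curve <- data.frame(thickness = thicknesses, slope = slopes, ratio = ratio)
  structure(
    list(curve = curve,
         ratio_fun = stats::splinefun(thicknesses, ratio, method = "hyman"),
         thickness_fun = stats::splinefun(ratio, thicknesses, method = "hyman")),
    class = "slope_response"
  )
}

#' @export
print.slope_response <- function(x, ...) {
  rng <- range(x$curve$thickness) * 1e6
  cat(sprintf("<slope_response> %d points, thickness %.3g-%.3g um, slope gain up to %.3g%%\n",
              nrow(x$curve), rng[1], rng[2],
              100 * (max(x$curve$ratio) - 1)))
  invisible(x)
}
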