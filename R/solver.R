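#' Spatial and temporal discretisation settings for the transient solver
#'
#' The stack is discretised with control volumes: uniform steps no coarser
#' than `film_dx` inside finite (thin-film) layers, and a geometrically
#' stretched grid reaching `domain_depth` into each semi-infinite half-space,
#' starting at `first_dx` and growing by `stretch` per cell. Time stepping is
#' backward Euler with `substeps` implicit steps per output sample; the first
#' output interval uses `first_substeps` geometrically graded steps (ratio
#' `first_ratio`) to resolve the sqrt(t) startup of the transient.
#'
#' @param film_dx Maximum cell size inside finite layers, m.
#' @param first_dx First cell size entering a semi-infinite layer, m.
#' @param stretch Geometric growth factor for semi-infinite grids.
#' @param domain_depth Truncation depth of semi-infinite layers, m. The far
#'   boundary is zero-flux; the depth must comfortably exceed the thermal
#'   penetration at the end of the pulse.
#' @param substeps Implicit substeps per output sample.
#' @param first_substeps Graded substeps inside the first output interval.
#' @param first_ratio Grading ratio of those first substeps.
#' @param max_film_nodes Cap on nodes per finite layer.
#' @return A list of class `grid_opts`.
#' @export
grid_opts <- function(film_dx = 1e-6, first_dx = 2e-6, stretch = 1.2,
                      domain_depth = 5e-3, substeps = 4L, first_substeps = 32L,
                      first_ratio = 1.25, max_film_nodes = 400L) {
  stopifnot(film_dx > 0, first_dx > 0, stretch > 1, domain_depth > 0,
            substeps >= 1, first_substeps >= 1, first_ratio >= 1)
  structure(list(film_dx = film_dx, first_dx = first_dx, stretch = stretch,
                 domain_depth = domain_depth, substeps = as.integer(substeps),
                 first_substeps = as.integer(first_substeps),
                 first_ratio = first_ratio,
                 max_film_nodes = as.integer(max_film_nodes)),
            class = "grid_opts")
}

# one side of the stack -> per-cell dx, k, volumetric heat capacity
discretise_side <- function(layers, opts) {
  dx <- k <- rhocp <- numeric(0)
  for (l in layers) {
    if (l$semi_infinite) {
      steps <- opts$first_dx * opts$stretch^(0:200)
      steps <- steps[cumsum(steps) <= opts$domain_depth * opts$stretch]
      if (sum(steps) < opts$domain_depth) {
        steps <- c(steps, opts$domain_depth - sum(steps))
      }
      dx <- c(dx, steps)
      k <- c(k, rep(l$k, length(steps)))
      rhocp <- c(rhocp, rep(l$rho * l$cp, length(steps)))
    } else {
      n <- min(max(1L, ceiling(l$thickness / opts$film_dx)), opts$max_film_nodes)
      dx <- c(dx, rep(l$thickness / n, n))
      k <- c(k, rep(l$k, n))
      rhocp <- c(rhocp, rep(l$rho * l$cp, n))
    }
  }
  list(dx = dx, k = k, rhocp = rhocp)
}

#' Simulate the heater temperature response to a constant-power step
#'
#' Solves 1-D transient conduction through the layered stack with the total
#' electrical power deposited at the lumped heater node; the solver resolves
#' how the heat splits between the substrate side and the culture side from
#' the stack itself. Implicit (backward Euler) finite differences on a
#' non-uniform grid; unconditionally stable, energy-conserving.
#'
#' @param stack A [layer_stack].
#' @param power Total heating power, W (>= 0).
#' @param duration Pulse duration, s.
#' @param sample_rate Output sampling rate, Hz. Output times are
#'   `1/sample_rate, 2/sample_rate, ..., duration` (the first sample after
#'   onset; dT = 0 at onset itself).
#' @param opts A [grid_opts()] list.
#' @param couple_alpha If non-`NULL`, the temperature coefficient of
#'   resistance used for constant-current electro-thermal coupling: the
#'   injected power follows `power * (1 + couple_alpha * dT_heater)` instead
#'   of staying constant. Off (`NULL`) by default.
#' @return A `transient_curve`: data.frame with columns `t` (s) and `dT` (K),
#'   with attributes `energy_balance` (relative error of stored vs injected
#'   energy) and `q_flux` (areal power, W m^-2).
#' @examples
#' curve <- simulate_step_response(default_sensor_stack(), power = 0.5,
#'                                 duration = 0.1, sample_rate = 500)
#' head(curve)
#' @export
simulate_step_response <- function(stack, power, duration, sample_rate = 500,
                                   opts = grid_opts(), couple_alpha = NULL) {
  if (!inherits(stack, "layer_stack")) stop_tp("stack must be a layer_stack", "configuration_error")
  if (power < 0) stop_tp("power must be >= 0", "configuration_error")
  if (duration <= 0) stop_tp("duration must be positive", "configuration_error")
  n_out <- as.integer(round(duration * sample_rate))
  if (n_out < 1) stop_tp("duration * sample_rate must be >= 1 sample", "configuration_error")

  # domain must comfortably contain the pulse's penetration into each
  # semi-infinite layer, else the zero-flux truncation contaminates dT
  for (l in c(stack$above, stack$below)) {
    if (l$semi_infinite) {
      pen <- probing_depth(thermal_diffusivity(l), duration)
      if (opts$domain_depth < 2 * pen) {
        stop_tp(sprintf(
          "domain_depth %.3g m < 2x thermal penetration %.3g m in layer '%s'; enlarge grid_opts(domain_depth=)",
          opts$domain_depth, pen, l$name), "configuration_error")
      }
    }
  }

  below <- discretise_side(stack$below, opts)
  above <- discretise_side(stack$above, opts)
  nb <- length(below$dx)

  # chain: far-below ... heater ... far-above; heater is a zero-width node
  dx <- c(rev(below$dx), 0, above$dx)
  kk <- c(rev(below$k), 1, above$k)
  C  <- c(rev(below$rhocp * below$dx), stack$heater_areal_heat_capacity,
          above$rhocp * above$dx)
  half <- 0.5 * dx / kk
  G <- 1 / (half[-length(half)] + half[-1])

  dt_out <- 1 / sample_rate
  raw <- opts$first_ratio^(0:(opts$first_substeps - 1))
  sub_first <- dt_out * raw / sum(raw)

  res <- fd_step_heater(C, G, heater = nb + 1L, q0 = power / stack$heater_area,
                        n_out = n_out, dt_out = dt_out, sub_first = sub_first,
                        substeps = opts$substeps,
                        couple = !is.null(couple_alpha),
                        alpha = couple_alpha %||% 0)

  stored <- sum(C * res$field)
  ebal <- if (res$energy_in > 0) (stored - res$energy_in) / res$energy_in else 0
  out <- data.frame(t = seq_len(n_out) * dt_out, dT = res$dT_heater)
  class(out) <- c("transient_curve", "data.frame")
  attr(out, "energy_balance") <- ebal
  attr(out, "q_flux") <- power / stack$heater_area
  out
}
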