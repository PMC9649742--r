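# Boltzmann constant in pN nm / K
.kB <- 1.380649e-2

#' Experimental environment: temperature, thermal energy and viscosity
#'
#' Bundles the thermodynamic constants every force-spectroscopy formula in
#' this package depends on. The thermal energy \eqn{k_B T} (pN nm) is the
#' primary quantity; the absolute temperature is derived from it (or vice
#' versa) so the two always agree through the Boltzmann constant. The dynamic
#' viscosity is used only by the Brownian-dynamics simulators, where it sets
#' the bead drag coefficient and hence the fluctuation correlation time.
#'
#' @param thermal_energy Thermal energy \eqn{k_B T} in pN nm. Default 4.114,
#'   i.e. room temperature.
#' @param temperature Absolute temperature in K. Supply either this or
#'   `thermal_energy`; the other is derived.
#' @param viscosity Dynamic viscosity in Pa s (default: water, 1.0e-3).
#'
#' @return An object of class `flow_environment`.
#' @examples
#' env <- flow_environment()
#' env$thermal_energy
#' @export
flow_environment <- function(thermal_energy = 4.114, temperature = NULL,
                             viscosity = 1.0e-3) {
  if (!is.null(temperature)) {
    stopifnot(is.numeric(temperature), length(temperature) == 1L,
              is.finite(temperature), temperature > 0)
    thermal_energy <- .kB * temperature
  } else {
    stopifnot(is.numeric(thermal_energy), length(thermal_energy) == 1L,
              is.finite(thermal_energy), thermal_energy > 0)
    temperature <- thermal_energy / .kB
  }
  stopifnot(is.numeric(viscosity), length(viscosity) == 1L,
            is.finite(viscosity), viscosity > 0)
  structure(
    list(temperature = temperature, thermal_energy = thermal_energy,
         viscosity = viscosity),
    class = "flow_environment"
  )
}

#' @export
print.flow_environment <- function(x, ...) {
  cat(sprintf("<flow_environment> T = %.2f K, kBT = %.4f pN nm, eta = %.3g Pa s\n",
              x$temperature, x$thermal_energy, x$viscosity))
  invisible(x)
}

as_flow_environment <- function(env) {
  if (inherits(env, "flow_environment")) return(env)
  if (is.null(env)) return(flow_environment())
  if (is.list(env)) return(do.call(flow_environment, env))
  stop("`env` must be a flow_environment object", call. = FALSE)
}

#' Bond energy-landscape parameters
#'
#' The two Bell-model parameters that characterize a slip bond: the
#' dissociation rate at zero force and the distance from the bound state to
#' the transition state along the pulling coordinate.
#'
#' @param k_off Zero-force dissociation rate in 1/s.
#' @param delta_x Distance to the transition state in nm.
#'
#' @return An object of class `energy_landscape`.
#' @examples
#' energy_landscape(k_off = 4.0e-4, delta_x = 0.76)
#' @export
energy_landscape <- function(k_off, delta_x) {
  stopifnot(is.numeric(k_off), length(k_off) == 1L, is.finite(k_off), k_off > 0,
            is.numeric(delta_x), length(delta_x) == 1L, is.finite(delta_x),
            delta_x > 0)
  structure(list(k_off = k_off, delta_x = delta_x), class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> k_off = %.3g 1/s, delta_x = %.3g nm\n",
              x$k_off, x$delta_x))
  invisible(x)
}

#' Reduced rupture-model parameters
#'
#' Collapses a landscape, a loading rate and the thermal energy into the two
#' reduced parameters in which the rupture-force density and cumulative
#' distribution are naturally written: `a1 = k_off / f_dot` (1/pN) and
#' `a2 = delta_x / (kB T)` (1/pN).
#'
#' @param landscape An [energy_landscape()].
#' @param f_dot Force loading rate in pN/s; must be positive.
#' @param env A [flow_environment()].
#'
#' @return A list with elements `a1` and `a2`.
#' @export
reduced_params <- function(landscape, f_dot, env = flow_environment()) {
  env <- as_flow_environment(env)
  check_loading_rate(f_dot)
  list(a1 = landscape$k_off / f_dot,
       a2 = landscape$delta_x / env$thermal_energy)
}

check_loading_rate <- function(f_dot) {
  if (!is.numeric(f_dot) || length(f_dot) != 1L || !is.finite(f_dot) ||
      f_dot <= 0) {
    stop("loading rate `f_dot` must be a single positive finite number (pN/s)",
         call. = FALSE)
  }
  invisible(f_dot)
}
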