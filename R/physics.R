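# Stokes settling model: forward (density -> terminal velocity) and inverse
# (terminal velocity -> density) for a rigid sphere in an unbounded quiescent
# fluid, plus the unit conversions used at every public boundary.
#
# Canonical units at the interface: radius um, velocity um/s, mass density
# fg/um^3 (numerically equal to kg/m^3), weight ng, volume um^3. Internally
# all hydrodynamics are evaluated in SI.

#' Standard gravitational acceleration (m/s^2)
#'
#' Fixed constant used by the settling model.
#' @export
GRAVITY <- 9.80665

# unit conversions at the SI boundary
.UM_TO_M <- 1e-6
.M_S_TO_UM_S <- 1e6
# 1 fg/um^3 == 1 kg/m^3 exactly, so densities pass through unchanged.
.FG_UM3_TO_NG <- 1e-6 # fg -> ng for weights

#' Fluid properties of the suspension medium
#'
#' Container for the settling medium (typically DPBS, water-like) in which
#' the spheroid free-falls. Density is expressed in fg/um^3, numerically
#' identical to kg/m^3.
#'
#' @param density Fluid mass density in fg/um^3 (= kg/m^3). Default 1005,
#'   a DPBS-like buffer at room temperature.
#' @param viscosity Dynamic viscosity in Pa s. Default 0.89e-3 (water-like
#'   at 25 degrees C).
#' @param temperature Temperature in degrees C (informational unless the
#'   fluid is derived via [fluid_from_temperature()]).
#' @return An object of class `fluid_properties` with fields `density`,
#'   `viscosity`, `temperature`.
#' @examples
#' fl <- fluid_properties()
#' fl$density
#' @export
fluid_properties <- function(density = 1005, viscosity = 0.89e-3,
                             temperature = 25) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop_invalid("fluid density must be a single positive number (fg/um^3)")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop_invalid("fluid dynamic viscosity must be a single positive number (Pa s)")
  }
  structure(
    list(density = as.numeric(density), viscosity = as.numeric(viscosity),
         temperature = as.numeric(temperature)),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf(
    "Fluid: density %.1f fg/um^3, viscosity %.3e Pa s, %.1f degC\n",
    x$density, x$viscosity, x$temperature
  ))
  invisible(x)
}

as_fluid <- function(fluid) {
  if (inherits(fluid, "fluid_properties")) return(fluid)
  if (is.list(fluid)) {
    return(fluid_properties(
      density = fluid$density %||% 1005,
      viscosity = fluid$viscosity %||% 0.89e-3,
      temperature = fluid$temperature %||% 25
    ))
  }
  stop_invalid("fluid must be a fluid_properties object or a list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive water-like fluid properties from temperature
#'
#' Evaluates empirical pure-water correlations: a Vogel-type equation for
#' dynamic viscosity (mu = 2.414e-5 * 10^(247.8 / (T_K - 140)) Pa s) and a
#' Kell-style polynomial for density. The measurement buffer (DPBS) is
#' treated as water-like; explicit `density` / `viscosity` overrides are
#' returned verbatim.
#'
#' @param temperature Temperature in degrees C, within 4-40.
#' @param density Optional override, fg/um^3; returned as given.
#' @param viscosity Optional override, Pa s; returned as given.
#' @return A [fluid_properties()] object.
#' @examples
#' fluid_from_temperature(25)
#' fluid_from_temperature(25, density = 1005, viscosity = 0.9e-3)
#' @export
fluid_from_temperature <- function(temperature, density = NULL,
                                   viscosity = NULL) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature)) {
    stop_invalid("temperature must be a single finite number (degrees C)")
  }
  if (temperature < 4 || temperature > 40) {
    stop_invalid(sprintf(
      "temperature %.1f degC outside supported range 4-40 degC", temperature
    ))
  }
  if (is.null(viscosity)) {
    t_k <- temperature + 273.15
    viscosity <- 2.414e-5 * 10^(247.8 / (t_k - 140))
  }
  if (is.null(density)) {
    # Kell (1975) density of air-free water, kg/m^3 == fg/um^3
    t <- temperature
    density <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
                  46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
                  280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
  }
  fluid_properties(density = density, viscosity = viscosity,
                   temperature = temperature)
}

check_radius <- function(radius_um, allow_zero = FALSE) {
  if (!is.numeric(radius_um) || any(!is.finite(radius_um))) {
    stop_invalid("radius must be finite numeric (um)")
  }
  bad <- if (allow_zero) any(radius_um < 0) else any(radius_um <= 0)
  if (bad) {
    stop_invalid(sprintf("radius must be %s (um)",
                         if (allow_zero) "non-negative" else "positive"))
  }
  invisible(radius_um)
}

#' Terminal settling velocity of a sphere (forward Stokes model)
#'
#' Buoyancy-corrected Stokes settling of a rigid sphere in an unbounded
#' quiescent fluid: v = 2 r^2 g (rho_s - rho_f) / (9 mu), evaluated in SI and
#' returned in um/s. Positive velocity means sinking (the fall direction);
#' negative means rising. An optional multiplicative wall-correction factor
#' rescales the velocity for confined channels.
#'
#' @param radius_um Sphere radius, um (> 0).
#' @param mass_density Sphere mass density, fg/um^3.
#' @param fluid A [fluid_properties()] object (or list with density,
#'   viscosity).
#' @param g Gravitational acceleration, m/s^2.
#' @param wall_correction Multiplicative velocity factor (default 1 =
#'   unbounded fluid).
#' @return Terminal velocity in um/s (vectorised over `radius_um` and
#'   `mass_density`).
#' @examples
#' terminal_velocity(75, 1050, fluid_properties(1005, 1.0e-3))
#' @export
terminal_velocity <- function(radius_um, mass_density,
                              fluid = fluid_properties(), g = GRAVITY,
                              wall_correction = 1) {
  fluid <- as_fluid(fluid)
  check_radius(radius_um)
  if (!is.numeric(mass_density) || any(!is.finite(mass_density)) ||
      any(mass_density <= 0)) {
    stop_invalid("mass_density must be positive (fg/um^3)")
  }
  r_m <- radius_um * .UM_TO_M
  drho <- mass_density - fluid$density # fg/um^3 == kg/m^3
  v_ms <- 2 * r_m^2 * g * drho / (9 * fluid$viscosity) * wall_correction
  v_ms * .M_S_TO_UM_S
}

#' Mass density from observed settling motion (inverse Stokes model)
#'
#' Algebraic inverse of [terminal_velocity()]:
#' rho_s = rho_f + 9 mu v / (2 r^2 g). Negative velocities (rising objects)
#' are allowed and yield densities below the fluid's.
#'
#' @param velocity_um_s Observed terminal velocity, um/s (positive =
#'   sinking).
#' @param radius_um Sphere radius, um (> 0).
#' @inheritParams terminal_velocity
#' @return Mass density in fg/um^3.
#' @examples
#' mass_density_from_motion(551.6, 75, fluid_properties(1005, 1.0e-3))
#' @export
mass_density_from_motion <- function(velocity_um_s, radius_um,
                                     fluid = fluid_properties(), g = GRAVITY,
                                     wall_correction = 1) {
  fluid <- as_fluid(fluid)
  check_radius(radius_um)
  if (!is.numeric(velocity_um_s) || any(!is.finite(velocity_um_s))) {
    stop_invalid("velocity must be finite numeric (um/s)")
  }
  r_m <- radius_um * .UM_TO_M
  v_ms <- velocity_um_s / .M_S_TO_UM_S / wall_correction
  fluid$density + 9 * fluid$viscosity * v_ms / (2 * r_m^2 * g)
}

#' Weight and volume of a spherical spheroid
#'
#' Volume V = (4/3) pi r^3 in um^3 and total mass ("weight") W = rho V in ng
#' (1 fg/um^3 * 1 um^3 = 1 fg = 1e-6 ng).
#'
#' @param mass_density Mass density, fg/um^3 (> 0).
#' @param radius_um Radius, um (>= 0).
#' @return List with `weight_ng` and `volume_um3` (vectorised).
#' @examples
#' weight_and_volume(1050, 75)
#' @export
weight_and_volume <- function(mass_density, radius_um) {
  check_radius(radius_um, allow_zero = TRUE)
  if (!is.numeric(mass_density) || any(!is.finite(mass_density)) ||
      any(mass_density <= 0)) {
    stop_invalid("mass_density must be positive (fg/um^3)")
  }
  volume <- 4 / 3 * pi * radius_um^3
  list(weight_ng = mass_density * volume * .FG_UM3_TO_NG,
       volume_um3 = volume)
}

#' Particle Reynolds number of the settling motion
#'
#' Re = rho_f |v| d / mu with d = 2r, evaluated in SI. Used as a validity
#' guard for the Stokes (creeping-flow) model: a `spherofall_warning` is
#' raised when Re exceeds `threshold`.
#'
#' @inheritParams mass_density_from_motion
#' @param threshold Stokes-regime guard (default 0.1); set `NA` to disable
#'   the warning.
#' @return Dimensionless Reynolds number (vectorised).
#' @examples
#' reynolds_number(551.6, 75, fluid_properties(1005, 1.0e-3))
#' @export
reynolds_number <- function(velocity_um_s, radius_um,
                            fluid = fluid_properties(), threshold = 0.1) {
  fluid <- as_fluid(fluid)
  check_radius(radius_um, allow_zero = TRUE)
  v_ms <- abs(velocity_um_s) / .M_S_TO_UM_S
  d_m <- 2 * radius_um * .UM_TO_M
  re <- fluid$density * v_ms * d_m / fluid$viscosity
  if (!is.na(threshold) && any(re > threshold)) {
    warn_spherofall(sprintf(
      "Reynolds number %.3g exceeds Stokes threshold %.3g; creeping-flow model may be inaccurate",
      max(re), threshold
    ), class = "spherofall_reynolds_warning")
  }
  re
}

#' Full physical record of a settling spheroid
#'
#' Combines the inverse Stokes model with the weight/volume relations to
#' produce the per-spheroid triplet reported by the method: diameter (um),
#' weight (ng) and mass density (fg/um^3), plus the Reynolds number and a
#' buoyancy classification.
#'
#' @inheritParams mass_density_from_motion
#' @param reynolds_threshold Stokes-regime guard passed to
#'   [reynolds_number()].
#' @return An object of class `spheroid_physical`: list with `radius_um`,
#'   `diameter_um`, `terminal_velocity_um_s`, `mass_density_fg_um3`,
#'   `weight_ng`, `volume_um3`, `reynolds`, `buoyancy_flag`
#'   (sinking/neutral/rising).
#' @examples
#' spheroid_physical(551.6, 75, fluid_properties(1005, 1.0e-3))
#' @export
spheroid_physical <- function(velocity_um_s, radius_um,
                              fluid = fluid_properties(), g = GRAVITY,
                              wall_correction = 1, reynolds_threshold = 0.1) {
  fluid <- as_fluid(fluid)
  rho <- mass_density_from_motion(velocity_um_s, radius_um, fluid, g,
                                  wall_correction)
  wv <- weight_and_volume(rho, radius_um)
  re <- reynolds_number(velocity_um_s, radius_um, fluid,
                        threshold = reynolds_threshold)
  flag <- if (velocity_um_s > 0) "sinking" else if (velocity_um_s < 0)
    "rising" else "neutral"
  structure(
    list(radius_um = radius_um, diameter_um = 2 * radius_um,
         terminal_velocity_um_s = velocity_um_s,
         mass_density_fg_um3 = rho, weight_ng = wv$weight_ng,
         volume_um3 = wv$volume_um3, reynolds = re, buoyancy_flag = flag,
         fluid = fluid),
    class = "spheroid_physical"
  )
}

#' @export
print.spheroid_physical <- function(x, ...) {
  cat(sprintf(
    paste0("Spheroid: diameter %.1f um, weight %.1f ng, ",
           "mass density %.1f fg/um^3\n  terminal velocity %.1f um/s (%s), ",
           "Re %.3g\n"),
    x$diameter_um, x$weight_ng, x$mass_density_fg_um3,
    x$terminal_velocity_um_s, x$buoyancy_flag, x$reynolds
  ))
  invisible(x)
}
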