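#' Define a molecule by molecular weight and bulk density
#'
#' Small molecules are modelled as hard spheres whose molar volume follows
#' from molecular weight and bulk density; this is the input to the
#' Stokes-Einstein transport chain ([hydrodynamic_radius()],
#' [stokes_einstein_diffusivity()], [channel_crossing_time()]).
#'
#' @param name Molecule name (single string).
#' @param mw Molecular weight, g/mol. Must be > 0.
#' @param density Bulk density, g/cm^3. Must be > 0.
#' @return An object of class `"molecule"`.
#' @examples
#' molecule("temozolomide", mw = 194.2, density = 2.0)
#' @export
molecule <- function(name, mw, density) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("`name` must be a single string", call. = FALSE)
  }
  check_scalar(mw, "mw", positive = TRUE)
  check_scalar(density, "density", positive = TRUE)
  structure(list(name = name, mw = mw, density = density),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: MW = %g g/mol, density = %g g/cm^3\n",
              x$name, x$mw, x$density))
  invisible(x)
}

#' Physical conditions for Stokes-Einstein transport calculations
#'
#' Defaults are the package's calibration for the perfusion experiments:
#' body temperature (310.15 K) with a dynamic viscosity of 1.01e-3 Pa s.
#' The Boltzmann constant and Avogadro number are fixed CODATA values.
#'
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity of the solvent, Pa s.
#' @return An object of class `"transport_conditions"`.
#' @export
transport_conditions <- function(temperature = 310.15, viscosity = 1.01e-3) {
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(viscosity, "viscosity", positive = TRUE)
  structure(list(temperature = temperature,
                 viscosity = viscosity,
                 boltzmann = 1.380649e-23,   # J/K
                 avogadro = 6.02214076e23),  # 1/mol
            class = "transport_conditions")
}

#' Hydrodynamic radius of a molecule modelled as a hard sphere
#'
#' The molar volume `MW / (N_A * rho)` is equated to the volume of a sphere,
#' giving `r = (3 MW / (4 pi N_A rho))^(1/3)`. Independent of temperature
#' and viscosity.
#'
#' @param molecule A [molecule()].
#' @param conditions A [transport_conditions()] (supplies Avogadro's number).
#' @return Hydrodynamic radius in metres.
#' @examples
#' hydrodynamic_radius(molecule("brilliant blue FCF", 792.9, 1.0))
#' @export
hydrodynamic_radius <- function(molecule, conditions = transport_conditions()) {
  stopifnot(inherits(molecule, "molecule"),
            inherits(conditions, "transport_conditions"))
  # molar volume in cm^3 per molecule, cube root in cm, then to metres
  vol_cm3 <- molecule$mw / (conditions$avogadro * molecule$density)
  r_cm <- (3 * vol_cm3 / (4 * pi))^(1 / 3)
  r_cm / 100
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = k T / (6 pi mu r)` for a sphere of radius `r` in a solvent of
#' viscosity `mu` at absolute temperature `T`.
#'
#' @param radius Hydrodynamic radius, m. Must be > 0.
#' @param conditions A [transport_conditions()].
#' @return Diffusion coefficient in m^2/s.
#' @export
stokes_einstein_diffusivity <- function(radius,
                                        conditions = transport_conditions()) {
  check_scalar(radius, "radius", positive = TRUE)
  stopifnot(inherits(conditions, "transport_conditions"))
  conditions$boltzmann * conditions$temperature /
    (6 * pi * conditions$viscosity * radius)
}

#' Diffusive crossing time over a distance
#'
#' One-dimensional diffusion time `t = x^2 / (2 D)` -- the time for a
#' molecule to diffuse across a channel of width `x`.
#'
#' @param diffusivity Diffusion coefficient, m^2/s. Must be > 0.
#' @param distance Diffusion distance, m. Must be >= 0.
#' @return Time in seconds.
#' @export
channel_crossing_time <- function(diffusivity, distance) {
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_scalar(distance, "distance", non_negative = TRUE)
  distance^2 / (2 * diffusivity)
}

#' Transport table for a panel of molecules
#'
#' Chains [hydrodynamic_radius()], [stokes_einstein_diffusivity()] and
#' [channel_crossing_time()] for each molecule, producing one row per
#' molecule with radius, diffusivity and the time to diffuse across
#' `distance` (default: the 150 um mixing-channel width).
#'
#' @param molecules A list of [molecule()] objects (non-empty).
#' @param conditions A [transport_conditions()].
#' @param distance Diffusion distance, m. Default 150e-6.
#' @return A data.frame with columns `name`, `mw_g_mol`, `density_g_cm3`,
#'   `radius_m`, `diffusivity_m2_s`, `crossing_time_s`.
#' @examples
#' transport_table(study_molecules())
#' @export
transport_table <- function(molecules,
                            conditions = transport_conditions(),
                            distance = 150e-6) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (!is.list(molecules) || length(molecules) == 0L) {
    stop("`molecules` must be a non-empty list of molecule objects",
         call. = FALSE)
  }
  rows <- lapply(molecules, function(m) {
    if (!inherits(m, "molecule")) {
      stop("all elements of `molecules` must be molecule objects",
           call. = FALSE)
    }
    r <- tryCatch(hydrodynamic_radius(m, conditions), error = function(e) {
      stop(sprintf("molecule '%s': %s", m$name, conditionMessage(e)),
           call. = FALSE)
    })
    d <- stokes_einstein_diffusivity(r, conditions)
    data.frame(name = m$name, mw_g_mol = m$mw, density_g_cm3 = m$density,
               radius_m = r, diffusivity_m2_s = d,
               crossing_time_s = channel_crossing_time(d, distance),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The dye and chemotherapeutic panel characterized on the device
#'
#' Brilliant Blue FCF (the mixing-visualization dye) and five FDA-approved
#' chemotherapeutics, with molecular weights (g/mol) and bulk densities
#' (g/cm^3) used throughout the transport analysis.
#'
#' @return A list of [molecule()] objects.
#' @export
study_molecules <- function() {
  list(
    molecule("Brilliant Blue FCF", 792.9, 1.0),
    molecule("Temozolomide", 194.2, 2.0),
    molecule("Paclitaxel", 853.9, 1.4),
    molecule("Doxorubicin", 543.5, 1.6),
    molecule("Carmustine", 214.1, 1.7),
    molecule("Lomustine", 233.7, 1.4)
  )
}

#' Mean linear velocity in parallel rectangular channels
#'
#' Splits a total volumetric flow evenly across `n_channels` rectangular
#' channels of cross-section `width * height`.
#'
#' @param total_flow Total volumetric flow rate, m^3/s.
#' @param n_channels Number of parallel channels.
#' @param width,height Channel cross-section, m.
#' @return Mean linear velocity, m/s.
#' @examples
#' # two inlets at 1 uL/min feeding four 150 x 50 um channels: ~1.1 mm/s
#' mean_velocity(2e-9 / 60, 4, 150e-6, 50e-6)
#' @export
mean_velocity <- function(total_flow, n_channels, width, height) {
  check_scalar(total_flow, "total_flow", positive = TRUE)
  check_scalar(n_channels, "n_channels", positive = TRUE)
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  (total_flow / n_channels) / (width * height)
}
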