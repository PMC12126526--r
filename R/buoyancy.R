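# Physical design model for the helium-balloon counterbalance: gas mixture
# density, buoyant lift, payload capacity, tether kinematics and an
# inertial-force audit. SI units throughout (m, kg, s, N); convenience
# conversions (litres, grams) happen only at interface boundaries.

#' Default gas and physical constants
#'
#' Dry-air and helium densities at 20 degrees C and sea-level pressure, and
#' standard gravity. The density pair reproduces the nominal lift of a 15 L
#' party balloon filled with an 80/20 helium-air mixture (about 12 g).
#'
#' @name buoyancy-constants
#' @keywords internal
NULL

RHO_AIR_20C <- 1.204    # kg m^-3, dry air, 20 C, 101.325 kPa
RHO_HE_20C <- 0.1664    # kg m^-3, helium, 20 C, 101.325 kPa
STANDARD_GRAVITY <- 9.80665  # m s^-2

#' Construct a gas mixture
#'
#' A gas mixture is a set of components, each with a density and a volume
#' fraction. Fractions must be non-negative and sum to one.
#'
#' @param names Character vector of component names.
#' @param densities Numeric vector of component densities (kg m^-3), all > 0.
#' @param fractions Numeric vector of volume fractions, non-negative, summing
#'   to 1 within `1e-9`.
#' @return An object of class `gas_mixture`.
#' @examples
#' gas_mixture(c("helium", "air"), c(0.1664, 1.204), c(0.8, 0.2))
#' @export
gas_mixture <- function(names, densities, fractions) {
  stopifnot(length(names) == length(densities),
            length(densities) == length(fractions))
  if (any(!is.finite(densities)) || any(densities <= 0)) {
    stop("component densities must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("volume fractions must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("volume fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(
    list(components = tibble::tibble(name = as.character(names),
                                     density = as.numeric(densities),
                                     fraction = as.numeric(fractions))),
    class = "gas_mixture"
  )
}

#' Helium-air filling mixture
#'
#' Convenience constructor for the standard balloon filling: a helium-air
#' blend given as the helium volume fraction (default 80% helium, 20% air).
#'
#' @param he_fraction Helium volume fraction in `[0, 1]`.
#' @param rho_he,rho_air Component densities (kg m^-3); defaults at 20 C.
#' @return A `gas_mixture`.
#' @export
helium_air_mixture <- function(he_fraction = 0.8,
                               rho_he = RHO_HE_20C,
                               rho_air = RHO_AIR_20C) {
  stopifnot(he_fraction >= 0, he_fraction <= 1)
  gas_mixture(c("helium", "air"), c(rho_he, rho_air),
              c(he_fraction, 1 - he_fraction))
}

#' Density of a gas mixture
#'
#' Volume-fraction-weighted mean of the component densities.
#'
#' @param gas A `gas_mixture`.
#' @return Density in kg m^-3.
#' @examples
#' mixture_density(helium_air_mixture(0.8))  # 0.37392
#' @export
mixture_density <- function(gas) {
  stopifnot(inherits(gas, "gas_mixture"))
  sum(gas$components$density * gas$components$fraction)
}

#' Construct a balloon specification
#'
#' Describes one inflated balloon assembly: envelope volume, filling gas,
#' envelope mass and rigging mass (cord plus hook). The default masses are
#' a 3 g envelope and 2 g of rigging, a 5 g assembly total.
#'
#' @param volume_m3 Inflated volume in m^3 (15 L = 0.015).
#' @param gas A `gas_mixture`; defaults to the 80/20 helium-air blend.
#' @param envelope_mass_kg Mass of the balloon envelope (kg).
#' @param rigging_mass_kg Mass of cord and hook (kg).
#' @param gravity Gravitational acceleration (m s^-2).
#' @return An object of class `balloon_spec`.
#' @export
balloon_spec <- function(volume_m3 = 0.015,
                         gas = helium_air_mixture(),
                         envelope_mass_kg = 0.003,
                         rigging_mass_kg = 0.002,
                         gravity = STANDARD_GRAVITY) {
  stopifnot(inherits(gas, "gas_mixture"))
  if (!is.finite(volume_m3) || volume_m3 <= 0) {
    stop("volume must be > 0", call. = FALSE)
  }
  if (envelope_mass_kg < 0 || rigging_mass_kg < 0) {
    stop("masses must be >= 0", call. = FALSE)
  }
  if (!is.finite(gravity) || gravity <= 0) {
    stop("gravity must be > 0", call. = FALSE)
  }
  structure(
    list(volume_m3 = volume_m3, gas = gas,
         envelope_mass_kg = envelope_mass_kg,
         rigging_mass_kg = rigging_mass_kg,
         gravity = gravity),
    class = "balloon_spec"
  )
}

#' Buoyant lift of a balloon
#'
#' Net buoyant force of the inflated envelope, `F = (rho_air - rho_gas) g V`,
#' and the equivalent mass it can support (`F / g`). Negative values mean
#' the filling gas is denser than the surrounding air.
#'
#' @param spec A `balloon_spec`.
#' @param rho_air Ambient air density (kg m^-3).
#' @return A list with `force_n` and `equivalent_mass_kg`.
#' @examples
#' buoyant_lift(balloon_spec(0.015))$equivalent_mass_kg  # ~0.0125 kg
#' @export
buoyant_lift <- function(spec, rho_air = RHO_AIR_20C) {
  stopifnot(inherits(spec, "balloon_spec"))
  drho <- rho_air - mixture_density(spec$gas)
  force <- drho * spec$gravity * spec$volume_m3
  list(force_n = force, equivalent_mass_kg = force / spec$gravity)
}

#' Payload capacity of a balloon assembly
#'
#' Mass of additional head-mounted weight the assembly can cancel: the
#' equivalent lift mass minus the envelope and rigging masses. Not clipped
#' at zero; a negative value flags an underweighted balloon.
#'
#' @inheritParams buoyant_lift
#' @return Payload mass in kg (may be negative).
#' @examples
#' payload_capacity(balloon_spec(0.015))  # ~0.0075 kg
#' @export
payload_capacity <- function(spec, rho_air = RHO_AIR_20C) {
  lift <- buoyant_lift(spec, rho_air)
  lift$equivalent_mass_kg - (spec$envelope_mass_kg + spec$rigging_mass_kg)
}

#' Balloon volume required for a target payload
#'
#' Closed-form inverse of [payload_capacity()]:
#' `V = (payload + assembly mass) / (rho_air - rho_gas)`.
#'
#' @param target_payload_kg Desired payload mass (kg).
#' @param gas Filling `gas_mixture`.
#' @param assembly_mass_kg Total envelope + rigging mass (kg).
#' @param rho_air Ambient air density (kg m^-3).
#' @return Required volume in m^3.
#' @export
required_volume <- function(target_payload_kg,
                            gas = helium_air_mixture(),
                            assembly_mass_kg = 0.005,
                            rho_air = RHO_AIR_20C) {
  drho <- rho_air - mixture_density(gas)
  if (drho <= 0) {
    stop("filling gas is not lighter than air; no volume is feasible",
         call. = FALSE)
  }
  v <- (target_payload_kg + assembly_mass_kg) / drho
  if (v < 0) {
    stop("target payload below -assembly mass is infeasible", call. = FALSE)
  }
  v
}

#' Construct a tether geometry
#'
#' The balloon cord runs through a low-friction guide anchored above the
#' arena. With a taut straight cord whose free length equals the anchor
#' height, lateral displacement of the animal raises the balloon.
#'
#' @param anchor_height_m Height of the anchor point above the arena (m).
#' @param lateral_offset_m Horizontal displacement of the animal from the
#'   point directly below the anchor (m).
#' @return An object of class `tether_geometry`.
#' @export
tether_geometry <- function(anchor_height_m, lateral_offset_m) {
  if (!is.finite(anchor_height_m) || anchor_height_m <= 0) {
    stop("anchor height must be > 0", call. = FALSE)
  }
  if (!is.finite(lateral_offset_m) || lateral_offset_m < 0) {
    stop("lateral offset must be >= 0", call. = FALSE)
  }
  structure(list(anchor_height_m = anchor_height_m,
                 lateral_offset_m = lateral_offset_m),
            class = "tether_geometry")
}

#' Vertical balloon displacement from animal movement
#'
#' Taut-cord model: the cord length equals the anchor height when the animal
#' is centered, so moving a lateral distance `d` lengthens the animal-anchor
#' segment to `sqrt(h^2 + d^2)` and lifts the balloon by the difference.
#' A 1.2 m anchor and 18 cm offset give 1.34 cm.
#'
#' @param geom A `tether_geometry`.
#' @return Vertical displacement in m.
#' @examples
#' tether_vertical_displacement(tether_geometry(1.2, 0.18))  # 0.0134 m
#' @export
tether_vertical_displacement <- function(geom) {
  stopifnot(inherits(geom, "tether_geometry"))
  sqrt(geom$anchor_height_m^2 + geom$lateral_offset_m^2) - geom$anchor_height_m
}

#' Inertial force of an added head-mounted mass
#'
#' Buoyancy cancels weight but not mass: accelerating the head still requires
#' `F = m a` of extra force. A 6 g mass at 1.5 m s^-2 needs 9 mN.
#'
#' @param added_mass_kg Added mass (kg), >= 0.
#' @param acceleration_m_s2 Head acceleration (m s^-2).
#' @return Force in N.
#' @examples
#' inertial_force(0.006, 1.5)  # 0.009 N
#' @export
inertial_force <- function(added_mass_kg, acceleration_m_s2) {
  if (!is.finite(added_mass_kg) || added_mass_kg < 0) {
    stop("added mass must be >= 0", call. = FALSE)
  }
  added_mass_kg * acceleration_m_s2
}

#' Balloon design report
#'
#' Summarises a design in interface units (litres, grams, centimetres):
#' mixture density, lift, payload capacity, tether displacement and the
#' inertial force audit for a given payload and peak acceleration.
#'
#' @param volume_l Balloon volume in litres.
#' @param he_fraction Helium volume fraction of the filling gas.
#' @param rho_air Ambient air density (kg m^-3).
#' @param assembly_g Envelope + rigging mass in grams.
#' @param anchor_m Anchor height (m); `NA` to skip tether output.
#' @param offset_m Lateral offset (m).
#' @param payload_g Added head-mounted mass in grams for the inertia audit.
#' @param accel Peak acceleration (m s^-2) for the inertia audit.
#' @return A named list of design quantities (also printable as JSON).
#' @export
buoyancy_report <- function(volume_l = 15, he_fraction = 0.8,
                            rho_air = RHO_AIR_20C, assembly_g = 5,
                            anchor_m = 1.2, offset_m = 0.18,
                            payload_g = 6, accel = 1.5) {
  gas <- helium_air_mixture(he_fraction, rho_air = rho_air)
  spec <- balloon_spec(volume_m3 = volume_l / 1000, gas = gas,
                       envelope_mass_kg = assembly_g / 1000,
                       rigging_mass_kg = 0)
  lift <- buoyant_lift(spec, rho_air)
  out <- list(
    volume_l = volume_l,
    he_fraction = he_fraction,
    mixture_density_kg_m3 = mixture_density(gas),
    lift_force_n = lift$force_n,
    lift_equivalent_g = lift$equivalent_mass_kg * 1000,
    payload_capacity_g = payload_capacity(spec, rho_air) * 1000,
    inertial_force_mn = inertial_force(payload_g / 1000, accel) * 1000
  )
  if (is.finite(anchor_m)) {
    out$tether_vertical_displacement_cm <-
      tether_vertical_displacement(tether_geometry(anchor_m, offset_m)) * 100
  }
  out
}
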