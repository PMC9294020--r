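#' Fluid physical properties
#'
#' Constructor for the working-fluid properties used by every conductance
#' closure.  Defaults are those of urine at body temperature, which is
#' hydraulically indistinguishable from water.
#'
#' @param density Fluid density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return An object of class `fluid_props`.
#' @examples
#' fluid_props()
#' @export
fluid_props <- function(density = 997.044, viscosity = 0.001) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("fluid density must be a single positive number (kg/m^3)")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("dynamic viscosity must be a single positive number (Pa s)")
  }
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Piecewise-linear axial profile of the ureter lumen
#'
#' The ureter lumen diameter is described by ordered stations
#' `(axial position, diameter)`; the diameter between stations is obtained
#' by linear interpolation.  Positions are measured from the ureteropelvic
#' junction (UPJ, x = 0) towards the vesicoureteric junction (VUJ,
#' x = `total_length`).
#'
#' @param positions Strictly increasing axial positions in m, starting at 0.
#' @param diameters Lumen diameters in m at each position, all positive.
#' @return An object of class `axial_profile` with fields `positions`,
#'   `diameters` and `total_length`.
#' @seealso [default_ureter_profile()]
#' @export
axial_profile <- function(positions, diameters) {
  if (length(positions) != length(diameters) || length(positions) < 2L) {
    stop("need at least two (position, diameter) stations of equal length")
  }
  if (any(!is.finite(positions)) || any(!is.finite(diameters))) {
    stop("profile stations must be finite")
  }
  if (positions[1L] != 0) stop("profile must start at axial position 0")
  if (any(diff(positions) <= 0)) {
    stop("axial positions must be strictly increasing")
  }
  if (any(diameters <= 0)) stop("lumen diameters must be strictly positive")
  structure(list(positions = as.numeric(positions),
                 diameters = as.numeric(diameters),
                 total_length = positions[length(positions)]),
            class = "axial_profile")
}

#' Default ureter lumen profile
#'
#' Builds the reference ureter used throughout: the lumen tapers from
#' 6.0 mm at the UPJ to 3.0 mm over the proximal third, holds approximately
#' 2.5 mm in the middle third and 2.4 mm in the distal third, and widens to
#' 2.9 mm at the VUJ.  The total length is not a printed dimension of the
#' reference geometry; 240 mm (a typical adult/porcine ureter) is used and
#' can be changed, since only the relative axial structure drives the flow
#' partition.
#'
#' @param total_length Ureter length in m (default 0.240).
#' @return An `axial_profile`.
#' @export
default_ureter_profile <- function(total_length = 0.240) {
  if (!is.numeric(total_length) || length(total_length) != 1L ||
      !is.finite(total_length) || total_length <= 0) {
    stop("total_length must be a single positive number (m)")
  }
  L <- total_length
  # fractions of length: taper over the proximal third, short blends between
  # the constant-diameter middle and distal thirds, VUJ flare over the last
  # ~3% of the length
  f <- c(0, 1 / 3, 1 / 3 + 1 / 60, 2 / 3, 2 / 3 + 1 / 60, 29 / 30, 1)
  d <- c(6.0, 3.0, 2.5, 2.5, 2.4, 2.4, 2.9) * 1e-3
  axial_profile(f * L, d)
}

#' Interpolated lumen diameter
#'
#' @param profile An `axial_profile`.
#' @param x Axial positions in m (vectorised), inside `[0, total_length]`.
#' @return Lumen diameters in m.
#' @export
lumen_diameter <- function(profile, x) {
  stopifnot(inherits(profile, "axial_profile"))
  if (any(x < -1e-12 | x > profile$total_length + 1e-12)) {
    stop("axial position outside [0, total_length]")
  }
  stats::approx(profile$positions, profile$diameters, xout = x,
                rule = 2)$y
}

#' Effective lumen diameter seen by the annular compartment
#'
#' The printed middle/distal ureter diameters (2.5/2.4 mm) do not exceed the
#' stent outer diameter (2.5 mm), which would close the extraluminal annulus
#' entirely, yet extraluminal flow is observed there.  A minimum radial
#' clearance between stent and ureter wall is therefore enforced:
#' `d_eff(x) = max(d(x), OD + 2 * min_clearance)`.
#'
#' @param profile An `axial_profile`.
#' @param stent A `stent_spec`.
#' @param x Axial positions in m.
#' @param min_clearance Minimum radial gap in m (default 1e-4, i.e. 0.1 mm).
#' @return Effective lumen diameters in m.
#' @export
effective_lumen_diameter <- function(profile, stent, x,
                                     min_clearance = 1e-4) {
  d <- lumen_diameter(profile, x)
  pmax(d, stent$outer_diameter + 2 * min_clearance)
}

#' Double-J stent specification
#'
#' @param inner_diameter Lumen diameter of the stent in m.
#' @param outer_diameter Outer diameter in m.
#' @param shaft_length Length of the stent shaft lying in the ureter, in m.
#' @param side_hole_diameter Diameter of each side hole in m.
#' @param n_side_holes Total number of side holes (coil + shaft).
#' @param holes_per_coil Side holes located on each of the two coils.
#' @param permeability Darcy permeability of the stent wall in m^2; 0 encodes
#'   an unporous wall.
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(inner_diameter = 1.5e-3,
                       outer_diameter = 2.5e-3,
                       shaft_length = 0.240,
                       side_hole_diameter = 0.8e-3,
                       n_side_holes = 42L,
                       holes_per_coil = 4L,
                       permeability = 0) {
  if (!(inner_diameter > 0) || !(outer_diameter > inner_diameter)) {
    stop("need 0 < inner_diameter < outer_diameter")
  }
  if (!(shaft_length > 0)) stop("shaft_length must be positive")
  if (!(side_hole_diameter > 0)) {
    stop("side_hole_diameter must be positive")
  }
  n_side_holes <- as.integer(n_side_holes)
  holes_per_coil <- as.integer(holes_per_coil)
  if (n_side_holes < 0L || holes_per_coil < 0L ||
      (n_side_holes > 0L && n_side_holes < 2L * holes_per_coil)) {
    stop("n_side_holes must be 0 or at least 2 * holes_per_coil")
  }
  if (!is.numeric(permeability) || length(permeability) != 1L ||
      !is.finite(permeability) || permeability < 0) {
    stop("permeability must be a single non-negative number (m^2)")
  }
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 shaft_length = shaft_length,
                 side_hole_diameter = side_hole_diameter,
                 n_side_holes = n_side_holes,
                 holes_per_coil = holes_per_coil,
                 permeability = permeability,
                 wall_thickness = (outer_diameter - inner_diameter) / 2),
            class = "stent_spec")
}

#' Default stent specification
#'
#' Reference double-J stent: 1.5 mm inner and 2.5 mm outer diameter, 42 side
#' holes of 0.8 mm, four of which sit on each coil; the remaining 34 holes
#' are distributed along the shaft.
#'
#' @param permeability Wall permeability in m^2 (default 0, unporous).
#' @param shaft_length Shaft length in m; defaults to the default ureter
#'   length so the stent spans UPJ to VUJ.
#' @return A `stent_spec`.
#' @export
default_stent_spec <- function(permeability = 0, shaft_length = 0.240) {
  stent_spec(inner_diameter = 1.5e-3, outer_diameter = 2.5e-3,
             shaft_length = shaft_length, side_hole_diameter = 0.8e-3,
             n_side_holes = 42L, holes_per_coil = 4L,
             permeability = permeability)
}

#' Axial positions of the stent side holes
#'
#' Hole indices run 1..42 from kidney to bladder: holes 1-4 sit on the
#' kidney coil, holes 5-38 are spaced uniformly along the shaft (hole j at
#' `shaft_length * (j - 4 - 0.5) / 34`), and holes 39-42 sit on the bladder
#' coil.  Coil holes are tagged and carry the end-of-shaft axial position;
#' they are lumped into the reservoir attachments by the network assembler.
#'
#' @param stent A `stent_spec`.
#' @param profile An `axial_profile`; the stent must span the whole ureter.
#' @return A data frame with columns `hole`, `position` (m) and `region`
#'   (one of `"kidney_coil"`, `"shaft"`, `"bladder_coil"`).
#' @export
side_hole_positions <- function(stent, profile) {
  stopifnot(inherits(stent, "stent_spec"), inherits(profile, "axial_profile"))
  if (stent$shaft_length < profile$total_length - 1e-12) {
    stop("stent shaft (", stent$shaft_length * 1e3,
         " mm) is shorter than the ureter (",
         profile$total_length * 1e3, " mm)")
  }
  if (stent$n_side_holes == 0L) {
    return(data.frame(hole = integer(0), position = numeric(0),
                      region = character(0)))
  }
  n_coil <- stent$holes_per_coil
  n_shaft <- stent$n_side_holes - 2L * n_coil
  L <- stent$shaft_length
  shaft_pos <- L * (seq_len(n_shaft) - 0.5) / n_shaft
  data.frame(
    hole = seq_len(stent$n_side_holes),
    position = c(rep(0, n_coil), shaft_pos, rep(L, n_coil)),
    region = c(rep("kidney_coil", n_coil), rep("shaft", n_shaft),
               rep("bladder_coil", n_coil))
  )
}

#' Occlusion specification
#'
#' A complete obstruction of the extraluminal annulus (e.g. by a mid-ureter
#' stone) over an axial extent.  The default extent is 6 mm, centred midway
#' between side holes 21 and 22 of the default stent.
#'
#' @param present Logical; is the ureter occluded?
#' @param start Axial start position in m.
#' @param length Axial extent in m.
#' @return An object of class `occlusion_spec`.
#' @export
occlusion_spec <- function(present = FALSE, start = 0.117, length = 0.006) {
  if (present) {
    if (!(length > 0) || !(start >= 0)) {
      stop("occlusion start/length must be non-negative and positive")
    }
  }
  structure(list(present = isTRUE(present), start = start, length = length),
            class = "occlusion_spec")
}

#' Assemble a simulation scenario
#'
#' A scenario bundles the geometry, the stent, the boundary pressures and
#' the fluid, and validates their mutual consistency.  The pressure boundary
#' conditions default to a constant gauge pressure of 97.8 Pa at the kidney
#' pelvis and 0 Pa at the bladder.
#'
#' @param profile An `axial_profile` (default [default_ureter_profile()]).
#' @param stent A `stent_spec`.
#' @param occlusion An `occlusion_spec`.
#' @param fluid A `fluid_props`.
#' @param inlet_pressure Kidney-pelvis gauge pressure in Pa.
#' @param outlet_pressure Bladder gauge pressure in Pa.
#' @param side_holes_enabled Logical; include side-hole exchange paths.
#' @param min_clearance Minimum stent-ureter radial gap in m; see
#'   [effective_lumen_diameter()].
#' @param case_id Optional reference case number 1..9 (set by
#'   [make_scenario()]).
#' @return An object of class `scenario`.
#' @export
scenario <- function(profile = default_ureter_profile(),
                     stent = default_stent_spec(),
                     occlusion = occlusion_spec(FALSE),
                     fluid = fluid_props(),
                     inlet_pressure = 97.8,
                     outlet_pressure = 0,
                     side_holes_enabled = stent$n_side_holes > 0L,
                     min_clearance = 1e-4,
                     case_id = NA_integer_) {
  sc <- structure(list(profile = profile, stent = stent,
                       occlusion = occlusion, fluid = fluid,
                       inlet_pressure = inlet_pressure,
                       outlet_pressure = outlet_pressure,
                       side_holes_enabled = isTRUE(side_holes_enabled),
                       min_clearance = min_clearance,
                       case_id = as.integer(case_id)),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario
#'
#' Checks every structural invariant of a `scenario`; violations raise an
#' error (they are never silently repaired).
#'
#' @param sc A `scenario`.
#' @return `sc`, invisibly, if valid.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (!inherits(sc$profile, "axial_profile")) stop("profile: wrong type")
  if (!inherits(sc$stent, "stent_spec")) stop("stent: wrong type")
  if (!inherits(sc$occlusion, "occlusion_spec")) stop("occlusion: wrong type")
  if (!inherits(sc$fluid, "fluid_props")) stop("fluid: wrong type")
  if (!is.finite(sc$inlet_pressure) || !is.finite(sc$outlet_pressure)) {
    stop("boundary pressures must be finite")
  }
  if (sc$inlet_pressure < sc$outlet_pressure) {
    stop("inlet_pressure must be >= outlet_pressure for forward flow")
  }
  if (!(sc$min_clearance > 0)) {
    d_all <- lumen_diameter(sc$profile, sc$profile$positions)
    closed <- d_all <= sc$stent$outer_diameter
    if (any(closed)) {
      stop(sprintf(
        "annulus closed at axial position %.1f mm (lumen %.2f mm <= stent OD %.2f mm) and min_clearance is not positive",
        sc$profile$positions[which(closed)[1L]] * 1e3,
        d_all[which(closed)[1L]] * 1e3,
        sc$stent$outer_diameter * 1e3))
    }
  }
  if (sc$side_holes_enabled && sc$stent$n_side_holes == 0L) {
    stop("side_holes_enabled is TRUE but the stent has no side holes")
  }
  if (sc$occlusion$present) {
    holes <- side_hole_positions(sc$stent, sc$profile)
    shaft <- holes[holes$region == "shaft", ]
    if (nrow(shaft) >= 18L) {
      # the obstruction must sit strictly between side holes 21 and 22
      p21 <- holes$position[holes$hole == 21L]
      p22 <- holes$position[holes$hole == 22L]
      o1 <- sc$occlusion$start
      o2 <- sc$occlusion$start + sc$occlusion$length
      if (!(o1 > p21 && o2 < p22)) {
        stop(sprintf(
          "occlusion [%.2f, %.2f] mm must lie strictly between side holes 21 (%.2f mm) and 22 (%.2f mm)",
          o1 * 1e3, o2 * 1e3, p21 * 1e3, p22 * 1e3))
      }
    } else {
      o2 <- sc$occlusion$start + sc$occlusion$length
      if (o2 > sc$profile$total_length) {
        stop("occlusion extends beyond the ureter")
      }
    }
  }
  invisible(sc)
}

#' @export
#' @method print scenario
print.scenario <- function(x, ...) {
  cat("Stented-ureter flow scenario",
      if (!is.na(x$case_id)) sprintf("(reference case %d)", x$case_id),
      "\n")
  cat(sprintf("  ureter length:     %.1f mm (%.1f -> %.1f mm lumen)\n",
              x$profile$total_length * 1e3, x$profile$diameters[1L] * 1e3,
              x$profile$diameters[length(x$profile$diameters)] * 1e3))
  cat(sprintf("  stent:             ID %.2f mm, OD %.2f mm, %d side holes%s\n",
              x$stent$inner_diameter * 1e3, x$stent$outer_diameter * 1e3,
              x$stent$n_side_holes,
              if (x$side_holes_enabled) "" else " (disabled)"))
  cat(sprintf("  wall permeability: %s m^2\n",
              format(x$stent$permeability, digits = 3)))
  cat(sprintf("  occlusion:         %s\n",
              if (x$occlusion$present) {
                sprintf("complete, %.1f mm at %.1f mm",
                        x$occlusion$length * 1e3, x$occlusion$start * 1e3)
              } else "none"))
  cat(sprintf("  pressure drop:     %.1f -> %.1f Pa\n",
              x$inlet_pressure, x$outlet_pressure))
  invisible(x)
}
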