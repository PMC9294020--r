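# The nine reference case studies: wall permeability (m^2), number of side
# holes, and whether the mid-ureter is completely occluded.
table1_cases <- data.frame(
  case_id = 1:9,
  permeability = c(0, 1e-10, 1e-11, 1e-12, 1e-14, 1e-18, 1e-10, 0, 1e-10),
  n_side_holes = c(42L, 42L, 42L, 42L, 42L, 42L, 0L, 42L, 42L),
  occluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
)

#' Reference case studies
#'
#' Returns one of the nine reference scenarios: cases 1-6 sweep the wall
#' permeability (0, i.e. unporous, then 1e-10 down to 1e-18 m^2) on the
#' unoccluded ureter with a 42-hole stent; case 7 is the porous
#' (1e-10 m^2) stent without side holes; cases 8 and 9 are the unporous and
#' porous (1e-10 m^2) stents in the completely occluded ureter.  All cases
#' share the 97.8/0 Pa boundary pressures and urine-like fluid properties.
#'
#' @param case_id Integer 1..9.
#' @param total_length Ureter length in m (default 0.240); not part of the
#'   case definition, exposed for sensitivity studies.
#' @return A validated `scenario` with `case_id` set.
#' @examples
#' make_scenario(9)
#' @export
make_scenario <- function(case_id, total_length = 0.240) {
  if (length(case_id) != 1L || !case_id %in% 1:9) {
    stop("case_id must be a single integer in 1..9")
  }
  row <- table1_cases[table1_cases$case_id == case_id, ]
  profile <- default_ureter_profile(total_length)
  stent <- default_stent_spec(permeability = row$permeability,
                              shaft_length = total_length)
  if (row$n_side_holes == 0L) {
    stent$n_side_holes <- 0L
    stent$holes_per_coil <- 0L
  }
  occ <- if (row$occluded) {
    default_occlusion(profile, default_stent_spec(shaft_length = total_length))
  } else {
    occlusion_spec(FALSE)
  }
  scenario(profile = profile, stent = stent, occlusion = occ,
           fluid = fluid_props(),
           inlet_pressure = 97.8, outlet_pressure = 0,
           side_holes_enabled = row$n_side_holes > 0L,
           case_id = as.integer(case_id))
}

#' Default occlusion for a given geometry
#'
#' A 6 mm complete obstruction centred midway between side holes 21 and 22.
#'
#' @param profile An `axial_profile`.
#' @param stent A `stent_spec` with at least 18 shaft holes.
#' @param length Occlusion extent in m (default 0.006).
#' @return An `occlusion_spec`.
#' @export
default_occlusion <- function(profile, stent, length = 0.006) {
  holes <- side_hole_positions(stent, profile)
  p21 <- holes$position[holes$hole == 21L]
  p22 <- holes$position[holes$hole == 22L]
  if (length(p21) != 1L || length(p22) != 1L) {
    stop("stent has no side holes 21/22; specify the occlusion explicitly")
  }
  if (p22 - p21 <= length) {
    stop("occlusion longer than the gap between side holes 21 and 22")
  }
  mid <- (p21 + p22) / 2
  occlusion_spec(TRUE, start = mid - length / 2, length = length)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Randomised synthetic scenario
#'
#' Draws a scenario around the reference geometry for property testing:
#' geometric dimensions are perturbed uniformly within `+/- perturb` of
#' their defaults, the wall permeability is either 0 (with probability
#' `p_unporous`) or log-uniform over `permeability_range`, and the occlusion
#' is present with probability `p_occluded`.  Identical seeds give identical
#' scenarios.
#'
#' @param seed Integer seed.
#' @param perturb Relative half-width of the geometric perturbation
#'   (default 0.2).
#' @param permeability_range Two permeabilities in m^2 bounding the
#'   log-uniform draw (default `c(1e-18, 1e-10)`).
#' @param p_unporous Probability of drawing an unporous stent (default 0.15).
#' @param p_occluded Probability of an occluded ureter (default 0.25).
#' @param side_holes `TRUE`, `FALSE`, or `NA` to randomise (default).
#' @return A validated `scenario`.
#' @export
random_scenario <- function(seed, perturb = 0.2,
                            permeability_range = c(1e-18, 1e-10),
                            p_unporous = 0.15, p_occluded = 0.25,
                            side_holes = NA) {
  if (length(seed) != 1L || !is.finite(seed)) stop("seed must be an integer")
  if (!(perturb >= 0 && perturb < 0.5)) stop("perturb must be in [0, 0.5)")
  if (length(permeability_range) != 2L ||
      any(permeability_range <= 0) ||
      permeability_range[1L] > permeability_range[2L]) {
    stop("permeability_range must be two positive increasing values")
  }
  with_seed(seed, {
    u <- function() stats::runif(1L, 1 - perturb, 1 + perturb)
    L <- 0.240 * u()
    d_upj <- 6.0e-3 * u()
    d_taper <- max(3.0e-3 * u(), 2.8e-3)
    d_mid <- 2.5e-3 * u()
    d_dist <- 2.4e-3 * u()
    d_vuj <- 2.9e-3 * u()
    f <- c(0, 1 / 3, 1 / 3 + 1 / 60, 2 / 3, 2 / 3 + 1 / 60, 29 / 30, 1)
    profile <- axial_profile(f * L, c(d_upj, d_taper, d_mid, d_mid, d_dist,
                                      d_dist, d_vuj))
    alpha <- if (stats::runif(1L) < p_unporous) {
      0
    } else {
      10^stats::runif(1L, log10(permeability_range[1L]),
                      log10(permeability_range[2L]))
    }
    stent <- default_stent_spec(permeability = alpha, shaft_length = L)
    holes_on <- if (is.na(side_holes)) stats::runif(1L) < 0.8 else
      isTRUE(side_holes)
    if (!holes_on) {
      stent$n_side_holes <- 0L
      stent$holes_per_coil <- 0L
    }
    occluded <- holes_on && stats::runif(1L) < p_occluded
    occ <- if (occluded) {
      # random extent, kept strictly between side holes 21 and 22
      gap <- side_hole_positions(stent, profile)
      p21 <- gap$position[gap$hole == 21L]
      p22 <- gap$position[gap$hole == 22L]
      len <- stats::runif(1L, 0.3, 0.85) * (p22 - p21)
      mid <- (p21 + p22) / 2
      occlusion_spec(TRUE, start = mid - len / 2, length = len)
    } else {
      occlusion_spec(FALSE)
    }
    scenario(profile = profile, stent = stent, occlusion = occ,
             fluid = fluid_props(),
             inlet_pressure = 97.8, outlet_pressure = 0,
             side_holes_enabled = holes_on)
  })
}
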