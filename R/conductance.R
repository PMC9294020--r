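# Laminar mass-flow conductances: every closure returns G in kg s^-1 Pa^-1
# such that mdot = G * dP.  All closures are linear in the pressure drop;
# inertial (quadratic) losses are neglected throughout, which keeps the whole
# network linear (Reynolds numbers in the stented ureter are far below the
# 2300 laminar threshold).

new_conductance <- function(value, kind) {
  if (!is.finite(value) || value < 0) {
    stop("conductance must be finite and non-negative, got ", value)
  }
  structure(list(value = value, kind = kind), class = "edge_conductance")
}

#' @export
#' @method print edge_conductance
print.edge_conductance <- function(x, ...) {
  cat(sprintf("<%s conductance: %.4g kg/s/Pa>\n", x$kind, x$value))
  invisible(x)
}

#' Hagen-Poiseuille pipe conductance
#'
#' Fully developed laminar flow in a circular pipe:
#' `G = rho * pi * d^4 / (128 * mu * L)`.
#'
#' @param diameter Pipe diameter in m.
#' @param length Pipe length in m.
#' @param fluid A [fluid_props()].
#' @return An `edge_conductance` of kind `"intra_pipe"`.
#' @export
pipe_conductance <- function(diameter, length, fluid = fluid_props()) {
  if (!(diameter > 0)) stop("pipe diameter must be positive")
  if (!(length > 0)) stop("pipe length must be positive")
  G <- fluid$density * pi * diameter^4 / (128 * fluid$viscosity * length)
  new_conductance(G, "intra_pipe")
}

#' Concentric-annulus conductance
#'
#' Laminar flow in the annular gap between the stent outer wall and the
#' ureter lumen:
#' `G = rho * pi / (8 mu L) * (Ro^4 - Ri^4 - (Ro^2 - Ri^2)^2 / ln(Ro/Ri))`.
#' The `Ri -> 0` limit recovers [pipe_conductance()] with `d = 2 Ro`; the
#' `Ri -> Ro` limit closes the annulus (G -> 0).
#'
#' @param outer_diameter Lumen (outer wall) diameter in m.
#' @param inner_diameter Stent outer diameter in m, `< outer_diameter`.
#' @param length Axial length in m.
#' @param fluid A [fluid_props()].
#' @return An `edge_conductance` of kind `"extra_annulus"`.
#' @export
annulus_conductance <- function(outer_diameter, inner_diameter, length,
                                fluid = fluid_props()) {
  if (!(inner_diameter > 0)) stop("inner diameter must be positive")
  if (inner_diameter >= outer_diameter) {
    stop("annulus closed: inner diameter >= outer diameter")
  }
  if (!(length > 0)) stop("annulus length must be positive")
  Ro <- outer_diameter / 2
  Ri <- inner_diameter / 2
  bracket <- Ro^4 - Ri^4 - (Ro^2 - Ri^2)^2 / log(Ro / Ri)
  G <- fluid$density * pi / (8 * fluid$viscosity * length) * max(bracket, 0)
  new_conductance(G, "extra_annulus")
}

#' Tapered-annulus conductance
#'
#' Conductance of an annular segment whose outer (ureter-lumen) diameter
#' varies axially, composed as a series chain of `n_sub` locally concentric
#' sub-segments (harmonic composition of conductances).  The outer diameter
#' is evaluated at each sub-segment midpoint via `diameter_fun`.
#'
#' @param x0,x1 Axial extent in m, `x1 > x0`.
#' @param inner_diameter Stent outer diameter in m.
#' @param diameter_fun Function mapping axial position (m) to the local
#'   effective lumen diameter (m).
#' @param fluid A [fluid_props()].
#' @param n_sub Number of sub-segments (minimum 8).
#' @return An `edge_conductance` of kind `"extra_annulus"`.
#' @export
tapered_annulus_conductance <- function(x0, x1, inner_diameter, diameter_fun,
                                        fluid = fluid_props(), n_sub = 8L) {
  if (!(x1 > x0)) stop("need x1 > x0")
  n_sub <- max(8L, as.integer(n_sub))
  edges <- seq(x0, x1, length.out = n_sub + 1L)
  mids <- (edges[-1L] + edges[-(n_sub + 1L)]) / 2
  lens <- diff(edges)
  R <- 0
  for (i in seq_len(n_sub)) {
    d_out <- diameter_fun(mids[i])
    g <- annulus_conductance(d_out, inner_diameter, lens[i], fluid)$value
    if (g <= 0) {
      stop(sprintf("annulus closed at axial position %.1f mm",
                   mids[i] * 1e3))
    }
    R <- R + 1 / g
  }
  new_conductance(1 / R, "extra_annulus")
}

#' Side-hole conductance
#'
#' Laminar exchange through one side hole of the stent wall, modelled as a
#' short Poiseuille tube through the wall thickness in series with a Sampson
#' orifice loss on its openings:
#' `R_vol = 128 mu t / (pi d^4) + 3 mu / (d/2)^3`, `G = rho / R_vol`.
#' `t = 0` reduces to the pure Sampson orifice.  A short-tube-only
#' alternative (no orifice term) is selectable for sensitivity checks.
#'
#' @param hole_diameter Side-hole diameter in m.
#' @param wall_thickness Stent wall thickness in m (>= 0).
#' @param fluid A [fluid_props()].
#' @param model `"sampson_tube"` (default) or `"tube_only"`.
#' @return An `edge_conductance` of kind `"side_hole"`.
#' @export
side_hole_conductance <- function(hole_diameter, wall_thickness,
                                  fluid = fluid_props(),
                                  model = c("sampson_tube", "tube_only")) {
  if (!(hole_diameter > 0)) stop("hole diameter must be positive")
  if (wall_thickness < 0) stop("wall thickness must be non-negative")
  model <- match.arg(model)
  mu <- fluid$viscosity
  R_tube <- 128 * mu * wall_thickness / (pi * hole_diameter^4)
  R_orifice <- 3 * mu / (hole_diameter / 2)^3
  R_vol <- switch(model,
                  sampson_tube = R_tube + R_orifice,
                  tube_only = if (wall_thickness > 0) R_tube else R_orifice)
  new_conductance(fluid$density / R_vol, "side_hole")
}

#' Radial Darcy conductance of the porous stent wall
#'
#' Darcy flow integrated radially across a cylindrical shell of permeability
#' `alpha` and axial extent `dz`:
#' `G = rho * 2 pi * alpha * dz / (mu * ln(r_o / r_i))`.
#' `alpha = 0` encodes the unporous wall and returns exactly 0.
#'
#' @param permeability Darcy permeability alpha in m^2 (>= 0).
#' @param inner_radius,outer_radius Shell radii in m, `outer > inner > 0`.
#' @param segment_length Axial extent dz in m.
#' @param fluid A [fluid_props()].
#' @return An `edge_conductance` of kind `"wall_darcy"`.
#' @export
wall_radial_conductance <- function(permeability, inner_radius, outer_radius,
                                    segment_length, fluid = fluid_props()) {
  if (permeability < 0) stop("permeability must be non-negative")
  if (!(inner_radius > 0) || !(outer_radius > inner_radius)) {
    stop("need outer_radius > inner_radius > 0")
  }
  if (!(segment_length > 0)) stop("segment_length must be positive")
  G <- fluid$density * 2 * pi * permeability * segment_length /
    (fluid$viscosity * log(outer_radius / inner_radius))
  new_conductance(G, "wall_darcy")
}

#' Reynolds number of an edge flow
#'
#' `Re = rho * u * D_h / mu` with the mean velocity recovered from the mass
#' flow, `u = mdot / (rho * A)`.  Flows with `Re < 2300` are flagged as
#' laminar.
#'
#' @param mass_flow Mass flow rate in kg/s (sign ignored).
#' @param hydraulic_diameter Characteristic length D_h in m.
#' @param flow_area Cross-sectional area A in m^2.
#' @param fluid A [fluid_props()].
#' @return A list with `Re`, `velocity` (m/s) and `laminar`.
#' @export
reynolds_number <- function(mass_flow, hydraulic_diameter, flow_area,
                            fluid = fluid_props()) {
  if (!(flow_area > 0)) stop("flow area must be positive")
  u <- abs(mass_flow) / (fluid$density * flow_area)
  Re <- fluid$density * u * hydraulic_diameter / fluid$viscosity
  list(Re = Re, velocity = u, laminar = Re < 2300)
}

# Peak-to-mean velocity ratio of the laminar concentric-annulus profile
# u(r) = C * (Ro^2 - r^2 - B * ln(Ro/r)), B = (Ro^2 - Ri^2) / ln(Ro/Ri);
# the maximum sits at r* = sqrt(B/2).
annulus_peak_factor <- function(outer_diameter, inner_diameter) {
  Ro <- outer_diameter / 2
  Ri <- inner_diameter / 2
  if (!(Ro > Ri) || !(Ri > 0)) stop("need Ro > Ri > 0")
  B <- (Ro^2 - Ri^2) / log(Ro / Ri)
  bracket <- Ro^4 - Ri^4 - (Ro^2 - Ri^2)^2 / log(Ro / Ri)
  umax_term <- Ro^2 - B / 2 - (B / 2) * log(2 * Ro^2 / B)
  2 * umax_term * (Ro^2 - Ri^2) / bracket
}
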