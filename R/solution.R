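#' Simulate urinary drainage through a stented ureter
#'
#' The main entry point: assembles the hydraulic network of a scenario,
#' solves it, and attaches the per-segment compartmental decomposition and
#' the per-side-hole fluxes.  The returned object has `print`, `summary`,
#' `plot`, `residuals` and `predict` methods.
#'
#' @param sc A [scenario()], or an integer 1..9 naming a reference case.
#' @param solver `"sparse"` (default) or `"dense"` (reference solver).
#' @return An object of class `stent_flow`; a `flow_solution` augmented
#'   with `segments` (see [segment_decomposition()]) and `holes`
#'   (see [side_hole_flows()]).
#' @examples
#' fit <- stent_flow(2)
#' summary(fit)
#' @export
stent_flow <- function(sc, solver = c("sparse", "dense")) {
  if (is.numeric(sc) && length(sc) == 1L) sc <- make_scenario(sc)
  solver <- match.arg(solver)
  net <- assemble_network(sc)
  sol <- if (solver == "sparse") solve_network(net) else
    brute_force_solve(net)
  sol$segments <- segment_decomposition(sol)
  sol$holes <- side_hole_flows(sol)
  class(sol) <- c("stent_flow", class(sol))
  sol
}

#' Per-segment compartmental flow decomposition
#'
#' At the reporting surface of every segment (midway between consecutive
#' side holes) the total axial mass flow is split into its intraluminal and
#' extraluminal parts, `m_total = m_intra + m_extra + m_wall`.  Axial
#' transport within the wall material is neglected by the network model
#' (the porous wall exchanges fluid radially), so `m_wall` is identically 0
#' and the radial exchange lumped in the segment is reported separately as
#' `wall_exchange` (positive into the lumen), together with each segment's
#' bounding side-hole indices.
#'
#' @param sol A `flow_solution`.
#' @param segment Optional segment index (0-based, 0 = UPJ end); default all.
#' @return A data frame with one row per reporting surface: `segment`,
#'   `hole_left`, `hole_right`, `x` (m), `m_intra`, `m_extra`, `m_wall`,
#'   `m_total`, `wall_exchange` (all kg/s).
#' @export
segment_decomposition <- function(sol, segment = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  net <- sol$network
  e <- sol$edges
  n_seg <- length(net$midpoints)
  segs <- 0:(n_seg - 1L)
  if (!is.null(segment)) {
    if (any(!segment %in% segs)) {
      stop("segment index out of range 0..", n_seg - 1L)
    }
    segs <- segment
  }
  axial <- e$kind %in% c("intra", "extra", "end")
  res <- lapply(segs, function(k) {
    mid <- net$midpoints[k + 1L]
    # flow crossing the surface just upstream of the midpoint node: the
    # chain edge whose extent ends at the midpoint
    left_of <- function(side) {
      sel <- axial & e$side == side & abs(e$x1 - mid) < 1e-12
      if (!any(sel)) 0 else sum(e$flow[sel])
    }
    m_i <- left_of("intra")
    m_e <- left_of("extra")
    w <- e$kind == "wall" & !is.na(e$segment) & e$segment == k
    data.frame(segment = k,
               hole_left = if (k >= 1L) net$hole_index[k] else NA_integer_,
               hole_right = if (k < n_seg - 1L) net$hole_index[k + 1L] else
                 NA_integer_,
               x = mid,
               m_intra = m_i, m_extra = m_e, m_wall = 0,
               m_total = m_i + m_e,
               wall_exchange = if (any(w)) sum(e$flow[w]) else 0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mass flow through each side hole
#'
#' @param sol A `flow_solution`.
#' @return A data frame `hole`, `x` (m), `flow` (kg/s; positive = into the
#'   stent lumen).  Empty when the stent has no side holes.
#' @export
side_hole_flows <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  e <- sol$edges[sol$edges$kind == "hole", ]
  if (nrow(e) == 0L) {
    return(data.frame(hole = integer(0), x = numeric(0), flow = numeric(0)))
  }
  out <- data.frame(hole = e$hole, x = e$x0, flow = e$flow)
  out[order(out$hole), , drop = FALSE]
}

#' Classify active side holes
#'
#' A side hole is "active" when it exchanges an appreciable fraction of the
#' total drained flow: `|flow| >= threshold * m_total`.
#'
#' @param hole_flows Data frame from [side_hole_flows()].
#' @param total_flow Total drained mass flow in kg/s (nonzero).
#' @param threshold Activity threshold as a fraction of `total_flow`,
#'   in (0, 1); default 0.01.
#' @return Integer vector of active hole indices.
#' @export
classify_active_holes <- function(hole_flows, total_flow, threshold = 0.01) {
  if (!is.finite(total_flow) || total_flow == 0) {
    stop("total_flow must be nonzero to define hole activity")
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)")
  }
  sort(hole_flows$hole[abs(hole_flows$flow) >=
                         threshold * abs(total_flow)])
}

#' Flow-distribution profile along the ureter
#'
#' The per-segment decomposition keyed for plotting against side-hole
#' number, mirroring the compartmental flow profiles of the reference
#' analysis.
#'
#' @param sol A `flow_solution`.
#' @return The [segment_decomposition()] table with an additional
#'   `position_frac` column (axial position as a fraction of ureter length).
#' @export
flow_profile <- function(sol) {
  seg <- if (!is.null(sol$segments)) sol$segments else
    segment_decomposition(sol)
  seg$position_frac <- seg$x / sol$network$scenario$profile$total_length
  seg
}

#' Mean and peak velocities at a reporting surface
#'
#' Mean velocities follow from `u = mdot / (rho A)`; peaks use the analytic
#' laminar profiles (parabolic in the lumen, peak/mean = 2; closed-form
#' concentric-annulus profile outside).
#'
#' @param sol A `flow_solution`.
#' @param segment Segment index (0-based).
#' @return A list with `intra_mean`, `intra_peak`, `extra_mean`,
#'   `extra_peak` in m/s.
#' @export
velocity_summary <- function(sol, segment) {
  seg <- segment_decomposition(sol, segment)
  sc <- sol$network$scenario
  st <- sc$stent
  rho <- sc$fluid$density
  A_in <- pi * st$inner_diameter^2 / 4
  u_in <- seg$m_intra / (rho * A_in)
  d_out <- effective_lumen_diameter(sc$profile, st, seg$x, sc$min_clearance)
  if (d_out > st$outer_diameter) {
    A_ex <- pi / 4 * (d_out^2 - st$outer_diameter^2)
    u_ex <- seg$m_extra / (rho * A_ex)
    pk <- annulus_peak_factor(d_out, st$outer_diameter)
  } else {
    u_ex <- 0
    pk <- 0
  }
  list(intra_mean = u_in, intra_peak = 2 * u_in,
       extra_mean = u_ex, extra_peak = pk * u_ex)
}

#' Reynolds-number report for every edge
#'
#' @param sol A `flow_solution`.
#' @return A data frame `kind`, `segment`, `Re`, `laminar`; the laminar
#'   flag is `Re < 2300`.
#' @export
reynolds_report <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  e <- sol$edges
  fl <- sol$network$scenario$fluid
  Re <- vapply(seq_len(nrow(e)), function(r) {
    reynolds_number(e$flow[r], e$D_h[r], e$area[r], fl)$Re
  }, numeric(1))
  data.frame(kind = e$kind, segment = e$segment, Re = Re,
             laminar = Re < 2300)
}

#' @export
#' @method print stent_flow
print.stent_flow <- function(x, ...) {
  sc <- x$network$scenario
  cat("Stented-ureter flow solution",
      if (!is.na(sc$case_id)) sprintf("(reference case %d)", sc$case_id),
      "\n")
  cat(sprintf("  total drained flow: %.4g kg/s under %.1f Pa\n",
              x$m_total, sc$inlet_pressure - sc$outlet_pressure))
  cat(sprintf("  max Kirchhoff residual: %.2g (relative)\n",
              x$max_residual))
  invisible(x)
}

#' @export
#' @method summary stent_flow
summary.stent_flow <- function(object, threshold = 0.01, ...) {
  seg <- object$segments
  rr <- reynolds_report(object)
  act <- if (nrow(object$holes)) {
    classify_active_holes(object$holes, object$m_total, threshold)
  } else {
    integer(0)
  }
  out <- list(scenario = object$network$scenario,
              m_total = mean(seg$m_total),
              m_intra_range = range(seg$m_intra),
              m_extra_range = range(seg$m_extra),
              max_Re = max(rr$Re), all_laminar = all(rr$laminar),
              active_holes = act, n_holes = nrow(object$holes),
              max_residual = object$max_residual)
  class(out) <- "summary.stent_flow"
  out
}

#' @export
#' @method print summary.stent_flow
print.summary.stent_flow <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  average total mass flow: %.4g kg/s\n", x$m_total))
  cat(sprintf("  intraluminal flow range: [%.3g, %.3g] kg/s\n",
              x$m_intra_range[1L], x$m_intra_range[2L]))
  cat(sprintf("  extraluminal flow range: [%.3g, %.3g] kg/s\n",
              x$m_extra_range[1L], x$m_extra_range[2L]))
  cat(sprintf("  max edge Reynolds number: %.1f (%s)\n", x$max_Re,
              if (x$all_laminar) "laminar" else "NOT laminar"))
  if (x$n_holes > 0L) {
    cat(sprintf("  active side holes (%d of %d): %s\n",
                length(x$active_holes), x$n_holes,
                paste(x$active_holes, collapse = " ")))
  }
  invisible(x)
}

#' @export
residuals.stent_flow <- function(object, ...) {
  e <- object$edges
  n <- nrow(object$network$nodes)
  imbalance <- numeric(n)
  for (r in seq_len(nrow(e))) {
    imbalance[e$from[r]] <- imbalance[e$from[r]] - e$flow[r]
    imbalance[e$to[r]] <- imbalance[e$to[r]] + e$flow[r]
  }
  stats::setNames(imbalance[!object$network$nodes$fixed],
                  object$network$nodes$name[!object$network$nodes$fixed])
}

#' Predict flows at a different driving pressure
#'
#' The network is linear, so all flows and gauge pressures scale with the
#' applied pressure drop; predictions at a new drop reuse the factorised
#' solution.
#'
#' @param object A `stent_flow`.
#' @param delta_p New kidney-bladder pressure drop in Pa.
#' @param ... Unused.
#' @return A list with the scaled `m_total`, `segments` and `holes`.
#' @export
predict.stent_flow <- function(object, delta_p, ...) {
  sc <- object$network$scenario
  s <- delta_p / (sc$inlet_pressure - sc$outlet_pressure)
  seg <- object$segments
  cols <- c("m_intra", "m_extra", "m_wall", "m_total", "wall_exchange")
  seg[cols] <- seg[cols] * s
  holes <- object$holes
  if (nrow(holes)) holes$flow <- holes$flow * s
  list(m_total = object$m_total * s, segments = seg, holes = holes)
}

#' @export
plot.stent_flow <- function(x, ...) {
  seg <- flow_profile(x)
  xx <- seg$position_frac
  graphics::matplot(xx, cbind(seg$m_total, seg$m_intra, seg$m_extra),
                    type = "l", lty = c(1, 2, 3), lwd = 2,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "axial position (fraction of ureter length)",
                    ylab = "mass flow rate (kg/s)", ...)
  graphics::legend("right", c("total", "intraluminal", "extraluminal"),
                   lty = c(1, 2, 3), lwd = 2,
                   col = c("black", "firebrick", "steelblue"), bty = "n")
  invisible(x)
}
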