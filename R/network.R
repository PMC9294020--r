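# Hydraulic-network assembly and linear solution.
#
# The stented ureter is discretised at the axial stations of the 34 shaft
# side holes.  Between consecutive stations (and between the first/last
# station and the UPJ/VUJ) lies one reporting segment; each segment owns a
# midpoint node pair where the distributed radial Darcy exchange through the
# porous wall is lumped.  Two parallel chains of axial conductances (stent
# lumen: Poiseuille pipes; extraluminal annulus: concentric-annulus elements
# with tapered composition) run from the kidney pelvis to the bladder, which
# are fixed-pressure reservoirs.  Side holes connect the chains at the
# stations; the stent end openings (with the coil holes lumped in parallel)
# attach the lumen chain to the reservoirs.
#
# Sign conventions: axial edges are oriented kidney -> bladder (positive
# flow drains towards the bladder); hole and wall edges are oriented
# extra -> intra (positive flow enters the stent lumen).

#' Assemble the hydraulic network of a scenario
#'
#' Builds nodes and laminar conductance edges for a [scenario()].  A
#' complete occlusion removes the extraluminal and wall edges whose axial
#' extent intersects it (the stone presses the ureter wall onto the stent),
#' leaving the lumen chain as the only local path.
#'
#' @param sc A validated `scenario`.
#' @return An object of class `hydraulic_network` with `nodes` and `edges`
#'   data frames, the boundary pressures, and the axial discretisation.
#' @export
assemble_network <- function(sc) {
  validate_scenario(sc)
  fl <- sc$fluid
  st <- sc$stent
  L <- sc$profile$total_length

  n_shaft <- if (st$n_side_holes > 0L) {
    st$n_side_holes - 2L * st$holes_per_coil
  } else {
    34L  # keep the reference reporting surfaces for hole-less stents
  }
  stations <- L * (seq_len(n_shaft) - 0.5) / n_shaft
  hole_index <- seq_len(n_shaft) + if (st$n_side_holes > 0L) {
    st$holes_per_coil
  } else {
    4L
  }
  b <- c(0, stations, L)               # segment boundaries, length n_shaft+2
  mids <- (b[-1L] + b[-length(b)]) / 2 # segment midpoints, length n_shaft+1
  seg_len <- diff(b)
  n_seg <- length(mids)

  d_eff <- function(x) {
    effective_lumen_diameter(sc$profile, st, x, sc$min_clearance)
  }
  closed <- d_eff(c(b, mids)) <= st$outer_diameter
  if (any(closed)) {
    xx <- c(b, mids)[which(closed)[1L]]
    stop(sprintf("annulus closed at axial position %.1f mm", xx * 1e3))
  }

  # ---- nodes ---------------------------------------------------------------
  # chain positions: m0, s1, m1, s2, ..., s_n, m_n
  chain_x <- numeric(2L * n_shaft + 1L)
  chain_is_mid <- logical(length(chain_x))
  chain_x[seq(1L, length(chain_x), by = 2L)] <- mids
  chain_is_mid[seq(1L, length(chain_x), by = 2L)] <- TRUE
  chain_x[seq(2L, length(chain_x), by = 2L)] <- stations

  mk_names <- function(side) {
    nm <- character(length(chain_x))
    nm[chain_is_mid] <- sprintf("%s_m%02d", side, seq_len(n_seg) - 1L)
    nm[!chain_is_mid] <- sprintf("%s_s%02d", side, seq_len(n_shaft))
    nm
  }
  nodes <- data.frame(
    name = c("pelvis", "bladder", mk_names("I"), mk_names("E")),
    side = c("reservoir", "reservoir",
             rep("intra", length(chain_x)), rep("extra", length(chain_x))),
    x = c(0, L, chain_x, chain_x),
    fixed = c(TRUE, TRUE, rep(FALSE, 2L * length(chain_x))),
    pressure = c(sc$inlet_pressure, sc$outlet_pressure,
                 rep(NA_real_, 2L * length(chain_x)))
  )
  nodes$id <- seq_len(nrow(nodes))
  idx <- function(name) nodes$id[match(name, nodes$name)]

  edges <- list()
  add_edge <- function(from, to, G, kind, side, seg = NA_integer_,
                       hole = NA_integer_, D_h = NA_real_, area = NA_real_,
                       x0 = NA_real_, x1 = NA_real_) {
    edges[[length(edges) + 1L]] <<- list(
      from = idx(from), to = idx(to), G = G, kind = kind, side = side,
      segment = seg, hole = hole, D_h = D_h, area = area, x0 = x0, x1 = x1)
  }

  seg_of <- function(x) findInterval(x, b, rightmost.closed = TRUE) - 1L
  A_in <- pi * st$inner_diameter^2 / 4
  one_seg <- L / n_shaft
  G_hole <- if (st$n_side_holes > 0L) {
    side_hole_conductance(st$side_hole_diameter, st$wall_thickness, fl)$value
  } else {
    0
  }

  # ---- intra chain ---------------------------------------------------------
  intra_names <- c("pelvis", mk_names("I"), "bladder")
  pos <- c(0, chain_x, L)
  for (i in seq_len(length(intra_names) - 1L)) {
    len <- pos[i + 1L] - pos[i]
    G_pipe <- pipe_conductance(st$inner_diameter, len, fl)$value
    at_end <- i == 1L || i == length(intra_names) - 1L
    if (at_end) {
      # stent end opening (short pipe of one segment length) with the coil
      # holes lumped in parallel, in series with the half-segment of lumen
      G_att <- pipe_conductance(st$inner_diameter, one_seg, fl)$value +
        st$holes_per_coil * G_hole
      G <- 1 / (1 / G_pipe + 1 / G_att)
      kind <- "end"
    } else {
      G <- G_pipe
      kind <- "intra"
    }
    add_edge(intra_names[i], intra_names[i + 1L], G, kind, "intra",
             seg = seg_of((pos[i] + pos[i + 1L]) / 2),
             D_h = st$inner_diameter, area = A_in,
             x0 = pos[i], x1 = pos[i + 1L])
  }

  # ---- extra chain ---------------------------------------------------------
  occ <- sc$occlusion
  occ_hit <- function(x0, x1) {
    occ$present && (max(x0, occ$start) < min(x1, occ$start + occ$length))
  }
  extra_names <- c("pelvis", mk_names("E"), "bladder")
  for (i in seq_len(length(extra_names) - 1L)) {
    x0 <- pos[i]; x1 <- pos[i + 1L]
    if (occ_hit(x0, x1)) next
    G <- tapered_annulus_conductance(x0, x1, st$outer_diameter, d_eff,
                                     fl, n_sub = 8L)$value
    d_mid <- d_eff((x0 + x1) / 2)
    at_end <- i == 1L || i == length(extra_names) - 1L
    add_edge(extra_names[i], extra_names[i + 1L], G,
             if (at_end) "end" else "extra", "extra",
             seg = seg_of((x0 + x1) / 2),
             D_h = d_mid - st$outer_diameter,
             area = pi / 4 * (d_mid^2 - st$outer_diameter^2),
             x0 = x0, x1 = x1)
  }

  # ---- side holes -----------------------------------------------------------
  if (sc$side_holes_enabled && st$n_side_holes > 0L) {
    A_hole <- pi * st$side_hole_diameter^2 / 4
    for (j in seq_len(n_shaft)) {
      add_edge(sprintf("E_s%02d", j), sprintf("I_s%02d", j), G_hole,
               "hole", NA_character_, hole = hole_index[j],
               D_h = st$side_hole_diameter, area = A_hole,
               x0 = stations[j], x1 = stations[j])
    }
  }

  # ---- porous wall ----------------------------------------------------------
  if (st$permeability > 0) {
    r_i <- st$inner_diameter / 2
    r_o <- st$outer_diameter / 2
    for (k in seq_len(n_seg)) {
      x0 <- b[k]; x1 <- b[k + 1L]
      if (occ_hit(x0, x1)) next
      G <- wall_radial_conductance(st$permeability, r_i, r_o,
                                   seg_len[k], fl)$value
      add_edge(sprintf("E_m%02d", k - 1L), sprintf("I_m%02d", k - 1L), G,
               "wall", NA_character_, seg = k - 1L,
               D_h = st$wall_thickness,
               area = 2 * pi * (r_i + r_o) / 2 * seg_len[k],
               x0 = x0, x1 = x1)
    }
  }

  edges <- data.frame(
    from = vapply(edges, function(r) as.integer(r$from), integer(1)),
    to = vapply(edges, function(r) as.integer(r$to), integer(1)),
    G = vapply(edges, function(r) r$G, numeric(1)),
    kind = vapply(edges, function(r) r$kind, character(1)),
    side = vapply(edges, function(r) as.character(r$side), character(1)),
    segment = vapply(edges, function(r) as.integer(r$segment), integer(1)),
    hole = vapply(edges, function(r) as.integer(r$hole), integer(1)),
    D_h = vapply(edges, function(r) r$D_h, numeric(1)),
    area = vapply(edges, function(r) r$area, numeric(1)),
    x0 = vapply(edges, function(r) r$x0, numeric(1)),
    x1 = vapply(edges, function(r) r$x1, numeric(1)))

  # drop free nodes left without any edge (e.g. the extraluminal midpoint
  # node inside an occluded segment)
  used <- nodes$fixed | nodes$id %in% c(edges$from, edges$to)
  dropped <- nodes$name[!used]
  nodes <- nodes[used, ]
  remap <- match(seq_len(max(edges$from, edges$to)), nodes$id)
  edges$from <- remap[edges$from]
  edges$to <- remap[edges$to]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges,
                 stations = stations, hole_index = hole_index,
                 boundaries = b, midpoints = mids, seg_lengths = seg_len,
                 dropped_nodes = dropped, scenario = sc),
            class = "hydraulic_network")
}

#' @export
#' @method print hydraulic_network
print.hydraulic_network <- function(x, ...) {
  cat(sprintf(
    "<hydraulic_network: %d nodes (%d fixed), %d edges [%s]>\n",
    nrow(x$nodes), sum(x$nodes$fixed), nrow(x$edges),
    paste(sprintf("%s:%d", names(table(x$edges$kind)),
                  as.integer(table(x$edges$kind))), collapse = ", ")))
  invisible(x)
}

# Free nodes reachable from the reservoirs through positive conductances.
check_connected <- function(net) {
  n <- nrow(net$nodes)
  adj <- vector("list", n)
  pos <- net$edges[net$edges$G > 0, c("from", "to")]
  for (i in seq_len(nrow(pos))) {
    adj[[pos$from[i]]] <- c(adj[[pos$from[i]]], pos$to[i])
    adj[[pos$to[i]]] <- c(adj[[pos$to[i]]], pos$from[i])
  }
  seen <- net$nodes$fixed
  queue <- which(seen)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen)) {
    stop("network is disconnected: node(s) ",
         paste(net$nodes$name[!seen], collapse = ", "),
         " cannot reach a reservoir")
  }
  invisible(TRUE)
}

finish_solution <- function(net, p_all, method, q_all = NULL) {
  e <- net$edges
  if (is.null(q_all)) {
    e$flow <- e$G * (p_all[e$from] - p_all[e$to])
  } else {
    # q is the pressure deficit below the highest reservoir (p + q = P_ref):
    # evaluating each edge drop in whichever representation is locally small
    # avoids the cancellation of near-reservoir drops against the large
    # absolute pressure, keeping Kirchhoff residuals near round-off
    dp_p <- p_all[e$from] - p_all[e$to]
    dp_q <- q_all[e$to] - q_all[e$from]
    use_q <- pmax(abs(q_all[e$from]), abs(q_all[e$to])) <
      pmax(abs(p_all[e$from]), abs(p_all[e$to]))
    e$flow <- e$G * ifelse(use_q, dp_q, dp_p)
  }
  pelvis <- net$nodes$id[net$nodes$name == "pelvis"]
  bladder <- net$nodes$id[net$nodes$name == "bladder"]
  out_pelvis <- sum(e$flow[e$from == pelvis]) - sum(e$flow[e$to == pelvis])
  in_bladder <- sum(e$flow[e$to == bladder]) - sum(e$flow[e$from == bladder])
  sol <- structure(list(network = net,
                        node_pressures = stats::setNames(p_all,
                                                         net$nodes$name),
                        edges = e,
                        m_total = out_pelvis,
                        pelvis_outflow = out_pelvis,
                        bladder_inflow = in_bladder,
                        method = method),
                   class = "flow_solution")
  sol$max_residual <- node_residuals(net, sol)
  sol
}

#' Solve the hydraulic network
#'
#' Eliminates the fixed-pressure reservoirs and solves the symmetric
#' positive-definite nodal conductance system `A p = rhs` with a direct
#' sparse factorisation, then recovers the signed mass flow on every edge.
#'
#' @param net A `hydraulic_network`.
#' @return An object of class `flow_solution` with node pressures (Pa),
#'   per-edge mass flows (kg/s), the total drained mass flow `m_total`, and
#'   the maximum relative Kirchhoff residual.
#' @export
solve_network <- function(net) {
  stopifnot(inherits(net, "hydraulic_network"))
  if (nrow(net$edges) == 0L) stop("empty network: no edges to solve")
  check_connected(net)
  nodes <- net$nodes
  free <- which(!nodes$fixed)
  if (length(free) == 0L) {
    # all pressures prescribed: flows follow directly
    return(finish_solution(net, nodes$pressure, "direct"))
  }
  fidx <- match(seq_len(nrow(nodes)), free)  # node id -> free index

  e <- net$edges[net$edges$G > 0, ]
  i_f <- fidx[e$from]; i_t <- fidx[e$to]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(length(free))
  both <- !is.na(i_f) & !is.na(i_t)
  # off-diagonal and diagonal stamps for free-free edges
  ii <- c(i_f[both], i_t[both], i_f[both], i_t[both])
  jj <- c(i_t[both], i_f[both], i_f[both], i_t[both])
  xx <- c(-e$G[both], -e$G[both], e$G[both], e$G[both])
  # edges touching a fixed node: diagonal stamp + rhs
  P_ref <- max(nodes$pressure[nodes$fixed])
  q_fix <- P_ref - nodes$pressure   # pressure deficit at the reservoirs
  rhs_q <- numeric(length(free))
  fix_a <- !is.na(i_f) & is.na(i_t)
  ii <- c(ii, i_f[fix_a]); jj <- c(jj, i_f[fix_a]); xx <- c(xx, e$G[fix_a])
  for (k in which(fix_a)) {
    rhs[i_f[k]] <- rhs[i_f[k]] + e$G[k] * nodes$pressure[e$to[k]]
    rhs_q[i_f[k]] <- rhs_q[i_f[k]] + e$G[k] * q_fix[e$to[k]]
  }
  fix_b <- is.na(i_f) & !is.na(i_t)
  ii <- c(ii, i_t[fix_b]); jj <- c(jj, i_t[fix_b]); xx <- c(xx, e$G[fix_b])
  for (k in which(fix_b)) {
    rhs[i_t[k]] <- rhs[i_t[k]] + e$G[k] * nodes$pressure[e$from[k]]
    rhs_q[i_t[k]] <- rhs_q[i_t[k]] + e$G[k] * q_fix[e$from[k]]
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(free), length(free)))
  dg <- Matrix::diag(A)
  if (any(dg <= 0)) {
    stop("singular nodal system: node(s) ",
         paste(nodes$name[free[dg <= 0]], collapse = ", "),
         " have no positive conductance attached")
  }
  As <- Matrix::forceSymmetric(A)
  refine <- function(rhs) {
    x <- as.numeric(Matrix::solve(As, rhs))
    # iterative refinement keeps the algebraic residual near round-off
    for (it in 1:2) {
      r <- rhs - as.numeric(As %*% x)
      if (max(abs(r)) == 0) break
      x <- x + as.numeric(Matrix::solve(As, r))
    }
    x
  }
  p_free <- refine(rhs)
  q_free <- refine(rhs_q)   # complementary system: q = P_ref - p

  p_all <- nodes$pressure
  p_all[free] <- p_free
  q_all <- q_fix
  q_all[free] <- q_free
  finish_solution(net, p_all, "sparse_cholesky", q_all)
}

#' Dense full-pivot reference solve
#'
#' Independent oracle for [solve_network()]: assembles the same nodal
#' balance as a dense matrix by direct edge stamping and solves it with a
#' column-pivoted LAPACK QR factorisation.  No sparsity or elimination
#' shortcut is shared with the production path.
#'
#' @param net A `hydraulic_network` with at most 500 nodes.
#' @return A `flow_solution`.
#' @export
brute_force_solve <- function(net) {
  stopifnot(inherits(net, "hydraulic_network"))
  if (nrow(net$nodes) > 500L) stop("brute-force solve limited to 500 nodes")
  if (nrow(net$edges) == 0L) stop("empty network: no edges to solve")
  check_connected(net)
  nodes <- net$nodes
  free <- which(!nodes$fixed)
  nf <- length(free)
  if (nf == 0L) {
    return(finish_solution(net, nodes$pressure, "direct"))
  }
  fidx <- match(seq_len(nrow(nodes)), free)
  A <- matrix(0, nf, nf)
  rhs <- numeric(nf)
  for (r in seq_len(nrow(net$edges))) {
    G <- net$edges$G[r]
    if (G <= 0) next
    a <- net$edges$from[r]; bn <- net$edges$to[r]
    ia <- fidx[a]; ib <- fidx[bn]
    if (!is.na(ia)) A[ia, ia] <- A[ia, ia] + G
    if (!is.na(ib)) A[ib, ib] <- A[ib, ib] + G
    if (!is.na(ia) && !is.na(ib)) {
      A[ia, ib] <- A[ia, ib] - G
      A[ib, ia] <- A[ib, ia] - G
    } else if (!is.na(ia)) {
      rhs[ia] <- rhs[ia] + G * nodes$pressure[bn]
    } else if (!is.na(ib)) {
      rhs[ib] <- rhs[ib] + G * nodes$pressure[a]
    }
  }
  qrA <- qr(A, LAPACK = TRUE)
  if (qrA$rank < nf) {
    stop("singular nodal system (rank ", qrA$rank, " < ", nf, ")")
  }
  p_free <- solve(qrA, rhs)
  for (it in 1:2) {
    r <- rhs - as.numeric(A %*% p_free)
    if (max(abs(r)) == 0) break
    p_free <- p_free + solve(qrA, r)
  }
  p_all <- nodes$pressure
  p_all[free] <- p_free
  finish_solution(net, p_all, "dense_qr")
}

#' Kirchhoff residuals of a solution
#'
#' Recomputes the net mass imbalance at every free node from the stored edge
#' flows and returns the maximum, relative to the total drained flow (or to
#' the largest edge flow when the net flow is zero).
#'
#' @param net A `hydraulic_network`.
#' @param sol A `flow_solution` for `net`.
#' @return Maximum relative residual (dimensionless).
#' @export
node_residuals <- function(net, sol) {
  stopifnot(inherits(net, "hydraulic_network"))
  if (nrow(net$edges) == 0L) stop("empty network")
  e <- sol$edges
  n <- nrow(net$nodes)
  imbalance <- numeric(n)
  for (r in seq_len(nrow(e))) {
    imbalance[e$from[r]] <- imbalance[e$from[r]] - e$flow[r]
    imbalance[e$to[r]] <- imbalance[e$to[r]] + e$flow[r]
  }
  free <- !net$nodes$fixed
  if (!any(free)) return(0)
  denom <- max(abs(sol$m_total), max(abs(e$flow)))
  if (denom == 0) denom <- 1
  max(abs(imbalance[free])) / denom
}
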