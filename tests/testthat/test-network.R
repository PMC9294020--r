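two_node_network <- function(G, p_in = 97.8, p_out = 0) {
  net <- random_test_network(1, n_nodes = 4L, n_extra = 0L)
  net$nodes$pressure[1L] <- p_in
  net$nodes$pressure[2L] <- p_out
  # chain pelvis - n1 - n2 - bladder with equal conductances
  net$edges <- data.frame(
    from = c(1L, 3L, 4L), to = c(3L, 4L, 2L), G = G,
    kind = "intra", side = "intra", segment = NA_integer_,
    hole = NA_integer_, D_h = 1e-3, area = 1e-6, x0 = 0, x1 = 0)
  net
}

test_that("the solver reproduces Ohmic single-path arithmetic", {
  # three equal conductances in series
  net <- two_node_network(2e-6)
  sol <- solve_network(net)
  expect_equal(sol$m_total, 97.8 / (3 / 2e-6), tolerance = 1e-12)
  # the documented two-conductance hand value
  net2 <- two_node_network(2e-6)
  net2$edges <- net2$edges[1:2, ]
  net2$edges$to[2L] <- 2L
  net2$nodes <- net2$nodes[net2$nodes$id != 4L, ]
  sol2 <- solve_network(net2)
  expect_equal(sol2$m_total, 9.78e-05, tolerance = 1e-12)
  # zero pressure drop: identically zero flows
  net0 <- two_node_network(2e-6, p_in = 0, p_out = 0)
  sol0 <- solve_network(net0)
  expect_true(all(sol0$edges$flow == 0))
})

test_that("assembly produces the edge census implied by the layout rules", {
  # per chain: one edge per half-segment (2 * 35) including the two end
  # attachments; 34 hole edges; one wall edge per unoccluded segment
  n_seg <- 35L
  chain <- 2L * n_seg
  census <- function(k) table(factor(assemble_network(
    make_scenario(k))$edges$kind,
    levels = c("intra", "extra", "end", "hole", "wall")))
  c1 <- census(1)
  expect_equal(sum(c1), 2L * chain + 34L)          # unporous, no wall edges
  expect_equal(unname(c1[["hole"]]), 34L)
  expect_equal(unname(c1[["end"]]), 4L)
  c7 <- census(7)
  expect_equal(unname(c7[["hole"]]), 0L)           # no side holes
  expect_equal(unname(c7[["wall"]]), n_seg)
  c8 <- census(8)                                  # occlusion severs 2 extra
  expect_equal(unname(c8[["extra"]]), chain - 2L - 2L)
  c9 <- census(9)
  expect_equal(unname(c9[["wall"]]), n_seg - 1L)   # occluded segment has none
  # the isolated extraluminal midpoint node was dropped
  expect_identical(assemble_network(make_scenario(8))$dropped_nodes, "E_m17")
})

test_that("occlusion leaves the lumen as the only pelvis-bladder path", {
  net <- assemble_network(make_scenario(8))
  expect_silent(solve_network(net))
  # removing the intra edges across the occluded segment disconnects it
  occ <- net$scenario$occlusion
  cut <- net$edges$side == "intra" &
    pmax(net$edges$x0, occ$start) < pmin(net$edges$x1,
                                         occ$start + occ$length)
  expect_true(any(cut))
  net$edges <- net$edges[!cut, ]
  expect_error(solve_network(net), "disconnected")
})

test_that("mass is conserved and the system is linear in the pressure drop", {
  for (k in c(1, 2, 7, 8, 9)) {
    sol <- case_fit(k)
    expect_lte(sol$max_residual, 1e-12)
    expect_lt(abs(sol$pelvis_outflow - sol$bladder_inflow) /
                abs(sol$m_total), 1e-12)
  }
  net <- assemble_network(make_scenario(2))
  base <- solve_network(net)
  # scaling the drop scales every flow
  net10 <- net
  net10$nodes$pressure[net10$nodes$fixed] <-
    10 * net10$nodes$pressure[net10$nodes$fixed]
  sol10 <- solve_network(net10)
  expect_equal(sol10$edges$flow, 10 * base$edges$flow,
               tolerance = 1e-12)
  # swapping the reservoir pressures negates every flow
  netsw <- net
  netsw$nodes$pressure[1:2] <- rev(netsw$nodes$pressure[1:2])
  solsw <- solve_network(netsw)
  expect_equal(solsw$edges$flow, -base$edges$flow, tolerance = 1e-12)
})

test_that("an unporous wall and absent wall edges are equivalent bit-for-bit", {
  net <- assemble_network(make_scenario(1))
  expect_false(any(net$edges$kind == "wall"))
  base <- solve_network(net)
  withwall <- net
  wall <- net$edges[net$edges$kind == "intra", ][1:5, ]
  wall$kind <- "wall"; wall$G <- 0
  withwall$edges <- rbind(net$edges, wall)
  sol <- solve_network(withwall)
  expect_identical(sol$node_pressures, base$node_pressures)
  expect_true(all(sol$edges$flow[sol$edges$kind == "wall"] == 0))
})

test_that("sparse and dense solvers agree on reference and random networks", {
  for (k in c(1, 7, 9)) {
    net <- assemble_network(make_scenario(k))
    expect_lt(solution_deviation(solve_network(net),
                                 brute_force_solve(net)), 1e-10)
  }
  for (s in 1:30) {
    net <- random_test_network(s)
    expect_lt(solution_deviation(solve_network(net),
                                 brute_force_solve(net)), 1e-10)
  }
  # identity on the smallest possible network
  net1 <- two_node_network(3e-6)
  net1$edges <- net1$edges[1, ]; net1$edges$to <- 2L
  net1$nodes <- net1$nodes[1:2, ]
  expect_equal(brute_force_solve(net1)$m_total, 97.8 * 3e-6,
               tolerance = 1e-14)
})

test_that("node residuals expose injected conservation violations", {
  net <- assemble_network(make_scenario(1))
  sol <- solve_network(net)
  expect_lte(node_residuals(net, sol), 1e-12)
  # perturb one trunk flow by 1%: the imbalance at its endpoints is ~1%
  trunk <- which(sol$edges$side == "intra" &
                   sol$edges$kind == "intra")[20L]
  sol$edges$flow[trunk] <- sol$edges$flow[trunk] * 1.01
  r <- node_residuals(net, sol)
  expect_gt(r, 0.005)
  expect_lt(r, 0.02)
  empty <- net
  empty$edges <- net$edges[0, ]
  expect_error(node_residuals(empty, sol), "empty")
  expect_error(solve_network(empty), "empty")
})

test_that("degenerate systems fail loudly with the culprit named", {
  net <- random_test_network(3, n_nodes = 10L)
  # orphan an interior node from every positive conductance
  cut <- net$edges$from == 5L | net$edges$to == 5L
  net$edges$G[cut] <- 0
  expect_error(solve_network(net), "n003")
})
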