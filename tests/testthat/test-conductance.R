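# Expected conductances below were re-derived by independent arithmetic
# (evaluating the closed-form expressions by hand) before implementation
# and are frozen to 8 significant digits.

test_that("closures reproduce the hand-derived reference values", {
  fl <- fluid_props(997.044, 0.001)
  expect_equal(pipe_conductance(1.5e-3, 0.1, fl)$value,
               1.2388515e-06, tolerance = 1e-6)
  expect_equal(annulus_conductance(3.0e-3, 2.5e-3, 0.1, fl)$value,
               1.1222146e-07, tolerance = 1e-6)
  expect_equal(side_hole_conductance(0.8e-3, 0.5e-3, fl)$value,
               1.0320200e-05, tolerance = 1e-6)
  expect_equal(wall_radial_conductance(1e-10, 0.75e-3, 1.25e-3, 5e-3,
                                       fl)$value,
               6.1318500e-06, tolerance = 1e-6)
})

test_that("closures obey their scaling laws", {
  fl <- fluid_props()
  g <- pipe_conductance(1.5e-3, 0.1, fl)$value
  expect_equal(pipe_conductance(1.5e-3, 0.2, fl)$value, g / 2)
  expect_equal(pipe_conductance(3.0e-3, 0.1, fl)$value, 16 * g)
  w <- wall_radial_conductance(1e-12, 0.75e-3, 1.25e-3, 5e-3, fl)$value
  expect_equal(wall_radial_conductance(1e-11, 0.75e-3, 1.25e-3, 5e-3,
                                       fl)$value, 10 * w)
  expect_identical(wall_radial_conductance(0, 0.75e-3, 1.25e-3, 5e-3,
                                           fl)$value, 0)
  # side hole conductance strictly increasing in diameter
  d <- seq(0.2e-3, 1.2e-3, by = 0.1e-3)
  gh <- vapply(d, function(x) side_hole_conductance(x, 0.5e-3, fl)$value,
               numeric(1))
  expect_true(all(diff(gh) > 0))
  # t = 0 reduces to the pure Sampson orifice
  expect_equal(side_hole_conductance(0.8e-3, 0, fl)$value,
               fl$density / (3 * fl$viscosity / (0.4e-3)^3))
})

test_that("all closures are homogeneous of degree -1 in viscosity", {
  f1 <- fluid_props(997.044, 0.001)
  f2 <- fluid_props(997.044, 0.002)
  closures <- list(
    function(fl) pipe_conductance(1.5e-3, 0.1, fl)$value,
    function(fl) annulus_conductance(3.0e-3, 2.5e-3, 0.1, fl)$value,
    function(fl) side_hole_conductance(0.8e-3, 0.5e-3, fl)$value,
    function(fl) wall_radial_conductance(1e-10, 0.75e-3, 1.25e-3, 5e-3,
                                         fl)$value)
  for (g in closures) {
    expect_equal(g(f2), g(f1) / 2)
    expect_true(is.finite(g(f1)) && g(f1) >= 0)
  }
})

test_that("annulus closure has the correct closed and open limits", {
  fl <- fluid_props()
  # closing gap: conductance vanishes
  expect_lt(annulus_conductance(2.5000001e-3, 2.5e-3, 0.1, fl)$value,
            1e-12)
  expect_error(annulus_conductance(2.5e-3, 2.5e-3, 0.1, fl), "closed")
  expect_error(annulus_conductance(2.0e-3, 2.5e-3, 0.1, fl), "closed")
  # vanishing core: converges to the pipe value, at a logarithmic rate
  pipe <- pipe_conductance(2e-3, 0.1, fl)$value
  ratios <- vapply(c(1e-3, 1e-6, 1e-12, 1e-45), function(r) {
    annulus_conductance(2e-3, 2e-3 * r, 0.1, fl)$value / pipe
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))   # monotone convergence from below
  expect_true(all(ratios < 1))
  expect_gt(ratios[4], 0.99)           # within 1% deep in the limit
})

test_that("cylindrical Darcy wall agrees with the flat-slab approximation", {
  fl <- fluid_props()
  r_i <- 0.75e-3; r_o <- 1.25e-3; dz <- 5e-3; a <- 1e-10
  cyl <- wall_radial_conductance(a, r_i, r_o, dz, fl)$value
  slab <- fl$density * a * (2 * pi * (r_i + r_o) / 2 * dz) /
    (fl$viscosity * (r_o - r_i))
  expect_lt(abs(cyl - slab) / slab, 0.15)
  expect_error(wall_radial_conductance(1e-10, 1.25e-3, 0.75e-3, 5e-3, fl),
               "outer_radius")
})

test_that("tapered composition reduces to the plain annulus and to series resistances", {
  fl <- fluid_props()
  flat <- tapered_annulus_conductance(0, 0.1, 2.5e-3,
                                      function(x) 3.0e-3, fl)$value
  expect_equal(flat, annulus_conductance(3.0e-3, 2.5e-3, 0.1, fl)$value,
               tolerance = 1e-12)
  # a two-step profile equals the harmonic series of the two halves
  dfun <- function(x) if (x < 0.05) 4e-3 else 3e-3
  g1 <- annulus_conductance(4e-3, 2.5e-3, 0.05, fl)$value
  g2 <- annulus_conductance(3e-3, 2.5e-3, 0.05, fl)$value
  expect_equal(tapered_annulus_conductance(0, 0.1, 2.5e-3, dfun,
                                           fl, n_sub = 8L)$value,
               1 / (1 / g1 + 1 / g2), tolerance = 1e-12)
  closed <- function(x) 2.5e-3
  expect_error(tapered_annulus_conductance(0, 0.1, 2.5e-3, closed, fl),
               "closed")
})

test_that("Reynolds numbers follow the mass-flow definition", {
  fl <- fluid_props(997.044, 0.001)
  r <- reynolds_number(1e-4, 1.5e-3, pi * (0.75e-3)^2, fl)
  expect_equal(r$velocity, 0.056756196, tolerance = 1e-6)
  expect_equal(r$Re, 84.882636, tolerance = 1e-6)
  expect_true(r$laminar)
  z <- reynolds_number(0, 1.5e-3, pi * (0.75e-3)^2, fl)
  expect_identical(z$Re, 0)
  expect_true(z$laminar)
  expect_equal(reynolds_number(2e-4, 1.5e-3, pi * (0.75e-3)^2, fl)$Re,
               2 * r$Re)
  expect_error(reynolds_number(1e-4, 1.5e-3, 0, fl), "area")
})
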