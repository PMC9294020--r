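test_that("default ureter profile matches the reference anatomy", {
  p <- default_ureter_profile()
  expect_equal(p$total_length, 0.240)
  expect_equal(lumen_diameter(p, 0), 6.0e-3)
  expect_equal(lumen_diameter(p, p$total_length), 2.9e-3)
  # taper ends at 3.0 mm at the end of the proximal third
  expect_equal(lumen_diameter(p, p$total_length / 3), 3.0e-3)
  expect_true(all(diff(p$positions) > 0))
  # after the clearance adjustment the annulus is open everywhere
  st <- default_stent_spec()
  xx <- seq(0, p$total_length, length.out = 200)
  expect_true(all(effective_lumen_diameter(p, st, xx) >
                    st$outer_diameter))
})

test_that("profile constructor rejects malformed stations", {
  expect_error(axial_profile(c(0, 0.1, 0.1), c(1, 1, 1) * 1e-3),
               "strictly increasing")
  expect_error(axial_profile(c(0.01, 0.1), c(1, 1) * 1e-3), "position 0")
  expect_error(axial_profile(c(0, 0.1), c(1, -1) * 1e-3), "positive")
  expect_error(lumen_diameter(default_ureter_profile(), 0.5), "outside")
})

test_that("default stent spec carries the reference dimensions", {
  st <- default_stent_spec()
  expect_equal(st$inner_diameter, 1.5e-3)
  expect_equal(st$outer_diameter, 2.5e-3)
  expect_equal(st$n_side_holes, 42L)
  expect_equal(st$side_hole_diameter, 0.8e-3)
  expect_equal(st$wall_thickness, 0.5e-3)
  expect_equal(st$n_side_holes - 2L * st$holes_per_coil, 34L)
  expect_error(stent_spec(inner_diameter = 3e-3, outer_diameter = 2e-3),
               "inner_diameter")
  expect_error(stent_spec(permeability = -1), "permeability")
})

test_that("side-hole layout is ordered kidney to bladder with room for the occlusion", {
  st <- default_stent_spec()
  p <- default_ureter_profile()
  h <- side_hole_positions(st, p)
  expect_equal(nrow(h), 42L)
  expect_equal(h$hole, 1:42)
  expect_true(all(diff(h$position) >= 0))
  shaft <- h[h$region == "shaft", ]
  expect_equal(nrow(shaft), 34L)
  expect_true(all(diff(shaft$position) > 0))
  # the 6 mm obstruction must fit strictly between holes 21 and 22
  gap <- h$position[h$hole == 22] - h$position[h$hole == 21]
  expect_gt(gap, 6e-3)
  occ <- default_occlusion(p, st)
  expect_gt(occ$start, h$position[h$hole == 21])
  expect_lt(occ$start + occ$length, h$position[h$hole == 22])
  expect_equal(occ$length, 6e-3)
  # stent shorter than the ureter is a geometry error
  expect_error(side_hole_positions(default_stent_spec(shaft_length = 0.1), p),
               "shorter")
})

test_that("the nine reference cases are reproduced field-for-field", {
  spec <- data.frame(
    case_id = 1:9,
    permeability = c(0, 1e-10, 1e-11, 1e-12, 1e-14, 1e-18, 1e-10, 0, 1e-10),
    holes = c(42L, 42L, 42L, 42L, 42L, 42L, 0L, 42L, 42L),
    occluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  for (i in seq_len(nrow(spec))) {
    sc <- make_scenario(spec$case_id[i])
    expect_identical(sc$case_id, spec$case_id[i])
    expect_identical(sc$stent$permeability, spec$permeability[i])
    expect_identical(sc$stent$n_side_holes, spec$holes[i])
    expect_identical(sc$occlusion$present, spec$occluded[i])
    expect_identical(sc$inlet_pressure, 97.8)
    expect_identical(sc$outlet_pressure, 0)
    expect_identical(sc$fluid$density, 997.044)
    expect_identical(sc$fluid$viscosity, 0.001)
  }
  expect_error(make_scenario(0), "1..9")
  expect_error(make_scenario(10), "1..9")
})

test_that("scenario validation raises on inconsistent inputs", {
  expect_error(scenario(inlet_pressure = 0, outlet_pressure = 97.8),
               "forward flow")
  sc <- make_scenario(7)
  sc$side_holes_enabled <- TRUE
  expect_error(validate_scenario(sc), "no side holes")
  expect_error(
    scenario(occlusion = occlusion_spec(TRUE, start = 0.010,
                                        length = 0.006)),
    "between side holes")
})

test_that("random scenarios are deterministic, non-degenerate and valid", {
  expect_identical(random_scenario(42), random_scenario(42))
  expect_false(random_scenario(1)$stent$permeability ==
                 random_scenario(2)$stent$permeability)
  for (s in 1:100) {
    sc <- random_scenario(s)
    expect_silent(validate_scenario(sc))
    if (sc$occlusion$present) {
      h <- side_hole_positions(sc$stent, sc$profile)
      expect_gt(sc$occlusion$start, h$position[h$hole == 21])
      expect_lt(sc$occlusion$start + sc$occlusion$length,
                h$position[h$hole == 22])
    }
  }
  expect_error(random_scenario(1, permeability_range = c(1e-10, 1e-18)),
               "increasing")
  expect_error(random_scenario(1, perturb = 0.9), "perturb")
})
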