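params <- kinetic_parameters()

test_that("Michaelis-Menten forms hit half-saturation at their constants", {
  expect_equal(phosphate_uptake(0.0333, params), 0.04)
  expect_equal(stored_phosphate_release(0.0833, params), 0.0004)
  # facilitated components after subtracting the passive term
  expect_equal(glucose_uptake(0.26, 0, params) - params$v_G1 * 0.26,
               0.093)
  expect_equal(xylose_uptake(3.33, params) - params$v_X1 * 3.33, 0.1)
  # zero at zero, bounded by v_max, monotone
  expect_equal(phosphate_uptake(0, params), 0)
  expect_equal(stored_phosphate_release(0, params), 0)
  expect_equal(glucose_uptake(0, 0, params), 0)
  expect_equal(xylose_uptake(0, params), 0)
  grid <- seq(0, 50, length.out = 200)
  v <- phosphate_uptake(grid, params)
  expect_true(all(diff(v) >= -1e-12))
  expect_true(all(v <= params$v_Pe_max + 1e-12))
  expect_lt(params$v_Pe_max - phosphate_uptake(1e6, params), 1e-4)
  v <- stored_phosphate_release(grid, params)
  expect_true(all(diff(v) >= -1e-12) && all(v <= params$v_P_max + 1e-15))
})

test_that("negative concentrations are rejected", {
  expect_error(phosphate_uptake(-1, params), ">= 0")
  expect_error(glucose_uptake(-1, 0, params), ">= 0")
  expect_error(glucose_uptake(1, -1, params), ">= 0")
  expect_error(xylose_uptake(-1, params), ">= 0")
  expect_error(gox_rate(-1, 5, params), ">= 0")
})

test_that("citrate non-competitively inhibits glucose uptake", {
  for (G in c(0.1, 10, 500, 900)) {
    cgrid <- seq(0, 500, length.out = 50)
    v <- vapply(cgrid, function(C) glucose_uptake(G, C, params),
                numeric(1))
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_lt(glucose_uptake(10, 100, params), glucose_uptake(10, 0, params))
})

test_that("the low-affinity systems switch on at 150 g/L", {
  g150 <- 150 / 180.16 * 1000
  below <- glucose_uptake(g150 * (1 - 1e-9), 0, params)
  at <- glucose_uptake(g150, 0, params)
  jump <- params$v_G3_max * g150 / (params$K_G3 + g150)
  expect_equal(at - below, jump, tolerance = 1e-6)
  x150 <- 150 / 150.13 * 1000
  belowx <- xylose_uptake(x150 * (1 - 1e-9), params)
  atx <- xylose_uptake(x150, params)
  jumpx <- params$v_X3_max * x150 / (params$K_X3 + x150)
  expect_equal(atx - belowx, jumpx, tolerance = 1e-6)
})

test_that("rates are invariant to the unit conversion path", {
  # computing from g/L converted to mM equals computing in mM directly
  for (gl in c(1, 42.7, 150, 200)) {
    mM <- gl / 180.16 * 1000
    expect_identical(glucose_uptake(mM, 0, params),
                     glucose_uptake(gl_to_mM(gl, "glucose"), 0, params))
  }
})

test_that("GOX activity is clamped and follows the quadratic", {
  expect_equal(p_gox(2), 0)             # raw value -0.194, clamped
  expect_equal(-0.102 * 4 + 1.082 * 2 - 1.95, -0.194)
  expect_equal(p_gox(5.3), 0.91942)
  ph <- seq(0.1, 13.9, by = 0.1)
  expect_true(all(p_gox(ph) >= 0 & p_gox(ph) <= 1))
  # saturated rate at the fitted enzyme loading
  expect_equal(gox_rate(1e9, 5.3, params), 0.91942 * 27.48 * 0.1,
               tolerance = 1e-6)
  expect_equal(gox_rate(500, 5.3, params, gox_knocked_out = TRUE), 0)
  expect_equal(gox_rate(500, 1.5, params), 0)   # inactive at low pH
})

test_that("phosphate uptake capacity switches 8 h in, keyed to start pH", {
  expect_equal(phosphate_uptake(1e6, params, t = 7.99, initial_pH = 2),
               0.08, tolerance = 1e-4)
  expect_equal(phosphate_uptake(1e6, params, t = 8, initial_pH = 2),
               0.015, tolerance = 1e-5)
  expect_equal(phosphate_uptake(1e6, params, t = 8, initial_pH = 7),
               0.004, tolerance = 1e-6)
})

test_that("secretion caps follow initial and current pH", {
  expect_equal(secretion_caps(2, 1.8, params),
               c(v_CIT_cap = 0.12, v_OXAL_cap = 0))
  expect_equal(secretion_caps(7, 6, params),
               c(v_CIT_cap = 0.016, v_OXAL_cap = 0.01))
  # boundary: current pH exactly 2 keeps oxalate open (strict "<")
  expect_equal(secretion_caps(2, 2, params)[["v_OXAL_cap"]], 0.01)
  expect_error(secretion_caps(0, 2, params), "pH")
})

test_that("parameter validation rejects nonsense", {
  expect_error(kinetic_parameters(v_CIT = -1), ">= 0")
  expect_error(kinetic_parameters(K_G2 = 0), "> 0")
  expect_error(kinetic_parameters(not_a_param = 1), "unknown")
})
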