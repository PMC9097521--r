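test_that("model constants validate their fields", {
  const <- model_constants()
  expect_s3_class(const, "model_constants")
  expect_equal(const$molecules_per_mol, 1000 * const$molecules_per_mmol)
  expect_error(model_constants(silica_density = -1), "positive")
  expect_error(model_constants(molecules_per_mol = 6.02e22), "1000")
  expect_error(constants_from_config(list(bogus = 1)), "unknown")
  cfg <- constants_from_config(list(reaction_layer_thickness_h = 1e-7))
  expect_equal(cfg$reaction_layer_thickness_h, 1e-7)
  expect_equal(cfg$silica_density, 2.196)
})

test_that("molecule count per particle follows the volume formula", {
  # frozen from direct evaluation of N_A * (4/3) pi R^3 rho / M
  expect_equal(molecules_per_particle(1.75e-6), 493971.2334, tolerance = 1e-8)
  expect_error(molecules_per_particle(-1e-6), "positive")
  # R^3 scaling: doubling the radius gives 8x the count
  R <- 10^seq(-6.5, -5, length.out = 7)
  expect_equal(molecules_per_particle(2 * R) / molecules_per_particle(R),
               rep(8, length(R)))
})

test_that("per-particle reactive area is pi(2Rh + h^2)", {
  expect_equal(reactive_area_per_particle(1.75e-6, 3.23e-7),
               3.879329714839631e-12, tolerance = 1e-12)
  expect_equal(reactive_area_per_particle(1e-6, 0), 0)
  h <- 2.5e-7
  expect_equal(reactive_area_per_particle(h, h), 3 * pi * h^2)
  expect_error(reactive_area_per_particle(1e-6, -1e-8), "non-negative")
})

test_that("specific reactive area reproduces the worked dispersion example", {
  A <- reactive_area_per_mmol(nm_to_cm(17.5))
  expect_equal(A, 4727.7176, tolerance = 1e-7)
  # 0.169 mol of SiO2 as 17.5 nm particles: ~8e5 cm^2 total
  expect_gt(169 * A, 7.9e5)
  expect_lt(169 * A, 8.1e5)
  # h = 0 kills the reactive area
  const0 <- model_constants(reaction_layer_thickness_h = 1e-30)
  expect_lt(reactive_area_per_mmol(1e-6, const0), 1e-15)
})

test_that("particle-count and molecule-count forms of A agree with the brute-force oracle", {
  const <- model_constants()
  R <- exp(seq(log(5e-7), log(1e-5), length.out = 60))
  ap <- reactive_area_per_particle(R, const$reaction_layer_thickness_h)
  # route 1: package (per-particle area x particles per mmol)
  A1 <- reactive_area_per_mmol(R, const)
  # route 2: molecule-count form via C_tr
  A2 <- const$molecules_per_mmol * ap / molecules_per_particle(R, const)
  # route 3: brute-force mass bookkeeping
  A3 <- ap * oracle_particles_per_mmol(R)
  expect_equal(A1, A2, tolerance = 1e-12)
  expect_equal(A1, A3, tolerance = 1e-12)
})

test_that("specific reactive area decreases strictly with radius", {
  const <- model_constants()
  R <- exp(seq(log(const$reaction_layer_thickness_h * 1.5), log(1e-4),
               length.out = 100))
  A <- reactive_area_per_mmol(R, const)
  expect_true(all(A > 0))
  expect_true(all(diff(A) < 0))
})

test_that("close-packed area per mmol scales as R^2 and inverts to a coverage", {
  expect_equal(close_packed_area_per_mmol(1.75e-6), 6386504340.2,
               tolerance = 1e-9)
  R <- c(1e-6, 3e-6)
  expect_equal(close_packed_area_per_mmol(2 * R) / close_packed_area_per_mmol(R),
               c(4, 4))
  expect_equal(close_packed_area_per_mmol(1e-6) * (1 / close_packed_area_per_mmol(1e-6)), 1)
})

test_that("maximum model depression is capped at full suppression below the crossover radius", {
  const <- model_constants()
  expect_equal(max_depression_model(1.75e-6), 11.7380243, tolerance = 1e-8)
  rc <- cap_radius(const)
  expect_equal(rc, 7.176910015755446e-07, tolerance = 1e-12)
  below <- rc * c(0.3, 0.7, 0.999)
  expect_equal(max_depression_model(below), rep(const$full_suppression_current, 3))
  R <- exp(seq(log(1e-7), log(1e-4), length.out = 80))
  expect_true(all(max_depression_model(R) <= const$full_suppression_current + 1e-12))
  # vanishes at large radius like 1/R
  expect_lt(max_depression_model(1e-3 * 0.1), max_depression_model(1e-5))
})

test_that("cap radius from bisection matches the closed-form quadratic root", {
  const <- model_constants()
  h <- const$reaction_layer_thickness_h
  f <- function(r) pi * (2 * r * h + h^2) - 2 * sqrt(3) * r^2
  expect_equal(oracle_bisect(f, 1e-8, 1e-5), cap_radius(const), tolerance = 1e-10)
})

test_that("the v factor ties depression and close-packed area together", {
  const <- model_constants()
  expect_equal(v_factor(1.75e-6), 74964943275.5, tolerance = 1e-9)
  # above the cap radius the model v equals the capped depression times SA
  R <- exp(seq(log(cap_radius(const) * 1.001), log(1e-5), length.out = 50))
  expect_equal(v_factor(R, const),
               max_depression_model(R, const) * close_packed_area_per_mmol(R, const),
               tolerance = 1e-12)
  # experimental variant at the cap radius with full current coincides with model
  rc <- cap_radius(const)
  expect_equal(v_factor(rc, const, max_depression = const$full_suppression_current),
               v_factor(rc, const), tolerance = 1e-12)
  expect_error(v_factor(1e-6, const, max_depression = 100), "full_suppression")
  expect_error(v_factor(1e-6, const, max_depression = 0), "full_suppression")
})

test_that("geometry_table is consistent with the scalar operations", {
  const <- model_constants()
  tab <- geometry_table(default_radii_cm, const)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$A_cm2_per_mmol,
               tab$per_particle_area_cm2 * tab$particles_per_mmol,
               tolerance = 1e-12)
  # uncapped identity: v_model / SA equals the uncapped depression ratio x I
  uncapped <- const$full_suppression_current *
    tab$per_particle_area_cm2 / (2 * sqrt(3) * tab$radius_cm^2)
  expect_equal(tab$v_model_uA_cm2_per_mmol / tab$SA_cm2_per_mmol, uncapped,
               tolerance = 1e-12)
  expect_error(geometry_table(c(6.75, 15)), "unit")
})
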