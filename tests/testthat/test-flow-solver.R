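test_that("step pressure drop reduces to Poiseuille and gates the expansion loss", {
  a <- pi * (1.5e-3)^2
  expect_equal(step_pressure_drop(0, a, a, 5e-4, 0.0035, 1056), 0)
  # uniform step: no expansion term
  dp_uniform <- step_pressure_drop(1.5e-6, a, a, 5e-4, 0.0035, 1056)
  expect_equal(dp_uniform, 8 * 0.0035 * 1.5e-6 * 5e-4 / (pi * (1.5e-3)^4))
  # widening step adds the expansion loss, narrowing does not
  a2 <- pi * (2e-3)^2
  dp_expand <- step_pressure_drop(1.5e-6, a, a2, 5e-4, 0.0035, 1056)
  dp_narrow <- step_pressure_drop(1.5e-6, a2, a, 5e-4, 0.0035, 1056)
  visc <- 8 * pi * 0.0035 * 1.5e-6 * 5e-4 / ((a + a2) / 2)^2
  expect_equal(dp_expand - visc, 0.5 * 1056 * (1.5e-6)^2 * (1 / a - 1 / a2)^2)
  expect_equal(dp_narrow, visc)
  expect_error(step_pressure_drop(-1e-6, a, a, 5e-4, 0.0035, 1056),
               class = "ctifr_invalid_parameter")
})

test_that("the uniform-tube solution matches closed-form Poiseuille at any step", {
  q <- 1.5e-6
  for (step in c(2, 0.5, 0.1)) {
    tube <- make_tube_tree(30, 1.5, step = step)
    bc <- boundary_conditions(pa_diastolic = 80, lv_mass = 1)
    abc <- assemble_bc(tube, bc)
    abc$segment_flows["0"] <- q
    sol <- solve_pressure_field(tube, abc)
    f <- sol$fields[["0"]]
    dp <- f$p[1] - f$p[nrow(f)]
    closed <- poiseuille_dp(q, 1.5e-3, 0.03)
    expect_lt(abs(dp - closed) / closed, 1e-10)
    expect_equal(closed, 79.2, tolerance = 1e-3)
    # distal ratio from the closed form: 1 - 8 mu L Q / (pi r^4 Pa)
    expect_lt(abs(f$ratio[nrow(f)] - (1 - closed / (80 * 133.322))), 1e-12)
    expect_equal(f$ratio[nrow(f)], 0.9926, tolerance = 1e-4)
    expect_identical(f$ratio[1], 1)
  }
})

test_that("pressure ratio is 1 at the inlet and non-increasing down every path", {
  tree <- standard_test_tree()
  bc <- boundary_conditions(lv_mass = 60)
  sol <- solve_pressure_field(tree, assemble_bc(tree, bc))
  expect_identical(sol$fields[[as.character(tree$inlet)]]$ratio[1], 1)
  for (f in sol$fields) {
    expect_true(all(diff(f$ratio) <= 0))
    expect_true(all(f$ratio > 0 & f$ratio <= 1))
  }
  # vanishing flow: no pressure loss anywhere
  abc <- assemble_bc(tree, bc)
  abc$segment_flows[] <- 1e-15
  sol0 <- solve_pressure_field(tree, abc)
  for (f in sol0$fields) expect_lt(max(1 - f$ratio), 1e-6)
})

test_that("the computed index decreases strictly with stenosis severity", {
  vals <- vapply(c(0, 30, 50, 70, 90), function(ds) {
    tree <- generate_synthetic_tree(
      inlet_radius = 2.0,
      stenoses = list(list(center_frac = 0.45, length_mm = 20, severity = ds)),
      seed = 7
    )
    solve_index(tree, lv_mass = 20)$ifr_ct
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # a severe lesion sits well below an unobstructed vessel
  expect_gt(vals[1], 0.95)
  expect_lt(vals[5], 0.89)
})

test_that("the FFR surrogate never exceeds the resting index when h > 1", {
  for (ds in c(0, 40, 60)) {
    tree <- generate_synthetic_tree(
      stenoses = list(list(center_frac = 0.45, length_mm = 20, severity = ds)),
      seed = 21
    )
    res <- solve_index(tree, with_ffr = TRUE)
    expect_lte(res$ffr_ct, res$ifr_ct)
  }
})

test_that("halving the resampling step barely changes the index", {
  tree <- standard_test_tree(step = 0.5)
  v1 <- solve_index(tree)$ifr_ct
  v2 <- solve_index(resample_centerline(tree, 0.25))$ifr_ct
  expect_lt(abs(v1 - v2), 0.001)
})

test_that("the sensor sits 30 mm past the lesion, clamped to the vessel end", {
  tube <- make_tube_tree(100, 2.0)
  lesioned <- insert_stenosis(tube, stenosis_spec(0L, 40, 10, 60))
  bc <- boundary_conditions(lv_mass = 60)
  sol <- solve_pressure_field(lesioned, assemble_bc(lesioned, bc))
  res <- index_at_measurement_point(sol, lesioned)
  expect_equal(res$measurement_s, 70)

  # lesion near the end: clamp to the distal tip
  distal <- insert_stenosis(tube, stenosis_spec(0L, 90, 10, 60))
  sol2 <- solve_pressure_field(distal, assemble_bc(distal, bc))
  res2 <- index_at_measurement_point(sol2, distal)
  expect_equal(res2$measurement_s, 100)

  # uniform tube with no lesion and no explicit point: an error
  sol3 <- solve_pressure_field(tube, assemble_bc(tube, bc))
  expect_error(index_at_measurement_point(sol3, tube),
               class = "ctifr_invalid_parameter")
})

test_that("hemodynamic significance is cutoff-inclusive", {
  tube <- make_tube_tree(100, 2.0)
  lesioned <- insert_stenosis(tube, stenosis_spec(0L, 40, 10, 60))
  bc <- boundary_conditions(lv_mass = 60)
  sol <- solve_pressure_field(lesioned, assemble_bc(lesioned, bc))
  res <- index_at_measurement_point(sol, lesioned)
  expect_identical(res$significant, res$ifr_ct <= 0.89)
  # a value exactly at the cutoff counts as significant
  at_cut <- index_at_measurement_point(sol, lesioned, cutoff_ifr = res$ifr_ct)
  expect_true(at_cut$significant)
  below <- index_at_measurement_point(sol, lesioned,
                                      cutoff_ifr = res$ifr_ct - 1e-9)
  expect_false(below$significant)
})

test_that("unsustainable prescribed flow raises a degenerate-physics error", {
  tube <- make_tube_tree(60, 1.0)
  lesioned <- insert_stenosis(tube, stenosis_spec(0L, 30, 20, 90))
  bc <- boundary_conditions(lv_mass = 120)
  expect_error(solve_pressure_field(lesioned, assemble_bc(lesioned, bc)),
               class = "ctifr_degenerate_physics")
})
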