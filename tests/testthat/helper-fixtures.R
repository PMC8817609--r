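# Fixtures shared across the suite; everything is built in code.

# straight tube along x, uniform or linearly tapering radius
make_tube_tree <- function(length_mm = 30, r_start = 1.5, r_end = r_start,
                           step = 0.5, label = "tube") {
  x <- seq(0, length_mm, by = step)
  if (x[length(x)] < length_mm) x <- c(x, length_mm)
  r <- r_start + (r_end - r_start) * x / length_mm
  centerline_tree(list(new_segment(0L, data.frame(x = x, y = 0, z = 0, r = r))),
                  inlet = 0L, label = label)
}

# parent + two straight daughters; radii constant per segment
make_y_tree <- function(r_parent = 2, r_left = 1.5, r_right = 1.5,
                        parent_len = 20, child_len = 20, step = 0.5) {
  xs <- seq(0, parent_len, by = step)
  parent <- new_segment(0L, data.frame(x = xs, y = 0, z = 0, r = r_parent))
  tc <- seq(0, child_len, by = step)
  left <- new_segment(1L, data.frame(
    x = parent_len + tc / sqrt(2), y = tc / sqrt(2), z = 0, r = r_left
  ), parent = 0L)
  right <- new_segment(2L, data.frame(
    x = parent_len + tc / sqrt(2), y = -tc / sqrt(2), z = 0, r = r_right
  ), parent = 0L)
  centerline_tree(list(parent, left, right), inlet = 0L, label = "Y")
}

# the standard synthetic test tree: LAD-like vessel with a mid-vessel
# DS = 50% lesion (close to the study's mean visual severity)
standard_test_tree <- function(step = 0.5, severity = 50) {
  generate_synthetic_tree(
    stenoses = list(list(center_frac = 0.45, length_mm = 20,
                         severity = severity)),
    step = step, seed = 7
  )
}

solve_index <- function(tree, lv_mass = 60, pa = 80, mode = "resting",
                        with_ffr = FALSE) {
  bc <- boundary_conditions(pa_diastolic = pa, lv_mass = lv_mass)
  rest <- solve_pressure_field(tree, assemble_bc(tree, bc, "resting"))
  hyp <- if (with_ffr) {
    solve_pressure_field(tree, assemble_bc(tree, bc, "hyperemic"))
  }
  index_at_measurement_point(rest, tree, hyperemic_solution = hyp)
}

# closed-form Poiseuille drop for a uniform tube (SI inputs)
poiseuille_dp <- function(q, r_m, length_m, mu = 0.0035) {
  8 * mu * length_m * q / (pi * r_m^4)
}
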