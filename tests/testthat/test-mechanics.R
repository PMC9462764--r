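# Overlapping-spheres mechanics: neighbours, force laws, divisions, updates.

test_that("neighbour lists respect the cutoff and the minimum image", {
  dom <- sim_domain(10, 10)
  far <- cell_df(id = 1:2, type = "diff", x = c(2, 5), y = c(2, 2),
                 z = c(5, 5))
  expect_equal(nrow(build_neighbor_lists(far, dom, 2)), 0)
  # periodic wrap: x = 0.5 and 9.7 are 0.8 CD apart
  wrap <- cell_df(id = 1:2, type = "diff", x = c(0.5, 9.7), y = c(2, 2),
                  z = c(5, 5))
  nl <- build_neighbor_lists(wrap, dom, 2)
  expect_equal(nrow(nl), 1)
  expect_equal(nl$dist, 0.8)
  # three mutually touching unit-diameter cells: 3 pairs at gap 0
  tri <- cell_df(id = 1:3, type = "diff",
                 x = c(3, 4, 3.5), y = c(3, 3, 3 + sqrt(3) / 2),
                 z = c(5, 5, 5))
  nl3 <- build_neighbor_lists(tri, dom, 2)
  expect_equal(nrow(nl3), 3)
  expect_equal(nl3$gap, rep(0, 3), tolerance = 1e-12)
  expect_error(build_neighbor_lists(far, sim_domain(3, 3), 2), "twice")
})

test_that("pair force law: zero at contact, log repulsion, adhesion peak", {
  p <- mechanics_params()
  expect_equal(pair_interaction_force(0, p$alpha_0, p), 0)
  expect_equal(pair_interaction_force(-0.1, p$alpha_0, p), 150 * log(0.9))
  expect_equal(abs(pair_interaction_force(-0.1, p$alpha_0, p)), 15.80,
               tolerance = 1e-3)
  expect_error(pair_interaction_force(-1, p$alpha_0, p), "overlap")
  # peak location/height against the brute-force scan oracle
  pk <- adhesion_peak(7)
  orc <- oracle_adhesion_peak(7)
  expect_equal(pk$g_max, orc$g_max, tolerance = 1e-6)
  expect_equal(pk$r_star, orc$r_star, tolerance = 1e-3)
  expect_equal(pk$g_max, 0.112, tolerance = 1e-2)
  expect_equal(pk$r_star, 0.23, tolerance = 5e-2)
  # shape: positive over the adhesive range, decaying to ~0 by r* = 4
  gaps <- seq(0.01, 2, by = 0.01)  # gap in CD; r* = gap/R_0 spans (0, 4]
  f <- pair_interaction_force(gaps, p$alpha_0, p)
  expect_true(all(f > -1e-12))
  expect_lt(f[length(f)], 1e-6)
})

test_that("alpha_0 calibration makes the peak force equal F_max", {
  p <- mechanics_params(F_max = 10)
  gaps <- seq(1e-4, 2, by = 1e-4)
  peak <- max(pair_interaction_force(gaps, p$alpha_0, p))
  expect_equal(peak, 10, tolerance = 1e-4)
  expect_equal(calibrate_alpha0(20, 7), 2 * calibrate_alpha0(10, 7))
  # the historical reference coefficient is recorded but inconsistent with
  # F_max under this force law (it would give a ~42 uN peak)
  expect_equal(p$alpha_0_reference, 374.7)
  expect_gt(374.7 * adhesion_peak(7)$g_max, 40)
})

test_that("adhesion coefficient averages the CND levels", {
  expect_equal(adhesion_coefficient(1, 1, 374.7), 374.7)
  expect_equal(adhesion_coefficient(0, 0, 374.7), 0)
  expect_equal(adhesion_coefficient(0.5, 0.3, 374.7), 149.88)
  expect_error(adhesion_coefficient(1.5, 0, 374.7), "0, 1")
})

test_that("rotational force restores vertical division axes", {
  expect_equal(division_rotation_force(c(0, 0, 0), c(0, 0, 1), 100),
               c(0, 0, 0))
  f <- division_rotation_force(c(0, 0, 1), c(1, 0, 1), 100)
  expect_equal(sqrt(sum(f^2)), 100 * pi / 2, tolerance = 1e-10)  # 157.08
  # perpendicular to the pair axis
  expect_equal(sum(f * c(1, 0, 0)), 0, tolerance = 1e-10)
  # tilted pair: force on the lower cell points downwards (rotates axis up)
  ft <- division_rotation_force(c(0, 0, 0), c(1, 0, 1), 100)
  expect_lt(ft[3], 0)
})

test_that("divisions conserve stems, inherit inhibitor and draw cycle times", {
  dom <- sim_domain(10, 10)
  p <- mechanics_params()
  prolif <- proliferation_params()
  cells <- cell_df(id = 1:3, type = c("stem", "stem", "diff"),
                   x = c(2, 6, 2), y = c(2, 2, 2), z = c(0.5, 0.5, 1.5),
                   birth_time = c(-20, -5, 0), t_c = c(15, 15, NA),
                   i_t_level = c(3e-10, 0, 0))
  set.seed(1)
  out <- attempt_divisions(cells, t = 0, prolif, p, dom)
  expect_equal(out$divisions, 1L)  # only the first stem is old enough
  expect_equal(sum(out$cells$type == "stem"), 2)
  daughter <- out$cells[nrow(out$cells), ]
  expect_equal(daughter$type, "diff")
  expect_equal(daughter$i_t_level, 3e-10)      # inherited, capped at e_T
  expect_equal(daughter$c_i, 1)                # i_T = e_T at birth
  expect_equal(daughter$radius, p$R_0 / 2)
  expect_true(daughter$z >= 0.5)               # upward hemisphere offset
  expect_equal(out$cells$partner[1], daughter$id)
  # stem's clock restarted with a fresh U(13, 17) draw
  expect_true(out$cells$t_c[1] >= 13 && out$cells$t_c[1] <= 17)
  # repeated division sequences never change the stem count
  set.seed(2)
  st <- out$cells
  for (t in seq(20, 200, by = 20)) {
    st <- attempt_divisions(st, t, prolif, p, dom)$cells
  }
  expect_equal(sum(st$type == "stem"), 2)
})

test_that("cycle-time draws match their distributions", {
  set.seed(3)
  single <- episkin:::draw_cycle_time(1e4, proliferation_params())
  expect_equal(mean(single), 15, tolerance = 0.01)
  expect_true(all(single >= 13 & single <= 17))
  dual <- episkin:::draw_cycle_time(
    1e4, proliferation_params(population_mode = "dual", T_1 = 10, dT_C = 20))
  expect_setequal(unique(dual), c(10, 30))
  expect_equal(harmonic_mean(c(10, 30)), 15)
})

test_that("overdamped update moves, wraps, clips and detects instability", {
  dom <- sim_domain(10, 10)
  cells <- cell_df(id = 1L, type = "diff", x = 9.9, y = 5, z = 5)
  # spec arithmetic: 5 uN vertical, eta = 0.1, dt = 30 s -> 0.4167 CD
  out <- advance_positions(cells, matrix(c(0, 0, 5), 1), 0.1, 1 / 120, dom)
  expect_equal(out$z - 5, 0.4167, tolerance = 1e-4)
  # zero force: unchanged
  out0 <- advance_positions(cells, matrix(0, 1, 3), 0.1, 1 / 120, dom)
  expect_equal(out0$x, cells$x)
  # lateral wrap
  outw <- advance_positions(cells, matrix(c(6, 0, 0), 1), 10, 1, dom)
  expect_equal(outw$x, 0.5, tolerance = 1e-9)
  expect_error(
    advance_positions(cells, matrix(c(0, 0, 200), 1), 0.1, 1 / 120, dom),
    "instability"
  )
})

test_that("pair forces obey Newton's third law and periodic invariance", {
  dom <- sim_domain(10, 10)
  p <- mechanics_params()
  set.seed(5)
  n <- 30
  cells <- cell_df(id = seq_len(n), type = "diff",
                   x = runif(n, 0, 10), y = runif(n, 0, 10),
                   z = runif(n, 3, 6), s = runif(n))
  F <- assemble_forces(cells, dom, p, F_D = 0)
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-9)
  shifted <- cells
  shifted$x <- episkin:::wrap_lateral(shifted$x + dom$Lx, dom$Lx)
  expect_equal(assemble_forces(shifted, dom, p, F_D = 0), F,
               tolerance = 1e-9)
})

test_that("two overlapping cells relax to contact under damped dynamics", {
  dom <- sim_domain(10, 10)
  p <- mechanics_params()
  cells <- two_cells(gap = -0.3)
  for (k in 1:400) {
    F <- assemble_forces(cells, dom, p, F_D = 0)
    # symmetric separation along the pair axis
    expect_equal(F[1, ], -F[2, ], tolerance = 1e-12)
    cells <- advance_positions(cells, F, p$eta, p$dt, dom)
  }
  gap <- abs(cells$x[2] - cells$x[1]) - 1
  expect_equal(gap, 0, tolerance = 1e-3)
})
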