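# Algorithm-1 coupling: height normalisation, thickness cache, step order,
# R-vs-compiled equivalence, initialisation.

test_that("normalised height clamps and handles a degenerate corneum", {
  expect_equal(normalized_height(4, 10, 4), 0)
  expect_equal(normalized_height(20, 10, 4), 1)
  expect_equal(normalized_height(9, 10, 4), 0.5)
  expect_equal(normalized_height(c(3, 5), 0, 4), c(0, 1))
  expect_error(normalized_height(5, -1, 4), "non-negative")
})

test_that("thickness is the mean surface height minus the corneum base", {
  dom <- sim_domain(5, 5)
  cells <- cell_df(id = 1:2, type = "diff", x = c(1.5, 3.5), y = c(1.5, 3.5),
                   z = c(10, 12))
  th <- update_thickness(cells, dom, h = 4)
  expect_equal(th$tissue, 11)
  expect_equal(th$tau, 7)
  flat <- cell_df(id = 1:2, type = "diff", x = c(1.5, 3.5), y = c(1.5, 3.5),
                  z = c(14.8, 14.8))
  expect_equal(update_thickness(flat, dom, h = 4)$tau, 10.8)
  low <- cell_df(id = 1L, type = "stem", x = 1, y = 1, z = 0.5)
  expect_equal(update_thickness(low, dom, h = 4)$tau, 0)
  expect_error(update_thickness(low[0, ], dom, 4), "empty")
})

test_that("a single basal stem cell neither reacts nor desquamates", {
  st <- make_fixture("single-cell")
  cfg <- run_config(domain = sim_domain(5, 5))
  out <- step_multiscale(st, cfg)
  expect_equal(nrow(out$cells), 1)
  expect_equal(out$cells$s, 1)       # chemistry frozen below z = h
  expect_equal(out$cells$p, 0)
  expect_equal(nrow(out$removals), 0)
})

test_that("one compiled step matches the pure-R reference step", {
  st <- make_fixture("mini-tissue")
  st$tau <- 4  # fixed cache used identically by both paths
  cfg <- run_config(domain = sim_domain(5, 5))
  r_out <- step_multiscale(st, cfg)
  c_out <- run_multiscale(st, cfg, steps = 1)
  expect_equal(c_out$cells$id, r_out$cells$id)
  for (col in c("x", "y", "z", "radius")) {
    expect_lt(max(abs(c_out$cells[[col]] - r_out$cells[[col]])), 1e-8,
              label = paste("column", col))
  }
  # the chemistry integrators differ (adaptive RK45 vs stability-bounded
  # RK4), so agreement is required within the chemistry integration tolerance
  for (col in c("e", "s", "i", "c_s", "c_i", "p")) {
    expect_lt(max(abs(c_out$cells[[col]] - r_out$cells[[col]])), 1e-5,
              label = paste("column", col))
  }
  expect_equal(c_out$cells$is_surface, r_out$cells$is_surface)
  expect_equal(c_out$tau, r_out$tau)
  # and over several steps the paths stay together
  r5 <- st; for (k in 1:5) r5 <- step_multiscale(r5, cfg)
  c5 <- run_multiscale(st, cfg, steps = 5)
  expect_lt(max(abs(c5$cells$z - r5$cells$z)), 1e-6)
  expect_lt(max(abs(c5$cells$s - r5$cells$s)), 1e-5)
})

test_that("chemistry below the corneum base stays frozen in long runs", {
  st <- make_fixture("mini-tissue")
  cfg <- run_config(domain = sim_domain(5, 5))
  set.seed(21)
  out <- run_multiscale(st, cfg, steps = 1000)
  low <- out$cells$z < 4 & is.na(out$cells$entry_time)
  expect_true(all(out$cells$s[low] == 1))
  expect_true(all(out$cells$p[low] == 0))
  # conservation invariants hold for every cell after 1000 steps
  r <- cfg$chem$e_T / cfg$chem$s_0
  enz <- out$cells$e + out$cells$c_s + out$cells$c_i
  sub <- out$cells$s + r * out$cells$c_s + out$cells$p
  inh <- out$cells$i + r * out$cells$c_i -
    pmin(out$cells$i_t_level, cfg$chem$e_T) / cfg$chem$s_0
  expect_lt(max(abs(enz - 1)), 1e-5)
  expect_lt(max(abs(sub - 1)), 1e-5)
  expect_lt(max(abs(inh)), 1e-5)
})

test_that("a free surface cell detaches within the ballistic bound", {
  # two-cell column: basal stem plus a fully degraded surface cell at
  # contact; with zero adhesion the removal force drives it 0.7 CD in
  # ceil(0.7 * eta / (F_D * dt)) = 168 steps
  cells <- cell_df(id = 1:2, type = c("stem", "diff"), x = c(2.5, 2.5),
                   y = c(2.5, 2.5), z = c(0.5, 1.5),
                   birth_time = c(-20, -10), t_c = c(200, NA),
                   s = c(0, 0), p = c(1, 1), c_i = 1, i_t_level = 0.1e-9,
                   is_surface = c(FALSE, TRUE))
  st <- simulation_state(cells)
  cfg <- run_config(domain = sim_domain(5, 5),
                    chem = chem_params(s_0 = 10e-6, e_T = 0))
  bound <- ceiling(0.7 * cfg$mechanics$eta /
                     (cfg$desquamation$F_D * cfg$mechanics$dt))
  set.seed(22)
  out <- run_multiscale(st, cfg, steps = bound + 20)
  expect_equal(nrow(out$removals), 1)
  expect_equal(out$removals$id, 2L)
  expect_lte(out$removals$time_hr, (bound + 20) * cfg$mechanics$dt)
})

test_that("the thickness cache refreshes hourly and is insensitive to
           refreshing every step", {
  st <- make_fixture("column-block")
  cfg <- run_config(domain = sim_domain(5, 5))
  s1 <- st
  for (k in 1:119) s1 <- step_multiscale(s1, cfg)
  expect_equal(nrow(s1$thickness), 0)  # no refresh before step 120
  s1 <- step_multiscale(s1, cfg)
  expect_equal(nrow(s1$thickness), 1)
  expect_equal(s1$thickness$t_hr, 1)
  # refresh-rate insensitivity on a short tissue run
  stm <- make_fixture("mini-tissue")
  cfg_hourly <- run_config(domain = sim_domain(5, 5))
  cfg_every <- run_config(domain = sim_domain(5, 5),
                          coupling = coupling_config(f_h = 120))
  set.seed(23)
  a <- run_multiscale(stm, cfg_hourly, steps = 2880)
  set.seed(23)
  b <- run_multiscale(stm, cfg_every, steps = 2880)
  expect_lt(abs(mean(a$thickness$tissue_cd) - mean(b$thickness$tissue_cd)) /
              mean(a$thickness$tissue_cd), 0.02)
})

test_that("tissue initialisation seeds one stem per CD^2 and fills under the
           ceiling", {
  cfg10 <- run_config()
  st <- initialize_tissue(cfg10, seed = 1, fill = FALSE)
  expect_equal(nrow(st$cells), 100)
  expect_true(all(st$cells$type == "stem"))
  expect_true(all(st$cells$z == 0.5))
  # different seeds: same stem count, different jitter
  st2 <- initialize_tissue(cfg10, seed = 2, fill = FALSE)
  expect_equal(nrow(st2$cells), 100)
  expect_false(all(st2$cells$x == st$cells$x))
  # short filling run respects the provisional ceiling
  cfg5 <- run_config(domain = sim_domain(5, 5),
                     coupling = coupling_config(fill_days = 0.5))
  stf <- initialize_tissue(cfg5, seed = 3)
  expect_true(all(stf$cells$z <= cfg5$coupling$fill_ceiling))
  expect_equal(sum(stf$cells$type == "stem"), 25)
})
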