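# Subcellular model: pH gradient, rate constants, ODE system, single cell.

test_that("pH polynomial evaluates, clamps and decreases monotonically", {
  m <- ph_model()
  expect_equal(ph_at(0, m), 6.8482)
  expect_equal(ph_at(1, m), 6.8482 - 0.3765 - 5.1663 + 3.1792)  # 4.4846
  expect_equal(ph_at(0.5, m), 5.765775, tolerance = 1e-10)
  # clamping outside [0, 1]
  expect_equal(ph_at(-2, m), ph_at(0, m))
  expect_equal(ph_at(7, m), ph_at(1, m))
  # strictly decreasing on [0, 1]
  xi <- seq(0, 1, by = 0.001)
  expect_true(all(diff(ph_at(xi, m)) < 0))
  expect_gt(ph_at(0, m), ph_at(1, m))
  expect_error(ph_at(NaN, m), "finite")
})

test_that("KLK-LEKTI rates follow the pH forms and stay non-negative", {
  r <- rate_constants()
  at_root <- klk_lekti_rates(19.5 / 5.2, r)
  expect_equal(at_root$k_plus3, 0)
  deep <- klk_lekti_rates(6.8482, r)
  expect_equal(deep$k_plus3, 1.611e8, tolerance = 1e-4)
  expect_equal(deep$k_minus3, 2.75e-3, tolerance = 1e-3)
  # floored below the root, non-negative across the physiological range
  expect_equal(klk_lekti_rates(3.0, r)$k_plus3, 0)
  ph <- seq(4.4, 7.0, by = 0.01)
  out <- klk_lekti_rates(ph, r)
  expect_true(all(out$k_plus3 >= 0) && all(out$k_minus3 >= 0))
})

test_that("rate constants enforce the Michaelis relation", {
  r <- rate_constants()
  expect_equal((r$k_minus1 + r$k_2) / r$k_plus1, r$K_M, tolerance = 0.005)
  expect_error(rate_constants(k_2 = 5e3), "Michaelis")
  expect_error(rate_constants(k_plus1 = -1), "non-negative")
})

test_that("time rescaling multiplies rates by lambda and reproduces the
           multiscale parameter set", {
  spec <- scaling_spec()
  expect_equal(spec$T_hat, 160)
  expect_equal(spec$lambda, 3)
  sc <- scale_rates(rate_constants(), spec)
  expect_equal(sc$k_2, 6.87e3)
  expect_equal(sc$k_plus1, 1.49e8, tolerance = 1e-3)
  expect_equal(sc$a3, 15.6)   # scaled k_plus3 linear form
  expect_equal(sc$b3, 58.5)
  expect_equal(sc$A3, 6.9e6)  # scaled k_minus3 prefactor
  expect_equal(sc$B3, 3.0)    # pH sensitivity unchanged
  expect_equal(sc$K_M, 4.60e-5)
  # identity scaling
  id <- scale_rates(rate_constants(), scaling_spec(T_M = 160, tau_T = 8))
  expect_equal(unclass(id), unclass(rate_constants()))
  expect_error(scaling_spec(v_z = 0), "positive")
})

test_that("quasi-equilibrium initial conditions match the closed forms", {
  rs <- multiscale_rates()
  # fully inhibited: everything locked in the inhibitor complex
  st <- initial_chem_state(chem_params(e_T = 1e-6, i_T = 1e-6), rs)
  expect_equal(chem_state_vec_list(st), c(0, 1, 0, 0, 1, 0))
  # no inhibitor
  st0 <- initial_chem_state(chem_params(s_0 = 10e-6, e_T = 1e-6, i_T = 0), rs)
  expect_equal(st0$e, 0.8218, tolerance = 2e-4)
  expect_equal(st0$c_s, 0.1782, tolerance = 1e-3)
  # half inhibited
  sth <- initial_chem_state(chem_params(s_0 = 10e-6, e_T = 1e-6, i_T = 0.5e-6), rs)
  expect_equal(sth$e, 0.4109, tolerance = 1e-3)
  expect_equal(sth$c_i, 0.5)
  expect_equal(sth$c_s, 0.0891, tolerance = 1e-3)
  # at t = 0 the enzyme and inhibitor totals are exact; the substrate total
  # is offset by (e_T/s_0) * c_s(0) because the quasi-equilibrium IC places
  # enzyme in complex without depleting s
  for (frac in c(0, 0.25, 0.9, 1)) {
    cp <- chem_params(s_0 = 10e-6, e_T = 0.7e-6, i_T = frac * 0.7e-6)
    ic <- initial_chem_state(cp, rs)
    res <- conservation_residuals(ic, cp)
    expect_equal(res[["enzyme"]], 0)
    expect_equal(res[["inhibitor"]], 0)
    expect_equal(res[["substrate"]], cp$e_T / cp$s_0 * ic$c_s)
  }
  expect_warning(initial_chem_state(chem_params(e_T = 0, i_T = 0), rs),
                 "degenerate")
})

test_that("chemical RHS conserves the three linear invariants algebraically", {
  cp <- chem_params(s_0 = 10e-6, e_T = 0.7e-6, i_T = 0.35e-6)
  rs <- rate_constants()
  set.seed(7)
  for (k in 1:20) {
    st <- random_chem_state(cp)
    d <- chem_rhs(st, cp, rs, pH = runif(1, 4.4, 7))
    r <- cp$e_T / cp$s_0
    expect_lt(abs(d[["e"]] + d[["c_s"]] + d[["c_i"]]), 1e-10)
    expect_lt(abs(d[["s"]] + r * d[["c_s"]] + d[["p"]]), 1e-10)
    expect_lt(abs(d[["i"]] + r * d[["c_i"]]), 1e-10)
  }
  # single surviving term: e = s = 1 with single-cell rates
  st1 <- chem_state(e = 1, s = 1, i = 0, c_s = 0, c_i = 0, p = 0)
  d <- chem_rhs(st1, chem_params(s_0 = 10e-6, e_T = 0.7e-6, i_T = 0),
                rs, pH = 19.5 / 5.2)  # k_plus3 = 0 there
  expect_equal(d[["e"]], -497)
  # all-zero rates freeze the system
  rz <- rate_constants(k_plus1 = 1e-300, k_2 = 0, K_M = 0, a3 = 0, b3 = 0,
                       A3 = 0)
  expect_equal(unname(chem_rhs(st1, cp, rz, 5)), rep(0, 6))
})

test_that("integrate_chem matches the brute-force RK4 oracle", {
  cp <- chem_params(s_0 = 10e-6, e_T = 0.7e-6, i_T = 0.35e-6)
  rs <- multiscale_rates()
  set.seed(11)
  for (k in 1:5) {
    st <- random_chem_state(cp)
    pH <- runif(1, 4.5, 6.8)
    got <- integrate_chem(st, cp, rs, pH, dt = 1)
    k3 <- klk_lekti_rates(pH, rs)
    want <- oracle_rk4(chem_state_vec_list(st), 1, 1e4, cp$s_0, cp$e_T,
                       rs$k_plus1, rs$k_minus1, rs$k_2,
                       k3$k_plus3, k3$k_minus3)
    expect_equal(chem_state_vec_list(got), want, tolerance = 1e-4)
  }
})

test_that("trajectories preserve conservation and monotonicity", {
  cp <- chem_params(s_0 = 10e-6, e_T = 1e-6, i_T = 0.5e-6)
  rs <- rate_constants()
  st <- initial_chem_state(cp, rs)
  res0 <- conservation_residuals(st, cp)
  svals <- st$s; pvals <- st$p
  for (k in 1:30) {
    st <- integrate_chem(st, cp, rs, pH = 5.5, dt = 0.5)
    # the three linear totals stay at their initial values
    expect_lt(max(abs(conservation_residuals(st, cp) - res0)), 1e-5)
    svals <- c(svals, st$s); pvals <- c(pvals, st$p)
  }
  expect_true(all(diff(svals) <= 1e-12))
  expect_true(all(diff(pvals) >= -1e-12))
})

test_that("degenerate regimes freeze the expected species", {
  rs <- rate_constants()
  # no enzyme: substrate untouched
  cp0 <- chem_params(s_0 = 10e-6, e_T = 0, i_T = 0)
  st <- chem_state(e = 0, s = 1, i = 0, c_s = 0, c_i = 0, p = 0)
  out <- integrate_chem(st, cp0, rs, pH = 5, dt = 10)
  expect_equal(out$s, 1)
  # fully inhibited with no dissociation: frozen at the IC
  rsA0 <- rate_constants(A3 = 0)
  cpi <- chem_params(e_T = 1e-6, i_T = 1e-6)
  sti <- initial_chem_state(cpi, rsA0)
  outi <- integrate_chem(sti, cpi, rsA0, pH = 5, dt = 10)
  expect_equal(chem_state_vec_list(outi), chem_state_vec_list(sti),
               tolerance = 1e-12)
})

test_that("time-rescaling equivalence: scaled rates over compressed time
           reproduce the unscaled trajectory", {
  cp <- chem_params(s_0 = 10e-6, e_T = 0.1e-9, i_T = 0.1e-9)
  base <- simulate_single_cell(0.05, 240, cp, rate_constants(),
                               dt_sample = 1)
  spec <- scaling_spec()  # lambda = 3
  fast <- simulate_single_cell(0.05 * spec$lambda, 240 / spec$lambda, cp,
                               scale_rates(rate_constants(), spec),
                               dt_sample = 1 / spec$lambda)
  expect_equal(fast$s[nrow(fast)], base$s[nrow(base)], tolerance = 1e-4)
  expect_equal(fast$c_i[nrow(fast)], base$c_i[nrow(base)], tolerance = 1e-4)
})

test_that("reducing the inhibitor never slows substrate degradation", {
  fracs <- c(0, 0.3, 0.7, 1)
  finals <- vapply(fracs, function(f) {
    cp <- chem_params(s_0 = 10e-6, e_T = 1e-6, i_T = f * 1e-6)
    tr <- simulate_single_cell(0.05, 24, cp, rate_constants(), dt_sample = 1)
    tr$s[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(finals) >= -1e-9))  # s(24) increases with i_T
})

test_that("single-cell runs reproduce the expected regimes", {
  # effective concentration: majority of s degraded by 20 days
  cp_eff <- chem_params(s_0 = 10e-6, e_T = 0.1e-9, i_T = 0.1e-9)
  tr <- simulate_single_cell(0.05, 480, cp_eff, rate_constants(),
                             dt_sample = 1)
  expect_lt(tr$s[nrow(tr)], 0.5)
  # stationary cell with no enzyme: flat trajectory
  tr0 <- suppressWarnings(  # degenerate e_T = 0 state warns at the IC
    simulate_single_cell(0, 24, chem_params(s_0 = 10e-6, e_T = 0, i_T = 0),
                         rate_constants(), dt_sample = 1))
  expect_true(all(tr0$s == 1) && all(tr0$p == 0))
})

test_that("enzyme concentration estimation matches the literature table", {
  expect_equal(estimate_enzyme_concentration(3.1, 33, 0.5, 0.13), 0.723e-6,
               tolerance = 1e-3)
  # linearity in the dry weight, inverse in the extracellular fraction
  base <- estimate_enzyme_concentration(3.1, 33, 0.5, 0.13)
  expect_equal(estimate_enzyme_concentration(6.2, 33, 0.5, 0.13), 2 * base)
  expect_equal(estimate_enzyme_concentration(3.1, 33, 0.5, 0.26), base / 2)
  expect_error(estimate_enzyme_concentration(3.1, 33, 0.5, 1.3),
               "extracellular_fraction")
})

test_that("CND concentration estimation follows the slab geometry oracle", {
  expect_equal(estimate_cnd_concentration(0, 0, 30, 0.3, 0.044), 0)
  base <- estimate_cnd_concentration(16, 10, 30, 0.3, 0.044)
  expect_equal(estimate_cnd_concentration(32, 20, 30, 0.3, 0.044), 2 * base)
  # independent hand calculation: counts over half-gap shell volume
  count <- 16 * (4 * 30 * 0.3) + 10 * (2 * 30^2)
  vol_l <- (4 * 30 * 0.3 + 2 * 30^2) * 0.044 / 2 * 1e-15
  expect_equal(base, count / (6.02214076e23 * vol_l), tolerance = 1e-12)
  expect_error(estimate_cnd_concentration(16, 10, 30, 0.3, 0), "gap")
})
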