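#' Reactant concentration parameters
#'
#' Total concentrations driving the dimensionless subcellular system:
#' initial corneodesmosome substrate `s_0`, total KLK enzyme `e_T` and total
#' LEKTI inhibitor `i_T` (all molar). Physiologically `i_T <= e_T` (the most
#' effective LEKTI fragments are equimolar with KLK5 in normal skin; Netherton
#' Syndrome reduces `i_T`). Defaults are the reference single-cell run:
#' `s_0 = 10` uM and `e_T = i_T = 1` uM, the enzyme level consistent with the
#' effective association rate `k_plus1 * e_T = 49.7` hr^-1 used to
#' parameterise the system.
#'
#' @param s_0 Initial corneodesmosome concentration, M.
#' @param e_T Total enzyme concentration, M.
#' @param i_T Total inhibitor concentration, M.
#' @return An object of class `chem_params`.
#' @export
chem_params <- function(s_0 = 10e-6, e_T = 1e-6, i_T = e_T) {
  if (!all(is.finite(c(s_0, e_T, i_T)))) stop("chem_params must be finite")
  if (s_0 <= 0) stop("s_0 must be positive")
  if (e_T < 0) stop("e_T must be non-negative")
  if (i_T < 0 || i_T > e_T + 1e-15 * max(e_T, 1)) {
    stop("require 0 <= i_T <= e_T")
  }
  structure(list(s_0 = s_0, e_T = e_T, i_T = i_T), class = "chem_params")
}

#' Dimensionless subcellular chemical state
#'
#' Fractions of the six species: `e`, `c_s`, `c_i` are fractions of total
#' enzyme `e_T`; `s`, `i`, `p` are fractions of `s_0`. Three linear
#' conservation laws hold along any trajectory:
#' enzyme `e + c_s + c_i = 1`; substrate `s + (e_T/s_0) c_s + p = 1`;
#' inhibitor `i + (e_T/s_0) c_i = i_T/s_0`.
#'
#' @param e,s,i,c_s,c_i,p Species fractions.
#' @param t Time, hr.
#' @return An object of class `chem_state`.
#' @export
chem_state <- function(e, s, i, c_s, c_i, p, t = 0) {
  v <- c(e = e, s = s, i = i, c_s = c_s, c_i = c_i, p = p)
  if (!all(is.finite(v))) stop("chem_state components must be finite")
  if (any(v < -1e-9)) stop("chem_state components must be >= -1e-9")
  structure(list(e = unname(e), s = unname(s), i = unname(i),
                 c_s = unname(c_s), c_i = unname(c_i), p = unname(p),
                 t = unname(t)),
            class = "chem_state")
}

chem_state_vec <- function(state) {
  c(state$e, state$s, state$i, state$c_s, state$c_i, state$p)
}

chem_state_from_vec <- function(y, t) {
  chem_state(e = y[1], s = y[2], i = y[3], c_s = y[4], c_i = y[5], p = y[6],
             t = t)
}

#' Check the conservation laws of a chemical state
#'
#' @param state A [chem_state()].
#' @param params A [chem_params()].
#' @return Named numeric vector of the three conservation residuals
#'   (enzyme, substrate, inhibitor).
#' @export
conservation_residuals <- function(state, params) {
  r <- params$e_T / params$s_0
  c(
    enzyme = state$e + state$c_s + state$c_i - 1,
    substrate = state$s + r * state$c_s + state$p - 1,
    inhibitor = state$i + r * state$c_i - params$i_T / params$s_0
  )
}

#' Initial conditions on entry to the corneum
#'
#' Corneodesmosomes start at full concentration (`s = 1`) and all inhibitor is
#' assumed pre-bound to enzyme (`c_i = i_T/e_T`, `i = 0`). Putting the
#' remaining enzyme entirely in the free pool makes the system stiff, so the
#' free enzyme and substrate complex are instead placed on their instantaneous
#' quasi-equilibrium:
#' `e(0) = k_2 / (k_plus1 * s_0 + k_2) * (1 - i_T/e_T)`, `c_s(0) = 1 - e(0) - c_i(0)`.
#'
#' @param params A [chem_params()].
#' @param rates A [rate_constants()].
#' @return A [chem_state()] at `t = 0`. If `e_T = 0` the enzyme pools are all
#'   zero (degenerate state, with a warning).
#' @export
initial_chem_state <- function(params, rates) {
  if (params$e_T == 0) {
    warning("e_T = 0: degenerate chemical state with no enzyme")
    return(chem_state(e = 0, s = 1, i = 0, c_s = 0, c_i = 0, p = 0))
  }
  frac_i <- params$i_T / params$e_T
  e0 <- rates$k_2 / (rates$k_plus1 * params$s_0 + rates$k_2) * (1 - frac_i)
  chem_state(e = e0, s = 1, i = 0, c_s = 1 - e0 - frac_i, c_i = frac_i, p = 0)
}

#' Time derivatives of the dimensionless subcellular system
#'
#' Mass-action rates for the competitive-inhibition scheme at a given pH. The
#' pH enters through the KLK-LEKTI rates `k_plus3(pH)` and `k_minus3(pH)`.
#' The derivative vector satisfies the three conservation laws algebraically:
#' `de + dc_s + dc_i = 0`, `ds + (e_T/s_0) dc_s + dp = 0`,
#' `di + (e_T/s_0) dc_i = 0`.
#'
#' @param state A [chem_state()].
#' @param params A [chem_params()].
#' @param rates A [rate_constants()].
#' @param pH Local pH.
#' @return Named numeric vector of derivatives `(e, s, i, c_s, c_i, p)`, hr^-1.
#' @export
chem_rhs <- function(state, params, rates, pH) {
  k3 <- klk_lekti_rates(pH, rates)
  y <- chem_state_vec(state)
  chem_rhs_vec(y, params, rates, k3$k_plus3, k3$k_minus3)
}

chem_rhs_vec <- function(y, params, rates, k_plus3, k_minus3) {
  e <- y[1]; s <- y[2]; i <- y[3]; c_s <- y[4]; c_i <- y[5]
  s0 <- params$s_0; eT <- params$e_T
  kp1 <- rates$k_plus1; km1 <- rates$k_minus1; k2 <- rates$k_2
  bind_s <- kp1 * s0 * e * s
  unbind_s <- (km1 + k2) * c_s
  bind_i <- k_plus3 * s0 * e * i
  unbind_i <- k_minus3 * c_i
  c(
    e = -bind_s + unbind_s - bind_i + unbind_i,
    s = (-kp1 * eT * e * s + km1 * (eT / s0) * c_s),
    i = (-k_plus3 * eT * e * i + k_minus3 * (eT / s0) * c_i),
    c_s = bind_s - unbind_s,
    c_i = bind_i - unbind_i,
    p = k2 * (eT / s0) * c_s
  )
}

# Adaptive Cash-Karp RK45 with PI-free step control. f(t, y) -> dy/dt.
# Returns y at t1. Written in-package because no ODE-solver package is
# available in the supported environment.
rk45_step <- function(f, t, y, h) {
  k1 <- f(t, y)
  k2 <- f(t + h / 5, y + h * (k1 / 5))
  k3 <- f(t + 3 * h / 10, y + h * (3 * k1 / 40 + 9 * k2 / 40))
  k4 <- f(t + 3 * h / 5, y + h * (3 * k1 / 10 - 9 * k2 / 10 + 6 * k3 / 5))
  k5 <- f(t + h, y + h * (-11 * k1 / 54 + 5 * k2 / 2 - 70 * k3 / 27 + 35 * k4 / 27))
  k6 <- f(t + 7 * h / 8,
          y + h * (1631 * k1 / 55296 + 175 * k2 / 512 + 575 * k3 / 13824 +
                     44275 * k4 / 110592 + 253 * k5 / 4096))
  y5 <- y + h * (37 * k1 / 378 + 250 * k3 / 621 + 125 * k4 / 594 +
                   512 * k6 / 1771)
  y4 <- y + h * (2825 * k1 / 27648 + 18575 * k3 / 48384 + 13525 * k4 / 55296 +
                   277 * k5 / 14336 + k6 / 4)
  list(y = y5, err = y5 - y4)
}

rk45_integrate <- function(f, y, t0, t1, rtol, atol, h0 = NULL) {
  t <- t0
  h <- if (is.null(h0)) (t1 - t0) / 100 else h0
  n_reject <- 0L
  while (t < t1 - 1e-12 * max(1, abs(t1))) {
    clipped <- h > t1 - t
    h_try <- if (clipped) t1 - t else h
    st <- rk45_step(f, t, y, h_try)
    if (any(!is.finite(st$y))) {
      h <- h_try / 2
      n_reject <- n_reject + 1L
      if (n_reject > 10000L) stop("ODE integration failed: non-finite state")
      next
    }
    sc <- atol + rtol * pmax(abs(y), abs(st$y))
    errn <- sqrt(mean((st$err / sc)^2))
    if (errn <= 1) {
      t <- t + h_try
      y <- st$y
      # grow only the unclipped proposal so segment ends do not shrink it
      if (!clipped) h <- h * min(5, max(0.2, 0.9 * errn^-0.2))
    } else {
      h <- h_try * max(0.1, 0.9 * errn^-0.25)
      n_reject <- n_reject + 1L
      if (n_reject > 100000L) stop("ODE integration failed: step size collapse")
    }
  }
  attr(y, "h_last") <- h
  y
}

#' Advance the subcellular state over a time step at fixed pH
#'
#' Integrates the six-species system for `dt` hours with the pH (and hence the
#' KLK-LEKTI rates) held constant, as in the per-step coupling of the tissue
#' model. Uses an embedded adaptive Runge-Kutta (Cash-Karp 4/5) scheme; on
#' failure the step is retried with halved initial step before erroring.
#'
#' @param state A [chem_state()].
#' @param params A [chem_params()].
#' @param rates A [rate_constants()].
#' @param pH Local pH, held fixed over the step.
#' @param dt Step duration, hr.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @return The advanced [chem_state()] at `state$t + dt`.
#' @export
integrate_chem <- function(state, params, rates, pH, dt,
                           rtol = 1e-4, atol = 1e-6) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  k3 <- klk_lekti_rates(pH, rates)
  f <- function(t, y) chem_rhs_vec(y, params, rates, k3$k_plus3, k3$k_minus3)
  y0 <- chem_state_vec(state)
  y <- tryCatch(
    rk45_integrate(f, y0, 0, dt, rtol, atol),
    error = function(e) {
      tryCatch(
        rk45_integrate(f, y0, 0, dt, rtol / 10, atol / 10, h0 = dt / 1e4),
        error = function(e2) {
          stop(sprintf(
            "chemical integration failed (pH %.3f, t %.3f hr): %s",
            pH, state$t, conditionMessage(e2)
          ))
        }
      )
    }
  )
  if (any(y < -1e-9)) {
    # undershoot beyond the state invariant: redo the step more accurately
    y <- rk45_integrate(f, y0, 0, dt, rtol / 100, 1e-12)
  }
  y[y < 0 & y > -1e-9] <- 0
  chem_state_from_vec(y, state$t + dt)
}

#' Solve the subcellular system for a single migrating cell
#'
#' The cell rises through the corneum at constant normalised velocity `v_xi`
#' (per day), so its height is `xi(t) = min(v_xi * t, 1)` and the pH it
#' experiences follows the corneum gradient continuously. This is the
#' reference single-cell solution that the coupled tissue model collapses onto
#' at homeostasis.
#'
#' @param v_xi Normalised vertical velocity, day^-1 (0.05 for a 20-day
#'   corneum transit).
#' @param duration Simulated time, hr.
#' @param params A [chem_params()].
#' @param rates A [rate_constants()].
#' @param ph_model A [ph_model()].
#' @param dt_sample Output sampling interval, hr (must be <= 1).
#' @param rtol,atol Integration tolerances.
#' @return A data.frame with columns `t_hr`, `xi`, `pH`, `e`, `s`, `i`,
#'   `c_s`, `c_i`, `p`.
#' @examples
#' tr <- simulate_single_cell(0.05, 48, chem_params(e_T = 0.1e-9))
#' tail(tr$s, 1)
#' @export
simulate_single_cell <- function(v_xi = 0.05, duration = 480,
                                 params = chem_params(),
                                 rates = rate_constants(),
                                 ph_model = episkin::ph_model(),
                                 dt_sample = 0.5,
                                 rtol = 1e-6, atol = 1e-9) {
  if (v_xi < 0) stop("v_xi must be non-negative")
  if (dt_sample <= 0 || dt_sample > 1) stop("dt_sample must be in (0, 1] hr")
  f <- function(t, y) {
    xi <- min(v_xi * t / 24, 1)
    k3 <- klk_lekti_rates(ph_at(xi, ph_model), rates)
    chem_rhs_vec(y, params, rates, k3$k_plus3, k3$k_minus3)
  }
  times <- seq(0, duration, by = dt_sample)
  if (times[length(times)] < duration) times <- c(times, duration)
  n <- length(times)
  out <- matrix(NA_real_, n, 6)
  y <- chem_state_vec(initial_chem_state(params, rates))
  out[1, ] <- y
  h_carry <- NULL  # reuse the accepted step size across sample segments
  for (k in seq_len(n - 1)) {
    y <- rk45_integrate(f, y, times[k], times[k + 1], rtol, atol,
                        h0 = h_carry)
    h_carry <- attr(y, "h_last")
    out[k + 1, ] <- y
  }
  xi <- pmin(v_xi * times / 24, 1)
  data.frame(
    t_hr = times, xi = xi, pH = ph_at(xi, ph_model),
    e = out[, 1], s = out[, 2], i = out[, 3],
    c_s = out[, 4], c_i = out[, 5], p = out[, 6]
  )
}
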