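#' Simulation state container
#'
#' @param cells A [cell_df()].
#' @param t Current time, hr.
#' @param tau Cached corneum thickness, CD.
#' @param step Step counter (mechanics steps since state creation).
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(cells, t = 0, tau = 0, step = 0L) {
  if (tau < 0) stop("tau must be non-negative")
  structure(list(
    cells = cells, t = t, tau = tau, step = as.integer(step),
    thickness = data.frame(t_hr = numeric(), tissue_cd = numeric(),
                           tau_cd = numeric()),
    removals = data.frame(id = integer(), time_hr = numeric(),
                          age_hr = numeric(), z_cd = numeric(), s = numeric(),
                          entry_time_hr = numeric(), clump = integer()),
    divisions = 0L,
    snapshots = list()
  ), class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(
    "<simulation state: %d cells, t = %.2f hr, corneum thickness %.2f CD>\n",
    nrow(x$cells), x$t, x$tau))
  invisible(x)
}

#' Normalised height of a cell in the corneum
#'
#' `xi = (z - h) / tau`, clamped to `[0, 1]`: cells above the cached corneum
#' surface see `xi = 1`, cells below the corneum base `xi = 0`. A degenerate
#' corneum (`tau = 0`) maps everything above `h` to `xi = 1`.
#'
#' @param z Cell centre height(s), CD.
#' @param tau Cached corneum thickness, CD.
#' @param h Corneum base height, CD.
#' @return `xi` in `[0, 1]`.
#' @export
normalized_height <- function(z, tau, h) {
  if (tau < 0) stop("tau must be non-negative")
  if (tau == 0) return(as.numeric(z > h))
  pmin(pmax((z - h) / tau, 0), 1)
}

#' Recompute tissue height and corneum thickness
#'
#' Tissue height is the mean centre height of the current surface cells;
#' corneum thickness is the tissue height minus the corneum base `h`, floored
#' at zero.
#'
#' @param cells A [cell_df()].
#' @param domain A [sim_domain()].
#' @param h Corneum base height, CD.
#' @param dx Surface grid size, CD.
#' @return List with `tissue` and `tau` (both CD).
#' @export
update_thickness <- function(cells, domain, h, dx = 1) {
  if (nrow(cells) == 0) stop("cannot compute thickness of an empty tissue")
  ids <- identify_surface_cells(cells, domain, dx)
  tissue <- mean(cells$z[cells$id %in% ids])
  list(tissue = tissue, tau = max(tissue - h, 0))
}

#' Advance the multiscale model by one mechanics step
#'
#' Pure-R reference implementation of the per-step coupling loop, in order:
#' (1) for every cell at or above the corneum base, map height to `xi`, `xi`
#' to pH, pH to KLK-LEKTI rates, and integrate the subcellular system over
#' `dt` (chemistry below the base is frozen); (2) assemble pair forces with
#' CND-scaled adhesion, rotational forces on dividing pairs, the basal
#' membrane interaction and the removal force on surface cells; (3) advance
#' positions; (4) attempt divisions; (5) cull detached cells; (6) refresh the
#' surface set; (7) refresh the cached thickness on its schedule.
#'
#' This path is used for small fixtures and verification; long simulations
#' use the compiled loop in [run_multiscale()], which is cross-checked
#' against this implementation in the test suite.
#'
#' @param state A [simulation_state()].
#' @param cfg A [run_config()].
#' @param mode `"normal"` (removal force + detachment cull) or `"filling"`
#'   (no removal force; cells above the provisional ceiling are deleted).
#' @return The advanced [simulation_state()].
#' @export
step_multiscale <- function(state, cfg, mode = c("normal", "filling")) {
  mode <- match.arg(mode)
  mech <- cfg$mechanics
  h <- cfg$coupling$h_corneum_base
  dt <- mech$dt
  cells <- state$cells

  # (1) subcellular chemistry
  in_corneum <- cells$z >= h
  newly <- in_corneum & is.na(cells$entry_time)
  cells$entry_time[newly] <- state$t
  for (m in which(in_corneum)) {
    xi <- normalized_height(cells$z[m], state$tau, h)
    pH <- ph_at(xi, cfg$ph)
    cp <- chem_params(s_0 = cfg$chem$s_0, e_T = cfg$chem$e_T,
                      i_T = min(cells$i_t_level[m], cfg$chem$e_T))
    st <- chem_state(cells$e[m], cells$s[m], cells$i[m],
                     cells$c_s[m], cells$c_i[m], cells$p[m], t = state$t)
    st <- integrate_chem(st, cp, cfg$rates, pH, dt)
    cells$e[m] <- st$e; cells$s[m] <- st$s; cells$i[m] <- st$i
    cells$c_s[m] <- st$c_s; cells$c_i[m] <- st$c_i; cells$p[m] <- st$p
  }

  # (2)-(3) forces and positions; the neighbour list is reused below for the
  # detachment cull (pre-move positions)
  F_D <- if (mode == "normal") cfg$desquamation$F_D else 0
  pairs <- build_neighbor_lists(cells, cfg$domain, mech$neighbour_cutoff)
  F <- assemble_forces(cells, cfg$domain, mech, F_D = F_D, pairs = pairs)
  cells <- advance_positions(cells, F, mech$eta, dt, cfg$domain)

  # newborn growth and pair release
  age <- state$t + dt - cells$birth_time
  young <- cells$type == "diff" & age < mech$growth_time
  cells$radius <- ifelse(young, mech$R_0 * (0.5 + 0.5 * age / mech$growth_time),
                         mech$R_0)
  paired <- which(!is.na(cells$partner))
  for (m in paired) {
    twin <- match(cells$partner[m], cells$id)
    if (is.na(twin)) { cells$partner[m] <- NA_integer_; next }
    d <- min_image(cells$x[twin] - cells$x[m], cells$y[twin] - cells$y[m],
                   cfg$domain)
    dist <- sqrt(d$dx^2 + d$dy^2 + (cells$z[twin] - cells$z[m])^2)
    if (dist >= 2 * mech$R_0) {
      cells$partner[m] <- NA_integer_
      cells$partner[twin] <- NA_integer_
    }
  }

  # (4) divisions
  div <- attempt_divisions(cells, state$t + dt, cfg$prolif, mech, cfg$domain,
                           chem = cfg$chem, rates = cfg$rates)
  cells <- div$cells
  state$divisions <- state$divisions + div$divisions
  state$cells <- cells
  state$t <- state$t + dt
  state$step <- state$step + 1L

  # (5) removal
  if (mode == "normal") {
    state <- cull_detached(state, cfg$desquamation, cfg$domain, pairs = pairs)
  } else {
    keep <- state$cells$z <= cfg$coupling$fill_ceiling
    if (!all(keep)) {
      kept <- as.data.frame(state$cells)[keep, , drop = FALSE]
      rownames(kept) <- NULL
      class(kept) <- c("cell_df", "data.frame")
      state$cells <- kept
    }
  }

  # (6) surface refresh
  ids <- identify_surface_cells(state$cells, cfg$domain, cfg$desquamation$dx)
  state$cells$is_surface <- state$cells$id %in% ids

  # (7) scheduled thickness refresh
  steps_per_refresh <- max(1L, round(1 / (cfg$coupling$f_h * dt)))
  if (state$step %% steps_per_refresh == 0L) {
    th <- update_thickness(state$cells, cfg$domain, h, cfg$desquamation$dx)
    state$tau <- th$tau
    state$thickness <- rbind(
      state$thickness,
      data.frame(t_hr = state$t, tissue_cd = th$tissue, tau_cd = th$tau)
    )
  }
  state
}

# stem i_T levels for a scenario; n_stem draws consume the session RNG only
# in the heterogeneous case (random subset of normal stems)
scenario_stem_levels <- function(n_stem, scenario, e_T) {
  if (is.null(scenario$normal_stem_fraction)) {
    rep(scenario$inhibitor_fraction * e_T, n_stem)
  } else {
    n_normal <- round(scenario$normal_stem_fraction * n_stem)
    lv <- rep(0, n_stem)
    lv[sample.int(n_stem, n_normal)] <- e_T
    lv
  }
}

#' Initialise a tissue at homeostasis entry
#'
#' Seeds one stem cell per CD^2 at `z = R_0` with small lateral jitter,
#' assigns scenario inhibitor levels and cycle times, then runs the filling
#' simulation (no removal force; cells above the provisional ceiling are
#' deleted) for `fill_days` to populate the domain. Burn-in is run by the
#' caller ([run_scenario()]).
#'
#' @param cfg A [run_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param fill Run the filling phase (set `FALSE` for bare stem layouts).
#' @return A [simulation_state()].
#' @export
initialize_tissue <- function(cfg = run_config(), seed = cfg$seed,
                              fill = TRUE) {
  set.seed(seed)
  nx <- round(cfg$domain$Lx)
  ny <- round(cfg$domain$Ly)
  n <- nx * ny
  gx <- rep(seq_len(nx) - 0.5, each = ny)
  gy <- rep(seq_len(ny) - 0.5, times = nx)
  jit <- 0.1
  levels <- scenario_stem_levels(n, cfg$scenario, cfg$chem$e_T)
  # chemistry initialised per stem's inhibitor level (frozen below the
  # corneum base, but kept consistent for snapshots and daughters)
  ics <- lapply(levels, function(lv) {
    if (cfg$chem$e_T == 0) {
      chem_state(e = 0, s = 1, i = 0, c_s = 0, c_i = 0, p = 0)
    } else {
      initial_chem_state(chem_params(s_0 = cfg$chem$s_0, e_T = cfg$chem$e_T,
                                     i_T = min(lv, cfg$chem$e_T)), cfg$rates)
    }
  })
  cells <- cell_df(
    id = seq_len(n), type = "stem",
    x = wrap_lateral(gx + stats::runif(n, -jit, jit), cfg$domain$Lx),
    y = wrap_lateral(gy + stats::runif(n, -jit, jit), cfg$domain$Ly),
    z = rep(cfg$mechanics$R_0, n),
    radius = cfg$mechanics$R_0,
    birth_time = -stats::runif(n, 0, cfg$prolif$cycle_high),
    t_c = draw_cycle_time(n, cfg$prolif),
    i_t_level = levels,
    e = vapply(ics, `[[`, numeric(1), "e"),
    c_s = vapply(ics, `[[`, numeric(1), "c_s"),
    c_i = vapply(ics, `[[`, numeric(1), "c_i")
  )
  state <- simulation_state(cells, t = 0, tau = 0)
  if (fill && cfg$coupling$fill_days > 0) {
    state <- run_multiscale(state, cfg,
                            steps = round(cfg$coupling$fill_days * 24 /
                                            cfg$mechanics$dt),
                            mode = "filling")
  }
  state
}

#' Advance the multiscale model with the compiled loop
#'
#' Runs `steps` mechanics steps of the coupled model in C++ (identical
#' algorithm to [step_multiscale()], with a stability-bounded fixed-substep
#' RK4 chemistry integrator). Randomness (cycle times, division directions)
#' is drawn from the R session RNG, so runs are reproducible under
#' `set.seed()`.
#'
#' @param state A [simulation_state()].
#' @param cfg A [run_config()].
#' @param steps Number of mechanics steps.
#' @param mode `"normal"` or `"filling"`.
#' @param snapshot_every Record per-cell snapshots every this many steps
#'   (0 = never).
#' @return The advanced [simulation_state()]; snapshots (if any) are
#'   accumulated in `state$snapshots`.
#' @export
run_multiscale <- function(state, cfg, steps, mode = c("normal", "filling"),
                           snapshot_every = 0L) {
  mode <- match.arg(mode)
  res <- run_steps_cpp(
    as.data.frame(state$cells), cpp_params(cfg, mode), as.integer(steps),
    state$t, state$tau, as.integer(state$step), as.integer(snapshot_every)
  )
  cells <- res$cells
  class(cells) <- c("cell_df", "data.frame")
  state$cells <- cells
  state$t <- res$t
  state$tau <- res$tau
  state$step <- res$step
  state$divisions <- state$divisions + res$divisions
  if (nrow(res$thickness) > 0) {
    state$thickness <- rbind(state$thickness, res$thickness)
  }
  if (nrow(res$removals) > 0) {
    res$removals$clump <- res$removals$clump + max(c(0L, state$removals$clump))
    state$removals <- rbind(state$removals, res$removals)
  }
  if (length(res$snapshots) > 0) {
    state$snapshots <- c(state$snapshots, res$snapshots)
  }
  state
}

# flatten a run_config into the numeric parameter list the C++ loop expects
cpp_params <- function(cfg, mode) {
  list(
    Lx = cfg$domain$Lx, Ly = cfg$domain$Ly,
    k_rep = cfg$mechanics$k_rep, gamma = cfg$mechanics$gamma,
    alpha_0 = cfg$mechanics$alpha_0, k_phi = cfg$mechanics$k_phi,
    eta = cfg$mechanics$eta, dt = cfg$mechanics$dt, R_0 = cfg$mechanics$R_0,
    cutoff = cfg$mechanics$neighbour_cutoff,
    division_offset = cfg$mechanics$division_offset,
    growth_time = cfg$mechanics$growth_time,
    dx = cfg$desquamation$dx, F_D = cfg$desquamation$F_D,
    contact_gap = cfg$desquamation$contact_gap,
    h = cfg$coupling$h_corneum_base, f_h = cfg$coupling$f_h,
    fill_ceiling = cfg$coupling$fill_ceiling,
    s_0 = cfg$chem$s_0, e_T = cfg$chem$e_T,
    k_plus1 = cfg$rates$k_plus1, k_minus1 = cfg$rates$k_minus1,
    k_2 = cfg$rates$k_2, a3 = cfg$rates$a3, b3 = cfg$rates$b3,
    A3 = cfg$rates$A3, B3 = cfg$rates$B3,
    ph_c0 = cfg$ph$c0, ph_c1 = cfg$ph$c1, ph_c2 = cfg$ph$c2,
    ph_c3 = cfg$ph$c3,
    cycle_low = cfg$prolif$cycle_low, cycle_high = cfg$prolif$cycle_high,
    dual_mode = as.integer(cfg$prolif$population_mode == "dual"),
    filling = as.integer(mode == "filling")
  )
}
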