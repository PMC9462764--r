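#' Mechanical parameters of the overlapping-spheres model
#'
#' All lengths are in cell diameters (CD), forces in uN, time in hours. The
#' pair force law combines logarithmic repulsion (spring constant `k_rep`)
#' for overlapping cells with a Gaussian-enveloped adhesion branch of shape
#' parameter `gamma` (and derived offset `c_shape = 1/(2*gamma)`) for
#' separated cells. `alpha_0` is calibrated by default so the peak adhesion
#' force between two undamaged cells equals `F_max` (see
#' [calibrate_alpha0()]); the historical reference coefficient 374.7 uN is
#' kept in `alpha_0_reference`.
#'
#' The drag coefficient default `eta = 10` uN.hr.CD^-1 corresponds to
#' 0.1 uN.hr.um^-1 with 100 um per CD; it reproduces the model's free-cell
#' removal time (0.7 CD at `F_D/eta = 0.5` CD/hr takes 1.4 hr) and keeps the
#' forward-Euler update stable against the repulsion stiffness at
#' `dt = 30` s.
#'
#' @param k_rep Repulsive spring constant, uN.
#' @param gamma Adhesion shape parameter.
#' @param alpha_0 Normal adhesion coefficient, uN (default: calibrated from
#'   `F_max` and `gamma`).
#' @param F_max Target peak adhesion force, uN.
#' @param k_phi Torsional spring constant for dividing pairs, uN.
#' @param eta Drag coefficient, uN.hr.CD^-1.
#' @param dt Mechanics time step, hr (default 30 s).
#' @param R_0 Normal cell radius, CD.
#' @param neighbour_cutoff Neighbour-search cutoff (centre distance), CD.
#' @param division_offset Initial separation of a new daughter, CD.
#' @param growth_time Time for a newborn cell to reach full radius, hr.
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(k_rep = 150, gamma = 7, alpha_0 = NULL,
                             F_max = 10, k_phi = 100, eta = 10,
                             dt = 1 / 120, R_0 = 0.5, neighbour_cutoff = 2,
                             division_offset = 0.3, growth_time = 1) {
  if (is.null(alpha_0)) alpha_0 <- calibrate_alpha0(F_max, gamma)
  p <- list(
    k_rep = k_rep, gamma = gamma, c_shape = 1 / (2 * gamma),
    alpha_0 = alpha_0, alpha_0_reference = 374.7, F_max = F_max,
    k_phi = k_phi, eta = eta, dt = dt, R_0 = R_0,
    neighbour_cutoff = neighbour_cutoff,
    division_offset = division_offset, growth_time = growth_time
  )
  num <- unlist(p)
  if (!all(is.finite(num)) || any(num <= 0)) {
    stop("all mechanics parameters must be positive and finite")
  }
  structure(p, class = "mechanics_params")
}

# adhesion shape function g(r*) such that F_adh = alpha_ij * g(r*/R_0)
adhesion_shape <- function(r_star, gamma) {
  c0 <- 1 / (2 * gamma)
  (r_star + c0) * exp(-gamma * (r_star + c0)^2) -
    c0 * exp(-gamma * (r_star^2 + c0^2))
}

#' Peak of the adhesion shape function
#'
#' Numerically maximises the adhesion envelope `g(r*)` over separations
#' `r* > 0`. For `gamma = 7` the peak is `g_max ~ 0.112` at `r* ~ 0.23`.
#'
#' @param gamma Adhesion shape parameter.
#' @return List with `g_max` and the maximising scaled separation `r_star`.
#' @export
adhesion_peak <- function(gamma = 7) {
  opt <- stats::optimize(function(r) adhesion_shape(r, gamma),
                         interval = c(0, 4), maximum = TRUE)
  list(g_max = opt$objective, r_star = opt$maximum)
}

#' Calibrate the adhesion coefficient to a target peak force
#'
#' Returns `alpha_0 = F_max / g_max` so that the maximum of the adhesion
#' branch over separations equals `F_max` exactly. Note this is deliberately
#' *not* the historical reference value 374.7 uN, which is inconsistent with
#' the force law as stated (374.7 x g_max ~ 42 uN, not 10 uN); the peak force
#' is treated as authoritative because the desquamation threshold argument
#' (`s* = F_D / (3 F_max)`) depends on it.
#'
#' @param F_max Target peak adhesion force, uN.
#' @param gamma Adhesion shape parameter.
#' @return Adhesion coefficient `alpha_0`, uN.
#' @export
calibrate_alpha0 <- function(F_max = 10, gamma = 7) {
  if (F_max <= 0) stop("F_max must be positive")
  F_max / adhesion_peak(gamma)$g_max
}

#' Signed pair interaction force
#'
#' Force magnitude along the axis from cell i to cell j as a function of the
#' boundary gap `r_ij` (centre distance minus summed radii, CD). Positive
#' values are attractive (towards the neighbour), negative repulsive.
#' Overlapping cells (`r_ij < 0`) repel with `k_rep * log(1 + r_ij)`;
#' separated cells (`r_ij > 0`) attract following the adhesion envelope
#' scaled by `alpha_ij`; the force is continuous (zero) at contact.
#'
#' @param r_ij Boundary gap(s), CD. Must be > -1 (total overlap is an error).
#' @param alpha_ij Adhesion coefficient(s), uN.
#' @param params A [mechanics_params()].
#' @return Signed force magnitude(s), uN.
#' @export
pair_interaction_force <- function(r_ij, alpha_ij, params = mechanics_params()) {
  if (any(r_ij <= -1)) stop("total overlap: r_ij <= -1 CD")
  out <- numeric(length(r_ij))
  neg <- r_ij < 0
  out[neg] <- params$k_rep * log(1 + r_ij[neg])
  pos <- r_ij > 0
  if (any(pos)) {
    out[pos] <- rep(alpha_ij, length.out = length(r_ij))[pos] *
      adhesion_shape(r_ij[pos] / params$R_0, params$gamma)
  }
  out
}

#' Adhesion coefficient between two cells
#'
#' Scales the normal adhesion coefficient by the mean remaining
#' corneodesmosome fraction of the pair: `alpha_ij = (s_i + s_j)/2 * alpha_0`.
#'
#' @param s_i,s_j Remaining CND fractions of the two cells, in `[0, 1]`.
#' @param alpha_0 Normal adhesion coefficient, uN.
#' @return `alpha_ij`, uN.
#' @export
adhesion_coefficient <- function(s_i, s_j, alpha_0) {
  if (any(s_i < -1e-9 | s_i > 1 + 1e-9) || any(s_j < -1e-9 | s_j > 1 + 1e-9)) {
    stop("s_i, s_j must be in [0, 1]")
  }
  0.5 * (s_i + s_j) * alpha_0
}

#' Neighbour pairs under the periodic minimum-image convention
#'
#' All unordered cell pairs whose centre distance is below `cutoff`, with the
#' minimum-image displacement in the laterally periodic domain. Coincident
#' centres are separated along a random direction (drawn from the session
#' RNG) and a warning is emitted.
#'
#' @param cells A [cell_df()].
#' @param domain A [sim_domain()].
#' @param cutoff Centre-distance cutoff, CD.
#' @return A data.frame with row indices `i`, `j` (i < j), centre distance
#'   `dist`, boundary gap `gap = dist - radius_i - radius_j`, and the unit
#'   vector (`ux`, `uy`, `uz`) from i to j.
#' @export
build_neighbor_lists <- function(cells, domain, cutoff = 2) {
  if (domain$Lx < 2 * cutoff || domain$Ly < 2 * cutoff) {
    stop("domain extent must be at least twice the neighbour cutoff")
  }
  n <- nrow(cells)
  if (n < 2) {
    return(data.frame(i = integer(), j = integer(), dist = numeric(),
                      gap = numeric(), ux = numeric(), uy = numeric(),
                      uz = numeric()))
  }
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- min_image(cells$x[j] - cells$x[i], cells$y[j] - cells$y[i], domain)
  dz <- cells$z[j] - cells$z[i]
  dist <- sqrt(d$dx^2 + d$dy^2 + dz^2)
  keep <- dist < cutoff
  i <- i[keep]; j <- j[keep]
  dx <- d$dx[keep]; dy <- d$dy[keep]; dz <- dz[keep]; dist <- dist[keep]
  zero <- dist < 1e-12
  if (any(zero)) {
    warning(sprintf("%d coincident cell pair(s); separating along random axes",
                    sum(zero)))
    for (k in which(zero)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      dx[k] <- u[1] * 1e-9; dy[k] <- u[2] * 1e-9; dz[k] <- u[3] * 1e-9
      dist[k] <- 1e-9
    }
  }
  data.frame(
    i = i, j = j, dist = dist,
    gap = dist - cells$radius[i] - cells$radius[j],
    ux = dx / dist, uy = dy / dist, uz = dz / dist
  )
}

#' Rotational force on a dividing daughter pair
#'
#' Torsional restoring force that rotates the inter-daughter axis towards the
#' vertical, keeping stem cells basal after division. The force on cell i is
#' `-k_phi * phi * n_hat` where `phi` is the angle between the vertical and
#' the axis from i to j, and `n_hat` is the unit component of the vertical
#' perpendicular to the axis. The twin receives the opposite force. A
#' perfectly vertical axis gives zero force.
#'
#' @param pos_i,pos_j Length-3 position vectors of the two daughters, CD
#'   (pos_j is conventionally the upper/differentiated daughter).
#' @param k_phi Torsional spring constant, uN.
#' @return Length-3 force vector on cell i, uN.
#' @export
division_rotation_force <- function(pos_i, pos_j, k_phi) {
  r <- pos_j - pos_i
  rn <- sqrt(sum(r^2))
  if (rn < 1e-12) return(c(0, 0, 0))
  vertical <- c(0, 0, 1)
  cosphi <- sum(r * vertical) / rn
  cosphi <- min(max(cosphi, -1), 1)
  phi <- acos(cosphi)
  # n_hat = component of vertical perpendicular to r, normalised
  perp <- vertical - cosphi * r / rn
  pn <- sqrt(sum(perp^2))
  if (pn < 1e-12) return(c(0, 0, 0))  # axis exactly vertical
  -k_phi * phi * perp / pn
}

#' Proliferation parameters
#'
#' In `single` mode every stem cell draws a fresh cycle time from
#' `U(cycle_low, cycle_high)` at each division. In `dual` mode a fraction
#' `fraction_fast` of stem cells cycle at fixed `T_1` hr and the rest at
#' `T_1 + dT_C` hr, which allows matched-harmonic-mean comparisons between
#' one and two proliferative populations.
#'
#' @param cycle_low,cycle_high Uniform cycle-time bounds, hr.
#' @param population_mode `"single"` or `"dual"`.
#' @param T_1 Fast-population cycle time, hr (dual mode).
#' @param dT_C Cycle-time difference of the slow population, hr (dual mode).
#' @param fraction_fast Fraction of stem cells in the fast population.
#' @return An object of class `proliferation_params`.
#' @export
proliferation_params <- function(cycle_low = 13, cycle_high = 17,
                                 population_mode = c("single", "dual"),
                                 T_1 = 10, dT_C = 20, fraction_fast = 0.5) {
  population_mode <- match.arg(population_mode)
  if (cycle_low <= 0 || cycle_high < cycle_low) stop("invalid cycle bounds")
  if (fraction_fast < 0 || fraction_fast > 1) stop("fraction_fast in [0,1]")
  structure(list(
    cycle_low = cycle_low, cycle_high = cycle_high,
    population_mode = population_mode, T_1 = T_1, dT_C = dT_C,
    fraction_fast = fraction_fast
  ), class = "proliferation_params")
}

draw_cycle_time <- function(n, prolif) {
  if (prolif$population_mode == "single") {
    stats::runif(n, prolif$cycle_low, prolif$cycle_high)
  } else {
    # the population composition is a design parameter: allocate exactly
    # round(fraction_fast * n) fast cyclers, in random spatial order
    n_fast <- round(prolif$fraction_fast * n)
    sample(c(rep(prolif$T_1, n_fast),
             rep(prolif$T_1 + prolif$dT_C, n - n_fast)))
  }
}

# uniform direction on the upper unit hemisphere
runif_hemisphere <- function() {
  repeat {
    u <- stats::rnorm(3)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-9) break
  }
  u <- u / nu
  u[3] <- abs(u[3])
  u
}

#' Attempt stem-cell divisions
#'
#' Every stem cell whose age has reached its assigned cycle time divides
#' asymmetrically: the stem daughter keeps the basal position and lineage
#' (age resets, a fresh cycle time is drawn per the proliferation mode), and
#' a differentiated daughter is created `division_offset` CD away along a
#' random upward-hemisphere direction. The daughter inherits the stem cell's
#' inhibitor level `i_t_level`, gets its chemistry initialised by
#' [initial_chem_state()], starts at half radius (growing to full size over
#' `growth_time` hr), and is paired with the stem cell for the rotational
#' force. Differentiated cells never divide, so the stem count is invariant.
#'
#' @param cells A [cell_df()].
#' @param t Current time, hr.
#' @param prolif A [proliferation_params()].
#' @param params A [mechanics_params()].
#' @param domain A [sim_domain()].
#' @param chem A [chem_params()] template (the daughter's `i_T` is its
#'   inherited `i_t_level`).
#' @param rates A [rate_constants()].
#' @return List with the updated `cells` and the number of `divisions`.
#' @export
attempt_divisions <- function(cells, t, prolif, params, domain,
                              chem = chem_params(e_T = 0.1e-9),
                              rates = multiscale_rates()) {
  ready <- which(cells$type == "stem" & !is.na(cells$t_c) &
                   (t - cells$birth_time) >= cells$t_c)
  if (length(ready) == 0) {
    return(list(cells = cells, divisions = 0L))
  }
  next_id <- max(cells$id) + 1L
  new_rows <- vector("list", length(ready))
  for (k in seq_along(ready)) {
    m <- ready[k]
    dirn <- runif_hemisphere()
    pos <- c(cells$x[m], cells$y[m], cells$z[m]) + params$division_offset * dirn
    cp <- chem_params(s_0 = chem$s_0, e_T = chem$e_T,
                      i_T = min(cells$i_t_level[m], chem$e_T))
    ic <- initial_chem_state(cp, rates)
    new_rows[[k]] <- data.frame(
      id = next_id, type = "diff",
      x = wrap_lateral(pos[1], domain$Lx), y = wrap_lateral(pos[2], domain$Ly),
      z = max(pos[3], 1e-6), radius = params$R_0 / 2,
      birth_time = t, t_c = NA_real_, i_t_level = cells$i_t_level[m],
      e = ic$e, s = ic$s, i = ic$i, c_s = ic$c_s, c_i = ic$c_i, p = ic$p,
      entry_time = NA_real_, is_surface = FALSE, partner = cells$id[m],
      stringsAsFactors = FALSE
    )
    cells$partner[m] <- next_id
    cells$birth_time[m] <- t
    if (prolif$population_mode == "single") {
      cells$t_c[m] <- draw_cycle_time(1, prolif)
    } # dual mode: the stem keeps its fixed class cycle time
    next_id <- next_id + 1L
  }
  out <- rbind(as.data.frame(cells), do.call(rbind, new_rows))
  class(out) <- c("cell_df", "data.frame")
  list(cells = out, divisions = length(ready))
}

#' Overdamped forward-Euler position update
#'
#' Moves every cell by `F * dt / eta`, wraps the lateral coordinates into the
#' periodic domain and clips `z` at the basal plane. A displacement exceeding
#' 1 CD in a single step indicates numerical instability and raises an error
#' naming the offending cell.
#'
#' @param cells A [cell_df()].
#' @param net_forces n x 3 matrix of net forces, uN.
#' @param eta Drag coefficient, uN.hr.CD^-1.
#' @param dt Time step, hr.
#' @param domain A [sim_domain()].
#' @return The updated `cells`.
#' @export
advance_positions <- function(cells, net_forces, eta, dt, domain) {
  if (!is.matrix(net_forces) || nrow(net_forces) != nrow(cells) ||
        ncol(net_forces) != 3) {
    stop("net_forces must be an n x 3 matrix")
  }
  disp <- net_forces * dt / eta
  dn <- sqrt(rowSums(disp^2))
  if (any(dn > 1)) {
    bad <- which.max(dn)
    stop(sprintf(
      "mechanics instability: cell id %d displaced %.2f CD in one step",
      cells$id[bad], dn[bad]
    ))
  }
  cells$x <- wrap_lateral(cells$x + disp[, 1], domain$Lx)
  cells$y <- wrap_lateral(cells$y + disp[, 2], domain$Ly)
  cells$z <- pmax(cells$z + disp[, 3], 0)
  cells
}

# basal membrane force on one cell: log repulsion below contact for all
# cells, adhesion branch above contact for stem cells (keeps stems basal).
basal_membrane_force_z <- function(z, radius, type, params) {
  gap <- z - radius
  if (gap < 0) {
    if (gap <= -1) stop("cell pushed fully through the basal membrane")
    -params$k_rep * log(1 + gap)
  } else if (type == "stem" && gap > 0) {
    -params$alpha_0 * adhesion_shape(gap / params$R_0, params$gamma)
  } else 0
}

#' Assemble net mechanical forces for a cell population
#'
#' Sums pair adhesion/repulsion forces (adhesion scaled by the pair's mean
#' CND level), basal-membrane interaction, division rotational forces for
#' paired daughters, and the vertical removal force on surface cells.
#'
#' @param cells A [cell_df()].
#' @param domain A [sim_domain()].
#' @param params A [mechanics_params()].
#' @param F_D Removal force magnitude on surface cells, uN (0 disables).
#' @param pairs Optional precomputed [build_neighbor_lists()] output.
#' @return n x 3 matrix of net forces, uN.
#' @export
assemble_forces <- function(cells, domain, params, F_D = 0, pairs = NULL) {
  n <- nrow(cells)
  F <- matrix(0, n, 3)
  if (is.null(pairs)) {
    pairs <- build_neighbor_lists(cells, domain, params$neighbour_cutoff)
  }
  if (nrow(pairs) > 0) {
    alpha <- adhesion_coefficient(cells$s[pairs$i], cells$s[pairs$j],
                                  params$alpha_0)
    fmag <- pair_interaction_force(pairs$gap, alpha, params)
    for (k in seq_len(nrow(pairs))) {
      u <- c(pairs$ux[k], pairs$uy[k], pairs$uz[k])
      F[pairs$i[k], ] <- F[pairs$i[k], ] + fmag[k] * u
      F[pairs$j[k], ] <- F[pairs$j[k], ] - fmag[k] * u
    }
  }
  for (m in seq_len(n)) {
    F[m, 3] <- F[m, 3] +
      basal_membrane_force_z(cells$z[m], cells$radius[m], cells$type[m], params)
  }
  paired <- which(!is.na(cells$partner))
  for (m in paired) {
    twin <- match(cells$partner[m], cells$id)
    if (is.na(twin)) next
    # apply from the lower cell's perspective; each member computes its own
    pi_ <- c(cells$x[m], cells$y[m], cells$z[m])
    pj <- c(cells$x[twin], cells$y[twin], cells$z[twin])
    d <- min_image(pj[1] - pi_[1], pj[2] - pi_[2], domain)
    pj_local <- c(pi_[1] + d$dx, pi_[2] + d$dy, pj[3])
    lower <- cells$z[m] < cells$z[twin] ||
      (cells$z[m] == cells$z[twin] && cells$id[m] < cells$id[twin])
    if (lower) {
      F[m, ] <- F[m, ] + division_rotation_force(pi_, pj_local, params$k_phi)
    } else {
      F[m, ] <- F[m, ] - division_rotation_force(pj_local, pi_, params$k_phi)
    }
  }
  if (F_D > 0) {
    F[cells$is_surface, 3] <- F[cells$is_surface, 3] + F_D
  }
  F
}
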