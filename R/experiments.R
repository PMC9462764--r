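#' Test burn-in adequacy by thickness stationarity
#'
#' The homeostatic sampling window must not start during a thickness
#' transient. Adequacy is asserted statistically rather than visually: the
#' corneum-thickness series over the trailing `n_blocks * block_days` days is
#' reduced to per-block means and the slope of a linear fit is t-tested; no
#' significant trend (p >= alpha) declares the burn-in adequate.
#'
#' @param thickness Thickness series data.frame (`t_hr`, `tau_cd`).
#' @param block_days Block length, days.
#' @param n_blocks Number of trailing blocks.
#' @param alpha Significance level of the slope test.
#' @return `TRUE` if stationary (no significant trend), `FALSE` otherwise
#'   (including when fewer than `n_blocks` full blocks are available).
#' @export
burn_in_stationary <- function(thickness, block_days = 5, n_blocks = 4,
                               alpha = 0.05) {
  span <- n_blocks * block_days * 24
  t_end <- max(thickness$t_hr)
  recent <- thickness[thickness$t_hr > t_end - span, , drop = FALSE]
  if (nrow(recent) < n_blocks * block_days * 12) return(FALSE)
  block <- floor((recent$t_hr - (t_end - span)) / (block_days * 24))
  block <- pmin(block, n_blocks - 1)
  means <- tapply(recent$tau_cd, block, mean)
  if (length(means) < n_blocks) return(FALSE)
  fit <- stats::lm(as.numeric(means) ~ seq_along(means))
  p <- stats::coef(summary(fit))[2, "Pr(>|t|)"]
  is.finite(p) && p >= alpha
}

#' Run one scenario realisation of the multiscale model
#'
#' Executes the full pipeline for a single realisation: filling simulation,
#' burn-in, then the homeostatic sampling window with daily per-cell
#' snapshots. After the configured minimum burn-in, the burn-in is extended
#' in 5-day increments until [burn_in_stationary()] passes (scenarios far
#' from the filled configuration, e.g. inhibitor-free tissue, take
#' substantially longer than the minimum to shed the filling transient), up
#' to `max_extra_days`. Thickness/removal records returned are restricted to
#' the sampling window.
#'
#' @param cfg A [run_config()].
#' @param seed Integer seed for this realisation.
#' @param snapshot_every_hr Snapshot cadence during sampling, hr.
#' @param extend_burn_in Extend the burn-in until stationary.
#' @param max_extra_days Cap on the burn-in extension, days.
#' @return A list with `state`, `thickness`, `removals`, `snapshots`,
#'   `sample_start` (hr) and `config`.
#' @export
run_scenario <- function(cfg, seed = cfg$seed, snapshot_every_hr = 24,
                         extend_burn_in = TRUE, max_extra_days = 30) {
  state <- initialize_tissue(cfg, seed = seed)
  dt <- cfg$mechanics$dt
  burn_steps <- round(cfg$coupling$burn_in_days * 24 / dt)
  if (burn_steps > 0) {
    state <- run_multiscale(state, cfg, burn_steps, mode = "normal")
  }
  if (extend_burn_in) {
    extra <- 0
    while (!burn_in_stationary(state$thickness) && extra < max_extra_days) {
      state <- run_multiscale(state, cfg, round(5 * 24 / dt), mode = "normal")
      extra <- extra + 5
    }
    if (extra >= max_extra_days && !burn_in_stationary(state$thickness)) {
      warning("thickness still trending after the maximum burn-in extension")
    }
  }
  sample_start <- state$t
  snap_steps <- max(1L, round(snapshot_every_hr / dt))
  state <- run_multiscale(state, cfg,
                          steps = round(cfg$coupling$sample_days * 24 / dt),
                          mode = "normal", snapshot_every = snap_steps)
  list(
    state = state,
    thickness = state$thickness[state$thickness$t_hr > sample_start, ,
                                drop = FALSE],
    removals = state$removals[state$removals$time_hr > sample_start, ,
                              drop = FALSE],
    snapshots = state$snapshots,
    sample_start = sample_start,
    config = cfg
  )
}

#' Steady-state thickness summary
#'
#' Computes the per-realisation time-mean of the corneum thickness over the
#' final `window_days` of each series, then summarises over realisations
#' (mean plus min/max ribbon).
#'
#' @param series Data.frame with columns `t_hr`, `tau_cd` and (optionally)
#'   `realisation`.
#' @param window_days Averaging window measured back from the latest sample;
#'   `NULL` uses the full series.
#' @return List with `mean`, `min`, `max` (CD) and the per-realisation means.
#' @export
steady_state_thickness <- function(series, window_days = NULL) {
  if (nrow(series) == 0) stop("empty thickness series")
  if (is.null(series$realisation)) series$realisation <- 1L
  if (!is.null(window_days)) {
    t_min <- max(series$t_hr) - window_days * 24
    series <- series[series$t_hr >= t_min, , drop = FALSE]
    if (nrow(series) == 0) stop("empty averaging window")
  }
  per <- tapply(series$tau_cd, series$realisation, mean)
  list(mean = mean(per), min = min(per), max = max(per),
       per_realisation = as.numeric(per))
}

#' Migratory-cell vertical velocity statistics
#'
#' Per-cell vertical velocities from consecutive snapshots (`delta z / delta
#' t`), excluding stem cells and cells flagged as surface cells (those
#' experience the removal force and move much faster than the bulk).
#'
#' @param snapshots List of per-cell snapshot data.frames (as produced by
#'   [run_scenario()]), each with columns `t_hr`, `id`, `stem`, `z_cd`,
#'   `is_surface`.
#' @return List with `mean`, `quartiles` (25/50/75%), `n` and the raw
#'   per-cell-interval `velocities` (CD/hr).
#' @export
migration_velocity_stats <- function(snapshots) {
  if (length(snapshots) < 2) stop("need at least two snapshots")
  vels <- numeric()
  for (k in seq_len(length(snapshots) - 1)) {
    a <- snapshots[[k]]
    b <- snapshots[[k + 1]]
    dtime <- b$t_hr[1] - a$t_hr[1]
    if (dtime <= 0) next
    idx <- match(a$id, b$id)
    ok <- !is.na(idx) & !a$stem & !a$is_surface & !b$is_surface[idx]
    vels <- c(vels, (b$z_cd[idx[ok]] - a$z_cd[ok]) / dtime)
  }
  if (length(vels) == 0) stop("no migratory cells found in snapshots")
  list(mean = mean(vels),
       quartiles = stats::quantile(vels, c(0.25, 0.5, 0.75)),
       n = length(vels), velocities = vels)
}

#' Turnover-time statistics from removal events
#'
#' @param removals Removal-event data.frame with `age_hr`, `time_hr` and
#'   `entry_time_hr` columns.
#' @return List with medians (hr) of age at removal, age at corneum entry,
#'   and the corneum transit time (difference of the two medians), plus
#'   quartiles of removal age.
#' @export
turnover_statistics <- function(removals) {
  if (nrow(removals) == 0) stop("no removal events")
  birth <- removals$time_hr - removals$age_hr
  entry_age <- removals$entry_time_hr - birth
  entry_age <- entry_age[!is.na(entry_age)]
  med_rm <- stats::median(removals$age_hr)
  med_entry <- if (length(entry_age)) stats::median(entry_age) else NA_real_
  list(
    median_age_at_removal = med_rm,
    median_age_at_entry = med_entry,
    median_corneum_transit = med_rm - med_entry,
    quartiles_age_at_removal = stats::quantile(removals$age_hr,
                                               c(0.25, 0.5, 0.75))
  )
}

#' Time-averaged total free enzyme in the corneum
#'
#' Sums the free-enzyme fraction `e` over all cells between the corneum base
#' and the steady-state height `h + tau_ss`, averaged over snapshots.
#'
#' @param snapshots List of snapshot data.frames with `z_cd` and `e`.
#' @param tau_ss Steady-state corneum thickness, CD.
#' @param h Corneum base height, CD.
#' @return Scalar time-averaged total of `e`.
#' @export
total_free_enzyme <- function(snapshots, tau_ss, h = 4) {
  if (length(snapshots) == 0) stop("no snapshots")
  totals <- vapply(snapshots, function(sn) {
    sel <- sn$z_cd >= h & sn$z_cd <= h + tau_ss
    sum(sn$e[sel])
  }, numeric(1))
  mean(totals)
}

#' Inhibitor-depletion (Netherton Syndrome) sweep
#'
#' Runs the scenario at each inhibitor fraction `i_T / e_T`, with seeds
#' shared across sweep points for variance reduction, and fits the
#' steady-state corneum thickness linearly against the fraction.
#'
#' @param fractions Inhibitor fractions in `[0, 1]`.
#' @param cfg Base [run_config()].
#' @param realisations Realisations per fraction.
#' @param seed Base seed; realisation r uses `seed + r - 1` at every fraction.
#' @return List with a tidy `results` data.frame (fraction, realisation,
#'   tau_ss), per-fraction `means`, and `fit` (an `lm` of mean thickness on
#'   fraction, `NULL` if fewer than 2 fractions).
#' @export
inhibitor_sweep <- function(fractions, cfg = run_config(),
                            realisations = cfg$coupling$realisations,
                            seed = cfg$seed) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0,1]")
  rows <- list()
  for (f in fractions) {
    cfg_f <- cfg
    cfg_f$scenario <- scenario_spec(inhibitor_fraction = f)
    for (r in seq_len(realisations)) {
      res <- run_scenario(cfg_f, seed = seed + r - 1L)
      sst <- steady_state_thickness(res$thickness)
      rows[[length(rows) + 1]] <- data.frame(
        fraction = f, realisation = r, tau_ss = sst$mean
      )
    }
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(tau_ss ~ fraction, data = results, FUN = mean)
  fit <- if (length(fractions) >= 2) fit_scenario_thickness(means, "linear")
         else NULL
  list(results = results, means = means, fit = fit)
}

#' Heterogeneous-recovery sweep
#'
#' Runs the scenario for each fraction of "normal" stem cells (stems with
#' `i_T = e_T`; the rest have `i_T = 0`, and every cell inherits its stem's
#' level), fits a quadratic in the fraction, and reports the linear baseline
#' expected if thickness responded to the *total* recovered inhibitor as in
#' the homogeneous sweep (the straight line between the two endpoint means).
#'
#' @param fractions Normal-stem fractions in `[0, 1]`.
#' @param cfg Base [run_config()].
#' @param realisations Realisations per fraction.
#' @param seed Base seed, shared across fractions.
#' @return List with `results`, `means`, quadratic `fit`, and
#'   `linear_baseline` (function of fraction).
#' @export
recovery_sweep <- function(fractions, cfg = run_config(),
                           realisations = cfg$coupling$realisations,
                           seed = cfg$seed) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0,1]")
  rows <- list()
  for (f in fractions) {
    cfg_f <- cfg
    cfg_f$scenario <- scenario_spec(inhibitor_fraction = 0,
                                    normal_stem_fraction = f)
    for (r in seq_len(realisations)) {
      res <- run_scenario(cfg_f, seed = seed + r - 1L)
      sst <- steady_state_thickness(res$thickness)
      rows[[length(rows) + 1]] <- data.frame(
        fraction = f, realisation = r, tau_ss = sst$mean
      )
    }
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(tau_ss ~ fraction, data = results, FUN = mean)
  fit <- if (length(fractions) >= 3) {
    fit_scenario_thickness(means, "quadratic")
  } else NULL
  lo <- means$tau_ss[which.min(means$fraction)]
  hi <- means$tau_ss[which.max(means$fraction)]
  f0 <- min(means$fraction); f1 <- max(means$fraction)
  linear_baseline <- function(f) lo + (hi - lo) * (f - f0) / (f1 - f0)
  list(results = results, means = means, fit = fit,
       linear_baseline = linear_baseline)
}

#' Fit steady-state thickness against a scenario fraction
#'
#' Ordinary least squares on scenario means, as used by the sweep analyses:
#' linear for the inhibitor sweep, quadratic for the recovery sweep.
#'
#' @param means Data.frame with columns `fraction` and `tau_ss`.
#' @param model `"linear"` or `"quadratic"`.
#' @return An `lm` fit.
#' @export
fit_scenario_thickness <- function(means, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  if (nrow(means) < 2 || (model == "quadratic" && nrow(means) < 3)) {
    stop("not enough sweep points for a ", model, " fit")
  }
  if (model == "linear") stats::lm(tau_ss ~ fraction, data = means)
  else stats::lm(tau_ss ~ fraction + I(fraction^2), data = means)
}

#' Critical CND level for desquamation
#'
#' For a surface cell bonded to `n_bonds` lower cells each at the peak
#' adhesion force, removal requires the degraded adhesion `s * F_max` per
#' bond to fall below the removal force share: `s* = F_D / (n_bonds * F_max)`.
#' With the defaults (5 uN removal force, 10 uN peak adhesion, tetrahedral
#' packing) this gives `s* ~ 0.17`.
#'
#' @param F_D Removal force, uN.
#' @param F_max Peak adhesion force, uN.
#' @param n_bonds Number of bonds to the layer below.
#' @return Critical remaining CND fraction `s*`.
#' @export
desquamation_threshold <- function(F_D = 5, F_max = 10, n_bonds = 3) {
  if (F_D < 0 || F_max <= 0 || n_bonds <= 0) stop("invalid inputs")
  F_D / (n_bonds * F_max)
}

#' Harmonic mean of cycle times
#'
#' The harmonic mean is the right average when matching overall proliferation
#' rates across populations: fast-cycling cells undergo proportionally more
#' divisions, and the harmonic mean weights them accordingly.
#'
#' @param x Positive cycle times, hr.
#' @return Harmonic mean, hr.
#' @export
harmonic_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("cycle times must be positive")
  length(x) / sum(1 / x)
}
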