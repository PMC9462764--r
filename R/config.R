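#' Coupling / scheduling configuration
#'
#' @param h_corneum_base Height of the corneum base above the membrane, CD.
#'   Cells below this height are in the living layers: their chemistry is
#'   frozen, so cells enter the corneum with `s = 1` exactly.
#' @param f_h Thickness-refresh frequency, hr^-1 (1 = every 120 steps at the
#'   default mechanics step).
#' @param burn_in_days Discarded equilibration period after filling, days.
#' @param sample_days Homeostatic sampling window, days.
#' @param realisations Number of stochastic realisations per scenario.
#' @param fill_days Duration of the filling simulation, days.
#' @param fill_ceiling Provisional removal ceiling during filling, CD.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(h_corneum_base = 4, f_h = 1,
                            burn_in_days = 30, sample_days = 30,
                            realisations = 10, fill_days = 12,
                            fill_ceiling = 12) {
  if (burn_in_days < 0 || sample_days <= 0 || fill_days < 0) {
    stop("invalid schedule")
  }
  if (f_h <= 0) stop("f_h must be positive")
  structure(list(
    h_corneum_base = h_corneum_base, f_h = f_h,
    burn_in_days = burn_in_days, sample_days = sample_days,
    realisations = realisations, fill_days = fill_days,
    fill_ceiling = fill_ceiling
  ), class = "coupling_config")
}

#' Scenario specification
#'
#' Homogeneous scenarios set every cell's inhibitor to
#' `inhibitor_fraction * e_T` (1 = normal tissue, 0 = fully depleted
#' inhibitor as in severe Netherton Syndrome). Heterogeneous-recovery
#' scenarios instead set `normal_stem_fraction` of the stem cells to
#' `i_T = e_T` and the rest to `i_T = 0`; every daughter inherits its stem
#' cell's level.
#'
#' @param inhibitor_fraction `i_T / e_T` for homogeneous scenarios, in `[0,1]`.
#' @param normal_stem_fraction Fraction of normal stem cells for
#'   heterogeneous scenarios, in `[0,1]`, or `NULL` for homogeneous.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(inhibitor_fraction = 1, normal_stem_fraction = NULL) {
  if (inhibitor_fraction < 0 || inhibitor_fraction > 1) {
    stop("inhibitor_fraction must be in [0, 1]")
  }
  if (!is.null(normal_stem_fraction) &&
        (normal_stem_fraction < 0 || normal_stem_fraction > 1)) {
    stop("normal_stem_fraction must be in [0, 1]")
  }
  structure(list(inhibitor_fraction = inhibitor_fraction,
                 normal_stem_fraction = normal_stem_fraction),
            class = "scenario_spec")
}

#' Full run configuration
#'
#' Bundles every parameter of the multiscale model with defaults matching the
#' reference tissue simulation: 10 x 10 CD periodic domain (100 stem cells),
#' the time-rescaled kinetic rates, effective enzyme concentration
#' `e_T = 0.1` nM with `s_0 = 10` uM, and the normal scenario
#' `i_T = e_T`.
#'
#' @param domain A [sim_domain()].
#' @param mechanics A [mechanics_params()].
#' @param desquamation A [desquamation_params()].
#' @param prolif A [proliferation_params()].
#' @param coupling A [coupling_config()].
#' @param chem A [chem_params()] holding `s_0` and the (effective) `e_T`;
#'   per-cell `i_T` comes from the scenario.
#' @param rates A [rate_constants()] (time-rescaled for tissue runs).
#' @param ph A [ph_model()].
#' @param scenario A [scenario_spec()].
#' @param seed Integer RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(domain = sim_domain(10, 10),
                       mechanics = mechanics_params(),
                       desquamation = desquamation_params(),
                       prolif = proliferation_params(),
                       coupling = coupling_config(),
                       chem = chem_params(s_0 = 10e-6, e_T = 0.1e-9),
                       rates = multiscale_rates(),
                       ph = ph_model(),
                       scenario = scenario_spec(),
                       seed = 1L) {
  stopifnot(inherits(domain, "sim_domain"),
            inherits(mechanics, "mechanics_params"),
            inherits(desquamation, "desquamation_params"),
            inherits(prolif, "proliferation_params"),
            inherits(coupling, "coupling_config"),
            inherits(chem, "chem_params"),
            inherits(rates, "rate_constants"),
            inherits(ph, "ph_model"),
            inherits(scenario, "scenario_spec"))
  if (coupling$f_h * mechanics$dt > 1) stop("f_h * dt must be <= 1")
  structure(list(
    domain = domain, mechanics = mechanics, desquamation = desquamation,
    prolif = prolif, coupling = coupling, chem = chem, rates = rates,
    ph = ph, scenario = scenario, seed = as.integer(seed)
  ), class = "run_config")
}
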