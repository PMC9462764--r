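#' Serialise a run configuration to JSON
#'
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  flat <- list(
    domain = cfg$domain[c("Lx", "Ly")],
    mechanics = cfg$mechanics[c("k_rep", "gamma", "alpha_0", "F_max", "k_phi",
                                "eta", "dt", "R_0", "neighbour_cutoff",
                                "division_offset", "growth_time")],
    desquamation = cfg$desquamation[c("dx", "F_D", "contact_gap")],
    prolif = cfg$prolif[c("cycle_low", "cycle_high", "population_mode", "T_1",
                          "dT_C", "fraction_fast")],
    coupling = cfg$coupling[c("h_corneum_base", "f_h", "burn_in_days",
                              "sample_days", "realisations", "fill_days",
                              "fill_ceiling")],
    chem = cfg$chem[c("s_0", "e_T")],
    rates = cfg$rates[c("k_plus1", "k_minus1", "k_2", "K_M", "a3", "b3",
                        "A3", "B3")],
    ph = cfg$ph[c("c0", "c1", "c2", "c3")],
    scenario = Filter(Negate(is.null),
                      cfg$scenario[c("inhibitor_fraction",
                                     "normal_stem_fraction")]),
    seed = cfg$seed
  )
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_keys <- function(got, allowed, section) {
  extra <- setdiff(names(got), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in config section '%s': %s",
                 section, paste(extra, collapse = ", ")))
  }
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration written by [save_config()] (or hand-edited),
#' rejecting unknown sections or keys, and rebuilds the nested [run_config()]
#' through the type constructors so every invariant (Michaelis relation,
#' `i_T <= e_T`, positivity, schedule validity) is re-checked at load.
#'
#' @param path Config file path.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sections <- c("domain", "mechanics", "desquamation", "prolif", "coupling",
                "chem", "rates", "ph", "scenario", "seed")
  check_keys(raw, sections, "<top level>")
  check_keys(raw$domain, c("Lx", "Ly"), "domain")
  check_keys(raw$mechanics,
             c("k_rep", "gamma", "alpha_0", "F_max", "k_phi", "eta", "dt",
               "R_0", "neighbour_cutoff", "division_offset", "growth_time"),
             "mechanics")
  check_keys(raw$desquamation, c("dx", "F_D", "contact_gap"), "desquamation")
  check_keys(raw$prolif, c("cycle_low", "cycle_high", "population_mode",
                           "T_1", "dT_C", "fraction_fast"), "prolif")
  check_keys(raw$coupling, c("h_corneum_base", "f_h", "burn_in_days",
                             "sample_days", "realisations", "fill_days",
                             "fill_ceiling"), "coupling")
  check_keys(raw$chem, c("s_0", "e_T"), "chem")
  check_keys(raw$rates, c("k_plus1", "k_minus1", "k_2", "K_M", "a3", "b3",
                          "A3", "B3"), "rates")
  check_keys(raw$ph, c("c0", "c1", "c2", "c3"), "ph")
  check_keys(raw$scenario, c("inhibitor_fraction", "normal_stem_fraction"),
             "scenario")
  run_config(
    domain = do.call(sim_domain, raw$domain),
    mechanics = do.call(mechanics_params, raw$mechanics),
    desquamation = do.call(desquamation_params, raw$desquamation),
    prolif = do.call(proliferation_params, raw$prolif),
    coupling = do.call(coupling_config, raw$coupling),
    chem = do.call(chem_params, raw$chem),
    rates = do.call(rate_constants, raw$rates),
    ph = do.call(ph_model, raw$ph),
    scenario = do.call(scenario_spec, as.list(raw$scenario)),
    seed = raw$seed
  )
}

#' Write simulation outputs to a directory
#'
#' Writes the thickness series, removal-event log, a final per-cell snapshot,
#' and a metadata JSON holding the full configuration and seed. Column
#' headers carry unit suffixes (`_cd`, `_hr`).
#'
#' @param result A [run_scenario()] result (or a list with `state`,
#'   `thickness`, `removals`, `config`).
#' @param outdir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  w <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  w(result$thickness, "thickness.csv")
  w(result$removals, "events.csv")
  st <- result$state
  cells <- as.data.frame(st$cells)
  snap <- data.frame(
    id = cells$id, type = cells$type,
    x_cd = cells$x, y_cd = cells$y, z_cd = cells$z,
    radius_cd = cells$radius, age_hr = st$t - cells$birth_time,
    s = cells$s, e = cells$e, c_i = cells$c_i,
    is_surface = cells$is_surface
  )
  w(snap, sprintf("snapshot_t%.0fhr.csv", st$t))
  meta <- file.path(outdir, "metadata.json")
  save_config(result$config, meta)
  files <- c(files, meta)
  invisible(files)
}

#' Deterministic toy states for tests and examples
#'
#' * `"single-cell"`: one basal stem cell in a 5 x 5 domain.
#' * `"chain-gap"`: five unit-diameter cells stacked vertically above a basal
#'   cell, touching except for one 0.9-CD boundary gap (detached above it).
#' * `"column-block"`: a 2 x 2 block of 4-cell columns.
#' * `"mini-tissue"`: a synthetic pre-filled 5 x 5 tissue (25 stems, columns
#'   of differentiated cells to ~8 CD, with ages consistent with a 0.05
#'   CD/hr rise). Constructed directly, not by simulation.
#'
#' @param name Fixture name.
#' @param seed Integer seed (jitter and cycle times).
#' @return A [simulation_state()].
#' @export
make_fixture <- function(name = c("single-cell", "chain-gap", "column-block",
                                  "mini-tissue"), seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "single-cell") {
    cells <- cell_df(id = 1L, type = "stem", x = 2.5, y = 2.5, z = 0.5,
                     t_c = stats::runif(1, 13, 17), i_t_level = 0.1e-9,
                     c_i = 1)
    return(simulation_state(cells))
  }
  if (name == "chain-gap") {
    z <- c(0.5, 1.5, 2.5, 4.4, 5.4)  # 0.9-CD boundary gap between 3rd and 4th
    cells <- cell_df(id = seq_along(z),
                     type = c("stem", rep("diff", 4)),
                     x = rep(2.5, 5), y = rep(2.5, 5), z = z,
                     birth_time = -z / 0.05,
                     t_c = c(stats::runif(1, 13, 17), rep(NA_real_, 4)),
                     i_t_level = 0.1e-9, c_i = 1)
    return(simulation_state(cells, tau = max(z) - 4))
  }
  if (name == "column-block") {
    grid <- expand.grid(x = c(2, 3), y = c(2, 3), z = c(0.5, 1.5, 2.5, 3.5))
    n <- nrow(grid)
    cells <- cell_df(id = seq_len(n),
                     type = ifelse(grid$z == 0.5, "stem", "diff"),
                     x = grid$x, y = grid$y, z = grid$z,
                     birth_time = -grid$z / 0.05,
                     t_c = ifelse(grid$z == 0.5, stats::runif(n, 13, 17),
                                  NA_real_),
                     i_t_level = 0.1e-9, c_i = 1)
    return(simulation_state(cells))
  }
  # mini-tissue: 25 columns, cells every 0.95 CD up to ~8 CD
  xy <- expand.grid(x = seq_len(5) - 0.5, y = seq_len(5) - 0.5)
  zs <- seq(0.5, 8, by = 0.95)
  rows <- list()
  idc <- 0L
  for (k in seq_len(nrow(xy))) {
    for (z in zs) {
      idc <- idc + 1L
      rows[[idc]] <- data.frame(
        x = xy$x[k] + stats::runif(1, -0.05, 0.05),
        y = xy$y[k] + stats::runif(1, -0.05, 0.05),
        z = z
      )
    }
  }
  pos <- do.call(rbind, rows)
  stem <- pos$z == 0.5
  cells <- cell_df(
    id = seq_len(nrow(pos)),
    type = ifelse(stem, "stem", "diff"),
    x = pos$x, y = pos$y, z = pos$z,
    birth_time = -pos$z / 0.05,
    t_c = ifelse(stem, stats::runif(nrow(pos), 13, 17), NA_real_),
    i_t_level = 0.1e-9, c_i = 1,
    entry_time = ifelse(pos$z >= 4, -(pos$z - 4) / 0.05, NA_real_)
  )
  st <- simulation_state(cells, tau = max(pos$z) - 4)
  ids <- identify_surface_cells(st$cells, sim_domain(5, 5), 1)
  st$cells$is_surface <- st$cells$id %in% ids
  st
}
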