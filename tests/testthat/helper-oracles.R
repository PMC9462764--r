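# Independent oracles, kept deliberately separate from the package internals.

# Brute-force fixed-step RK4 integrator for the six-species system, with its
# own transcription of the mass-action right-hand side.
oracle_chem_rhs <- function(y, s0, eT, kp1, km1, k2, k3p, k3m) {
  e <- y[1]; s <- y[2]; i <- y[3]; cs <- y[4]; ci <- y[5]
  c(
    -kp1 * s0 * e * s + (km1 + k2) * cs - k3p * s0 * e * i + k3m * ci,
    -kp1 * eT * e * s + km1 * (eT / s0) * cs,
    -k3p * eT * e * i + k3m * (eT / s0) * ci,
    kp1 * s0 * e * s - (km1 + k2) * cs,
    k3p * s0 * e * i - k3m * ci,
    k2 * (eT / s0) * cs
  )
}

oracle_rk4 <- function(y, dt, n_steps, s0, eT, kp1, km1, k2, k3p, k3m) {
  h <- dt / n_steps
  for (k in seq_len(n_steps)) {
    k1 <- oracle_chem_rhs(y, s0, eT, kp1, km1, k2, k3p, k3m)
    k2v <- oracle_chem_rhs(y + h / 2 * k1, s0, eT, kp1, km1, k2, k3p, k3m)
    k3v <- oracle_chem_rhs(y + h / 2 * k2v, s0, eT, kp1, km1, k2, k3p, k3m)
    k4v <- oracle_chem_rhs(y + h * k3v, s0, eT, kp1, km1, k2, k3p, k3m)
    y <- y + h / 6 * (k1 + 2 * k2v + 2 * k3v + k4v)
  }
  y
}

# random valid chemical state satisfying the conservation laws for given
# totals (uses the session RNG; callers set the seed)
random_chem_state <- function(params) {
  c_i_max <- if (params$e_T > 0) params$i_T / params$e_T else 0
  c_i <- runif(1, 0, c_i_max)
  rest <- 1 - c_i
  e <- rest * runif(1)
  c_s <- rest - e
  r <- params$e_T / params$s_0
  p_max <- 1 - r * c_s
  s <- runif(1, 0, p_max)
  p <- p_max - s
  i <- params$i_T / params$s_0 - r * c_i
  chem_state(e = e, s = s, i = i, c_s = c_s, c_i = c_i, p = p)
}

# numerical scan oracle for the adhesion envelope peak
oracle_adhesion_peak <- function(gamma, alpha = 1, R0 = 0.5) {
  r <- seq(1e-4, 4, by = 1e-4)            # in units of R0
  c0 <- 1 / (2 * gamma)
  g <- (r + c0) * exp(-gamma * (r + c0)^2) - c0 * exp(-gamma * (r^2 + c0^2))
  list(g_max = max(g) * alpha, r_star = r[which.max(g)])
}

# small two-cell population helper
two_cells <- function(gap, z = 5, type = c("diff", "diff")) {
  cell_df(id = 1:2, type = type, x = c(2, 2 + 1 + gap), y = c(2, 2),
          z = c(z, z), birth_time = c(0, 0))
}

chem_state_vec_list <- function(st) c(st$e, st$s, st$i, st$c_s, st$c_i, st$p)
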