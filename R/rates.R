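#' Kinetic rate constants for the KLK/LEKTI/CND system
#'
#' Container for the rate parameters of the competitive-inhibition scheme
#' E + S <-> C_S -> E + P (rates `k_plus1`, `k_minus1`, `k_2`) and
#' E + I <-> C_I (pH-dependent rates `k_plus3`, `k_minus3`). The KLK-LEKTI
#' rates are parameterised as
#' `k_plus3(pH) = (a3 * pH - b3) * 1e7` (M^-1 hr^-1, floored at 0) and
#' `k_minus3(pH) = A3 * exp(-B3 * pH)` (hr^-1).
#'
#' Defaults are the single-cell literature values; `k_minus1 = 0` is the
#' stated approximation (the Michaelis constant then fixes `k_plus1`). The
#' Michaelis relation `K_M = (k_minus1 + k_2) / k_plus1` is validated to 0.5%.
#'
#' @param k_plus1 KLK-CND association rate, M^-1 hr^-1.
#' @param k_minus1 KLK-CND dissociation rate, hr^-1.
#' @param k_2 C_S degradation (catalytic) rate, hr^-1.
#' @param K_M KLK-CND Michaelis constant, M.
#' @param a3,b3 Coefficients of the linear pH form of `k_plus3` (x 1e7).
#' @param A3 Prefactor of `k_minus3`, hr^-1.
#' @param B3 Exponential pH coefficient of `k_minus3`, pH^-1.
#' @return An object of class `rate_constants`.
#' @seealso [scale_rates()], [klk_lekti_rates()]
#' @export
rate_constants <- function(k_plus1 = 4.97e7, k_minus1 = 0, k_2 = 2.29e3,
                           K_M = 4.60e-5, a3 = 5.2, b3 = 19.5,
                           A3 = 2.3e6, B3 = 3.0) {
  vals <- c(k_plus1, k_minus1, k_2, K_M, a3, b3, A3, B3)
  if (!all(is.finite(vals))) stop("rate constants must be finite")
  if (k_plus1 <= 0 || k_2 < 0 || k_minus1 < 0 || A3 < 0) {
    stop("rate constants must be non-negative (k_plus1 > 0)")
  }
  km_implied <- (k_minus1 + k_2) / k_plus1
  if (K_M < 0) stop("K_M must be non-negative")
  if (K_M == 0 && km_implied > 0 ||
      K_M > 0 && abs(km_implied - K_M) / K_M > 0.005) {
    stop(sprintf(
      "Michaelis relation violated: (k_minus1 + k_2)/k_plus1 = %.4g but K_M = %.4g",
      km_implied, K_M
    ))
  }
  structure(list(
    k_plus1 = k_plus1, k_minus1 = k_minus1, k_2 = k_2, K_M = K_M,
    a3 = a3, b3 = b3, A3 = A3, B3 = B3
  ), class = "rate_constants")
}

#' pH-dependent KLK-LEKTI association/dissociation rates
#'
#' The association rate is linear in pH and floored at zero below its root
#' (pH 19.5/5.2 = 3.75 for the defaults); the dissociation rate is a decaying
#' exponential in pH, so inhibition is strong in the neutral deep corneum and
#' weak at the acidic surface.
#'
#' @param pH pH value(s).
#' @param rates A [rate_constants()].
#' @return A list with components `k_plus3` (M^-1 hr^-1) and `k_minus3`
#'   (hr^-1), each the same length as `pH`.
#' @export
klk_lekti_rates <- function(pH, rates = rate_constants()) {
  if (!is.numeric(pH) || any(!is.finite(pH))) stop("pH must be finite numeric")
  list(
    k_plus3 = pmax(rates$a3 * pH - rates$b3, 0) * 1e7,
    k_minus3 = rates$A3 * exp(-rates$B3 * pH)
  )
}

#' Time-rescaling specification for the multiscale model
#'
#' The tissue simulation uses a faster proliferation rate and a thinner target
#' corneum than physiological skin, so cells traverse the corneum in
#' `T_hat = tau_T / v_z` hours instead of the physiological single-cell
#' migration time `T_M`. All kinetic rates are multiplied by
#' `lambda = T_M / T_hat` so that the chemistry completes over the compressed
#' migration. Defaults give `T_hat = 8 / 0.05 = 160` hr and `lambda = 3`.
#'
#' @param T_M Physiological single-cell corneum migration time, hr.
#' @param tau_T Target corneum thickness in the tissue model, CD.
#' @param v_z Expected vertical cell velocity in the tissue model, CD hr^-1.
#' @return An object of class `scaling_spec` with derived `T_hat` and `lambda`.
#' @export
scaling_spec <- function(T_M = 480, tau_T = 8, v_z = 0.05) {
  T_hat <- tau_T / v_z
  if (!is.finite(T_hat) || T_hat <= 0) stop("T_hat = tau_T/v_z must be positive")
  lambda <- T_M / T_hat
  if (lambda <= 0) stop("scale factor lambda = T_M/T_hat must be positive")
  structure(list(T_M = T_M, tau_T = tau_T, v_z = v_z,
                 T_hat = T_hat, lambda = lambda),
            class = "scaling_spec")
}

#' Rescale rate constants for the multiscale model
#'
#' Multiplies every rate constant (`k_plus1`, `k_2`, `k_minus1`, the
#' `a3`/`b3` pair and `A3`) by `lambda = T_M / T_hat`. `B3` (a pH
#' sensitivity, not a rate) and `K_M` (a ratio of rates) are unchanged.
#'
#' @param rates A [rate_constants()].
#' @param spec A [scaling_spec()].
#' @return A new `rate_constants` object.
#' @examples
#' scale_rates(rate_constants(), scaling_spec())$k_2  # 6.87e3 hr^-1
#' @export
scale_rates <- function(rates = rate_constants(), spec = scaling_spec()) {
  lam <- spec$lambda
  rate_constants(
    k_plus1 = rates$k_plus1 * lam,
    k_minus1 = rates$k_minus1 * lam,
    k_2 = rates$k_2 * lam,
    K_M = rates$K_M,
    a3 = rates$a3 * lam,
    b3 = rates$b3 * lam,
    A3 = rates$A3 * lam,
    B3 = rates$B3
  )
}

#' Multiscale (time-rescaled) rate constants
#'
#' Convenience wrapper: the single-cell literature rates scaled by the default
#' [scaling_spec()] (`lambda = 3`), matching the tissue-model parameter set.
#'
#' @param spec A [scaling_spec()].
#' @return A `rate_constants` object.
#' @export
multiscale_rates <- function(spec = scaling_spec()) {
  scale_rates(rate_constants(), spec)
}
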