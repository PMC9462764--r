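#' pH gradient through the stratum corneum
#'
#' Cubic polynomial model of pH as a function of normalised height `xi` in the
#' corneum (`xi = 0` at the corneum base, `xi = 1` at the skin surface). The
#' default coefficients are a fit to tape-stripping measurements of human
#' epidermal pH and give a monotone decrease from pH 6.85 (deep corneum) to
#' pH 4.48 (surface).
#'
#' @param c0,c1,c2,c3 Polynomial coefficients (pH units per power of `xi`).
#' @return An object of class `ph_model`.
#' @examples
#' m <- ph_model()
#' ph_at(0, m)   # 6.8482, deep corneum
#' ph_at(1, m)   # 4.4846, surface
#' @export
ph_model <- function(c0 = 6.8482, c1 = -0.3765, c2 = -5.1663, c3 = 3.1792) {
  coefs <- c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(coefs))) stop("ph_model coefficients must be finite")
  structure(as.list(coefs), class = "ph_model")
}

#' Evaluate the corneum pH gradient
#'
#' Heights outside `[0, 1]` are clamped before evaluation: `xi = 1` above the
#' corneum surface, `xi = 0` below its base.
#'
#' @param xi Normalised height(s) in the corneum.
#' @param model A [ph_model()].
#' @return pH value(s), same length as `xi`.
#' @export
ph_at <- function(xi, model = ph_model()) {
  if (!is.numeric(xi) || any(!is.finite(xi))) {
    stop("xi must be finite numeric")
  }
  xi <- pmin(pmax(xi, 0), 1)
  model$c0 + model$c1 * xi + model$c2 * xi^2 + model$c3 * xi^3
}
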