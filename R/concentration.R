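#' Estimate a molar enzyme concentration from tissue dry-weight data
#'
#' Literature KLK abundances are reported as nanograms of enzyme per milligram
#' of dry corneum tissue. To convert to a molar concentration in extracellular
#' space: the enzyme mass becomes moles via the molecular weight, and the
#' solvent volume is the extracellular fraction of the tissue water (at
#' 1 g/mL). `water_content` is grams of water per gram of *wet* tissue, so one
#' milligram of dry tissue carries `water_content / (1 - water_content)`
#' milligrams of water.
#'
#' @param dry_weight Enzyme dry weight, ng per mg dry tissue.
#' @param mw Enzyme molecular weight, kDa.
#' @param water_content Tissue water content, g water per g wet tissue.
#' @param extracellular_fraction Fraction of tissue water that is
#'   extracellular, in (0, 1].
#' @return Molar concentration, M.
#' @examples
#' # KLK5 reference inputs give ~0.723 uM
#' estimate_enzyme_concentration(3.1, 33, 0.5, 0.13)
#' @export
estimate_enzyme_concentration <- function(dry_weight, mw, water_content,
                                          extracellular_fraction) {
  if (any(c(dry_weight, mw, water_content) <= 0)) {
    stop("dry_weight, mw and water_content must be positive")
  }
  if (water_content >= 1) stop("water_content must be < 1 g/g wet tissue")
  if (extracellular_fraction <= 0 || extracellular_fraction > 1) {
    stop("extracellular_fraction must be in (0, 1]")
  }
  moles_per_mg_dry <- dry_weight * 1e-9 / (mw * 1e3)       # g / (g/mol)
  water_g_per_mg_dry <- water_content / (1 - water_content) * 1e-3
  ecv_l <- water_g_per_mg_dry * extracellular_fraction * 1e-3  # 1 g/mL
  moles_per_mg_dry / ecv_l
}

#' Estimate the corneodesmosome protein concentration from cell geometry
#'
#' The corneum cell is idealised as a square slab `cell_width` x `cell_width`
#' x `cell_height` separated from each neighbour by an extracellular gap of
#' which it owns half. Corneodesmosome surface densities (proteins per um^2)
#' may differ between the peripheral (vertical, side) faces and the central
#' (horizontal, top/bottom) faces. The concentration is the total protein
#' count over the half-gap extracellular shell volume around the cell.
#'
#' Note: the literature value of 6.6 uM is *not* reproduced by this slab
#' geometry under any simple counting convention (the published derivation
#' uses unpublished supplementary assumptions), so the model's default `s_0`
#' is a configuration constant rather than the output of this helper.
#'
#' @param peripheral_density Protein density on the side faces, um^-2.
#' @param central_density Protein density on the top/bottom faces, um^-2.
#' @param cell_width Slab width, um.
#' @param cell_height Slab height, um.
#' @param gap Extracellular gap between neighbouring cells, um.
#' @return Molar concentration, M.
#' @export
estimate_cnd_concentration <- function(peripheral_density, central_density,
                                       cell_width, cell_height, gap) {
  if (peripheral_density < 0 || central_density < 0) {
    stop("densities must be non-negative")
  }
  if (cell_width <= 0 || cell_height <= 0) stop("cell dimensions must be positive")
  if (gap <= 0) stop("gap must be positive")
  side_area <- 4 * cell_width * cell_height
  flat_area <- 2 * cell_width^2
  count <- peripheral_density * side_area + central_density * flat_area
  shell_um3 <- (side_area + flat_area) * gap / 2
  avogadro <- 6.02214076e23
  count / (avogadro * shell_um3 * 1e-15)  # um^3 -> L
}
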