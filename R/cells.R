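#' Construct a cell population table
#'
#' Cells are rows of a plain data.frame. Positions are in CD (lateral
#' coordinates wrapped into the periodic domain), `type` is `"stem"` or
#' `"diff"`, `t_c` the assigned cycle time (hr, NA for differentiated cells),
#' `i_t_level` the inherited total-inhibitor concentration (M), and the six
#' chemistry columns hold the cell's dimensionless [chem_state()].
#' `entry_time` records the first time the cell centre crossed the corneum
#' base (NA until then); `partner` is the row id of a division twin while the
#' rotational force is active.
#'
#' @param id Integer ids.
#' @param type `"stem"` or `"diff"`.
#' @param x,y,z Positions, CD.
#' @param radius Cell radii, CD.
#' @param birth_time Birth times, hr.
#' @param t_c Cycle times, hr.
#' @param i_t_level Inherited inhibitor concentration, M.
#' @param e,s,i,c_s,c_i,p Chemistry fractions.
#' @param entry_time Corneum entry times, hr.
#' @param is_surface Surface-cell flags.
#' @param partner Division twin ids.
#' @return A data.frame of class `cell_df`.
#' @export
cell_df <- function(id, type, x, y, z, radius = 0.5, birth_time = 0,
                    t_c = NA_real_, i_t_level = 0,
                    e = 0, s = 1, i = 0, c_s = 0, c_i = 0, p = 0,
                    entry_time = NA_real_, is_surface = FALSE,
                    partner = NA_integer_) {
  df <- data.frame(
    id = as.integer(id), type = as.character(type),
    x = x, y = y, z = z, radius = radius,
    birth_time = birth_time, t_c = t_c, i_t_level = i_t_level,
    e = e, s = s, i = i, c_s = c_s, c_i = c_i, p = p,
    entry_time = entry_time, is_surface = is_surface,
    partner = as.integer(partner),
    stringsAsFactors = FALSE
  )
  if (any(df$radius <= 0 | df$radius > 0.5 + 1e-12)) {
    stop("cell radius must be in (0, R_0]")
  }
  if (any(df$z < 0)) stop("cell z must be >= 0")
  class(df) <- c("cell_df", "data.frame")
  df
}

#' @export
print.cell_df <- function(x, ...) {
  cat(sprintf("<cell population: %d cells (%d stem, %d differentiated)>\n",
              nrow(x), sum(x$type == "stem"), sum(x$type == "diff")))
  NextMethod()
}

#' Periodic simulation domain
#'
#' Laterally periodic box of extent `Lx` x `Ly` CD with a rigid basal
#' membrane at `z = 0`. Lateral extents must be at least twice the
#' neighbour-search cutoff for the minimum-image convention to be valid.
#'
#' @param Lx,Ly Lateral extents, CD.
#' @return An object of class `sim_domain`.
#' @export
sim_domain <- function(Lx = 10, Ly = 10) {
  if (Lx <= 0 || Ly <= 0) stop("domain extents must be positive")
  structure(list(Lx = Lx, Ly = Ly), class = "sim_domain")
}

# minimum-image displacement from (x1,y1,z1) to (x2,y2,z2)
min_image <- function(dx, dy, domain) {
  dx <- dx - domain$Lx * round(dx / domain$Lx)
  dy <- dy - domain$Ly * round(dy / domain$Ly)
  list(dx = dx, dy = dy)
}

wrap_lateral <- function(v, L) v - L * floor(v / L)
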