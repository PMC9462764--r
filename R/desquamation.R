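#' Desquamation (force-based removal) parameters
#'
#' @param dx Surface-identification grid size, CD (must divide the domain).
#' @param F_D Vertical removal force applied to surface cells, uN.
#' @param contact_gap Boundary-to-boundary gap below which two cells count as
#'   "in contact" for main-body connectivity, CD. The same threshold defines
#'   the basal seed band.
#' @return An object of class `desquamation_params`.
#' @export
desquamation_params <- function(dx = 1, F_D = 5, contact_gap = 0.7) {
  if (dx <= 0) stop("dx must be positive")
  if (F_D < 0) stop("F_D must be non-negative")
  if (contact_gap <= 0 || contact_gap >= 2) {
    stop("contact_gap must be in (0, neighbour_cutoff)")
  }
  structure(list(dx = dx, F_D = F_D, contact_gap = contact_gap),
            class = "desquamation_params")
}

#' Identify the surface cells on a lateral grid
#'
#' The horizontal plane is split into squares of side `dx`; the highest cell
#' centre in each occupied square is flagged as a surface cell. With a fully
#' occupied `Lx x Ly` domain at `dx = 1` this yields `Lx * Ly` surface cells,
#' matching the number of basal stem cells.
#'
#' @param cells A [cell_df()].
#' @param domain A [sim_domain()].
#' @param dx Grid size, CD.
#' @return Integer vector of surface-cell `id`s.
#' @export
identify_surface_cells <- function(cells, domain, dx = 1) {
  nx <- domain$Lx / dx
  ny <- domain$Ly / dx
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("dx must divide the domain extents")
  }
  if (nrow(cells) == 0) return(integer())
  gx <- pmin(floor(wrap_lateral(cells$x, domain$Lx) / dx), round(nx) - 1)
  gy <- pmin(floor(wrap_lateral(cells$y, domain$Ly) / dx), round(ny) - 1)
  key <- gx * round(ny) + gy
  top <- tapply(seq_len(nrow(cells)), key, function(idx) idx[which.max(cells$z[idx])])
  cells$id[unlist(top)]
}

#' Removal forces on surface cells
#'
#' @param cells A [cell_df()].
#' @param surface_ids Ids from [identify_surface_cells()].
#' @param F_D Removal force magnitude, uN.
#' @return n x 3 matrix: `+z` force `F_D` on surface cells, zero elsewhere.
#' @export
removal_forces <- function(cells, surface_ids, F_D) {
  F <- matrix(0, nrow(cells), 3)
  F[cells$id %in% surface_ids, 3] <- F_D
  F
}

#' Partition cells into main tissue body and detached cells
#'
#' Connectivity closure from the basal seed set (cells whose centre height is
#' within `R_0 + contact_gap` of the membrane): a cell joins the main body if
#' its boundary gap to any main-body cell is below `contact_gap` (periodic
#' minimum image). Everything else is detached.
#'
#' @param cells A [cell_df()].
#' @param domain A [sim_domain()].
#' @param contact_gap Contact threshold on boundary gaps, CD.
#' @param pairs Optional precomputed [build_neighbor_lists()] output.
#' @param R_0 Normal cell radius (sets the basal seed band), CD.
#' @return Logical vector: `TRUE` for main-body cells.
#' @export
main_body_labels <- function(cells, domain, contact_gap = 0.7, pairs = NULL,
                             R_0 = 0.5) {
  n <- nrow(cells)
  main <- cells$z <= R_0 + contact_gap
  if (!any(main)) stop("simulation integrity: no cells in the basal seed band")
  if (is.null(pairs)) {
    pairs <- build_neighbor_lists(cells, domain, cutoff = 2)
  }
  touch <- pairs[pairs$gap < contact_gap, c("i", "j"), drop = FALSE]
  # iterative closure over the contact graph
  adj <- vector("list", n)
  for (k in seq_len(nrow(touch))) {
    adj[[touch$i[k]]] <- c(adj[[touch$i[k]]], touch$j[k])
    adj[[touch$j[k]]] <- c(adj[[touch$j[k]]], touch$i[k])
  }
  queue <- which(main)
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!main[w]) {
        main[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  main
}

# dividing pairs are in physical contact: add a zero-gap edge so newborn
# daughters (absent from a pre-division neighbour list) stay attached
add_partner_edges <- function(pairs, cells) {
  paired <- which(!is.na(cells$partner))
  if (length(paired) == 0) return(pairs)
  twin <- match(cells$partner[paired], cells$id)
  ok <- !is.na(twin) & paired < twin
  if (!any(ok)) return(pairs)
  extra <- data.frame(
    i = paired[ok], j = twin[ok], dist = 0, gap = 0,
    ux = 0, uy = 0, uz = 1
  )
  rbind(pairs, extra)
}

# connected components of the detached set under the contact graph; returns
# integer clump labels aligned with `rows` (cell_df row indices)
clump_components <- function(rows, pairs, contact_gap) {
  pos <- match(seq_len(max(c(rows, 1))), rows)  # row index -> position in rows
  touch <- pairs[pairs$gap < contact_gap &
                   pairs$i %in% rows & pairs$j %in% rows, , drop = FALSE]
  adj <- vector("list", length(rows))
  for (k in seq_len(nrow(touch))) {
    a <- pos[touch$i[k]]; b <- pos[touch$j[k]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lab <- rep(NA_integer_, length(rows))
  comp <- 0L
  for (start in seq_along(rows)) {
    if (!is.na(lab[start])) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(lab[w])) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' Remove detached cells and log removal events
#'
#' Cells not path-connected to the basal seed set are deleted. Each removed
#' cell produces one removal event; cells removed in the same step that are
#' mutually connected share a clump id (desquamation in squames).
#'
#' @param state A [simulation_state()].
#' @param desq A [desquamation_params()].
#' @param domain A [sim_domain()].
#' @param pairs Optional precomputed neighbour list (e.g. the one used for
#'   the force assembly of this step). Pair rows index `state$cells` rows;
#'   cells absent from it (newborn daughters) are attached through their
#'   division-partner edge.
#' @return The updated state, with new rows appended to `state$removals`.
#' @export
cull_detached <- function(state, desq = desquamation_params(),
                          domain = sim_domain(), pairs = NULL) {
  cells <- state$cells
  if (is.null(pairs)) {
    pairs <- build_neighbor_lists(cells, domain, cutoff = 2)
  }
  pairs <- add_partner_edges(pairs, cells)
  main <- main_body_labels(cells, domain, desq$contact_gap, pairs = pairs)
  gone <- which(!main)
  if (length(gone) == 0) return(state)
  clump <- clump_components(gone, pairs, desq$contact_gap)
  ev <- data.frame(
    id = cells$id[gone], time_hr = state$t,
    age_hr = state$t - cells$birth_time[gone],
    z_cd = cells$z[gone], s = cells$s[gone],
    entry_time_hr = cells$entry_time[gone],
    clump = max(c(0L, state$removals$clump)) + clump
  )
  state$removals <- rbind(state$removals, ev)
  kept <- as.data.frame(cells)[main, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("cell_df", "data.frame")
  state$cells <- kept
  state
}
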