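#' Per-cell protection status under a reserve layer
#'
#' A cell counts as protected by a tier iff at least one reserve polygon of
#' that tier intersects the cell rectangle with positive area — a reserve
#' merely touching a cell edge does not protect it. A hotspot cell
#' protected by neither tier is a conservation gap.
#'
#' @param grid A [grid_spec()].
#' @param reserves A [reserve_layer()].
#' @return A data.frame with one row per grid cell and logical columns
#'   `by_nnr`, `by_pnr`, `by_either`.
#' @export
protection_status <- function(grid, reserves) {
  nc <- n_cells(grid)
  by_nnr <- logical(nc)
  by_pnr <- logical(nc)
  s <- grid$cell_size
  for (k in seq_along(reserves$polygons)) {
    p <- reserves$polygons[[k]]
    # candidate cells from the polygon bounding box
    i0 <- max(0L, floor((min(p[, 1]) - grid$x0) / s))
    i1 <- min(grid$n_cols - 1L, floor((max(p[, 1]) - grid$x0) / s))
    j0 <- max(0L, floor((min(p[, 2]) - grid$y0) / s))
    j1 <- min(grid$n_rows - 1L, floor((max(p[, 2]) - grid$y0) / s))
    if (i1 < i0 || j1 < j0) next
    tgt <- if (reserves$tier[k] == "NNR") quote(by_nnr) else quote(by_pnr)
    for (j in j0:j1) for (i in i0:i1) {
      cell <- j * grid$n_cols + i + 1L
      hit <- if (reserves$tier[k] == "NNR") by_nnr[cell] else by_pnr[cell]
      if (hit) next
      rect <- c(grid$x0 + i * s, grid$y0 + j * s,
                grid$x0 + (i + 1) * s, grid$y0 + (j + 1) * s)
      if (poly_rect_area(p, rect) > 1e-9) {
        if (reserves$tier[k] == "NNR") by_nnr[cell] <- TRUE else by_pnr[cell] <- TRUE
      }
    }
  }
  data.frame(cell = seq_len(nc), by_nnr = by_nnr, by_pnr = by_pnr,
             by_either = by_nnr | by_pnr)
}

status_column <- function(status, tier = c("either", "NNR", "PNR")) {
  tier <- match.arg(tier)
  switch(tier, NNR = status$by_nnr, PNR = status$by_pnr,
         either = status$by_either)
}

#' Conservation gap cells
#'
#' Hotspot cells not protected by the given reserve tier.
#'
#' @param hotspot_cells Integer vector of hotspot cell ids.
#' @param status Output of [protection_status()].
#' @param tier `"NNR"`, `"PNR"` or `"either"` (default).
#' @return Integer vector of gap cell ids.
#' @export
gap_cells <- function(hotspot_cells, status, tier = c("either", "NNR", "PNR")) {
  prot <- status_column(status, match.arg(tier))
  hotspot_cells[!prot[hotspot_cells]]
}

#' Conservation effectiveness and gap summary
#'
#' For each reserve tier (NNR, PNR, either) and protection side (protected
#' / unprotected), counts hotspot cells and the species — all, endemic and
#' threatened — having at least one presence in those cells. Percentages
#' use the hotspot cell count as the denominator for cells and the full
#' checklist group totals for species, rounded half-up to 2 decimals. A
#' leading `final_hotspots` block summarizes the hotspot set itself.
#'
#' @param hotspot_cells Integer vector of hotspot cell ids.
#' @param status Output of [protection_status()].
#' @param pm Presence matrix from [build_presence()].
#' @param checklist Checklist data.frame (see [species_subset()]).
#' @return A data.frame with columns `block`, `measure`, `count`, `denom`,
#'   `pct`.
#' @export
effectiveness_summary <- function(hotspot_cells, status, pm, checklist) {
  hotspot_cells <- as.integer(hotspot_cells)
  if (length(hotspot_cells) == 0)
    warning("empty hotspot set: summary is all zeros")
  groups <- list(
    species_all = species_subset(checklist, "all"),
    species_endemic = species_subset(checklist, "endemic"),
    species_threatened = species_subset(checklist, "threatened"))
  species_in <- function(cells) {
    if (length(cells) == 0) return(character(0))
    colnames(pm)[Matrix::colSums(pm[cells, , drop = FALSE]) > 0]
  }
  block_rows <- function(block, cells) {
    rows <- data.frame(block = block, measure = "cells",
                       count = length(cells), denom = length(hotspot_cells),
                       pct = pct(length(cells), length(hotspot_cells)))
    sp <- species_in(cells)
    for (g in names(groups)) {
      cnt <- sum(groups[[g]] %in% sp)
      rows <- rbind(rows, data.frame(block = block, measure = g,
                                     count = cnt, denom = length(groups[[g]]),
                                     pct = pct(cnt, length(groups[[g]]))))
    }
    rows
  }
  out <- block_rows("final_hotspots", hotspot_cells)
  for (tier in c("NNR", "PNR", "either")) {
    prot <- status_column(status, tier)
    out <- rbind(out,
                 block_rows(paste0("protected_", tier),
                            hotspot_cells[prot[hotspot_cells]]),
                 block_rows(paste0("unprotected_", tier),
                            hotspot_cells[!prot[hotspot_cells]]))
  }
  rownames(out) <- NULL
  out
}

#' Per-species protection of occurrence records
#'
#' Fraction of each species' occurrence records falling inside any reserve
#' polygon (either tier; records on a polygon boundary count as inside).
#' Species are flagged when strictly less than 30% or strictly more than
#' 90% of their records are protected.
#'
#' @param occ Occurrence data.frame with columns `species_id`, `x`, `y`.
#' @param reserves A [reserve_layer()].
#' @return A data.frame with columns `species_id`, `n_records`,
#'   `n_protected`, `fraction`, `under_30`, `over_90`.
#' @export
species_record_protection <- function(occ, reserves) {
  occ <- occ[!is.na(occ$species_id), , drop = FALSE]
  inside <- rep(FALSE, nrow(occ))
  for (p in reserves$polygons) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    # bounding-box prefilter
    bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    cand <- todo[occ$x[todo] >= bb[1] - 1e-9 & occ$x[todo] <= bb[3] + 1e-9 &
                 occ$y[todo] >= bb[2] - 1e-9 & occ$y[todo] <= bb[4] + 1e-9]
    if (length(cand) == 0) next
    inside[cand] <- point_in_polygon(occ$x[cand], occ$y[cand], p)
  }
  sp <- as.character(occ$species_id)
  n_rec <- table(sp)
  n_prot <- tapply(inside, sp, sum)
  ids <- names(n_rec)
  frac <- as.numeric(n_prot[ids]) / as.numeric(n_rec[ids])
  data.frame(species_id = ids,
             n_records = as.integer(n_rec[ids]),
             n_protected = as.integer(n_prot[ids]),
             fraction = frac,
             under_30 = frac < 0.30,
             over_90 = frac > 0.90,
             row.names = NULL)
}
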