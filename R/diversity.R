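#' Select a species subset from the checklist
#'
#' The three standard subsets used throughout the analysis are all species,
#' endemic species, and threatened species (categories CR, EN and VU).
#'
#' @param checklist Checklist data.frame with columns `species_id`,
#'   `endemic` (logical) and `category` (one of CR/EN/VU/NT/CC).
#' @param subset One of `"all"`, `"endemic"`, `"threatened"`.
#' @return Character vector of species ids.
#' @export
species_subset <- function(checklist, subset = c("all", "endemic", "threatened")) {
  subset <- match.arg(subset)
  ids <- as.character(checklist$species_id)
  switch(subset,
         all = ids,
         endemic = ids[checklist$endemic],
         threatened = ids[checklist$category %in% c("CR", "EN", "VU")])
}

# restrict a presence matrix to a species-id subset
subset_pm <- function(pm, subset_ids = NULL) {
  if (is.null(subset_ids)) return(pm)
  keep <- colnames(pm) %in% subset_ids
  pm[, keep, drop = FALSE]
}

new_surface <- function(values, metric, subset = "all") {
  structure(as.numeric(values), metric = metric, subset = subset,
            class = "diversity_surface")
}

#' @export
print.diversity_surface <- function(x, ...) {
  cat(sprintf("diversity_surface [%s, %s]: %d cells, range %g..%g\n",
              attr(x, "metric"), attr(x, "subset"), length(x),
              min(x), max(x)))
  invisible(x)
}

#' Species richness surface
#'
#' Number of (subset) species present in each grid cell — the classic
#' hotspot indicator.
#'
#' @param pm Presence matrix from [build_presence()].
#' @param subset_ids Optional character vector of species ids restricting
#'   the metric to a subset (e.g. from [species_subset()]).
#' @return A numeric `diversity_surface`, one value per grid cell.
#' @export
richness_surface <- function(pm, subset_ids = NULL) {
  m <- subset_pm(pm, subset_ids)
  new_surface(Matrix::rowSums(m), "richness",
              if (is.null(subset_ids)) "all" else "subset")
}

#' Greedy complementarity (set-cover) cell selection
#'
#' Iteratively selects the cell covering the largest number of species not
#' yet represented, removes those species from consideration, and repeats
#' until every species present is covered — the classical complementarity
#' heuristic for minimum-area representation. Ties are broken by the lowest
#' cell id so the selection is deterministic.
#'
#' @inheritParams richness_surface
#' @return A data.frame with columns `cell` (selected cell id, in selection
#'   order) and `gain` (number of species newly covered by that cell).
#'   The gains sum to the number of species present in the subset.
#' @export
complementarity_selection <- function(pm, subset_ids = NULL) {
  m <- subset_pm(pm, subset_ids)
  present <- Matrix::colSums(m) > 0
  m <- m[, present, drop = FALSE]
  k <- ncol(m)
  cells <- integer(0)
  gains <- integer(0)
  remaining <- rep(TRUE, k)
  while (any(remaining)) {
    g <- Matrix::rowSums(m[, remaining, drop = FALSE])
    best <- which.max(g)            # first maximum = lowest cell id
    if (g[best] == 0) break          # cannot happen if columns are non-empty
    covered <- as.logical(m[best, remaining])
    remaining[which(remaining)[covered]] <- FALSE
    cells <- c(cells, best)
    gains <- c(gains, as.integer(g[best]))
  }
  data.frame(cell = as.integer(cells), gain = gains)
}

#' Complementarity gain surface
#'
#' Scalarizes a complementarity selection onto the grid so it can be
#' standardized and correlated like the other two metrics: a selected cell
#' carries its gain (species newly covered at selection), all other cells 0.
#'
#' @param sel Selection from [complementarity_selection()].
#' @param n_cells Total number of grid cells.
#' @return A numeric `diversity_surface`.
#' @export
complementarity_surface <- function(sel, n_cells) {
  v <- numeric(n_cells)
  v[sel$cell] <- sel$gain
  new_surface(v, "complementarity")
}

#' Weighted endemism (range-size rarity) surface
#'
#' Each species is weighted by the reciprocal of its range size (occupied
#' cell count); the weights of all (subset) species present in a cell are
#' summed. Narrow-range species therefore dominate the surface. Each
#' species contributes total weight 1 across the grid, so the surface sums
#' to the number of species present in the subset.
#'
#' @inheritParams richness_surface
#' @return A numeric `diversity_surface`.
#' @export
weighted_endemism_surface <- function(pm, subset_ids = NULL) {
  m <- subset_pm(pm, subset_ids)
  rs <- Matrix::colSums(m)
  present <- rs > 0
  m <- m[, present, drop = FALSE]
  w <- 1 / rs[present]
  v <- as.numeric(m %*% w)
  new_surface(v, "weighted_endemism",
              if (is.null(subset_ids)) "all" else "subset")
}

#' Pearson correlation between two diversity surfaces
#'
#' @param a,b Numeric surfaces of equal length; neither may be constant.
#' @return A list with `r` (sample Pearson coefficient) and `p` (two-sided
#'   p-value from the t distribution with n - 2 degrees of freedom).
#' @export
correlate_surfaces <- function(a, b) {
  if (length(a) != length(b)) abort("surfaces differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort("correlation undefined for a constant surface")
  ct <- stats::cor.test(as.numeric(a), as.numeric(b), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classify a Pearson correlation coefficient into strength bands
#'
#' Bands on `|r|`: negligible (0, 0.1), weak \[0.1, 0.4), moderate
#' \[0.4, 0.7), strong \[0.7, 0.9), very strong \[0.9, 1\]. Exactly 0 is
#' labelled `"none"`; `|r| = 1` closes the top band.
#'
#' @param r Numeric vector of correlation coefficients, `|r| <= 1`.
#' @return Character vector of band labels.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1)) abort("|r| must not exceed 1")
  a <- abs(r)
  ifelse(a == 0, "none",
  ifelse(a < 0.1, "negligible",
  ifelse(a < 0.4, "weak",
  ifelse(a < 0.7, "moderate",
  ifelse(a < 0.9, "strong", "very strong")))))
}

#' Correlation matrix of the nine standard diversity surfaces
#'
#' Convenience wrapper computing richness, complementarity and weighted
#' endemism for the all/endemic/threatened subsets and correlating every
#' pair.
#'
#' @param pm Presence matrix.
#' @param checklist Checklist data.frame (see [species_subset()]).
#' @return A data.frame with columns `a`, `b`, `r`, `p`, `band`, one row
#'   per unordered surface pair.
#' @export
surface_correlations <- function(pm, checklist) {
  subsets <- c("all", "endemic", "threatened")
  surfaces <- list()
  for (s in subsets) {
    ids <- species_subset(checklist, s)
    tag <- toupper(substr(s, 1, 1))
    surfaces[[paste0(tag, "SR")]] <- richness_surface(pm, ids)
    sel <- complementarity_selection(pm, ids)
    surfaces[[paste0(tag, "SC")]] <- complementarity_surface(sel, nrow(pm))
    surfaces[[paste0(tag, "WE")]] <- weighted_endemism_surface(pm, ids)
  }
  nm <- names(surfaces)
  out <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    ct <- correlate_surfaces(surfaces[[i]], surfaces[[j]])
    out[[length(out) + 1L]] <- data.frame(a = nm[i], b = nm[j],
                                          r = ct$r, p = ct$p,
                                          band = classify_correlation(ct$r))
  }
  do.call(rbind, out)
}
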