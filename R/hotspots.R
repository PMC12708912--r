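#' Min-max standardize a surface to \[0, 1\]
#'
#' `(v - min) / (max - min)`; a constant surface maps to all zeros so a
#' degenerate subset contributes nothing to the composite.
#'
#' @param x Numeric surface.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_standardize <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng))) abort("surface must be finite")
  if (rng[1] == rng[2]) return(numeric(length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# z-score alternative (constant surface -> zeros)
zscore_standardize <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Composite score across species subsets for one algorithm
#'
#' Standardizes the all-species, endemic and threatened surfaces of one
#' algorithm and sums them cellwise, so each subset contributes on a
#' commensurable 0–1 scale and the composite lies in \[0, 3\] under
#' min-max standardization.
#'
#' @param all,endemic,threatened Numeric surfaces of one algorithm on one
#'   grid (equal lengths).
#' @param standardize `"minmax"` (default) or `"zscore"`.
#' @return Numeric composite surface.
#' @export
composite_score <- function(all, endemic, threatened,
                            standardize = c("minmax", "zscore")) {
  standardize <- match.arg(standardize)
  if (length(all) != length(endemic) || length(all) != length(threatened))
    abort("surfaces are on different grids")
  f <- if (standardize == "minmax") minmax_standardize else zscore_standardize
  f(all) + f(endemic) + f(threatened)
}

#' Top-fraction hotspot cells with boundary-tie inclusion
#'
#' Ranks the base cells by score (descending), takes the nominal count
#' `m = round(fraction * n_base)` (halves up), and additionally includes
#' every cell tying the m-th score — which is how a "top 10%" set of 280
#' nominal cells can contain 281 cells when the 280th and 281st tie. If
#' every base cell ties on the score the grid is degenerate and an empty
#' set is returned with a warning.
#'
#' @param score Numeric composite surface (one value per grid cell).
#' @param fraction Fraction in (0, 1\].
#' @param base_cells Cell ids forming the percentile base (normally the
#'   occupied cells, see [occupied_cells()]).
#' @return Integer vector of hotspot cell ids (unordered).
#' @export
top_fraction <- function(score, fraction, base_cells) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  base_cells <- as.integer(base_cells)
  if (length(base_cells) == 0) return(integer(0))
  s <- score[base_cells]
  if (length(unique(s)) == 1 && length(s) > 1) {
    warning("constant composite over the base cells: no hotspots returned")
    return(integer(0))
  }
  m <- round_half_up(fraction * length(base_cells))
  if (m < 1) return(integer(0))
  cutoff <- sort(s, decreasing = TRUE)[min(m, length(s))]
  base_cells[s >= cutoff]
}

#' Consensus class of hotspot cells across the three algorithms
#'
#' A cell selected by all three algorithms is Class I, by two Class II, by
#' one Class III; the classes partition the union of the three sets.
#'
#' @param set_r,set_c,set_w Hotspot cell sets of the richness,
#'   complementarity and weighted-endemism algorithms at one threshold.
#' @return A data.frame with columns `cell`, `n_algorithms` and `class`
#'   (factor with levels I, II, III).
#' @export
consensus_classes <- function(set_r, set_c, set_w) {
  cells <- sort(unique(c(set_r, set_c, set_w)))
  n <- (cells %in% set_r) + (cells %in% set_c) + (cells %in% set_w)
  data.frame(cell = as.integer(cells), n_algorithms = as.integer(n),
             class = factor(c("III", "II", "I")[n], levels = c("I", "II", "III")))
}

#' Dense competition ranks over the base cells
#'
#' Rank 1 is the best (highest) score; tied scores share a rank and the
#' next distinct score takes the next integer rank.
#'
#' @param score Numeric surface.
#' @param base_cells Cell ids ranked.
#' @return Integer vector of ranks, named by cell id.
#' @export
dense_ranks <- function(score, base_cells) {
  s <- score[base_cells]
  r <- match(s, sort(unique(s), decreasing = TRUE))
  stats::setNames(as.integer(r), base_cells)
}

#' Rank-sum priority order of hotspot cells
#'
#' Sums each hotspot cell's rank under the three algorithms and sorts
#' ascending (lowest rank sum = highest priority); ties are broken by the
#' lower cell id.
#'
#' @param ranks A list of three named rank vectors (from [dense_ranks()],
#'   one per algorithm) covering all hotspot cells.
#' @param cells Hotspot cell ids to order.
#' @return A data.frame with columns `cell` and `rank_sum`, in priority
#'   order.
#' @export
rank_sum_priority <- function(ranks, cells) {
  cells <- as.integer(cells)
  key <- as.character(cells)
  rs <- rowSums(vapply(ranks, function(r) {
    v <- r[key]
    if (anyNA(v)) abort("a hotspot cell is missing a rank")
    as.numeric(v)
  }, numeric(length(cells))))
  ord <- order(rs, cells)
  data.frame(cell = cells[ord], rank_sum = as.integer(rs[ord]))
}

#' Identify multi-threshold consensus hotspots
#'
#' Full hotspot pipeline: for each of the three algorithms (richness,
#' complementarity, weighted endemism) the all/endemic/threatened subset
#' surfaces are standardized and summed into a composite; the top
#' `fraction` of the base cells (with boundary-tie inclusion) is selected
#' per algorithm; the final hotspot set is the union (or intersection) of
#' the three selections, with consensus Class I/II/III and a rank-sum
#' priority order.
#'
#' @param pm Presence matrix from [build_presence()].
#' @param checklist Checklist data.frame (see [species_subset()]).
#' @param fractions Numeric vector of thresholds (defaults to the 5, 10,
#'   17 and 30 percent conservation-target thresholds).
#' @param base_cells Percentile base; defaults to the occupied cells.
#' @param standardize `"minmax"` (default) or `"zscore"`.
#' @param combine `"union"` (default) or `"intersection"` of the three
#'   algorithms' top sets.
#' @return A named list, one element per fraction, each a data.frame with
#'   columns `cell`, `composite_R`, `composite_C`, `composite_W`,
#'   `n_algorithms`, `class`, `rank_sum`, ordered by priority. The per-
#'   algorithm top sets are attached as attribute `"sets"`.
#' @export
identify_hotspots <- function(pm, checklist,
                              fractions = c(0.05, 0.10, 0.17, 0.30),
                              base_cells = occupied_cells(pm),
                              standardize = c("minmax", "zscore"),
                              combine = c("union", "intersection")) {
  standardize <- match.arg(standardize)
  combine <- match.arg(combine)
  nc <- nrow(pm)
  subsets <- lapply(c(all = "all", endemic = "endemic", threatened = "threatened"),
                    species_subset, checklist = checklist)
  surf <- function(f) lapply(subsets, f)
  rich <- surf(function(ids) richness_surface(pm, ids))
  comp <- surf(function(ids)
    complementarity_surface(complementarity_selection(pm, ids), nc))
  we <- surf(function(ids) weighted_endemism_surface(pm, ids))
  composites <- list(
    R = composite_score(rich$all, rich$endemic, rich$threatened, standardize),
    C = composite_score(comp$all, comp$endemic, comp$threatened, standardize),
    W = composite_score(we$all, we$endemic, we$threatened, standardize))
  ranks <- lapply(composites, dense_ranks, base_cells = base_cells)
  out <- list()
  for (f in fractions) {
    sets <- lapply(composites, top_fraction, fraction = f, base_cells = base_cells)
    cons <- consensus_classes(sets$R, sets$C, sets$W)
    if (combine == "intersection")
      cons <- cons[cons$n_algorithms == 3L, , drop = FALSE]
    prio <- rank_sum_priority(ranks, cons$cell)
    cons <- cons[match(prio$cell, cons$cell), , drop = FALSE]
    res <- data.frame(cell = prio$cell,
                      composite_R = composites$R[prio$cell],
                      composite_C = composites$C[prio$cell],
                      composite_W = composites$W[prio$cell],
                      n_algorithms = cons$n_algorithms,
                      class = cons$class,
                      rank_sum = prio$rank_sum)
    rownames(res) <- NULL
    attr(res, "sets") <- sets
    attr(res, "fraction") <- f
    out[[sprintf("top_%g", 100 * f)]] <- res
  }
  out
}
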