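#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the synthetic study system: a species checklist
#' with threat categories and endemism, occurrence records with a
#' heavy-tailed range-size distribution and spatially clustered
#' narrow-range species, a two-tier reserve layer, correlated
#' environmental layers, and current/future habitat-suitability stacks
#' with planted per-species loss and gain fractions. Every generator is a
#' pure function of this configuration; the same config yields byte-
#' identical output.
#'
#' Defaults emulate the study conditions the package is designed around:
#' 458 species (264 threatened over CR/EN/VU, 56 NT, 138 CC; 232 endemic)
#' on a 64 x 64 grid of 50-km cells (4096 cells, close to a 4069-cell
#' national grid), with ~18% reserve coverage and 20 environmental layers.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_species Number of species.
#' @param extent `c(xmin, ymin, xmax, ymax)` in planar km.
#' @param cell_size Grid cell side, km.
#' @param frac_endemic Probability a species is flagged endemic.
#' @param category_fractions Named proportions over CR, EN, VU, NT, CC;
#'   must sum to 1. Counts are fixed by largest-remainder rounding.
#' @param range_size_meanlog,range_size_sdlog Parameters of the truncated
#'   discrete lognormal occupied-cell-count distribution (many narrow
#'   species, few wide ones).
#' @param narrow_cutoff Species with target range <= this many cells are
#'   "narrow" and placed inside a hotspot cluster disk.
#' @param n_hotspot_clusters Number of planted cluster disks (0 disables
#'   clustering).
#' @param cluster_radius Cluster disk radius, km.
#' @param n_nnr,n_pnr Number of national / provincial reserve rectangles.
#' @param reserve_coverage Target total reserve area as a fraction of the
#'   extent area (must be <= 1).
#' @param n_env_layers Number of environmental layers (>= 2).
#' @param env_corr Target pairwise correlation between layers, in
#'   \[-1, 1\].
#' @param loss_fractions Per-species planted fraction of current-range
#'   cells lost in the future scenario, in \[0, 1\]; a scalar is recycled;
#'   `NULL` draws each from U(0, 0.7) under the seed.
#' @param gain_fractions Per-species planted expansion fraction (new
#'   above-threshold cells as a fraction of current range), >= 0; `NULL`
#'   draws from U(0, 0.8).
#' @param n_low_auc Number of species planted with AUC below 0.7.
#' @param records_per_cell_mean Mean extra records per occupied cell
#'   (records per cell are 1 + Poisson).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_species = 458L,
                             extent = c(0, 0, 3200, 3200),
                             cell_size = 50,
                             frac_endemic = 232 / 458,
                             category_fractions = c(CR = 66, EN = 102, VU = 96,
                                                    NT = 56, CC = 138) / 458,
                             range_size_meanlog = log(8),
                             range_size_sdlog = 1.3,
                             narrow_cutoff = 3L,
                             n_hotspot_clusters = 3L,
                             cluster_radius = 150,
                             n_nnr = 46L,
                             n_pnr = 80L,
                             reserve_coverage = 0.18,
                             n_env_layers = 20L,
                             env_corr = 0.5,
                             loss_fractions = NULL,
                             gain_fractions = NULL,
                             n_low_auc = 1L,
                             records_per_cell_mean = 1) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$category_fractions) - 1) > 1e-9)
    abort("category_fractions must sum to 1")
  if (!setequal(names(cfg$category_fractions), c("CR", "EN", "VU", "NT", "CC")))
    abort("category_fractions must name CR, EN, VU, NT, CC")
  if (cfg$frac_endemic < 0 || cfg$frac_endemic > 1)
    abort("frac_endemic must lie in [0, 1]")
  if (cfg$cell_size <= 0) abort("cell_size must be positive")
  if (cfg$extent[3] <= cfg$extent[1] || cfg$extent[4] <= cfg$extent[2])
    abort("extent is empty")
  if (cfg$reserve_coverage > 1 || cfg$reserve_coverage < 0)
    abort("reserve_coverage must lie in [0, 1]")
  if (abs(cfg$env_corr) > 1) abort("|env_corr| must not exceed 1")
  if (!is.null(cfg$loss_fractions) &&
      any(cfg$loss_fractions < 0 | cfg$loss_fractions > 1))
    abort("loss_fractions must lie in [0, 1]")
  if (!is.null(cfg$gain_fractions) && any(cfg$gain_fractions < 0))
    abort("gain_fractions must be non-negative")
  if (cfg$n_species < 1) abort("n_species must be at least 1")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d species, %g-km cells over [%g,%g]x[%g,%g], seed %d\n",
              x$n_species, x$cell_size, x$extent[1], x$extent[3],
              x$extent[2], x$extent[4], x$seed))
  invisible(x)
}

species_ids <- function(n) sprintf("sp%04d", seq_len(n))

#' Generate a synthetic species checklist
#'
#' Category counts are fixed from `category_fractions` by largest-
#' remainder rounding (so the paper-style composition 264 + 56 + 138 over
#' 458 species is reproduced exactly) and shuffled over species; endemic
#' flags are independent Bernoulli(`frac_endemic`) draws.
#'
#' @param cfg A [synthetic_config()].
#' @return A data.frame with columns `species_id`, `name`, `endemic`,
#'   `category`.
#' @export
generate_checklist <- function(cfg) {
  validate_config(cfg)
  withr::with_seed(cfg$seed + 1L, {
    counts <- largest_remainder(cfg$n_species, cfg$category_fractions)
    category <- sample(rep(names(counts), counts))
    endemic <- stats::runif(cfg$n_species) < cfg$frac_endemic
  })
  data.frame(species_id = species_ids(cfg$n_species),
             name = paste("Species", seq_len(cfg$n_species)),
             endemic = endemic,
             category = factor(category, levels = c("CR", "EN", "VU", "NT", "CC")))
}

#' Generate synthetic occurrence records
#'
#' Each species receives a target occupied-cell count from a truncated
#' discrete lognormal (minimum one cell). Narrow-range species (target <=
#' `narrow_cutoff`) have their cells drawn from one of the planted hotspot
#' cluster disks; wide-ranging species are scattered uniformly. Every
#' occupied cell receives at least one record placed uniformly inside the
#' cell, so the presence matrix rebuilt from the records reproduces the
#' chosen cells exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param checklist Checklist from [generate_checklist()].
#' @return A data.frame with columns `species_id`, `x`, `y` and attributes
#'   `grid` (the [grid_spec()]), `targets` (per-species target cell
#'   counts), `narrow_species` (ids placed in clusters), `cluster_cells`
#'   (list per cluster of the cells actually occupied by its narrow
#'   species).
#' @export
generate_occurrences <- function(cfg, checklist) {
  validate_config(cfg)
  grid <- build_grid(cfg$extent, cfg$cell_size)
  nc <- n_cells(grid)
  centers <- cell_centers(grid)
  n <- nrow(checklist)
  withr::with_seed(cfg$seed + 2L, {
    targets <- pmin(pmax(1L, as.integer(round(stats::rlnorm(
      n, cfg$range_size_meanlog, cfg$range_size_sdlog)))), nc)
    narrow <- targets <= cfg$narrow_cutoff & cfg$n_hotspot_clusters > 0
    pools <- list()
    if (cfg$n_hotspot_clusters > 0) {
      r <- cfg$cluster_radius
      lo <- cfg$extent[1:2] + r
      hi <- cfg$extent[3:4] - r
      if (any(hi < lo))
        abort("extent too small to place clusters of radius %g", r)
      for (k in seq_len(cfg$n_hotspot_clusters)) {
        cx <- stats::runif(1, lo[1], hi[1])
        cy <- stats::runif(1, lo[2], hi[2])
        pool <- centers$cell[(centers$x - cx)^2 + (centers$y - cy)^2 <= r^2]
        if (length(pool) == 0)
          abort("cluster radius %g too small for cell size %g", r, cfg$cell_size)
        pools[[k]] <- pool
      }
    }
    cluster_of <- integer(n)
    cluster_of[narrow] <- 1L + (seq_len(sum(narrow)) - 1L) %% max(1L, cfg$n_hotspot_clusters)
    rows <- vector("list", n)
    for (s in seq_len(n)) {
      pool <- if (narrow[s]) pools[[cluster_of[s]]] else centers$cell
      cells <- pool[sample.int(length(pool), min(targets[s], length(pool)))]
      b <- cell_bounds(grid, cells)
      nrec <- 1L + stats::rpois(length(cells), cfg$records_per_cell_mean - 1)
      idx <- rep(seq_along(cells), nrec)
      rows[[s]] <- data.frame(
        species_id = checklist$species_id[s],
        x = stats::runif(length(idx), b[idx, "xmin"], b[idx, "xmax"]),
        y = stats::runif(length(idx), b[idx, "ymin"], b[idx, "ymax"]))
    }
  })
  occ <- do.call(rbind, rows)
  rownames(occ) <- NULL
  ids <- as.character(checklist$species_id)
  cluster_cells <- lapply(seq_along(pools), function(k) {
    sp <- ids[narrow & cluster_of == k]
    sub <- occ[occ$species_id %in% sp, , drop = FALSE]
    sort(unique(locate(sub$x, sub$y, grid)))
  })
  structure(occ, grid = grid,
            targets = stats::setNames(targets, ids),
            narrow_species = ids[narrow],
            cluster_cells = cluster_cells)
}

#' Generate a synthetic two-tier reserve layer
#'
#' Draws `n_nnr + n_pnr` axis-aligned rectangles with jittered areas that
#' sum exactly to `reserve_coverage` times the extent area (rectangles may
#' overlap, so union coverage can be slightly lower), placed uniformly
#' inside the extent.
#'
#' @param cfg A [synthetic_config()].
#' @return A [reserve_layer()].
#' @export
generate_reserves <- function(cfg) {
  validate_config(cfg)
  n <- cfg$n_nnr + cfg$n_pnr
  if (n == 0) return(reserve_layer(list(), character(0)))
  ext <- cfg$extent
  A <- (ext[3] - ext[1]) * (ext[4] - ext[2])
  withr::with_seed(cfg$seed + 3L, {
    a <- stats::runif(n, 0.7, 1.3)
    a <- a / sum(a) * cfg$reserve_coverage * A
    aspect <- stats::runif(n, 0.5, 2)
    w <- pmin(sqrt(a * aspect), ext[3] - ext[1])
    h <- pmin(a / w, ext[4] - ext[2])
    x0 <- stats::runif(n, ext[1], ext[3] - w)
    y0 <- stats::runif(n, ext[2], ext[4] - h)
  })
  polys <- lapply(seq_len(n), function(k)
    rect_poly(x0[k], y0[k], x0[k] + w[k], y0[k] + h[k]))
  tier <- rep(c("NNR", "PNR"), c(cfg$n_nnr, cfg$n_pnr))
  id <- c(sprintf("nnr%03d", seq_len(cfg$n_nnr)),
          sprintf("pnr%03d", seq_len(cfg$n_pnr)))
  reserve_layer(polys, tier, id)
}

#' Generate current and future habitat-suitability stacks
#'
#' Current suitability is ~0.8 on each species' occupied cells and ~0.2
#' elsewhere, with jitter bounded away from the 0.6 occurrence threshold
#' so binarization is unambiguous. The future stack moves exactly
#' `round(loss_fraction * range size)` current-range cells below the
#' threshold and raises `round(gain_fraction * range size)` new cells
#' above it, so the generator's loss fraction is recoverable from the
#' stacks to within half a cell. An AUC table assigns each species a
#' model AUC, with `n_low_auc` species planted below 0.7.
#'
#' @param cfg A [synthetic_config()].
#' @param pm Presence matrix of the generated occurrences (defines each
#'   species' current range cells).
#' @return A list with elements `current` and `future` (numeric cells x
#'   species matrices), `auc` (data.frame `species_id`, `auc`) and
#'   `planted` (data.frame `species_id`, `loss_fraction`, `gain_fraction`,
#'   `a_cur`, `n_lost`, `n_gained`).
#' @export
generate_suitability <- function(cfg, pm) {
  validate_config(cfg)
  nc <- nrow(pm)
  sp <- colnames(pm)
  n <- length(sp)
  loss <- cfg$loss_fractions
  gain <- cfg$gain_fractions
  if (!is.null(loss)) loss <- rep_len(loss, n)
  if (!is.null(gain)) gain <- rep_len(gain, n)
  withr::with_seed(cfg$seed + 4L, {
    if (is.null(loss)) loss <- stats::runif(n, 0, 0.7)
    if (is.null(gain)) gain <- stats::runif(n, 0, 0.8)
    lo_draw <- function(k) 0.2 + stats::runif(k, -0.15, 0.15)
    hi_draw <- function(k) 0.8 + stats::runif(k, -0.15, 0.15)
    cur <- matrix(lo_draw(nc * n), nc, n, dimnames = list(NULL, sp))
    fut <- NULL
    planted <- data.frame(species_id = sp, loss_fraction = loss,
                          gain_fraction = gain, a_cur = 0L,
                          n_lost = 0L, n_gained = 0L)
    for (s in seq_len(n)) {
      range_cells <- which(pm[, s])
      cur[range_cells, s] <- hi_draw(length(range_cells))
    }
    fut <- cur
    for (s in seq_len(n)) {
      range_cells <- which(pm[, s])
      a <- length(range_cells)
      n_lost <- as.integer(round_half_up(loss[s] * a))
      n_gained <- as.integer(round_half_up(gain[s] * a))
      avail <- setdiff(seq_len(nc), range_cells)
      n_gained <- min(n_gained, length(avail))
      if (n_lost > 0) {
        drop <- range_cells[sample.int(a, n_lost)]
        fut[drop, s] <- lo_draw(n_lost)
      }
      if (n_gained > 0) {
        add <- avail[sample.int(length(avail), n_gained)]
        fut[add, s] <- hi_draw(n_gained)
      }
      planted$a_cur[s] <- a
      planted$n_lost[s] <- n_lost
      planted$n_gained[s] <- n_gained
    }
    auc <- stats::runif(n, 0.75, 0.99)
    if (cfg$n_low_auc > 0) {
      low <- sample.int(n, min(cfg$n_low_auc, n))
      auc[low] <- stats::runif(length(low), 0.55, 0.69)
    }
  })
  attr(cur, "scenario") <- "current"
  attr(fut, "scenario") <- "future"
  list(current = cur, future = fut,
       auc = data.frame(species_id = sp, auc = auc),
       planted = planted)
}

#' Generate correlated environmental layers
#'
#' Cell values are drawn from a multivariate normal with unit variances
#' and constant pairwise correlation `env_corr` (via the Cholesky factor
#' of the equicorrelation matrix).
#'
#' @param cfg A [synthetic_config()] with `n_env_layers >= 2`.
#' @param grid A [grid_spec()].
#' @return A numeric matrix, cells x layers, with columns `env01`, ...
#' @export
generate_env_layers <- function(cfg, grid) {
  validate_config(cfg)
  k <- cfg$n_env_layers
  if (k < 2) abort("n_env_layers must be at least 2")
  rho <- cfg$env_corr
  if (rho <= -1 / (k - 1))
    abort("env_corr %g is not a valid equicorrelation for %d layers", rho, k)
  R <- matrix(rho, k, k); diag(R) <- 1
  # symmetric square root via eigendecomposition (handles |rho| = 1, where
  # the equicorrelation matrix is singular and Cholesky fails)
  eig <- eigen(R, symmetric = TRUE)
  sqrtR <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  nc <- n_cells(grid)
  withr::with_seed(cfg$seed + 5L, {
    Z <- matrix(stats::rnorm(nc * k), nc, k)
  })
  E <- Z %*% sqrtR
  colnames(E) <- sprintf("env%02d", seq_len(k))
  E
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator in order and assembles the objects downstream
#' stages consume.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `cfg`, `grid`, `checklist`, `occurrences`,
#'   `pm` (presence matrix over the checklist species), `reserves`,
#'   `suitability` (see [generate_suitability()]) and `env`.
#' @export
generate_dataset <- function(cfg) {
  checklist <- generate_checklist(cfg)
  occ <- generate_occurrences(cfg, checklist)
  grid <- attr(occ, "grid")
  pm <- build_presence(occ, grid, species = as.character(checklist$species_id))
  list(cfg = cfg, grid = grid, checklist = checklist, occurrences = occ,
       pm = pm, reserves = generate_reserves(cfg),
       suitability = generate_suitability(cfg, pm),
       env = generate_env_layers(cfg, grid))
}
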