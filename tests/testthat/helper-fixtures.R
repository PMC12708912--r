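# Shared fixtures and independent oracles, built in code at test time.

# Small, fast synthetic configuration for generic pipeline tests.
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_species = 60, extent = c(0, 0, 500, 500),
         cell_size = 50, n_nnr = 3, n_pnr = 5,
         n_hotspot_clusters = 1, cluster_radius = 100,
         n_env_layers = 4),
    list(...))
  do.call(synthetic_config, args)
}

# Configuration for the planted narrow-endemic cluster recovery tests: one
# cluster disk holding ~22 cells (just above the nominal top-5% count of a
# ~400-cell occupied base) packed with ~100 narrow-range species over a
# diffuse wide-ranging background.
cluster_cfg <- function(seed) {
  synthetic_config(seed = seed, n_species = 200, extent = c(0, 0, 1000, 1000),
                   cell_size = 50, range_size_meanlog = log(4),
                   range_size_sdlog = 1.3, narrow_cutoff = 4,
                   n_hotspot_clusters = 1, cluster_radius = 135,
                   n_env_layers = 4)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Constructed reporting-convention fixture: a 150 x 1 strip grid whose first
# 140 cells are the hotspot set, with reserve rectangles covering cells
# 1..90 (NNR) and 45..117 (PNR), and a 458-species checklist whose presence
# pattern pins the species-level numerators.
effectiveness_fixture <- function() {
  grid <- build_grid(c(0, 0, 1500, 10), 10)   # 150 x 1 cells
  checklist <- data.frame(
    species_id = sprintf("sp%04d", 1:458),
    endemic = rep(c(TRUE, FALSE), c(232, 226)),
    category = factor(rep(c("CR", "EN", "VU", "NT", "CC"),
                          c(66, 102, 96, 56, 138)),
                      levels = c("CR", "EN", "VU", "NT", "CC")))
  cx <- function(cell) (cell - 0.5) * 10      # cell centre x
  occ <- data.frame(
    species_id = checklist$species_id,
    x = c(rep(cx(120), 325),   # species 1..325 in an unprotected hotspot cell
          rep(cx(1), 121),     # species 326..446 in an NNR-protected cell
          rep(cx(141), 12)),   # species 447..458 outside the hotspot set
    y = 5)
  reserves <- reserve_layer(
    list(rect_poly(0, 0, 900, 10),        # covers cells 1..90
         rect_poly(440, 0, 1170, 10)),    # covers cells 45..117
    tier = c("NNR", "PNR"))
  pm <- build_presence(occ, grid, species = as.character(checklist$species_id))
  list(grid = grid, checklist = checklist, occ = occ, reserves = reserves,
       pm = pm, hotspot_cells = 1:140)
}

# Record-protection fixture reproducing the printed species-level
# protection counts: 42 species fully protected, 13 under 30%, the rest at
# 50%, 10 records each.
record_protection_fixture <- function() {
  ids <- sprintf("sp%04d", 1:458)
  n_prot <- rep(5L, 458)
  n_prot[1:42] <- 10L
  n_prot[43:55] <- 2L
  occ <- do.call(rbind, lapply(1:458, function(s) {
    k <- n_prot[s]
    data.frame(species_id = ids[s],
               x = c(rep(50, k), rep(1200, 10L - k)),
               y = 5)
  }))
  reserves <- reserve_layer(list(rect_poly(0, 0, 100, 10)), tier = "NNR")
  list(occ = occ, reserves = reserves)
}

# Exhaustive minimum set-cover size; independent oracle for the greedy
# complementarity selection on tiny instances.
min_cover_size <- function(m) {
  nc <- nrow(m)
  for (k in seq_len(nc)) {
    for (comb in utils::combn(nc, k, simplify = FALSE)) {
      if (all(colSums(m[comb, , drop = FALSE]) > 0)) return(k)
    }
  }
  stop("no cover exists")
}

# Random tiny presence instance with every species present somewhere.
random_instance <- function(n_cells, n_species, p = 0.35) {
  m <- matrix(stats::runif(n_cells * n_species) < p, n_cells, n_species)
  for (s in which(colSums(m) == 0)) m[sample.int(n_cells, 1), s] <- TRUE
  colnames(m) <- sprintf("s%02d", seq_len(n_species))
  m
}

# Random sparse presence matrix as built by build_presence.
random_pm <- function(n_cells = 40, n_species = 15, p = 0.2) {
  m <- random_instance(n_cells, n_species, p)
  Matrix::Matrix(m, sparse = TRUE,
                 dimnames = list(as.character(seq_len(n_cells)), colnames(m)))
}
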