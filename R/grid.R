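#' Regular analysis grid
#'
#' A `grid_spec` describes a regular rectangular grid in planar coordinates
#' (kilometres). Cell `(i, j)` (column `i`, row `j`, both 0-based) spans the
#' half-open rectangle `[x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s)`,
#' so a point on a shared edge belongs to the cell whose lower/left edge it
#' lies on and no point is assigned twice. Cells are numbered 1..n_cells
#' row-major from the lower-left corner: `cell = j * n_cols + i + 1`.
#'
#' @param x0,y0 Coordinates of the grid origin (lower-left corner), km.
#' @param cell_size Cell side length, km; must be positive.
#' @param n_cols,n_rows Number of columns / rows; must be >= 1.
#' @return An object of class `grid_spec`.
#' @seealso [build_grid()] to derive a grid from an extent.
#' @export
grid_spec <- function(x0, y0, cell_size, n_cols, n_rows) {
  if (cell_size <= 0) abort("cell_size must be positive")
  if (n_cols < 1 || n_rows < 1) abort("grid must have at least one cell")
  structure(
    list(x0 = x0, y0 = y0, cell_size = cell_size,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km (origin %g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$x0, x$y0))
  invisible(x)
}

#' Build a grid covering a rectangular extent
#'
#' The number of columns and rows is the ceiling of extent width and height
#' over the cell size, so the grid always covers the full extent (the last
#' column/row may overhang).
#'
#' @param extent Numeric vector `c(xmin, ymin, xmax, ymax)` in km.
#' @param cell_size Cell side length in km.
#' @return A [grid_spec()].
#' @examples
#' build_grid(c(0, 0, 101, 100), 50)  # 3 x 2 cells
#' @export
build_grid <- function(extent, cell_size) {
  extent <- as.numeric(extent)
  if (length(extent) != 4) abort("extent must be c(xmin, ymin, xmax, ymax)")
  w <- extent[3] - extent[1]
  h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) abort("extent is empty")
  if (cell_size <= 0) abort("cell_size must be positive")
  grid_spec(extent[1], extent[2], cell_size,
            ceiling(w / cell_size), ceiling(h / cell_size))
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Locate points on the grid
#'
#' Maps planar points to 1-based cell ids using the half-open cell
#' convention (`floor((coord - origin) / cell_size)`). Points outside the
#' grid extent are mapped to `NA` — being outside is a value, not an error.
#'
#' @param x,y Point coordinates (km), recycled to common length.
#' @param grid A [grid_spec()].
#' @return Integer vector of cell ids, `NA` for points outside the grid.
#' @export
locate <- function(x, y, grid) {
  i <- floor((x - grid$x0) / grid$cell_size)
  j <- floor((y - grid$y0) / grid$cell_size)
  out <- i < 0 | i >= grid$n_cols | j < 0 | j >= grid$n_rows |
    !is.finite(i) | !is.finite(j)
  cell <- as.integer(j * grid$n_cols + i + 1L)
  cell[out] <- NA_integer_
  cell
}

#' Cell centre coordinates
#' @param grid A [grid_spec()].
#' @param cells Cell ids (default all cells).
#' @return A data.frame with columns `cell`, `x`, `y`.
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  i <- (cells - 1L) %% grid$n_cols
  j <- (cells - 1L) %/% grid$n_cols
  data.frame(cell = cells,
             x = grid$x0 + (i + 0.5) * grid$cell_size,
             y = grid$y0 + (j + 0.5) * grid$cell_size)
}

#' Cell bounding rectangles
#' @param grid A [grid_spec()].
#' @param cells Cell ids (default all cells).
#' @return A matrix with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
cell_bounds <- function(grid, cells = seq_len(n_cells(grid))) {
  i <- (cells - 1L) %% grid$n_cols
  j <- (cells - 1L) %/% grid$n_cols
  s <- grid$cell_size
  cbind(xmin = grid$x0 + i * s, ymin = grid$y0 + j * s,
        xmax = grid$x0 + (i + 1) * s, ymax = grid$y0 + (j + 1) * s)
}

#' Build the cells-by-species presence matrix
#'
#' Assigns every occurrence record to a grid cell and records presence
#' (not abundance): entry `[c, s]` is `TRUE` iff at least one record of
#' species `s` falls in cell `c`. Records outside the grid are dropped with
#' a message stating how many. Rows are cells 1..n_cells in grid order;
#' columns are `species` if supplied (e.g. the checklist ids, so that
#' species with no in-grid record keep an all-`FALSE` column), otherwise
#' the sorted unique species ids observed.
#'
#' @param occ Occurrence data.frame with columns `species_id`, `x`, `y`
#'   (extra columns are ignored).
#' @param grid A [grid_spec()].
#' @param species Optional character vector fixing the column universe and
#'   order.
#' @return A sparse logical matrix (cells x species) from the Matrix
#'   package, with `dimnames` cell ids and species ids.
#' @export
build_presence <- function(occ, grid, species = NULL) {
  if (!all(c("species_id", "x", "y") %in% names(occ)))
    abort("occ must have columns species_id, x, y")
  if (is.null(species)) species <- sort(unique(as.character(occ$species_id)))
  nc <- n_cells(grid)
  if (nrow(occ) == 0) {
    warning("empty occurrence set: presence matrix is all-FALSE")
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = logical(),
                                dims = c(nc, length(species)),
                                dimnames = list(as.character(seq_len(nc)), species)))
  }
  cell <- locate(occ$x, occ$y, grid)
  n_out <- sum(is.na(cell))
  if (n_out > 0)
    message(sprintf("build_presence: dropped %d record(s) outside the grid", n_out))
  keep <- !is.na(cell)
  sp <- match(as.character(occ$species_id)[keep], species)
  if (anyNA(sp)) abort("occurrence species_id not in the species universe")
  Matrix::sparseMatrix(i = cell[keep], j = sp, x = TRUE,
                       dims = c(nc, length(species)), use.last.ij = TRUE,
                       dimnames = list(as.character(seq_len(nc)), species))
}

#' Per-species range sizes (occupied cell counts)
#'
#' The range size of a species is the number of grid cells it occupies —
#' the denominator of the weighted-endemism weight 1/range.
#'
#' @param pm Presence matrix from [build_presence()].
#' @return Named integer vector of occupied-cell counts per species.
#' @export
range_sizes <- function(pm) {
  stats::setNames(as.integer(Matrix::colSums(pm)), colnames(pm))
}

#' Cells occupied by at least one species
#'
#' The occupied-cell set is the base over which hotspot percentile
#' thresholds are taken.
#'
#' @param pm Presence matrix from [build_presence()].
#' @return Integer vector of occupied cell ids.
#' @export
occupied_cells <- function(pm) {
  unname(which(Matrix::rowSums(pm) > 0))
}
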