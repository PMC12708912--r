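#' Read occurrence records from CSV
#'
#' Expects columns `species_id`, `x`, `y`; extra columns are tolerated and
#' ignored. Rows with a missing id or non-finite coordinates are dropped
#' with a message.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `species_id`, `x`, `y`.
#' @export
read_occurrences_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "x", "y")
  if (!all(need %in% names(d)))
    abort("occurrence CSV must have columns species_id, x, y")
  d <- d[, need]
  bad <- is.na(d$species_id) | !is.finite(d$x) | !is.finite(d$y)
  if (any(bad)) {
    message(sprintf("read_occurrences_csv: dropped %d invalid record(s)", sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Write occurrence records to CSV
#' @param occ Occurrence data.frame (`species_id`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ[, c("species_id", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read a species checklist from CSV
#'
#' Expects columns `species_id`, `endemic` (logical or 0/1) and `category`
#' (CR/EN/VU/NT/CC); a `name` column is optional.
#'
#' @param path CSV file path.
#' @return A checklist data.frame.
#' @export
read_checklist_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "endemic", "category")
  if (!all(need %in% names(d)))
    abort("checklist CSV must have columns species_id, endemic, category")
  if (!all(d$category %in% c("CR", "EN", "VU", "NT", "CC")))
    abort("unknown threat category in checklist")
  d$endemic <- as.logical(d$endemic)
  d$category <- factor(d$category, levels = c("CR", "EN", "VU", "NT", "CC"))
  d
}

#' Write a species checklist to CSV
#' @param checklist Checklist data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checklist_csv <- function(checklist, path) {
  utils::write.csv(checklist, path, row.names = FALSE)
  invisible(path)
}

#' Export a presence matrix as sparse triplets
#'
#' Writes one `(cell_id, species_id)` row per occupied cell-species pair.
#'
#' @param pm Presence matrix from [build_presence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_presence_csv <- function(pm, path) {
  tr <- Matrix::which(pm, arr.ind = TRUE)
  d <- data.frame(cell_id = as.integer(tr[, 1]),
                  species_id = colnames(pm)[tr[, 2]])
  d <- d[order(d$cell_id, d$species_id), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a surface as an ESRI ASCII grid
#'
#' Rows are written north to south as the format requires.
#'
#' @param values Numeric surface, one value per grid cell (grid order).
#' @param grid A [grid_spec()].
#' @param path Output `.asc` path.
#' @param nodata NODATA value written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, grid, path, nodata = -9999) {
  m <- matrix(as.numeric(values), grid$n_rows, grid$n_cols, byrow = TRUE)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$x0),
               sprintf("yllcorner %.10g", grid$y0),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  for (j in grid$n_rows:1)
    writeLines(paste(format(m[j, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return A list with `values` (numeric surface in grid order, `NA` for
#'   NODATA) and `grid` (a [grid_spec()]).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$ncols, hdr$nrows)
  rows <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)           # first row = northernmost
  m[m == hdr$nodata_value] <- NA
  values <- as.numeric(t(m[grid$n_rows:1, , drop = FALSE]))
  list(values = values, grid = grid)
}

#' Write a suitability stack as long-form CSV
#'
#' One row per (species, cell) with columns `species_id`, `cell_id`,
#' `scenario`, `suitability`.
#'
#' @param stack Numeric cells x species matrix.
#' @param scenario Scenario label (e.g. `"current"`, `"RCP2.6"`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_suitability_csv <- function(stack, scenario, path) {
  d <- data.frame(species_id = rep(colnames(stack), each = nrow(stack)),
                  cell_id = rep(seq_len(nrow(stack)), ncol(stack)),
                  scenario = scenario,
                  suitability = as.numeric(stack))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-form suitability CSV into a stack
#'
#' @param path CSV with columns `species_id`, `cell_id`, `scenario`,
#'   `suitability`.
#' @param scenario Scenario label to extract.
#' @param n_cells Number of grid cells.
#' @return A numeric cells x species matrix.
#' @export
read_suitability_csv <- function(path, scenario, n_cells) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$scenario == scenario, , drop = FALSE]
  sp <- sort(unique(d$species_id))
  m <- matrix(0, n_cells, length(sp), dimnames = list(NULL, sp))
  m[cbind(d$cell_id, match(d$species_id, sp))] <- d$suitability
  attr(m, "scenario") <- scenario
  m
}

#' Write / read a synthetic configuration as YAML
#'
#' @param cfg A [synthetic_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [synthetic_config()] (read).
#' @export
write_config_yaml <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$category_fractions <- as.list(vals$category_fractions)  # keep names
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$category_fractions))
    vals$category_fractions <- unlist(vals$category_fractions)
  do.call(synthetic_config, vals)
}
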