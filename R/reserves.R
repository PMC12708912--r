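#' Nature-reserve polygon layer
#'
#' A `reserve_layer` holds simple polygons (closed coordinate rings in
#' planar km) each tagged with a reserve tier: `"NNR"` (national) or
#' `"PNR"` (provincial). Polygons with fewer than three distinct vertices
#' or zero area are rejected with a warning naming the offending id.
#'
#' @param polygons List of 2-column coordinate matrices (x, y). Rings may
#'   be open (first point repeated or not); they are stored closed.
#' @param tier Character vector of tiers, one per polygon, each `"NNR"` or
#'   `"PNR"`.
#' @param id Optional polygon ids (default `res1`, `res2`, ...).
#' @return An object of class `reserve_layer`: a list with elements
#'   `polygons`, `tier`, `id`.
#' @export
reserve_layer <- function(polygons, tier, id = NULL) {
  if (length(polygons) != length(tier))
    abort("one tier per polygon required")
  if (!all(tier %in% c("NNR", "PNR"))) abort("tier must be NNR or PNR")
  if (is.null(id)) id <- paste0("res", seq_along(polygons))
  keep <- rep(TRUE, length(polygons))
  polygons <- lapply(polygons, close_ring)
  for (k in seq_along(polygons)) {
    p <- polygons[[k]]
    if (nrow(p) < 4 || abs(poly_area(p)) < 1e-12) {
      warning(sprintf("rejecting degenerate reserve polygon '%s'", id[k]))
      keep[k] <- FALSE
    }
  }
  structure(list(polygons = polygons[keep], tier = tier[keep], id = id[keep]),
            class = "reserve_layer")
}

#' @export
print.reserve_layer <- function(x, ...) {
  cat(sprintf("reserve_layer: %d polygons (%d NNR, %d PNR)\n",
              length(x$polygons), sum(x$tier == "NNR"), sum(x$tier == "PNR")))
  invisible(x)
}

#' Axis-aligned rectangle as a polygon ring
#' @param xmin,ymin,xmax,ymax Rectangle bounds (km).
#' @return A closed 2-column coordinate matrix.
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymax * 0 + ymin))
}

close_ring <- function(p) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  if (nrow(p) < 1) return(p)
  if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

# signed shoelace area of a closed ring
poly_area <- function(p) {
  n <- nrow(p)
  if (n < 4) return(0)
  x <- p[, 1]; y <- p[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# Sutherland-Hodgman clip of a polygon ring against an axis-aligned
# rectangle c(xmin, ymin, xmax, ymax); returns the clipped ring (possibly
# with 0 rows)
clip_poly_rect <- function(p, rect) {
  pts <- p[-nrow(p), , drop = FALSE]   # open ring
  halfplanes <- list(
    function(q) q[1] >= rect[1], function(q) q[1] <= rect[3],
    function(q) q[2] >= rect[2], function(q) q[2] <= rect[4])
  intersec <- function(a, b, k) {
    # intersection of segment a-b with boundary line of halfplane k
    if (k <= 2) {                       # vertical line x = c
      cx <- rect[ifelse(k == 1, 1, 3)]
      t <- (cx - a[1]) / (b[1] - a[1])
      c(cx, a[2] + t * (b[2] - a[2]))
    } else {                            # horizontal line y = c
      cy <- rect[ifelse(k == 3, 2, 4)]
      t <- (cy - a[2]) / (b[2] - a[2])
      c(a[1] + t * (b[1] - a[1]), cy)
    }
  }
  for (k in seq_along(halfplanes)) {
    inside <- halfplanes[[k]]
    if (nrow(pts) == 0) break
    out <- list()
    n <- nrow(pts)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1 else i + 1, ]
      ain <- inside(a); bin <- inside(b)
      if (ain) out[[length(out) + 1L]] <- a
      if (xor(ain, bin)) out[[length(out) + 1L]] <- intersec(a, b, k)
    }
    pts <- if (length(out)) do.call(rbind, out) else
      matrix(numeric(0), ncol = 2)
  }
  if (nrow(pts) > 0) close_ring(pts) else pts
}

# area of polygon-rectangle intersection
poly_rect_area <- function(p, rect) {
  bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  if (bb[3] <= rect[1] || bb[1] >= rect[3] ||
      bb[4] <= rect[2] || bb[2] >= rect[4]) return(0)
  cl <- clip_poly_rect(p, rect)
  if (nrow(cl) < 4) return(0)
  abs(poly_area(cl))
}

#' Test whether points lie inside (or on the boundary of) a polygon
#'
#' Even-odd ray casting; points within `tol` of a polygon edge count as
#' inside, so records lying exactly on a reserve boundary are treated as
#' protected.
#'
#' @param x,y Point coordinates.
#' @param poly Closed coordinate ring.
#' @param tol Boundary tolerance in km (default 1e-9).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px) - 1L            # closed ring
  vapply(seq_along(x), function(q) {
    xq <- x[q]; yq <- y[q]
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- px[i]; y1 <- py[i]; x2 <- px[i + 1]; y2 <- py[i + 1]
      # boundary check: distance from point to segment
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      t <- if (L2 == 0) 0 else max(0, min(1, ((xq - x1) * dx + (yq - y1) * dy) / L2))
      d2 <- (xq - (x1 + t * dx))^2 + (yq - (y1 + t * dy))^2
      if (d2 <= tol * tol) return(TRUE)
      if ((y1 > yq) != (y2 > yq)) {
        xint <- x1 + (yq - y1) / (y2 - y1) * dx
        if (xq < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Write a reserve layer as GeoJSON
#'
#' Emits a `FeatureCollection` of `Polygon` features with properties `id`
#' and `tier`.
#'
#' @param reserves A [reserve_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reserves_geojson <- function(reserves, path) {
  features <- lapply(seq_along(reserves$polygons), function(k) {
    p <- reserves$polygons[[k]]
    list(type = "Feature",
         properties = list(id = reserves$id[k], tier = reserves$tier[k]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(i) unname(p[i, ])))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a reserve layer from GeoJSON
#'
#' Reads `Polygon` features (outer ring only) with a `tier` property.
#'
#' @param path GeoJSON file path.
#' @return A [reserve_layer()].
#' @export
read_reserves_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) return(reserve_layer(list(), character(0)))
  polys <- list(); tier <- character(0); id <- character(0)
  for (ft in fc$features) {
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
    polys[[length(polys) + 1L]] <- m
    tier <- c(tier, ft$properties$tier)
    id <- c(id, ft$properties$id %||% paste0("res", length(polys)))
  }
  reserve_layer(polys, tier, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
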