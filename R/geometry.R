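#' Planar polygon utilities
#'
#' Geometries are lists of rings; a ring is an N x 2 numeric matrix of
#' projected coordinates in metres (vertices in order, not closed). A geometry
#' with several rings represents a multipolygon of disjoint parts; holes are
#' not supported. All overlay arithmetic (areas, intersections, rasterization)
#' is exact for simple rings: general pairs are triangulated by ear clipping
#' and intersected triangle-by-triangle against a convex clipper.
#'
#' @name sapm-geometry
#' @keywords internal
NULL

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("a ring must be an N x 2 coordinate matrix")
  # drop an explicit closing vertex and consecutive duplicates
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(m))) > 0)
  m[keep, , drop = FALSE]
}

#' Geometric area of a geometry in square kilometres
#' @param geom list of rings (N x 2 matrices, metres)
#' @return numeric scalar, km^2
#' @export
geom_area_km2 <- function(geom) {
  sum(vapply(geom, cpp_ring_area, numeric(1))) / 1e6
}

geom_bbox <- function(geom) {
  xy <- do.call(rbind, geom)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

#' Validate a geometry
#'
#' Checks each ring has at least three distinct vertices, positive area and no
#' self-intersection. Returns the normalised geometry or raises an error
#' naming the offending ring.
#' @param geom list of rings
#' @param id label used in error messages
#' @export
validate_geom <- function(geom, id = "geometry") {
  if (!is.list(geom) || length(geom) == 0L) stop(id, ": empty geometry")
  geom <- lapply(geom, as_ring)
  for (k in seq_along(geom)) {
    r <- geom[[k]]
    if (nrow(r) < 3L) stop(id, ": ring ", k, " has fewer than 3 distinct vertices")
    if (!cpp_ring_simple(r)) stop(id, ": ring ", k, " is self-intersecting")
    if (cpp_ring_area(r) <= 0) stop(id, ": ring ", k, " has zero area")
  }
  geom
}

# Ear-clipping triangulation of one simple ring; returns a list of 3 x 2
# matrices. O(n^2), fine at survey-polygon vertex counts.
triangulate_ring <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 3L) return(list())
  x <- ring[, 1]; y <- ring[, 2]
  # force counter-clockwise
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) { x <- rev(x); y <- rev(y) }
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  nt <- 0L
  guard <- 0L
  while (length(idx) > 3L && guard < n * n) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1L) m else k - 1L]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1L else k + 1L]
      cr <- (x[i1] - x[i0]) * (y[i2] - y[i0]) - (y[i1] - y[i0]) * (x[i2] - x[i0])
      if (cr <= 0) next # reflex or degenerate corner
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others) > 0L) {
        tri <- rbind(c(x[i0], y[i0]), c(x[i1], y[i1]), c(x[i2], y[i2]))
        inside <- cpp_points_in_ring(x[others], y[others], tri)
        if (any(inside)) next
      }
      nt <- nt + 1L
      tris[[nt]] <- rbind(c(x[i0], y[i0]), c(x[i1], y[i1]), c(x[i2], y[i2]))
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("triangulation failed: ring is not simple")
  }
  if (length(idx) == 3L) {
    nt <- nt + 1L
    tris[[nt]] <- cbind(x[idx], y[idx])
  }
  tris[seq_len(nt)]
}

# Exact area of intersection of two simple rings (triangulate one, clip each
# triangle - convex - against triangles of the other).
ring_intersection_area <- function(ra, rb) {
  ta <- triangulate_ring(ra)
  tb <- triangulate_ring(rb)
  tot <- 0
  for (a in ta) for (b in tb) tot <- tot + cpp_convex_clip_area(a, b)
  tot
}

#' Exact intersection area of two geometries, in square kilometres
#'
#' Parts within each geometry are assumed disjoint (the multipolygon
#' convention); the result is then exact for simple rings.
#' @param ga,gb geometries (lists of rings)
#' @export
geom_intersection_km2 <- function(ga, gb) {
  tot <- 0
  for (ra in ga) for (rb in gb) tot <- tot + ring_intersection_area(ra, rb)
  tot / 1e6
}

#' Jaccard index of two geometries
#'
#' |A intersect B| / |A union B|, exact when each geometry is a single simple
#' polygon (union by inclusion-exclusion). Multi-part geometries are compared
#' on a fine grid (side `cell` metres) instead, since an exact polygon-set
#' union is not attempted.
#' @param ga,gb geometries
#' @param cell grid side in metres for the multi-part fallback
#' @export
geom_jaccard <- function(ga, gb, cell = 250) {
  if (length(ga) == 1L && length(gb) == 1L) {
    ia <- geom_intersection_km2(ga, gb)
    ua <- geom_area_km2(ga) + geom_area_km2(gb) - ia
    if (ua <= 0) return(0)
    return(ia / ua)
  }
  bb <- geom_bbox(c(ga, gb))
  gx0 <- floor(bb["xmin"] / cell) * cell
  gy0 <- floor(bb["ymin"] / cell) * cell
  nx <- max(1L, ceiling((bb["xmax"] - gx0) / cell))
  ny <- max(1L, ceiling((bb["ymax"] - gy0) / cell))
  cov <- function(g) {
    m <- matrix(0, ny, nx)
    for (r in g) m <- m + cpp_rasterize_ring(r, gx0, gy0, cell, nx, ny, 1L)
    m > 0
  }
  a <- cov(ga); b <- cov(gb)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Are points inside a geometry?
#' @param x,y point coordinates (metres)
#' @param geom geometry
#' @return logical vector
#' @export
geom_contains <- function(x, y, geom) {
  inside <- rep(FALSE, length(x))
  for (r in geom) inside <- inside | cpp_points_in_ring(x, y, as_ring(r))
  inside
}
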