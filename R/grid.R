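#' Equal-area gridding of weighted priority layers
#'
#' Rasters live on an axis-aligned grid in the projected CRS, default 1000 m
#' square cells, origin snapped to the cell lattice; cells are half-open
#' `[x, x+cell) x [y, y+cell)`. Values are SAP km^-2 per cell. Never-touched
#' cells (no-data) are tracked separately from true zeros. The default
#' "exact_area" mode accumulates `density x covered fraction` per cell, so the
#' raster conserves the vector-space total SAP; "cell_center" mimics a plain
#' GIS rasterizer (full density wherever the cell centre falls inside).
#'
#' @name sapm-gridding
NULL

#' Define a grid
#' @param x0,y0 origin (lower-left corner) in metres
#' @param nx,ny number of columns / rows
#' @param cell cell side in metres (default 1000, i.e. 1 km^2 cells)
#' @export
sapm_grid <- function(x0, y0, nx, ny, cell = 1000) {
  stopifnot(cell > 0, nx >= 1, ny >= 1)
  structure(list(x0 = x0, y0 = y0, nx = as.integer(nx), ny = as.integer(ny),
                 cell = cell), class = "sapm_grid")
}

#' Smallest snapped grid covering a set of layers
#' @param layers a `sap_layers` data frame (or anything with a geometry list)
#' @param cell cell side in metres
#' @param snap snap the origin to the cell lattice
#' @export
grid_for_layers <- function(layers, cell = 1000, snap = TRUE) {
  bb <- geom_bbox(do.call(c, layers$geometry))
  x0 <- bb["xmin"]; y0 <- bb["ymin"]
  if (snap) { x0 <- floor(x0 / cell) * cell; y0 <- floor(y0 / cell) * cell }
  sapm_grid(unname(x0), unname(y0),
            nx = ceiling((bb["xmax"] - x0) / cell),
            ny = ceiling((bb["ymax"] - y0) / cell), cell = cell)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

new_raster <- function(grid, values = NULL, touched = NULL, tag = "fleet") {
  if (is.null(values)) values <- matrix(0, grid$ny, grid$nx)
  if (is.null(touched)) touched <- matrix(FALSE, grid$ny, grid$nx)
  structure(list(grid = grid, values = values, touched = touched, tag = tag),
            class = "sapm_raster")
}

#' Total SAP mass of a raster (sum of values x cell area)
#' @param raster a `sapm_raster`
#' @export
raster_total <- function(raster) {
  sum(raster$values) * (raster$grid$cell / 1000)^2
}

#' Rasterize weighted layers
#'
#' @param layers a `sap_layers` data frame
#' @param grid a `sapm_grid`; by default fitted to the layers
#' @param mode "exact_area" (mass-conserving, default) or "cell_center"
#' @param tag label stored on the raster
#' @return a `sapm_raster` of SAP km^-2
#' @export
rasterize_layers <- function(layers, grid = grid_for_layers(layers, cell),
                             mode = c("exact_area", "cell_center"),
                             cell = 1000, tag = "fleet") {
  mode <- match.arg(mode)
  m <- if (mode == "exact_area") 0L else 1L
  r <- new_raster(grid, tag = tag)
  if (nrow(layers) == 0) return(r)
  xmax <- grid$x0 + grid$nx * grid$cell
  ymax <- grid$y0 + grid$ny * grid$cell
  for (i in seq_len(nrow(layers))) {
    bb <- geom_bbox(layers$geometry[[i]])
    if (bb["xmin"] < grid$x0 || bb["ymin"] < grid$y0 ||
        bb["xmax"] > xmax || bb["ymax"] > ymax)
      stop(sprintf(paste0("area %s extends outside the grid; required extent ",
                          "[%.0f, %.0f] x [%.0f, %.0f]"),
                   layers$area_id[i], bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"]))
    d <- layers$weighted_density[i]
    for (ring in layers$geometry[[i]]) {
      frac <- cpp_rasterize_ring(ring, grid$x0, grid$y0, grid$cell,
                                 grid$nx, grid$ny, m)
      r$values <- r$values + d * frac
      r$touched <- r$touched | (frac > 0)
    }
  }
  r
}

#' Cell-wise sum of rasters on an identical grid
#' @param rasters list of `sapm_raster`
#' @param tag label for the result
#' @export
combine_rasters <- function(rasters, tag = NULL) {
  stopifnot(length(rasters) >= 1)
  g <- rasters[[1]]$grid
  for (r in rasters[-1])
    if (!same_grid(g, r$grid))
      stop("rasters are on different grids; no silent resampling is done")
  out <- new_raster(g, tag = if (is.null(tag))
    paste(unique(vapply(rasters, `[[`, "", "tag")), collapse = "+") else tag)
  for (r in rasters) {
    out$values <- out$values + r$values
    out$touched <- out$touched | r$touched
  }
  out
}

#' Raster for a subset of layers (per fishery, combo or port)
#'
#' @param layers a `sap_layers` data frame
#' @param grid grid shared with the fleet map
#' @param fishery,combo,port optional filters (values to keep)
#' @param mode rasterization mode
#' @return a `sapm_raster`; an empty selection warns and returns a zero raster
#' @export
subset_map <- function(layers, grid, fishery = NULL, combo = NULL, port = NULL,
                       mode = "exact_area") {
  keep <- rep(TRUE, nrow(layers))
  if (!is.null(fishery)) keep <- keep & layers$fishery %in% fishery
  if (!is.null(combo)) keep <- keep & layers$combo %in% combo
  if (!is.null(port)) keep <- keep & vapply(strsplit(layers$combo, "|", fixed = TRUE),
                                            `[[`, "", 1L) %in% port
  tag <- paste(c(fishery, combo, port), collapse = "+")
  if (!any(keep)) {
    warning("subset matches no layers; returning an all-zero raster")
    return(new_raster(grid, tag = tag))
  }
  rasterize_layers(layers[keep, , drop = FALSE], grid, mode = mode, tag = tag)
}

#' Relative priority: divide by a group's total SAP
#'
#' With the raster's own total, the result integrates to 1 over the map,
#' making fisheries of different absolute size comparable.
#' @param raster a `sapm_raster`
#' @param total total SAP to normalise by (default the raster's own)
#' @export
relative_priority <- function(raster, total = raster_total(raster)) {
  if (total <= 0) stop("total SAP must be positive")
  raster$values <- raster$values / total
  raster$tag <- paste0(raster$tag, " (relative)")
  raster
}

#' SAP impact of closures on fleet groups
#'
#' For each group, the fraction of its total SAP falling inside the closure
#' polygons, computed vector-exactly (polygon intersection areas). Closure
#' parts are assumed mutually disjoint.
#'
#' @param layers a `sap_layers` data frame
#' @param closure a geometry (list of rings) or a polygon data frame from
#'   [read_polygons()]
#' @param by grouping: "fleet", "fishery", "combo", or "port"
#' @return data frame: group, sap_inside, sap_total, fraction
#' @export
closure_impact <- function(layers, closure, by = "fishery") {
  if (is.data.frame(closure)) closure <- do.call(c, closure$geometry)
  if (length(closure) > 0) closure <- validate_geom(closure, id = "closure")
  grp <- switch(by,
    fleet = rep("fleet", nrow(layers)),
    fishery = layers$fishery,
    combo = layers$combo,
    port = vapply(strsplit(layers$combo, "|", fixed = TRUE), `[[`, "", 1L),
    stop("unknown grouping: ", by))
  inside <- vapply(seq_len(nrow(layers)), function(i) {
    if (length(closure) == 0) return(0)
    layers$weighted_density[i] *
      geom_intersection_km2(layers$geometry[[i]], closure)
  }, numeric(1))
  tot <- layers$weighted_density * layers$area_km2
  res <- data.frame(group = sort(unique(grp)), stringsAsFactors = FALSE)
  res$sap_inside <- as.vector(tapply(inside, grp, sum)[res$group])
  res$sap_total <- as.vector(tapply(tot, grp, sum)[res$group])
  # clamp tiny numerical overshoot at full closure
  res$fraction <- pmin(1, pmax(0, res$sap_inside / res$sap_total))
  res
}

#' Write a raster as an ESRI ASCII grid
#'
#' Text format readable by standard GIS software; never-touched cells are
#' written as the no-data value.
#' @param raster a `sapm_raster`
#' @param path output file (.asc)
#' @param nodata no-data sentinel
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[!raster$touched] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$nx), paste("nrows", g$ny),
               paste("xllcorner", format(g$x0, scientific = FALSE)),
               paste("yllcorner", format(g$y0, scientific = FALSE)),
               paste("cellsize", format(g$cell, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  # ASCII grids run north to south; our rows run south to north
  for (r in rev(seq_len(g$ny)))
    writeLines(paste(format(v[r, ], trim = TRUE, scientific = FALSE,
                            digits = 15), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a `sapm_raster`
#' @param path .asc file
#' @param tag label for the raster
#' @export
read_ascii_grid <- function(path, tag = basename(path)) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  g <- sapm_grid(hdr$xllcorner, hdr$yllcorner, hdr$ncols, hdr$nrows,
                 cell = hdr$cellsize)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[(i + 1L):length(lines)], quiet = TRUE)
  v <- matrix(vals, nrow = g$ny, ncol = g$nx, byrow = TRUE)
  v <- v[rev(seq_len(g$ny)), , drop = FALSE]
  touched <- v != nodata
  v[!touched] <- 0
  new_raster(g, values = v, touched = touched, tag = tag)
}
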