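#' Fit a spatial access priority model
#'
#' Runs the full pipeline: build the port-gear-length combination table from
#' the register, estimate stratum crew E from the interview sample, compute
#' up-scaling weights W = E/S (with donor fallback for unsampled strata),
#' attach weighted SAP densities to the respondents' priority areas, and
#' rasterize fleet and per-fishery maps onto the equal-area grid. The result
#' carries a conservation audit: in exact-area mode the raster total equals
#' the vector total, which equals 100 x the total estimated crew.
#'
#' @param register validated register data frame or CSV path
#' @param responses a `response_set` or GeoJSON path
#' @param scheme category scheme (default the eight-category scheme)
#' @param grid a `sapm_grid`; fitted to the data when NULL
#' @param cell cell side in metres when fitting the grid
#' @param mode rasterization mode, "exact_area" or "cell_center"
#' @param port_coords,coastal_order port location config for donor fallback
#' @param processor_fte optional named vector: shore-processor FTE per
#'   fishery, folded into E before weighting
#' @param landed_value,fishers optional named vectors for landings-value
#'   weighting of the layers
#' @return an object of class `sapm`
#' @examples
#' pop <- generate_population(sapm_scenario(n_vessels = 60, n_ports = 6), seed = 7)
#' smp <- draw_interviews(pop, seed = 7)
#' fit <- sapm(smp$register, smp$responses, port_coords = smp$port_coords)
#' fit
#' coef(fit)[1:3]
#' @export
sapm <- function(register, responses, scheme = default_category_scheme(),
                 grid = NULL, cell = 1000,
                 mode = c("exact_area", "cell_center"),
                 port_coords = NULL, coastal_order = NULL,
                 processor_fte = NULL, landed_value = NULL, fishers = NULL) {
  mode <- match.arg(mode)
  if (is.character(register)) register <- read_register(register)
  else register <- validate_register(register)
  if (is.character(responses)) responses <- read_responses(responses, register)
  combos <- build_combo_table(register, scheme)
  if (!is.null(processor_fte))
    combos <- adapt_processors(combos, processor_fte)
  combos <- compute_weights(combos, port_coords = port_coords,
                            coastal_order = coastal_order)
  layers <- weight_responses(responses, register, combos, scheme)
  if (!is.null(landed_value))
    layers <- adapt_landings(layers, landed_value, fishers)
  if (is.null(grid)) grid <- grid_for_layers(layers, cell = cell)
  fleet <- rasterize_layers(layers, grid, mode = mode, tag = "fleet")
  fisheries <- sort(unique(layers$fishery))
  fmaps <- lapply(fisheries, function(f)
    subset_map(layers, grid, fishery = f, mode = mode))
  names(fmaps) <- fisheries
  vt <- total_sap(layers)
  structure(list(register = register, scheme = scheme, combos = combos,
                 layers = layers, grid = grid, mode = mode,
                 fleet_raster = fleet, fishery_rasters = fmaps,
                 port_coords = port_coords,
                 totals = list(vector = vt, raster = raster_total(fleet),
                               expected = if (is.null(landed_value))
                                 100 * sum(combos$E) else NA_real_),
                 crs = attr(responses, "crs")),
            class = "sapm")
}

#' @export
print.sapm <- function(x, ...) {
  cat("Spatial access priority model\n")
  cat(sprintf("  fleet: %d active vessels, %d interviewed (%.1f%%)\n",
              sum(x$register$active),
              sum(x$register$active & x$register$interviewed),
              100 * mean(x$register$interviewed[x$register$active])))
  cat(sprintf("  areas: %d priority areas from %d respondents; fisheries: %s\n",
              nrow(x$layers), length(unique(x$layers$respondent_id)),
              paste(names(x$fishery_rasters), collapse = ", ")))
  cat(sprintf("  grid: %d x %d cells of %.0f m (%s mode)\n",
              x$grid$nx, x$grid$ny, x$grid$cell, x$mode))
  cat(sprintf("  total SAP: vector %.2f, raster %.2f", x$totals$vector,
              x$totals$raster))
  if (is.finite(x$totals$expected))
    cat(sprintf(", 100 x estimated crew %.2f", x$totals$expected))
  cat("\n")
  invisible(x)
}

#' @export
summary.sapm <- function(object, ...) {
  w <- object$combos$W
  out <- list(totals = object$totals,
              n_combos = nrow(object$combos),
              n_sampled = sum(object$combos$S > 0),
              n_represented = sum(!is.na(object$combos$donor)),
              weight_range = range(w, na.rm = TRUE),
              fishery_sap = vapply(object$fishery_rasters, raster_total,
                                   numeric(1)),
              conservation_rel_err =
                abs(object$totals$raster - object$totals$vector) /
                max(object$totals$vector, .Machine$double.eps),
              fit = object)
  class(out) <- "summary.sapm"
  out
}

#' @export
print.summary.sapm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  combinations: %d (%d sampled, %d represented via donors)\n",
              x$n_combos, x$n_sampled, x$n_represented))
  cat(sprintf("  weights W in [%.3f, %.3f]\n", x$weight_range[1],
              x$weight_range[2]))
  cat("  SAP by fishery:\n")
  for (f in names(x$fishery_sap))
    cat(sprintf("    %-10s %12.2f\n", f, x$fishery_sap[[f]]))
  cat(sprintf("  raster/vector conservation, relative error: %.2e\n",
              x$conservation_rel_err))
  invisible(x)
}

#' Up-scaling weights of a fitted model
#' @param object a `sapm` fit
#' @param ... unused
#' @return named vector of combination weights W (NA for represented strata)
#' @export
coef.sapm <- function(object, ...) {
  stats::setNames(object$combos$W, object$combos$combo)
}

#' Predict SAP density at point locations
#'
#' Vector-exact by default: sums the weighted densities of all priority areas
#' containing each point. `type = "raster"` looks the grid cell up instead.
#'
#' @param object a `sapm` fit
#' @param newdata data frame with columns x, y (metres, model CRS)
#' @param type "vector" (exact overlay) or "raster" (cell lookup)
#' @param ... unused
#' @return numeric vector of SAP km^-2 at the points
#' @export
predict.sapm <- function(object, newdata, type = c("vector", "raster"), ...) {
  type <- match.arg(type)
  stopifnot(all(c("x", "y") %in% names(newdata)))
  if (type == "vector") {
    out <- numeric(nrow(newdata))
    for (i in seq_len(nrow(object$layers))) {
      hit <- geom_contains(newdata$x, newdata$y, object$layers$geometry[[i]])
      out[hit] <- out[hit] + object$layers$weighted_density[i]
    }
    out
  } else {
    g <- object$grid
    cc <- floor((newdata$x - g$x0) / g$cell) + 1
    rr <- floor((newdata$y - g$y0) / g$cell) + 1
    ok <- cc >= 1 & cc <= g$nx & rr >= 1 & rr <= g$ny
    out <- rep(0, nrow(newdata))
    out[ok] <- object$fleet_raster$values[cbind(rr[ok], cc[ok])]
    out
  }
}

#' Plot a priority raster (or the fleet map of a fit)
#'
#' @param x a `sapm` fit or `sapm_raster`
#' @param which for a fit: "fleet" or a fishery name
#' @param ... passed to [graphics::image()]
#' @export
plot.sapm <- function(x, which = "fleet", ...) {
  r <- if (identical(which, "fleet")) x$fleet_raster
       else x$fishery_rasters[[which]]
  if (is.null(r)) stop("no raster named ", which)
  plot(r, ...)
  if (!is.null(x$port_coords))
    graphics::points(x$port_coords$x, x$port_coords$y, pch = 17)
  invisible(x)
}

#' @rdname plot.sapm
#' @export
plot.sapm_raster <- function(x, ...) {
  g <- x$grid
  v <- x$values
  v[!x$touched] <- NA
  graphics::image(x = g$x0 + (seq_len(g$nx) - 0.5) * g$cell,
                  y = g$y0 + (seq_len(g$ny) - 0.5) * g$cell,
                  z = t(v), xlab = "x (m)", ylab = "y (m)",
                  main = paste0("SAP km⁻² (", x$tag, ")"),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Export a Marxan cost layer
#'
#' Aggregates the SAP mass of the weighted layers into planning units by
#' vector-exact polygon intersection: the cost of a unit is the total SAP
#' inside it, so costs over a tiling of the mapped region sum to the total
#' SAP. Written as the two-column `id,cost` planning-unit table Marxan
#' consumes.
#'
#' @param x a `sapm` fit or a `sap_layers` data frame
#' @param units planning units: data frame with `id` and `geometry` list
#'   column (e.g. from [read_polygons()])
#' @param path optional output CSV (header `id,cost`)
#' @return data frame id, cost (invisibly when writing)
#' @export
export_marxan <- function(x, units, path = NULL) {
  layers <- if (inherits(x, "sapm")) x$layers else x
  if (anyDuplicated(units$id))
    stop("duplicate planning-unit id(s): ",
         paste(unique(units$id[duplicated(units$id)]), collapse = ", "))
  cost <- vapply(units$geometry, function(g) {
    s <- 0
    for (i in seq_len(nrow(layers)))
      s <- s + layers$weighted_density[i] *
        geom_intersection_km2(layers$geometry[[i]], g)
    s
  }, numeric(1))
  out <- data.frame(id = units$id, cost = cost)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Rectangular planning-unit tiling of a grid extent
#'
#' Convenience tiler for cost-layer export and tests: splits the grid's
#' bounding box into `nx` x `ny` rectangular units.
#' @param grid a `sapm_grid`
#' @param nx,ny number of units along x and y
#' @return data frame with id and geometry list column
#' @export
tile_planning_units <- function(grid, nx = 5, ny = 5) {
  W <- grid$nx * grid$cell; H <- grid$ny * grid$cell
  xs <- grid$x0 + W * (0:nx) / nx
  ys <- grid$y0 + H * (0:ny) / ny
  ids <- character(0); geoms <- list()
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    ids[k] <- as.character(k)
    geoms[[k]] <- list(rbind(c(xs[i], ys[j]), c(xs[i + 1], ys[j]),
                             c(xs[i + 1], ys[j + 1]), c(xs[i], ys[j + 1])))
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}
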