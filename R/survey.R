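#' Survey responses: priority polygons and importance values
#'
#' A response set is one row per priority area: `area_id`, `respondent_id`,
#' `vessel_id`, `fishery`, `raw_importance` with `raw_kind` ("months" on
#' (0,12] or a positive unitless "rank" weight), the normalised `importance`
#' (percent of the fisher's total priority, summing to 100 per
#' respondent-vessel), `area_km2`, and a `geometry` list column of polygon
#' rings in a projected equal-area CRS (metres). Each full-time-equivalent
#' fisher carries a total spatial access priority (SAP) of 100, distributed
#' over their areas by the importance values.
#'
#' @name sapm-survey
NULL

FISHERIES <- c("nephrops", "pots", "scallops", "whitefish", "other")

#' Construct a response set from a data frame
#'
#' @param df data frame with area_id, respondent_id, vessel_id, fishery,
#'   raw_importance, raw_kind and a `geometry` list column
#' @param crs CRS label (an authority code such as "EPSG:32629"); must be a
#'   projected CRS in metres
#' @param register optional validated register for link checking
#' @param normalize normalise importances to sum 100 per respondent-vessel
#' @return a `response_set` data frame
#' @export
response_set <- function(df, crs, register = NULL, normalize = TRUE) {
  need <- c("area_id", "respondent_id", "vessel_id", "fishery", "geometry")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("responses missing column(s): ", paste(miss, collapse = ", "))
  if (!"raw_importance" %in% names(df)) df$raw_importance <- NA_real_
  if (!"raw_kind" %in% names(df)) df$raw_kind <- NA_character_
  if (anyDuplicated(df$area_id)) stop("duplicate area_id in responses")
  bad <- setdiff(unique(df$fishery), FISHERIES)
  if (length(bad) > 0)
    stop("unknown fishery label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(FISHERIES, collapse = ", "), ")")
  check_projected_crs(crs)
  df$geometry <- lapply(seq_len(nrow(df)),
                        function(i) validate_geom(df$geometry[[i]],
                                                  id = paste0("area ", df$area_id[i])))
  df$area_km2 <- vapply(df$geometry, geom_area_km2, numeric(1))
  if (!is.null(register)) {
    unknown <- setdiff(unique(df$vessel_id), register$vessel_id)
    if (length(unknown) > 0)
      stop("responses reference vessel_id(s) absent from register: ",
           paste(unknown, collapse = ", "))
    st <- register[match(df$vessel_id, register$vessel_id), ]
    off <- unique(df$vessel_id[!(st$active & st$interviewed)])
    if (length(off) > 0)
      stop("responses reference vessels not flagged active+interviewed: ",
           paste(off, collapse = ", "))
  }
  attr(df, "crs") <- crs
  class(df) <- c("response_set", "data.frame")
  if (normalize) df <- normalize_importance(df)
  df
}

check_projected_crs <- function(crs) {
  if (is.null(crs) || !nzchar(crs))
    stop("responses carry no CRS; a projected equal-area CRS (metres) with an ",
         "authority code is required")
  geographic <- c("EPSG:4326", "OGC:CRS84", "CRS84", "urn:ogc:def:crs:OGC:1.3:CRS84",
                  "urn:ogc:def:crs:EPSG::4326")
  if (toupper(crs) %in% toupper(geographic))
    stop("responses are in a geographic (degree) CRS (", crs,
         "); reproject to a projected equal-area CRS in metres first")
  invisible(crs)
}

#' Normalise importance values so each respondent-vessel sums to 100
#'
#' Months-of-year are converted to percent of the year and rescaled so the
#' respondent's importances sum to exactly 100 (stated months need not sum to
#' 12); rank weights are scaled proportionally; a single area with no stated
#' raw value receives 100, and several areas with no raw values share the 100
#' equally. Kinds may not be mixed within one respondent-vessel.
#'
#' @param responses a `response_set` (or compatible data frame)
#' @return the response set with the `importance` column (re)computed
#' @export
normalize_importance <- function(responses) {
  key <- paste(responses$respondent_id, responses$vessel_id, sep = "\r")
  responses$importance <- NA_real_
  for (k in unique(key)) {
    i <- which(key == k)
    raw <- responses$raw_importance[i]
    kind <- unique(responses$raw_kind[i][!is.na(raw)])
    if (length(kind) > 1)
      stop("mixed raw importance kinds (", paste(kind, collapse = ", "),
           ") for respondent-vessel ", sub("\r", "/", k, fixed = TRUE))
    if (all(is.na(raw))) {
      responses$importance[i] <- 100 / length(i)
      next
    }
    if (anyNA(raw))
      stop("partially missing raw importance for respondent-vessel ",
           sub("\r", "/", k, fixed = TRUE))
    if (any(raw <= 0)) stop("raw importance values must be positive")
    if (identical(kind, "months") && any(raw > 12))
      stop("months-of-year importance must lie in (0, 12]")
    if (!kind %in% c("months", "rank"))
      stop("raw_kind must be 'months' or 'rank', got: ", kind)
    # months/12*100 then rescale to total 100 == proportional scaling; ranks
    # are proportional by definition
    responses$importance[i] <- raw / sum(raw) * 100
  }
  responses
}

#' Read survey responses from GeoJSON
#'
#' The file must be a FeatureCollection with Polygon or MultiPolygon features
#' carrying the response attributes, and a `crs` member naming a projected
#' CRS (files in geographic coordinates are refused). Polygon holes are not
#' supported.
#'
#' @param path GeoJSON file
#' @param register optional validated register for link checking
#' @return a `response_set`
#' @export
read_responses <- function(path, register = NULL) {
  if (!file.exists(path)) stop("responses file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  crs <- gj$crs$properties$name
  if (is.null(crs)) crs <- ""
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    p <- f$properties
    data.frame(area_id = as.character(p$area_id),
               respondent_id = as.character(p$respondent_id),
               vessel_id = as.character(p$vessel_id),
               fishery = as.character(p$fishery),
               raw_importance = if (is.null(p$raw_importance)) NA_real_
                                else as.numeric(p$raw_importance),
               raw_kind = if (is.null(p$raw_kind)) NA_character_
                          else as.character(p$raw_kind),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$geometry <- lapply(feats, function(f) geojson_to_rings(f$geometry))
  response_set(df, crs = crs, register = register)
}

geojson_to_rings <- function(g) {
  ring_of <- function(coords) {
    as_ring(do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]]))))
  }
  if (identical(g$type, "Polygon")) {
    if (length(g$coordinates) > 1)
      stop("polygon holes are not supported")
    list(ring_of(g$coordinates[[1]]))
  } else if (identical(g$type, "MultiPolygon")) {
    lapply(g$coordinates, function(poly) {
      if (length(poly) > 1) stop("polygon holes are not supported")
      ring_of(poly[[1]])
    })
  } else {
    stop("unsupported geometry type: ", g$type)
  }
}

rings_to_geojson <- function(geom) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  polys <- lapply(geom, function(r) {
    r <- close_ring(as_ring(r))
    list(lapply(seq_len(nrow(r)), function(i) list(r[i, 1], r[i, 2])))
  })
  if (length(polys) == 1L) list(type = "Polygon", coordinates = polys[[1]])
  else list(type = "MultiPolygon", coordinates = polys)
}

#' Write a response set (or closure polygons) to GeoJSON
#'
#' Mirrors [read_responses()] for round-tripping.
#' @param responses a `response_set`
#' @param path output file
#' @export
write_responses <- function(responses, path) {
  feats <- lapply(seq_len(nrow(responses)), function(i) {
    list(type = "Feature",
         properties = list(area_id = responses$area_id[i],
                           respondent_id = responses$respondent_id[i],
                           vessel_id = responses$vessel_id[i],
                           fishery = responses$fishery[i],
                           raw_importance = responses$raw_importance[i],
                           raw_kind = responses$raw_kind[i]),
         geometry = rings_to_geojson(responses$geometry[[i]]))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = attr(responses, "crs"))),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = FALSE)
  invisible(path)
}

#' Read closure (or planning-unit) polygons from GeoJSON
#'
#' Features need only an `id` property; geometries are validated.
#' @param path GeoJSON file
#' @return data frame with `id` and a `geometry` list column
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0)
    return(data.frame(id = character(0)))
  ids <- vapply(seq_along(feats), function(i) {
    id <- feats[[i]]$properties$id
    if (is.null(id)) as.character(i) else as.character(id)
  }, character(1))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$geometry <- lapply(seq_along(feats), function(i)
    validate_geom(geojson_to_rings(feats[[i]]$geometry), id = paste0("feature ", ids[i])))
  out
}
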