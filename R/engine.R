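#' SAP densities, up-scaling weights and weighted layers
#'
#' The priority of one respondent's area is its SAP density: pro-rata crew of
#' the associated boat times the importance value, divided by the area in
#' square kilometres (SAP km^-2). Sample maps are scaled to the whole fleet
#' by stratum weights W = estimated crew E / sampled crew S per
#' port-gear-length combination, with donor fallback for unsampled strata.
#'
#' @name sapm-engine
NULL

#' SAP density of a priority area
#'
#' `crew x importance / area`: one full-time fisher (crew 1) assigning all
#' their importance (100) to a 10 km^2 area yields 10 SAP km^-2, i.e. a tenth
#' of a fisher per square kilometre.
#'
#' @param crew pro-rata FTE crew of the associated boat
#' @param importance normalised importance (percent of the fisher's total)
#' @param area_km2 polygon area in km^2 (> 0)
#' @return SAP km^-2
#' @export
sap_density <- function(crew, importance, area_km2) {
  if (any(area_km2 <= 0)) stop("area_km2 must be positive")
  if (any(importance < 0) || any(crew < 0)) stop("crew and importance must be >= 0")
  crew * importance / area_km2
}

port_distances <- function(from, ports, port_coords = NULL, coastal_order = NULL) {
  if (!is.null(port_coords)) {
    i <- match(from, port_coords$port)
    j <- match(ports, port_coords$port)
    if (is.na(i) || anyNA(j))
      stop("port coordinates missing for: ",
           paste(setdiff(c(from, ports), port_coords$port), collapse = ", "))
    if (all(c("x", "y") %in% names(port_coords))) {
      sqrt((port_coords$x[j] - port_coords$x[i])^2 +
           (port_coords$y[j] - port_coords$y[i])^2)
    } else if (all(c("lon", "lat") %in% names(port_coords))) {
      geosphere::distHaversine(c(port_coords$lon[i], port_coords$lat[i]),
                               cbind(port_coords$lon[j], port_coords$lat[j]))
    } else stop("port_coords needs columns x,y (projected) or lon,lat")
  } else if (!is.null(coastal_order)) {
    i <- match(from, coastal_order); j <- match(ports, coastal_order)
    if (is.na(i) || anyNA(j))
      stop("coastal_order does not list: ",
           paste(setdiff(c(from, ports), coastal_order), collapse = ", "))
    abs(j - i)
  } else {
    stop("unsampled combination at a port with no same-gear sample requires ",
         "port_coords or coastal_order to locate the nearest port")
  }
}

#' Compute up-scaling weights with donor fallback
#'
#' Sampled combinations get W = E/S. An unsampled combination (S = 0, E > 0)
#' is represented by a donor: the sampled same-port same-gear combination of
#' nearest length class (ties broken toward the smaller class); failing that,
#' the nearest port with a sampled combination of that gear. The donor's
#' weight becomes (E_donor + sum of represented E) / S_donor, so the total
#' estimated crew is conserved: sum(W x S) = sum(E).
#'
#' @param combos a `combo_table` from [build_combo_table()]
#' @param port_coords optional data frame (port, x, y) in metres or
#'   (port, lon, lat) in degrees, used for nearest-port fallback
#' @param coastal_order optional character vector of ports in coastal
#'   sequence, used when coordinates are absent
#' @return the combo table with columns W (NA for represented combos),
#'   donor (combo id of the donor, NA for sampled combos) and represents
#' @export
compute_weights <- function(combos, port_coords = NULL, coastal_order = NULL) {
  sampled <- combos$S > 0
  gear_unsampled <- setdiff(unique(combos$gear[combos$E > 0]),
                            unique(combos$gear[sampled]))
  if (length(gear_unsampled) > 0)
    stop("no interviewed vessel fleet-wide for gear(s): ",
         paste(gear_unsampled, collapse = ", "), "; cannot upscale")
  combos$W <- NA_real_
  combos$donor <- NA_character_
  extraE <- stats::setNames(rep(0, nrow(combos)), combos$combo)
  for (i in which(!sampled & combos$E > 0)) {
    cand <- which(sampled & combos$gear == combos$gear[i] &
                  combos$port == combos$port[i])
    if (length(cand) == 0) {
      with_gear <- which(sampled & combos$gear == combos$gear[i])
      d <- port_distances(combos$port[i], combos$port[with_gear],
                          port_coords, coastal_order)
      nearest <- combos$port[with_gear][which.min(d)]
      cand <- with_gear[combos$port[with_gear] == nearest]
    }
    dd <- abs(combos$class_index[cand] - combos$class_index[i])
    cand <- cand[dd == min(dd)]
    # tie toward the smaller length class (the under-sampled stratum)
    donor <- cand[which.min(combos$class_index[cand])]
    combos$donor[i] <- combos$combo[donor]
    extraE[donor] <- extraE[donor] + combos$E[i]
  }
  combos$W[sampled] <- (combos$E[sampled] + extraE[sampled]) / combos$S[sampled]
  combos$represents <- I(lapply(seq_len(nrow(combos)), function(i)
    combos$combo[!is.na(combos$donor) & combos$donor == combos$combo[i]]))
  combos
}

#' Attach weights and weighted SAP densities to responses
#'
#' Each area inherits its vessel's combination weight; the weighted density
#' is W x sap_density. Over a respondent-vessel's areas, the unweighted
#' densities integrate to 100 x pro-rata crew by construction.
#'
#' @param responses a normalised `response_set`
#' @param register validated register
#' @param combos combo table with weights ([compute_weights()])
#' @param scheme category scheme used to build the combo table
#' @return a `sap_layers` data frame (one row per area) with crew,
#'   sap_density, weight and weighted_density
#' @export
weight_responses <- function(responses, register, combos,
                             scheme = default_category_scheme()) {
  v <- register[match(responses$vessel_id, register$vessel_id), ]
  if (anyNA(v$vessel_id))
    stop("responses reference vessel_id(s) absent from register: ",
         paste(setdiff(responses$vessel_id, register$vessel_id), collapse = ", "))
  cls <- categorize(v$gear, v$length_m, scheme)
  key <- combo_id(v$port, v$gear, cls)
  j <- match(key, combos$combo)
  if (anyNA(j))
    stop("no combination table entry for combo(s): ",
         paste(unique(key[is.na(j)]), collapse = ", "))
  w <- combos$W[j]
  if (anyNA(w))
    stop("combo(s) without a weight (represented strata hold no responses): ",
         paste(unique(key[is.na(w)]), collapse = ", "))
  out <- responses
  out$combo <- key
  out$crew <- v$crew
  out$sap_density <- sap_density(out$crew, out$importance, out$area_km2)
  out$weight <- w
  out$weighted_density <- out$weight * out$sap_density
  class(out) <- c("sap_layers", class(responses))
  out
}

#' Fold shore-based processor employment into the estimated crew
#'
#' Each fishery's processor FTE is divided between that fishery's
#' combinations in proportion to their share of the fishery's estimated crew
#' E, and added to E. Recompute weights afterwards.
#'
#' @param combos a `combo_table`
#' @param processor_fte named numeric vector, FTE per fishery
#' @param gear_fisheries named vector mapping gear to fishery
#' @return the combo table with adjusted E (weights dropped)
#' @export
adapt_processors <- function(combos, processor_fte,
                             gear_fisheries = default_gear_fisheries()) {
  if (any(processor_fte < 0)) stop("processor FTE must be >= 0")
  fish <- unname(gear_fisheries[combos$gear])
  for (f in names(processor_fte)) {
    fte <- processor_fte[[f]]
    if (fte == 0) next
    i <- which(fish == f)
    if (length(i) == 0 || sum(combos$E[i]) <= 0)
      stop("processor FTE given for fishery with no combinations: ", f)
    combos$E[i] <- combos$E[i] + fte * combos$E[i] / sum(combos$E[i])
  }
  combos$W <- NULL; combos$donor <- NULL; combos$represents <- NULL
  combos
}

#' Landings-value weighting of layers
#'
#' Multiplies each layer's weight (and weighted density) by the fishery's
#' landed value per fisher, turning SAP into a currency-scaled cost surface.
#'
#' @param layers a `sap_layers` data frame
#' @param landed_value named numeric vector, total landings value per fishery
#' @param fishers named numeric vector, FTE fishers per fishery
#' @return layers with value-scaled weight and weighted_density
#' @export
adapt_landings <- function(layers, landed_value, fishers) {
  for (f in names(landed_value)) {
    if (landed_value[[f]] == 0) next
    if (is.null(fishers[[f]]) || fishers[[f]] <= 0)
      stop("fishery ", f, " has landed value but no (positive) fisher count")
  }
  vpf <- rep(1, nrow(layers))
  has <- layers$fishery %in% names(landed_value)
  vpf[has] <- unname(landed_value[layers$fishery[has]] /
                     fishers[layers$fishery[has]])
  layers$weight <- layers$weight * vpf
  layers$weighted_density <- layers$weight * layers$sap_density
  layers
}

#' Vector-space total SAP of a set of layers
#' @param layers a `sap_layers` data frame
#' @param weighted use weighted densities (default) or raw
#' @return total SAP (sum of density x area over areas)
#' @export
total_sap <- function(layers, weighted = TRUE) {
  d <- if (weighted) layers$weighted_density else layers$sap_density
  sum(d * layers$area_km2)
}
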