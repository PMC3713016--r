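#' Synthetic fleets and surveys
#'
#' Generates a fleet register, port coordinates and a census of priority
#' polygons with the statistical structure the up-scaling method assumes:
#' a few large trawl/dredge ports plus many minor pot ports along a
#' coastline, gear and length mixtures shaped like an inshore fleet of ~250
#' vessels, crew increasing with vessel size (pot boats crewed lighter,
#' pelagic boats much heavier), vessel range from port increasing with
#' length, high footprint overlap within a port-gear-length combination, and
#' stratified interview subsampling at roughly half the fleet.
#'
#' Footprints are annular sectors anchored off the home port: respondents in
#' one combination share a combination-level heading and radial band and get
#' small individual jitters, so within-combination overlap is high while pot
#' combinations at different ports barely overlap. Crew is a deterministic
#' function of the vessel's category, so category mean crew estimated from
#' any sample is exact and a census run reproduces the fleet identically.
#'
#' @name sapm-synthetic
NULL

#' Scenario parameters for the synthetic generator
#'
#' Defaults give 20 ports and a 246-vessel active fleet with gear counts,
#' length mixtures and ~48% interview coverage shaped like a small national
#' inshore fleet; they run in seconds.
#'
#' @param n_vessels total number of active vessels
#' @param n_ports number of ports along the synthetic coast
#' @param port_spacing_m distance between neighbouring ports, metres
#' @param p_interview interview inclusion probability per stratum (a single
#'   number, or a named vector by gear)
#' @param ensure_category_coverage force at least one interview in every
#'   category that holds vessels (a category with no sample cannot be
#'   up-scaled)
#' @param p_second_vessel probability a skipper owns a second vessel of the
#'   same port and gear (they then answer once per vessel)
#' @param crs authority code of the synthetic projected CRS
#' @return a `sapm_scenario` list
#' @export
sapm_scenario <- function(n_vessels = 246, n_ports = 20,
                          port_spacing_m = 12000, p_interview = 0.48,
                          ensure_category_coverage = TRUE,
                          p_second_vessel = 0.06, crs = "EPSG:3035") {
  stopifnot(n_vessels >= 20, n_ports >= 4)
  structure(list(n_vessels = n_vessels, n_ports = n_ports,
                 port_spacing_m = port_spacing_m, p_interview = p_interview,
                 ensure_category_coverage = ensure_category_coverage,
                 p_second_vessel = p_second_vessel, crs = crs),
            class = "sapm_scenario")
}

# deterministic crew model: full-time crew and seasonal entries per category
category_crew_model <- function() {
  list("pelagic" = list(ft = 9, seas = ""),
       "<7m" = list(ft = 1, seas = ""),
       "7-<9m" = list(ft = 1, seas = ""),
       "9-<10m pots" = list(ft = 1, seas = ""),
       "9-<10m non-pots" = list(ft = 2, seas = "1:6"),
       "10-<15m" = list(ft = 2, seas = "1:6"),
       "15-<20m" = list(ft = 3, seas = "1:6"),
       ">=20m non-pelagic" = list(ft = 5, seas = ""))
}

# maximum range from port (metres): increases with length; pot boats are
# short-ranged
vessel_range_m <- function(gear, length_m) {
  ifelse(gear == "pots",
         pmin(pmax(800 * length_m, 2000), 8000),
         pmin(pmax(2000 * length_m, 4000), 60000))
}

draw_lengths <- function(gear, n) {
  pool <- switch(gear,
    pots = list(v = c(5, 6, 6.5, 7, 8, 9, 9.5, 12),
                w = c(15, 20, 15, 10, 10, 12, 14, 4)),
    nephrops_trawl = list(v = c(9.5, 12, 14, 16, 18, 21, 24, 32),
                          w = c(10, 10, 10, 22, 24, 14, 8, 2)),
    dredge = list(v = c(10, 12, 15, 17), w = c(3, 3, 2, 2)),
    scallop_dredge = list(v = c(12, 16), w = c(1, 1)),
    gill_net = list(v = c(5, 6, 8), w = c(2, 2, 1)),
    hand = list(v = 5, w = 1),
    seine = list(v = 17, w = 1),
    pelagic = list(v = c(22, 28, 35), w = c(1, 1, 1)),
    stop("no length model for gear ", gear))
  if (length(pool$v) == 1L) return(rep(pool$v, n))
  sample(pool$v, n, replace = TRUE, prob = pool$w)
}

# gear composition scaled to the requested fleet size (default shares of a
# 246-vessel fleet dominated by a langoustine trawl fishery and potting)
gear_counts <- function(n_vessels) {
  base <- c(nephrops_trawl = 133, pots = 88, dredge = 5, scallop_dredge = 2,
            gill_net = 13, hand = 1, seine = 1, pelagic = 3)
  n <- round(base / sum(base) * n_vessels)
  n[n < 1] <- 1
  # adjust the dominant gear so counts total n_vessels
  n["nephrops_trawl"] <- n["nephrops_trawl"] + n_vessels - sum(n)
  n
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

sector_ring <- function(ox, oy, theta, half_angle, r_in, r_out, n_arc = 8) {
  a <- seq(theta - half_angle, theta + half_angle, length.out = n_arc + 1)
  outer <- cbind(ox + r_out * cos(a), oy + r_out * sin(a))
  inner <- cbind(ox + r_in * cos(rev(a)), oy + r_in * sin(rev(a)))
  as_ring(rbind(outer, inner))
}

#' Generate a synthetic fleet register and census response set
#'
#' Every active vessel receives a home port, gear, length, category-determined
#' crew, and a census interview: 1-3 priority areas as jittered annular
#' sectors off the port, with months-of-year importance drawn from a
#' Dirichlet allocation. The same seed reproduces identical output.
#'
#' @param scenario a [sapm_scenario()]
#' @param seed integer RNG seed
#' @return list: `register` (all vessels flagged interviewed, i.e. a census),
#'   `responses` (census `response_set`), `port_coords`, `crs`, `scenario`
#' @export
generate_population <- function(scenario = sapm_scenario(), seed = 1) {
  set.seed(seed)
  np <- scenario$n_ports
  port_names <- sprintf("port_%02d", seq_len(np))
  port_coords <- data.frame(port = port_names,
                            x = (seq_len(np) - 1) * scenario$port_spacing_m,
                            y = 0, stringsAsFactors = FALSE)
  main_ports <- port_names[round(c(0.2, 0.5, 0.8) * np)]
  minor_ports <- setdiff(port_names, main_ports)

  ng <- gear_counts(scenario$n_vessels)
  gear <- rep(names(ng), ng)
  port <- character(length(gear))
  for (i in seq_along(gear)) {
    port[i] <- if (gear[i] == "pots") {
      # potting is dispersed: most pot boats sit in the minor ports
      if (stats::runif(1) < 0.35) sample(main_ports, 1)
      else sample(minor_ports, 1)
    } else sample(main_ports, 1, prob = c(0.45, 0.35, 0.2))
  }
  length_m <- numeric(length(gear))
  for (g in names(ng)) length_m[gear == g] <- draw_lengths(g, ng[[g]])

  scheme <- default_category_scheme()
  cat <- categorize(gear, length_m, scheme)
  crew_model <- category_crew_model()
  ft <- vapply(cat, function(k) crew_model[[k]]$ft, numeric(1))
  seas <- vapply(cat, function(k) crew_model[[k]]$seas, character(1))

  register <- data.frame(
    vessel_id = sprintf("V%03d", seq_along(gear)),
    port = port, gear = gear, length_m = length_m,
    crew_fulltime = ft, seasonal_crew = seas,
    active = TRUE, interviewed = TRUE, stringsAsFactors = FALSE)
  register <- validate_register(register)

  # skipper assignment: a few respondents own two vessels of one port+gear
  resp <- sprintf("R%03d", seq_len(nrow(register)))
  key <- paste(register$port, register$gear)
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(i) >= 2 && stats::runif(1) < scenario$p_second_vessel * length(i))
      resp[i[2]] <- resp[i[1]]
  }

  # combination-level footprint model: shared heading and band => overlap
  cmb <- combo_id(register$port, register$gear, cat)
  ucmb <- unique(cmb)
  base_theta <- stats::setNames(stats::runif(length(ucmb), pi / 2 - 0.45,
                                             pi / 2 + 0.45), ucmb)
  base_half <- stats::setNames(stats::runif(length(ucmb), 0.35, 0.5), ucmb)

  gear_fish <- default_gear_fisheries()
  rows <- vector("list", nrow(register))
  for (i in seq_len(nrow(register))) {
    r_max <- vessel_range_m(register$gear[i], register$length_m[i]) *
      stats::runif(1, 0.9, 1.1)
    k_areas <- if (register$gear[i] == "pots") sample(1:2, 1, prob = c(0.7, 0.3))
               else sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    theta <- base_theta[[cmb[i]]] + stats::runif(1, -0.08, 0.08)
    half <- base_half[[cmb[i]]] * stats::runif(1, 0.9, 1.1)
    px <- port_coords$x[match(register$port[i], port_coords$port)]
    py <- 400 # just offshore
    bounds <- c(200, sort(stats::runif(k_areas - 1, 0.25, 0.9)) * r_max, r_max)
    months <- 12 * rdirichlet1(rep(2, k_areas))
    fish <- rep(unname(gear_fish[register$gear[i]]), k_areas)
    if (register$gear[i] == "nephrops_trawl" && k_areas >= 2 &&
        stats::runif(1) < 0.15)
      fish[k_areas] <- "whitefish"
    geoms <- lapply(seq_len(k_areas), function(k)
      list(sector_ring(px, py, theta, half, bounds[k], bounds[k + 1])))
    rows[[i]] <- data.frame(
      area_id = sprintf("%s_A%d", register$vessel_id[i], seq_len(k_areas)),
      respondent_id = resp[i], vessel_id = register$vessel_id[i],
      fishery = fish, raw_importance = months, raw_kind = "months",
      stringsAsFactors = FALSE)
    rows[[i]]$geometry <- geoms
  }
  responses <- do.call(rbind, rows)
  responses <- response_set(responses, crs = scenario$crs, register = register)
  list(register = register, responses = responses, port_coords = port_coords,
       crs = scenario$crs, scenario = scenario)
}

#' Draw a stratified interview subsample from a synthetic population
#'
#' Bernoulli sampling per gear stratum; optionally guarantees every category
#' with vessels keeps at least one interview so the combination table stays
#' estimable. Responses of non-interviewed vessels are dropped, emulating a
#' real survey of part of the fleet.
#'
#' @param population output of [generate_population()]
#' @param p inclusion probability (single number or named by gear); defaults
#'   to the scenario's
#' @param seed integer RNG seed
#' @return list like `population` but with `interviewed` flags set and
#'   `responses` restricted to interviewed vessels
#' @export
draw_interviews <- function(population, p = NULL, seed = 1) {
  set.seed(seed)
  reg <- population$register
  scen <- population$scenario
  if (is.null(p)) p <- scen$p_interview
  pv <- if (length(p) == 1L && is.null(names(p))) rep(p, nrow(reg))
        else {
          if (!all(reg$gear %in% names(p)))
            stop("p must name every gear present")
          unname(p[reg$gear])
        }
  reg$interviewed <- stats::runif(nrow(reg)) < pv
  if (isTRUE(scen$ensure_category_coverage) && any(reg$interviewed)) {
    # an unsampled category (or gear) cannot be up-scaled at all, so keep at
    # least one interview in each stratum that holds vessels
    cat <- categorize(reg$gear, reg$length_m)
    for (strata in list(cat, reg$gear)) {
      for (k in unique(strata)) {
        i <- which(strata == k)
        if (!any(reg$interviewed[i]) && max(pv[i]) > 0)
          reg$interviewed[sample(rep(i, 2), 1)] <- TRUE
      }
    }
  }
  resp <- population$responses
  keep <- resp$vessel_id %in% reg$vessel_id[reg$interviewed]
  resp <- resp[keep, , drop = FALSE]
  out <- population
  out$register <- reg
  out$responses <- resp
  out$realized_coverage <- mean(reg$interviewed[reg$active])
  out
}
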