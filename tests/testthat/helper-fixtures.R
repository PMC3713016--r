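# fixture builders shared across tests; everything is generated in code

# axis-aligned rectangle ring (metres)
sq <- function(x0, y0, w, h = w) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}

# register with one row per description list(port, gear, len, ft, seas, int)
mk_register <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(vessel_id = sprintf("V%02d", i), port = r$port, gear = r$gear,
               length_m = r$len, crew_fulltime = r$ft,
               seasonal_crew = if (is.null(r$seas)) "" else r$seas,
               active = if (is.null(r$active)) TRUE else r$active,
               interviewed = if (is.null(r$int)) TRUE else r$int,
               stringsAsFactors = FALSE)
  }))
  validate_register(df)
}

# response set: one row per list(vessel, geom, fishery, raw, kind, resp)
mk_responses <- function(register, ..., crs = "EPSG:3035") {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(area_id = sprintf("A%02d", i),
               respondent_id = if (is.null(r$resp)) paste0("R_", r$vessel) else r$resp,
               vessel_id = r$vessel,
               fishery = if (is.null(r$fishery)) "pots" else r$fishery,
               raw_importance = if (is.null(r$raw)) NA_real_ else r$raw,
               raw_kind = if (is.null(r$kind)) NA_character_ else r$kind,
               stringsAsFactors = FALSE)
  }))
  df$geometry <- lapply(rows, function(r) if (is.matrix(r$geom)) list(r$geom) else r$geom)
  response_set(df, crs = crs, register = register)
}

# a small population + ~50% sample, cached per test run
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_population(sapm_scenario(n_vessels = 80, n_ports = 8),
                                    seed = 42)
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- small_pop()
      smp <- draw_interviews(pop, seed = 43)
      cache <<- sapm(smp$register, smp$responses, port_coords = smp$port_coords)
    }
    cache
  }
})
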