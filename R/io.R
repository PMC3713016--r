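#' Audit exports and run provenance
#'
#' @name sapm-io
NULL

#' @useDynLib sapm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Write the final weighting scheme as an audit CSV
#'
#' One row per port-gear-length combination: register count, estimated and
#' sampled crew, weight, donor assignment and represented strata.
#' @param combos a weighted `combo_table`
#' @param path output CSV
#' @export
write_weight_table <- function(combos, path) {
  out <- as.data.frame(combos)
  if ("represents" %in% names(out)) {
    out$represents <- vapply(out$represents, paste, character(1), collapse = ";")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable provenance record for a run
#'
#' Records the configuration (and its md5), seed, package and R versions and
#' a timestamp, so any output file can be traced to the exact run.
#' @param config list of run parameters
#' @param path output JSON
#' @param seed the run seed (if any)
#' @export
write_provenance <- function(config, path, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(cfg_json, tf)
  rec <- list(config = config,
              config_md5 = unname(tools::md5sum(tf)),
              seed = seed,
              package_version = as.character(utils::packageVersion("sapm")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
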