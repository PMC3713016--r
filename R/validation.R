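#' Sample representativeness and response-consistency checks
#'
#' Before up-scaling, the interview sample is compared with the fleet on its
#' three main vessel characteristics (length, registered port, gear), and
#' within-combination footprint overlap quantifies whether respondents in one
#' port-gear-length stratum report consistent grounds (if they did not,
#' scaling a few responses up to the stratum would be unsound).
#'
#' @name sapm-validation
NULL

#' Vessel-length size bins used for coverage reporting
#' @param length_m vessel lengths in metres
#' @return factor of size-class labels
#' @export
size_bins <- function(length_m) {
  cut(length_m, breaks = c(0, 7, 9, 10, 15, 20, 30, Inf), right = FALSE,
      labels = c("under 7", "7 to <9", "9 to <10", "10 to <15",
                 "15 to <20", "20 to <30", "30+"))
}

#' Per-stratum interview coverage
#' @param register validated register
#' @param by a column name ("port", "gear") or a vector of stratum labels for
#'   the active vessels
#' @return data frame: stratum, n_active, n_interviewed, percent
#' @export
coverage_table <- function(register, by = "gear") {
  act <- register[register$active, , drop = FALSE]
  strata <- if (is.character(by) && length(by) == 1L && by %in% names(act))
    act[[by]] else rep_len(by, nrow(act))
  strata <- as.character(strata)
  n_act <- table(strata)
  n_int <- table(factor(strata[act$interviewed], levels = names(n_act)))
  out <- data.frame(stratum = names(n_act),
                    n_active = as.vector(n_act),
                    n_interviewed = as.vector(n_int),
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$n_interviewed / out$n_active, 1)
  out
}

group_strata <- function(strata, grouping = NULL) {
  if (is.null(grouping)) return(strata)
  for (g in names(grouping))
    strata[strata %in% grouping[[g]]] <- g
  strata
}

chisq_sample_vs_population <- function(sample_counts, pop_counts) {
  # goodness of fit of the sample frequencies against population proportions
  keep <- pop_counts > 0
  if (any(!keep)) stop("stratum with zero population count")
  p <- pop_counts[keep] / sum(pop_counts[keep])
  expected <- sum(sample_counts[keep]) * p
  if (any(expected <= 0))
    stop("expected counts of zero; group small strata more coarsely")
  ht <- suppressWarnings(stats::chisq.test(sample_counts[keep], p = p))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

pooled_t_test <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Test whether the interview sample represents the fleet
#'
#' A pooled two-sided t-test compares vessel lengths between sampled vessels
#' and the active fleet, and chi-squared goodness-of-fit tests compare the
#' sample's port and gear frequencies with the fleet's. Small ports should be
#' grouped geographically via `port_grouping` (a named list, group ->
#' character vector of ports) so expected counts stay usable.
#'
#' @param register validated register
#' @param port_grouping optional named list grouping small ports
#' @param gear_grouping optional named list grouping rare gears
#' @return a `sapm_representativeness` list: length_test, port_test,
#'   gear_test, coverage by gear and by size class
#' @export
representativeness <- function(register, port_grouping = NULL,
                               gear_grouping = NULL) {
  act <- register[register$active, , drop = FALSE]
  smp <- act[act$interviewed, , drop = FALSE]
  if (nrow(smp) < 2) stop("need at least two interviewed active vessels")
  ports <- group_strata(act$port, port_grouping)
  gears <- group_strata(act$gear, gear_grouping)
  if (length(unique(ports)) < 2 || length(unique(gears)) < 2)
    stop("need at least two strata per chi-squared test after grouping")
  pop_port <- table(ports)
  smp_port <- table(factor(ports[act$interviewed], levels = names(pop_port)))
  pop_gear <- table(gears)
  smp_gear <- table(factor(gears[act$interviewed], levels = names(pop_gear)))
  out <- list(
    length_test = pooled_t_test(smp$length_m, act$length_m),
    port_test = chisq_sample_vs_population(as.vector(smp_port), as.vector(pop_port)),
    gear_test = chisq_sample_vs_population(as.vector(smp_gear), as.vector(pop_gear)),
    coverage_gear = coverage_table(register, "gear"),
    coverage_size = coverage_table(register, size_bins(act$length_m)),
    n_active = nrow(act), n_interviewed = nrow(smp))
  class(out) <- "sapm_representativeness"
  out
}

#' @export
print.sapm_representativeness <- function(x, ...) {
  cat("Sample representativeness:", x$n_interviewed, "of", x$n_active,
      sprintf("active vessels interviewed (%.1f%%)\n",
              100 * x$n_interviewed / x$n_active))
  f <- function(t) sprintf("stat = %.3f, df = %s, p = %.3f",
                           t$statistic, format(t$df), t$p.value)
  cat("  length (pooled t): ", f(x$length_test), "\n")
  cat("  port (chi-squared):", f(x$port_test), "\n")
  cat("  gear (chi-squared):", f(x$gear_test), "\n")
  cat("Coverage by gear:\n")
  print(x$coverage_gear, row.names = FALSE)
  invisible(x)
}

#' Crew difference between gear groups in a length window
#'
#' Pooled two-sided two-sample t-test on pro-rata crew of interviewed vessels
#' inside `[lo, hi)` metres, split into `gear` versus the rest. This is the
#' check that justifies splitting a length class by gear (pot boats of 9-10 m
#' carry fewer crew than trawl or dredge boats of the same size).
#'
#' @param register validated register
#' @param lo,hi length window in metres, half-open
#' @param gear gear forming the first group (default "pots")
#' @return list(statistic, df, p.value, n1, n2)
#' @export
crew_gear_difference <- function(register, lo = 9, hi = 10, gear = "pots") {
  smp <- register[register$interviewed & register$length_m >= lo &
                  register$length_m < hi, , drop = FALSE]
  a <- smp$crew[smp$gear == gear]
  b <- smp$crew[smp$gear != gear]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two interviewed vessels per gear group in the window")
  c(pooled_t_test(a, b), list(n1 = length(a), n2 = length(b)))
}

#' Within-combination footprint overlap
#'
#' For each port-gear-length combination with at least two respondents, the
#' mean pairwise Jaccard index of the respondents' footprints (union of each
#' respondent's areas). High overlap supports up-scaling a stratum from its
#' sampled respondents; singleton combinations are skipped.
#'
#' @param responses a `response_set` (importance not needed)
#' @param register validated register
#' @param scheme category scheme
#' @return data frame: combo, n_respondents, mean_jaccard
#' @export
within_combo_overlap <- function(responses, register,
                                 scheme = default_category_scheme()) {
  v <- register[match(responses$vessel_id, register$vessel_id), ]
  cls <- categorize(v$gear, v$length_m, scheme)
  combo <- combo_id(v$port, v$gear, cls)
  res <- list()
  for (cb in unique(combo)) {
    i <- which(combo == cb)
    resp <- unique(responses$respondent_id[i])
    if (length(resp) < 2) next
    foot <- lapply(resp, function(r)
      do.call(c, responses$geometry[i][responses$respondent_id[i] == r]))
    pairs <- utils::combn(length(resp), 2)
    jac <- apply(pairs, 2, function(p) geom_jaccard(foot[[p[1]]], foot[[p[2]]]))
    res[[cb]] <- data.frame(combo = cb, n_respondents = length(resp),
                            mean_jaccard = mean(jac), stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(combo = character(0), n_respondents = integer(0),
                      mean_jaccard = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Congruency of the priority map with an external effort raster
#'
#' Every cell fished (effort > 0) should carry some access priority. Reports
#' the fraction of effort-positive cells with positive priority, plus a
#' Spearman rank correlation over the effort-positive cells as a supplementary
#' pattern diagnostic.
#'
#' @param priority a `sapm_raster` of SAP km^-2
#' @param effort a `sapm_raster` of fishing effort on the identical grid
#' @return list(coverage, spearman, n_effort_cells)
#' @export
effort_congruency <- function(priority, effort) {
  if (!same_grid(priority$grid, effort$grid))
    stop("priority and effort rasters are on different grids")
  eff <- effort$values > 0 & effort$touched
  n <- sum(eff)
  if (n == 0) stop("effort raster has no positive cells")
  coverage <- sum(priority$values[eff] > 0) / n
  rho <- if (n >= 3 && stats::sd(priority$values[eff]) > 0 &&
             stats::sd(effort$values[eff]) > 0)
    stats::cor(priority$values[eff], effort$values[eff], method = "spearman")
  else NA_real_
  list(coverage = coverage, spearman = rho, n_effort_cells = n)
}
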