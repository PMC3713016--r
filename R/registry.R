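#' Fleet register handling
#'
#' The register is one row per vessel: `vessel_id`, `port`, `gear`,
#' `length_m`, `crew_fulltime`, `seasonal_crew` (encoded
#' `"headcount:months;headcount:months"`), `active` (0/1), `interviewed`
#' (0/1). Gear labels are a controlled vocabulary after normalisation through
#' a gear map (mixed registered gears such as "Dredge & Nephrops trawl" are
#' mapped to a primary gear at ingest).
#'
#' @name sapm-registry
NULL

GEARS <- c("pots", "nephrops_trawl", "dredge", "scallop_dredge",
           "whitefish_trawl", "gill_net", "seine", "hand", "pelagic")

#' Default mapping from registered gear labels to the primary-gear vocabulary
#' @return named character vector (raw label -> primary gear)
#' @export
default_gear_map <- function() {
  c("Dredge" = "dredge",
    "Dredge & Nephrops trawl" = "nephrops_trawl",
    "Gill Net" = "gill_net",
    "Hand Fishing" = "hand",
    "Nephrops & Whitefish trawl" = "nephrops_trawl",
    "Nephrops trawl" = "nephrops_trawl",
    "Pelagic trawl" = "pelagic",
    "Nephrops trawl & Gill net" = "nephrops_trawl",
    "Pots" = "pots",
    "Pots & Nephrops trawl" = "pots",
    "Pots, Dredge & Nephrops trawl" = "pots",
    "Scallop Dredge" = "scallop_dredge",
    "Seine netting" = "seine",
    "Pots & Dredge" = "pots")
}

#' Map primary gears to the fishery partition used for sub-fleet maps
#' @return named character vector (gear -> fishery)
#' @export
default_gear_fisheries <- function() {
  c(pots = "pots", nephrops_trawl = "nephrops", dredge = "scallops",
    scallop_dredge = "scallops", whitefish_trawl = "whitefish",
    gill_net = "other", seine = "other", hand = "other", pelagic = "other")
}

normalize_gear <- function(gear, gear_map = default_gear_map()) {
  out <- ifelse(gear %in% GEARS, gear, unname(gear_map[gear]))
  bad <- unique(gear[is.na(out)])
  if (length(bad) > 0)
    stop("unknown gear label(s) not in vocabulary or gear map: ",
         paste(bad, collapse = ", "))
  out
}

parse_seasonal <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), 0, 2))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p)
    suppressWarnings(as.numeric(p[1:2]))))
  colnames(m) <- c("headcount", "months")
  if (anyNA(m)) stop("malformed seasonal_crew entry: ", s)
  if (any(m[, "headcount"] < 1)) stop("seasonal headcount must be >= 1: ", s)
  if (any(m[, "months"] <= 0 | m[, "months"] > 12))
    stop("seasonal months must lie in (0, 12]: ", s)
  m
}

#' Pro-rata crew (full-time-equivalent crew count)
#'
#' Seasonal or part-year crew count as months/12 of a full-time member, so a
#' boat with 4 full-time crew plus one extra full-timer for six months has a
#' pro-rata crew of 4.5.
#'
#' @param crew_fulltime number of year-round full-time crew (>= 0)
#' @param seasonal_crew character vector, each element encoding seasonal
#'   entries as `"headcount:months"` joined by `";"` (empty/NA for none)
#' @return numeric vector of FTE crew
#' @examples
#' pro_rata_crew(4, "1:6")   # 4.5
#' pro_rata_crew(2, "1:3;1:3")
#' @export
pro_rata_crew <- function(crew_fulltime, seasonal_crew = "") {
  if (any(is.na(crew_fulltime)) || any(crew_fulltime < 0))
    stop("crew_fulltime must be non-negative")
  seasonal_crew <- rep_len(as.character(seasonal_crew), length(crew_fulltime))
  extra <- vapply(seasonal_crew, function(s) {
    m <- parse_seasonal(s)
    if (nrow(m) == 0) 0 else sum(m[, "headcount"] * m[, "months"] / 12)
  }, numeric(1), USE.NAMES = FALSE)
  crew_fulltime + extra
}

#' Read and validate a fleet register CSV
#'
#' @param path CSV path with columns vessel_id, port, gear, length_m,
#'   crew_fulltime, seasonal_crew, active, interviewed
#' @param gear_map named vector mapping raw gear labels to the primary-gear
#'   vocabulary
#' @return validated register data frame with normalised gear and a
#'   `crew` column of pro-rata FTE
#' @export
read_register <- function(path, gear_map = default_gear_map()) {
  if (!file.exists(path)) stop("register file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(vessel_id = "character"))
  validate_register(reg, gear_map)
}

#' @rdname read_register
#' @param register a register data frame
#' @export
validate_register <- function(register, gear_map = default_gear_map()) {
  need <- c("vessel_id", "port", "gear", "length_m", "crew_fulltime")
  miss <- setdiff(need, names(register))
  if (length(miss) > 0) stop("register missing column(s): ", paste(miss, collapse = ", "))
  if (!"seasonal_crew" %in% names(register)) register$seasonal_crew <- ""
  if (!"active" %in% names(register)) register$active <- TRUE
  if (!"interviewed" %in% names(register)) register$interviewed <- FALSE
  register$seasonal_crew[is.na(register$seasonal_crew)] <- ""
  register$active <- as.logical(register$active)
  register$interviewed <- as.logical(register$interviewed)
  if (anyDuplicated(register$vessel_id))
    stop("duplicate vessel_id in register: ",
         paste(unique(register$vessel_id[duplicated(register$vessel_id)]), collapse = ", "))
  bad <- which(!is.finite(register$length_m) | register$length_m <= 0)
  if (length(bad) > 0)
    stop("non-positive vessel length at row(s) ", paste(bad, collapse = ", "),
         " (vessel ", paste(register$vessel_id[bad], collapse = ", "), ")")
  register$gear <- normalize_gear(register$gear, gear_map)
  register$crew <- pro_rata_crew(register$crew_fulltime, register$seasonal_crew)
  register
}

#' The default eight-category vessel scheme
#'
#' Length classes (metres, half-open) with a gear split for 9 to <10 m boats
#' (pots carry fewer crew than trawl/dredge boats of the same size) and a
#' dedicated pelagic category at any length (pelagic crews, 8-10, dwarf all
#' others). Rows are evaluated in order and the first match wins, which is how
#' pelagic gear overrides the length classes.
#'
#' @return a `category_scheme` data frame with columns id, lo, hi, gear,
#'   gear_negate, class_index
#' @export
default_category_scheme <- function() {
  s <- data.frame(
    id = c("pelagic", "<7m", "7-<9m", "9-<10m pots", "9-<10m non-pots",
           "10-<15m", "15-<20m", ">=20m non-pelagic"),
    lo = c(0, 0, 7, 9, 9, 10, 15, 20),
    hi = c(Inf, 7, 9, 10, 10, 15, 20, Inf),
    gear = c("pelagic", NA, NA, "pots", "pots", NA, NA, NA),
    gear_negate = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    class_index = c(0L, 1L, 2L, 3L, 3L, 4L, 5L, 6L),
    stringsAsFactors = FALSE)
  class(s) <- c("category_scheme", "data.frame")
  s
}

#' Assign vessels to categories
#'
#' @param gear,length_m vectors of primary gear and length in metres
#' @param scheme a category scheme (see [default_category_scheme()])
#' @return character vector of category ids
#' @export
categorize <- function(gear, length_m, scheme = default_category_scheme()) {
  n <- max(length(gear), length(length_m))
  gear <- rep_len(gear, n); length_m <- rep_len(length_m, n)
  out <- rep(NA_character_, n)
  for (r in seq_len(nrow(scheme))) {
    g <- scheme$gear[r]
    gm <- if (is.na(g)) rep(TRUE, n)
          else if (scheme$gear_negate[r]) gear != g else gear == g
    hit <- is.na(out) & gm & length_m >= scheme$lo[r] & length_m < scheme$hi[r]
    out[hit] <- scheme$id[r]
  }
  if (anyNA(out)) {
    gaps <- unique(paste0("(", gear[is.na(out)], ", ", length_m[is.na(out)], " m)"))
    stop("category scheme does not cover: ", paste(gaps, collapse = ", "))
  }
  out
}

#' Mean pro-rata crew per category from the interview sample
#'
#' @param register validated register (uses interviewed vessels only)
#' @param scheme category scheme
#' @return named numeric vector, mean FTE crew per sampled category
#' @export
category_mean_crew <- function(register, scheme = default_category_scheme()) {
  smp <- register[register$interviewed, , drop = FALSE]
  if (nrow(smp) == 0) stop("no interviewed vessels in register")
  cat <- categorize(smp$gear, smp$length_m, scheme)
  tapply(smp$crew, cat, mean)
}

combo_id <- function(port, gear, length_class) {
  paste(port, gear, length_class, sep = "|")
}

#' Build the port x gear x length-class combination table
#'
#' For every combination with at least one active vessel: `n_vessels` (active
#' register count), `E` = n_vessels x category mean crew estimated from the
#' interview sample, and `S` = summed pro-rata crew of interviewed vessels in
#' the combination. Categories holding active vessels but no interviewed
#' vessel anywhere in the fleet cannot be estimated and raise an error.
#'
#' @param register validated register
#' @param scheme category scheme
#' @return a `combo_table` data frame (combo, port, gear, length_class,
#'   class_index, n_vessels, mean_crew, E, S)
#' @export
build_combo_table <- function(register, scheme = default_category_scheme()) {
  act <- register[register$active, , drop = FALSE]
  if (nrow(act) == 0) stop("register has no active vessels")
  act$length_class <- categorize(act$gear, act$length_m, scheme)
  catmean <- category_mean_crew(register, scheme)
  missing_cat <- setdiff(unique(act$length_class), names(catmean))
  if (length(missing_cat) > 0)
    stop("no interviewed vessel in category(ies): ",
         paste(missing_cat, collapse = ", "),
         "; cannot estimate mean crew")
  key <- combo_id(act$port, act$gear, act$length_class)
  first <- !duplicated(key)
  tab <- data.frame(combo = key[first],
                    port = act$port[first],
                    gear = act$gear[first],
                    length_class = act$length_class[first],
                    stringsAsFactors = FALSE)
  tab$class_index <- scheme$class_index[match(tab$length_class, scheme$id)]
  tab$n_vessels <- as.vector(table(key)[tab$combo])
  tab$mean_crew <- unname(catmean[tab$length_class])
  tab$E <- tab$n_vessels * tab$mean_crew
  sampled <- act[act$interviewed, , drop = FALSE]
  skey <- combo_id(sampled$port, sampled$gear, sampled$length_class)
  ssum <- tapply(sampled$crew, skey, sum)
  tab$S <- ifelse(tab$combo %in% names(ssum), unname(ssum[tab$combo]), 0)
  tab <- tab[order(tab$port, tab$gear, tab$class_index), ]
  rownames(tab) <- NULL
  class(tab) <- c("combo_table", "data.frame")
  tab
}
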