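test_that("an identity sample is indistinguishable from the fleet", {
  pop <- small_pop()
  rep <- representativeness(pop$register)
  expect_lt(abs(rep$length_test$statistic), 1e-8)
  expect_gt(rep$length_test$p.value, 0.999)
  expect_lt(rep$port_test$statistic, 1e-8)
  expect_lt(rep$gear_test$statistic, 1e-8)
  expect_true(all(rep$coverage_gear$percent == 100))
})

test_that("chi-squared matches the textbook formula on a two-stratum toy", {
  # population 30/70, sample 10/10: X2 = sum (O-E)^2/E with E = (6, 14)
  obs <- c(10, 10); pop <- c(30, 70)
  got <- sapm:::chisq_sample_vs_population(obs, pop)
  expected <- sum(obs) * pop / sum(pop)
  expect_equal(got$statistic, sum((obs - expected)^2 / expected))
  expect_equal(got$df, 1)
  # invariant to stratum ordering
  got_rev <- sapm:::chisq_sample_vs_population(rev(obs), rev(pop))
  expect_equal(got_rev$statistic, got$statistic)
})

test_that("pooled t-test matches the closed form on a toy", {
  a <- c(1, 1, 2); b <- c(2, 2, 3)
  reg <- mk_register(
    list(port = "p", gear = "pots", len = 9.5, ft = 1),
    list(port = "p", gear = "pots", len = 9.5, ft = 1),
    list(port = "p", gear = "pots", len = 9.5, ft = 2),
    list(port = "p", gear = "nephrops_trawl", len = 9.5, ft = 2),
    list(port = "p", gear = "nephrops_trawl", len = 9.5, ft = 2),
    list(port = "p", gear = "nephrops_trawl", len = 9.5, ft = 3))
  got <- crew_gear_difference(reg, lo = 9, hi = 10, gear = "pots")
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$df, 4) # n1 + n2 - 2
  expect_equal(got$p.value, 2 * stats::pt(-abs(t_hand), 4))
  # identical groups: t = 0 by symmetry
  rege <- mk_register(
    list(port = "p", gear = "pots", len = 9.5, ft = 1),
    list(port = "p", gear = "pots", len = 9.5, ft = 2),
    list(port = "p", gear = "nephrops_trawl", len = 9.5, ft = 1),
    list(port = "p", gear = "nephrops_trawl", len = 9.5, ft = 2))
  expect_equal(crew_gear_difference(rege)$statistic, 0)
  expect_error(crew_gear_difference(reg, lo = 20, hi = 30), "at least two")
})

test_that("the crew t-test detects a true gear gap at reasonable power", {
  set.seed(31)
  rejections <- 0
  reps <- 150
  for (r in seq_len(reps)) {
    a <- stats::rnorm(8, 1.2, 0.5) # pot crews
    b <- stats::rnorm(8, 2.7, 0.5) # trawl crews of the same size class
    ht <- stats::t.test(a, b, var.equal = TRUE)
    rejections <- rejections + (ht$p.value < 0.05)
  }
  # effect of 3 sd at n = 8 per group: power is near 1
  expect_gt(rejections / reps, 0.95)
})

test_that("stratum coverage reproduces the printed-percentage convention", {
  # a stratum with 23 active vessels of which 13 interviewed -> 56.5%
  strata <- c(rep("dn", 23), rep("other", 5))
  int <- c(rep(TRUE, 13), rep(FALSE, 10), rep(TRUE, 3), rep(FALSE, 2))
  rows <- lapply(seq_along(strata), function(i)
    list(port = "p", gear = "pots", len = 6, ft = 1, int = int[i]))
  reg <- do.call(mk_register, rows)
  cov <- coverage_table(reg, by = strata)
  expect_equal(cov$percent[cov$stratum == "dn"], 56.5)
})

test_that("port grouping merges strata before the chi-squared test", {
  pop <- small_pop()
  smp <- draw_interviews(pop, seed = 9)
  ports <- sort(unique(smp$register$port))
  grouping <- list(minor = ports[-(1:2)])
  rep <- representativeness(smp$register, port_grouping = grouping)
  expect_equal(rep$port_test$df, 2) # two kept ports + "minor"
  expect_true(rep$port_test$p.value >= 0 && rep$port_test$p.value <= 1)
})

test_that("within-combination overlap follows the Jaccard geometry", {
  reg <- mk_register(
    list(port = "p", gear = "pots", len = 6, ft = 1),
    list(port = "p", gear = "pots", len = 6, ft = 1),
    list(port = "p", gear = "gill_net", len = 6, ft = 1),
    list(port = "p", gear = "gill_net", len = 6, ft = 1),
    list(port = "p", gear = "nephrops_trawl", len = 12, ft = 2))
  rs <- mk_responses(reg,
    list(vessel = "V01", geom = sq(0, 0, 1000)),
    list(vessel = "V02", geom = sq(0, 0, 1000)),          # identical -> 1
    list(vessel = "V03", geom = sq(5000, 0, 1000), fishery = "other"),
    list(vessel = "V04", geom = sq(9000, 0, 1000), fishery = "other"), # disjoint -> 0
    list(vessel = "V05", geom = sq(0, 5000, 1000), fishery = "nephrops")) # singleton
  ov <- within_combo_overlap(rs, reg)
  expect_equal(nrow(ov), 2) # singleton combo skipped
  expect_equal(ov$mean_jaccard[ov$combo == "p|pots|<7m"], 1)
  expect_equal(ov$mean_jaccard[ov$combo == "p|gill_net|<7m"], 0)
  # two unit squares overlapping half -> 1/3
  rs2 <- mk_responses(reg,
    list(vessel = "V01", geom = sq(0, 0, 1000)),
    list(vessel = "V02", geom = sq(500, 0, 1000)))
  ov2 <- within_combo_overlap(rs2, reg)
  expect_equal(ov2$mean_jaccard, 1 / 3)
})

test_that("generated fleets overlap as the range model intends", {
  pop <- small_pop()
  ov <- within_combo_overlap(pop$responses, pop$register)
  cmb <- do.call(rbind, strsplit(ov$combo, "|", fixed = TRUE))
  trawl <- ov$mean_jaccard[cmb[, 2] == "nephrops_trawl"]
  expect_gt(mean(trawl), 0.4) # shared combo core -> high overlap
  # pot footprints from different ports barely overlap
  pots <- pop$responses[pop$responses$fishery == "pots", ]
  reg <- pop$register
  ports <- reg$port[match(pots$vessel_id, reg$vessel_id)]
  pA <- do.call(c, pots$geometry[ports == unique(ports)[1]])
  pB <- do.call(c, pots$geometry[ports == unique(ports)[2]])
  expect_lt(geom_jaccard(pA, pB, cell = 500), 0.05)
})

test_that("effort congruency counts covered effort cells", {
  g <- sapm_grid(0, 0, 4, 1, cell = 1000)
  pri <- new_raster(g, values = matrix(c(1, 2, 0, 0), 1),
                    touched = matrix(c(TRUE, TRUE, TRUE, FALSE), 1))
  eff <- new_raster(g, values = matrix(c(3, 0, 5, 0), 1),
                    touched = matrix(TRUE, 1, 4))
  got <- effort_congruency(pri, eff)
  expect_equal(got$n_effort_cells, 2)
  expect_equal(got$coverage, 0.5) # cell 1 covered, cell 3 not
  # containment -> 1; disjoint -> 0
  eff1 <- new_raster(g, values = matrix(c(3, 1, 0, 0), 1),
                     touched = matrix(TRUE, 1, 4))
  expect_equal(effort_congruency(pri, eff1)$coverage, 1)
  eff0 <- new_raster(g, values = matrix(c(0, 0, 5, 2), 1),
                     touched = matrix(TRUE, 1, 4))
  expect_equal(effort_congruency(pri, eff0)$coverage, 0)
  expect_error(effort_congruency(pri, new_raster(sapm_grid(0, 0, 2, 1))),
               "different grids")
})

test_that("effort congruency matches brute-force enumeration on random rasters", {
  set.seed(41)
  g <- sapm_grid(0, 0, 12, 9, cell = 1000)
  for (rep in 1:5) {
    pv <- matrix(stats::rbinom(108, 1, 0.5) * stats::runif(108), 9, 12)
    ev <- matrix(stats::rbinom(108, 1, 0.4) * stats::runif(108), 9, 12)
    pri <- new_raster(g, values = pv, touched = matrix(TRUE, 9, 12))
    eff <- new_raster(g, values = ev, touched = matrix(TRUE, 9, 12))
    if (sum(ev > 0) == 0) next
    got <- effort_congruency(pri, eff)
    brute <- sum(pv > 0 & ev > 0) / sum(ev > 0)
    expect_equal(got$coverage, brute)
  }
  # monotone in priority support growth
  pv <- matrix(stats::runif(108) * (stats::runif(108) < 0.3), 9, 12)
  ev <- matrix(stats::runif(108), 9, 12)
  pri1 <- new_raster(g, values = pv, touched = matrix(TRUE, 9, 12))
  pv2 <- pv; pv2[pv2 == 0][1:20] <- 0.5
  pri2 <- new_raster(g, values = pv2, touched = matrix(TRUE, 9, 12))
  eff <- new_raster(g, values = ev, touched = matrix(TRUE, 9, 12))
  expect_gte(effort_congruency(pri2, eff)$coverage,
             effort_congruency(pri1, eff)$coverage)
})
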