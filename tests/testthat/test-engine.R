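test_that("SAP density is crew x importance / area", {
  expect_equal(sap_density(1, 100, 10), 10) # a tenth of a fisher per km^2
  expect_equal(sap_density(1, 0, 10), 0)
  expect_error(sap_density(1, 100, 0), "positive")
  # any importance partition summing to 100 gives a boat total of 100 x crew
  imp <- c(12.5, 37.5, 50)
  areas <- c(2, 5, 11.3)
  expect_equal(sum(sap_density(4.5, imp, areas) * areas), 450)
})

test_that("per-respondent SAP conservation holds on generated data", {
  pop <- small_pop()
  rs <- pop$responses
  crew <- pop$register$crew[match(rs$vessel_id, pop$register$vessel_id)]
  d <- sap_density(crew, rs$importance, rs$area_km2)
  key <- paste(rs$respondent_id, rs$vessel_id)
  tot <- tapply(d * rs$area_km2, key, sum)
  want <- tapply(100 * crew, key, function(x) x[1])
  expect_equal(as.vector(tot), as.vector(want[names(tot)]), tolerance = 1e-9)
})

test_that("weight arithmetic matches hand computation", {
  # E = 6.0 (3 vessels x mean 2.0), S = 2.0 sampled -> W = 3.0; scaling the
  # sample by W recovers the whole stratum: W x S = E
  reg <- mk_register(
    list(port = "p1", gear = "pots", len = 6, ft = 2, int = TRUE),
    list(port = "p1", gear = "pots", len = 6, ft = 2, int = FALSE),
    list(port = "p1", gear = "pots", len = 6, ft = 2, int = FALSE))
  w <- compute_weights(build_combo_table(reg))
  expect_equal(w$E, 6)
  expect_equal(w$S, 2)
  expect_equal(w$W, 3)
  # census: every vessel interviewed -> all W = 1
  pop <- small_pop()
  wc <- compute_weights(build_combo_table(pop$register))
  expect_true(all(abs(wc$W - 1) < 1e-12))
})

test_that("donor fallback conserves total estimated crew", {
  # sampled combo A (E=4, S=2) absorbs unsampled same-port same-gear B (E=2):
  # W_A = (E_A + E_B) / S_A = 3, and total E is conserved
  reg2 <- mk_register(
    list(port = "p1", gear = "pots", len = 6, ft = 2, int = TRUE),
    list(port = "p1", gear = "pots", len = 6, ft = 2, int = FALSE),
    list(port = "p1", gear = "pots", len = 8, ft = 2, int = FALSE),
    list(port = "p2", gear = "pots", len = 8, ft = 2, int = TRUE))
  tab2 <- build_combo_table(reg2)
  w2 <- compute_weights(tab2)
  a <- w2[w2$port == "p1" & w2$length_class == "<7m", ]
  b <- w2[w2$port == "p1" & w2$length_class == "7-<9m", ]
  expect_equal(a$E, 4); expect_equal(a$S, 2)
  expect_equal(b$E, 2) # one vessel x category mean crew 2
  expect_equal(a$W, (4 + 2) / 2)
  expect_true(is.na(b$W))
  expect_equal(b$donor, a$combo)
  expect_true(b$combo %in% a$represents[[1]])
  # conservation: sum(W x S) over sampled == sum(E) over all
  sampled <- w2$S > 0
  expect_equal(sum(w2$W[sampled] * w2$S[sampled]), sum(w2$E), tolerance = 1e-12)
})

test_that("donor ties break toward the smaller length class", {
  reg <- mk_register(
    list(port = "p1", gear = "nephrops_trawl", len = 12, ft = 2, int = TRUE), # class idx 4
    list(port = "p1", gear = "nephrops_trawl", len = 22, ft = 2, int = TRUE), # class idx 6
    list(port = "p1", gear = "nephrops_trawl", len = 16, ft = 2, int = FALSE), # class idx 5
    list(port = "p2", gear = "nephrops_trawl", len = 16, ft = 2, int = TRUE))
  w <- compute_weights(build_combo_table(reg))
  unsampled <- w[w$S == 0, ]
  expect_equal(nrow(unsampled), 1)
  expect_equal(unsampled$donor,
               w$combo[w$port == "p1" & w$length_class == "10-<15m"])
})

test_that("nearest-port fallback uses configured coordinates", {
  pc <- data.frame(port = c("p1", "p2", "p3"), x = c(0, 10000, 50000), y = 0)
  reg <- mk_register(
    list(port = "p1", gear = "pots", len = 6, ft = 1, int = FALSE),
    list(port = "p2", gear = "pots", len = 6, ft = 1, int = TRUE),
    list(port = "p3", gear = "pots", len = 6, ft = 1, int = TRUE))
  w <- compute_weights(build_combo_table(reg), port_coords = pc)
  expect_equal(w$donor[w$port == "p1"], w$combo[w$port == "p2"])
  # same with a coastal sequence instead of coordinates
  w2 <- compute_weights(build_combo_table(reg),
                        coastal_order = c("p1", "p2", "p3"))
  expect_equal(w2$donor[w2$port == "p1"], w2$combo[w2$port == "p2"])
  # neither given -> instructive error
  expect_error(compute_weights(build_combo_table(reg)), "port_coords")
})

test_that("a gear with no samples fleet-wide cannot be upscaled", {
  reg <- mk_register(
    list(port = "p1", gear = "pots", len = 6, ft = 1, int = TRUE),
    list(port = "p1", gear = "gill_net", len = 6, ft = 1, int = FALSE))
  expect_error(compute_weights(build_combo_table(reg)), "gill_net.*cannot upscale")
})

test_that("weighted layers scale linearly and conserve fleet SAP", {
  pop <- small_pop()
  smp <- draw_interviews(pop, seed = 5)
  tab <- compute_weights(build_combo_table(smp$register),
                         port_coords = smp$port_coords)
  layers <- weight_responses(smp$responses, smp$register, tab)
  expect_equal(layers$weighted_density, layers$weight * layers$sap_density)
  # fleet conservation, exact in vector space
  expect_equal(total_sap(layers), 100 * sum(tab$E), tolerance = 1e-9)
  # census: W = 1 everywhere makes weighted = unweighted
  tabc <- compute_weights(build_combo_table(pop$register))
  layc <- weight_responses(pop$responses, pop$register, tabc)
  expect_equal(layc$weighted_density, layc$sap_density, tolerance = 1e-12)
  # doubling every register count doubles E and every weighted density
  tab2 <- tab
  tab2$n_vessels <- tab2$n_vessels * 2
  tab2$E <- tab2$n_vessels * tab2$mean_crew
  tab2 <- compute_weights(tab2[setdiff(names(tab2), c("W", "donor", "represents"))],
                          port_coords = smp$port_coords)
  layers2 <- weight_responses(smp$responses, smp$register, tab2)
  expect_equal(layers2$weighted_density, 2 * layers$weighted_density,
               tolerance = 1e-12)
})

test_that("weight monotonicity: more vessels never lowers a combo's map", {
  pop <- small_pop()
  smp <- draw_interviews(pop, seed = 5)
  tab <- build_combo_table(smp$register)
  w1 <- compute_weights(tab, port_coords = smp$port_coords)
  l1 <- weight_responses(smp$responses, smp$register, w1)
  tab2 <- tab
  i <- which.max(tab2$S)
  tab2$n_vessels[i] <- tab2$n_vessels[i] + 5
  tab2$E <- tab2$n_vessels * tab2$mean_crew
  w2 <- compute_weights(tab2, port_coords = smp$port_coords)
  l2 <- weight_responses(smp$responses, smp$register, w2)
  sel <- l1$combo == tab$combo[i]
  expect_true(all(l2$weighted_density[sel] >= l1$weighted_density[sel] - 1e-12))
})

test_that("processor employment is folded into E proportionally", {
  reg <- mk_register(
    list(port = "p1", gear = "nephrops_trawl", len = 12, ft = 2, int = TRUE),
    list(port = "p2", gear = "nephrops_trawl", len = 12, ft = 2, int = TRUE))
  tab <- build_combo_table(reg)
  expect_equal(adapt_processors(tab, c(nephrops = 0))$E, tab$E)
  # 500 FTE over two equal-E combos -> +250 each
  tab2 <- adapt_processors(tab, c(nephrops = 500))
  expect_equal(tab2$E, tab$E + 250)
  expect_equal(sum(tab2$E), sum(tab$E) + 500)
  expect_error(adapt_processors(tab, c(whitefish = 10)), "whitefish")
  # random allocation conserves totals
  pop <- small_pop()
  tabp <- build_combo_table(pop$register)
  fte <- c(nephrops = 321.5, pots = 77.25)
  expect_equal(sum(adapt_processors(tabp, fte)$E), sum(tabp$E) + sum(fte),
               tolerance = 1e-9)
})

test_that("landings-value weighting rescales layers per fishery", {
  pop <- small_pop()
  tab <- compute_weights(build_combo_table(pop$register))
  layers <- weight_responses(pop$responses, pop$register, tab)
  fisheries <- unique(layers$fishery)
  ones <- stats::setNames(rep(1, length(fisheries)), fisheries)
  same <- adapt_landings(layers, landed_value = ones, fishers = ones)
  expect_equal(same$weighted_density, layers$weighted_density)
  # value 1000 over 10 fishers -> x100
  v <- stats::setNames(rep(1000, length(fisheries)), fisheries)
  f10 <- stats::setNames(rep(10, length(fisheries)), fisheries)
  scaled <- adapt_landings(layers, v, f10)
  expect_equal(scaled$weighted_density, 100 * layers$weighted_density)
  # two-fishery toy by hand: nephrops x50, pots x5
  sel <- layers$fishery %in% c("nephrops", "pots")
  toy <- adapt_landings(layers[sel, ],
                        c(nephrops = 500, pots = 25),
                        c(nephrops = 10, pots = 5))
  want <- ifelse(layers$fishery[sel] == "nephrops", 50, 5)
  expect_equal(toy$weighted_density, want * layers$weighted_density[sel])
  expect_error(adapt_landings(layers, c(nephrops = 10), c(nephrops = 0)),
               "fisher")
})
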