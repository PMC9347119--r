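test_that("the biofilm exchange pattern is reproduced on the default toy", {
  sol <- default_solution()
  cm <- default_community()
  ex <- extract_exchanges(sol, cm)

  # every species imports hydrogen
  h2 <- ex[ex$metabolite == "h2", ]
  expect_setequal(h2$species_id, cm$species$species_id)
  expect_true(all(h2$flux_species < 0))

  # methane is produced by exactly one species, the methanogen
  ch4 <- ex[ex$metabolite == "ch4" & ex$flux_species > 0, ]
  expect_identical(ch4$species_id, "sp02_methanogen")

  # formate is imported only by the methanogen
  formate_in <- ex[ex$metabolite == "for" & ex$flux_species < 0, ]
  expect_identical(formate_in$species_id, "sp02_methanogen")

  # the acetogen is the largest CO2 consumer
  co2 <- ex[ex$metabolite == "co2", ]
  expect_identical(co2$species_id[which.min(co2$flux_community)],
                   "sp01_acetogen")

  # VFA accumulation is zero while interspecies acetate flux persists
  ac <- ex[ex$metabolite == "ac", ]
  expect_equal(sum(ac$flux_community), 0, tolerance = 1e-6)
  expect_gt(max(ac$flux_community), 0.3)
})

test_that("extract_exchanges demands an optimal solution and drops zero rows", {
  cm <- default_community()
  bad <- structure(list(status = "infeasible"), class = "tradeoff_solution")
  expect_error(extract_exchanges(bad, cm), "optimal")
  # a community with a closed substrate yields an all-zero solution
  cz <- capped_pair()
  cz <- set_community_exchange_bounds(cz, "s", lb = 0)
  solz <- cooperative_tradeoff(cz)
  expect_identical(solz$status, "optimal")
  expect_equal(nrow(extract_exchanges(solz, cz)), 0)
})

test_that("proportional allocation conserves flow and honours the threshold", {
  tab <- data.frame(
    species_id = c("p1", "c1"), metabolite = "m",
    flux_species = c(2, -2), flux_community = c(2, -2),
    stringsAsFactors = FALSE
  )
  net <- build_network(tab, threshold = 0)
  expect_equal(nrow(net), 1)
  expect_equal(net$flux, 2)
  expect_identical(c(net$from, net$to), c("p1", "c1"))

  tab2 <- data.frame(
    species_id = c("p1", "p2", "c1"), metabolite = "m",
    flux_species = c(2, 1, -3), flux_community = c(2, 1, -3),
    stringsAsFactors = FALSE
  )
  net2 <- build_network(tab2, threshold = 0)
  expect_equal(sort(net2$flux), c(1, 2))   # proportional split

  # surplus routes to the medium node, conserving flow per metabolite
  tab3 <- data.frame(
    species_id = c("p1", "c1"), metabolite = "m",
    flux_species = c(3, -1), flux_community = c(3, -1),
    stringsAsFactors = FALSE
  )
  net3 <- build_network(tab3, threshold = 0)
  expect_equal(sum(net3$flux[net3$to == "medium"]), 2)
  expect_equal(sum(net3$flux[net3$from == "p1"]), 3)

  # strict thresholding at the default 0.3
  tab4 <- data.frame(
    species_id = c("p1", "c1", "p2", "c2"), metabolite = c("x", "x", "y", "y"),
    flux_species = c(0.25, -0.25, 0.35, -0.35),
    flux_community = c(0.25, -0.25, 0.35, -0.35),
    stringsAsFactors = FALSE
  )
  net4 <- build_network(tab4)
  expect_identical(unique(net4$metabolite), "y")
  expect_error(build_network(tab4, threshold = -1), "non-negative")
})

test_that("raising the threshold only removes edges", {
  sol <- default_solution()
  ex <- extract_exchanges(sol, default_community())
  n_low <- nrow(build_network(ex, 0.1))
  n_mid <- nrow(build_network(ex, 0.3))
  n_high <- nrow(build_network(ex, 1.5))
  expect_gte(n_low, n_mid)
  expect_gte(n_mid, n_high)
  key <- function(n) paste(n$from, n$metabolite, n$to)
  expect_true(all(key(build_network(ex, 0.3)) %in% key(build_network(ex, 0.1))))
})

test_that("metabolites classify into methanogenesis, amino acid and other", {
  expect_identical(classify_metabolite("for"), "methanogenesis")
  expect_identical(classify_metabolite("formate"), "methanogenesis")
  expect_identical(classify_metabolite("ch4"), "methanogenesis")
  expect_identical(classify_metabolite("pyr"), "methanogenesis")
  expect_identical(classify_metabolite("ser__L"), "amino_acid")
  expect_identical(classify_metabolite("l-Serine"), "amino_acid")
  expect_identical(classify_metabolite("gly"), "amino_acid")
  expect_identical(classify_metabolite("spermidine"), "other")
  expect_identical(classify_metabolite("trc"), "other")
})
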