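test_that("toy-json and SBML round-trips preserve the model field by field", {
  toy <- default_toy()
  for (m in toy$models[c(1, 2)]) {
    for (ext in c(".json", ".xml")) {
      path <- withr::local_tempfile(fileext = ext)
      write_model(m, path)
      m2 <- read_model(path)
      expect_identical(m2$species_id, m$species_id)
      expect_identical(m2$metabolites$id, m$metabolites$id)
      expect_identical(m2$metabolites$compartment, m$metabolites$compartment)
      expect_identical(m2$reactions$id, m$reactions$id)
      expect_equal(m2$reactions$lb, m$reactions$lb, tolerance = 1e-12)
      expect_equal(m2$reactions$ub, m$reactions$ub, tolerance = 1e-12)
      expect_equal(m2$reactions$stoich, m$reactions$stoich,
                   tolerance = 1e-12)
      expect_identical(m2$biomass_reaction_id, m$biomass_reaction_id)
    }
  }
})

test_that("the two dialects yield identical FBA optima", {
  toy <- default_toy()
  for (m in toy$models) {
    pj <- withr::local_tempfile(fileext = ".json")
    px <- withr::local_tempfile(fileext = ".xml")
    write_model(m, pj)
    write_model(m, px)
    fj <- fba(read_model(pj))
    fx <- fba(read_model(px))
    expect_equal(fj$objective, fx$objective, tolerance = 1e-9)
    expect_equal(fj$objective, fba(m)$objective, tolerance = 1e-9)
  }
})

test_that("bounds absent from a file fall back to reversibility defaults", {
  doc <- list(
    species_id = "mini",
    metabolites = list(list(id = "a", compartment = "environment")),
    reactions = list(
      list(id = "EX_a", stoich = list(a = -1), reversible = TRUE),
      list(id = "SINK", stoich = list(a = -1))
    ),
    biomass = "SINK"
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  m <- read_model(path)
  expect_equal(m$reactions$lb, c(-1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000))
})

test_that("validate_model reports violations as data and read_model enforces them", {
  toy <- default_toy()
  good <- toy$models[[1]]
  expect_length(validate_model(good), 0)

  bad_bounds <- good
  bad_bounds$reactions$lb[2] <- 5
  bad_bounds$reactions$ub[2] <- 1
  v <- validate_model(bad_bounds)
  expect_length(v, 1)
  expect_match(v, "lower_bound > upper_bound")
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(write_model(bad_bounds, path), "invalid model")

  dup_met <- good
  dup_met$metabolites <- rbind(dup_met$metabolites, dup_met$metabolites[1, ])
  v <- validate_model(dup_met)
  expect_match(v, dup_met$metabolites$id[1], all = FALSE)

  two_met_ex <- good
  i <- which(two_met_ex$reactions$is_exchange)[1]
  two_met_ex$reactions$stoich[[i]] <-
    c(two_met_ex$reactions$stoich[[i]], atp = 1)
  v <- validate_model(two_met_ex)
  expect_match(v, "exactly one environment metabolite", all = FALSE)

  no_bio <- good
  no_bio$biomass_reaction_id <- "NOPE"
  expect_match(validate_model(no_bio), "resolves to 0", all = FALSE)
})

test_that("a model with no reactions writes and reads back", {
  m <- species_model(
    "empty", "no reactions",
    metabolites = data.frame(id = "x", name = "x",
                             compartment = "environment",
                             formula = NA_character_),
    reactions = {
      r <- data.frame(id = "BIOMASS", lb = 0, ub = 0,
                      objective_coefficient = 1)
      r$stoich <- list(c(x = -1))
      r
    },
    biomass_reaction_id = "BIOMASS"
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  expect_equal(read_model(path)$reactions$id, "BIOMASS")
})

test_that("non-integer stoichiometry is preserved exactly", {
  toy <- default_toy()
  aceto <- toy$models[[1]]
  s <- aceto$reactions$stoich[[match("WLP", aceto$reactions$id)]]
  expect_equal(unname(s[["h2"]]), -0.5)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(aceto, path)
  s2 <- read_model(path)$reactions$stoich[[match("WLP",
                                                 aceto$reactions$id)]]
  expect_equal(s2[["h2"]], -0.5)
})

test_that("malformed files raise parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', path)
  expect_error(read_model(path), "missing element")
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml/>", path2)
  expect_error(read_model(path2), "no <model>")
  expect_error(read_model(tempfile()), "does not exist")
})

test_that("the synthetic methanogen grows on unconstrained H2/CO2", {
  # hand check on the lumped network: with open gas exchanges the direct
  # hydrogenotrophic route is capped at 3 mmol/gDW/h and formate at 6,
  # giving at most (0.5*3 + 0.4*6)*jitter ATP; biomass costs 20 ATP per
  # unit growth, so mu ~= (1.5 + 2.4)/20 ~= 0.195.
  meth <- default_toy()$models[[2]]
  expect_identical(meth$species_id, "sp02_methanogen")
  f <- fba(meth)
  expect_identical(f$status, "optimal")
  expect_gt(f$objective, 0.15)
  expect_lt(f$objective, 0.25)
})
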