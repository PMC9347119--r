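test_that("the default five-guild community has the expected exchange topology", {
  toy <- default_toy()
  expect_length(toy$models, 5)
  expect_equal(toy$abundances$fraction, c(0.33, 0.26, 0.20, 0.11, 0.10))

  has_rxn <- function(m, id) id %in% m$reactions$id
  ch4 <- vapply(toy$models, has_rxn, logical(1), id = "EX_ch4")
  expect_equal(which(ch4), 2L)  # the methanogen, and only the methanogen

  # formate: importable only by the methanogen, export-only for bacteria
  for (i in seq_along(toy$models)) {
    rx <- toy$models[[i]]$reactions
    j <- match("EX_for", rx$id)
    if (is.na(j)) next
    if (i == 2) expect_lt(rx$lb[j], 0) else expect_gte(rx$lb[j], 0)
  }

  # the acetogen exchanges all seven cross-fed amino acids
  aceto <- toy$models[[1]]
  aa7 <- c("glu__L", "asp__L", "gln__L", "ser__L", "thr__L", "ala__L", "gly")
  expect_true(all(paste0("EX_", aa7) %in% aceto$reactions$id))

  # H2 exchanges are import-only everywhere
  for (m in toy$models) {
    j <- match("EX_h2", m$reactions$id)
    expect_equal(m$reactions$ub[j], 0)
  }
  # every model validates
  for (m in toy$models) expect_length(validate_model(m), 0)
})

test_that("the generator is deterministic in the seed", {
  expect_identical(make_toy_community(), make_toy_community())
  b1 <- community_blueprint(seed = 1)
  b2 <- community_blueprint(seed = 2)
  expect_false(identical(make_toy_community(b1), make_toy_community(b2)))
})

test_that("blueprint validation rejects bad compositions", {
  expect_error(community_blueprint(abundances = c(0.5, 0.6, 0.1, 0.1, 0.1)),
               "sum to 1")
  expect_error(community_blueprint(archetypes = c("methanogen", "methanogen"),
                                   abundances = c(0.5, 0.5)),
               "methanogen")
  expect_error(community_blueprint(archetypes = c("dragon"),
                                   abundances = 1),
               "unknown archetype")
})

test_that("a methanogen-acetogen pair is solvable on the toy medium", {
  bp <- community_blueprint(archetypes = c("acetogen", "methanogen"),
                            abundances = c(0.6, 0.4))
  toy <- make_toy_community(bp)
  cm <- build_community(toy$models, toy$abundances)
  cm <- suppressWarnings(apply_medium(cm, recipe_to_bounds(make_toy_medium())))
  # the medium alone carries no electron donor, so the optimum is zero
  # growth, but the model is feasible
  f <- fba(cm)
  expect_identical(f$status, "optimal")
  # with gas made available, the pair grows
  cm <- set_community_exchange_bounds(cm, "h2", lb = -20)
  cm <- set_community_exchange_bounds(cm, "co2", lb = -20)
  expect_gt(fba(cm)$objective, 0)
})

test_that("dropping the methanogen makes the methane constraint unsatisfiable", {
  bp <- community_blueprint(
    archetypes = c("acetogen", "vfa_consumer", "fermenter", "fermenter"),
    abundances = c(0.4, 0.3, 0.2, 0.1)
  )
  toy <- make_toy_community(bp)
  cm <- build_community(toy$models, toy$abundances)
  cm <- suppressWarnings(apply_medium(cm, recipe_to_bounds(make_toy_medium())))
  # no species carries a CH4 exchange, so pinning the operating point
  # already fails to find the methane exchange
  expect_error(apply_operating_point(cm, operating_point()),
               "no community exchange for metabolite 'ch4'")
})

test_that("methane carbon export never exceeds community carbon uptake", {
  carbon <- c(co2 = 1, "for" = 1, ac = 2, ppa = 3, but = 4, ch4 = 1,
              glu__L = 5, asp__L = 4, gln__L = 5, ser__L = 3, thr__L = 4,
              ala__L = 3, gly = 2)
  sol <- default_solution()
  cm <- default_community()
  ex <- community_exchanges(cm)
  fl <- unname(sol$fluxes[ex$id])
  cvec <- ifelse(ex$metabolite %in% names(carbon), carbon[ex$metabolite], 0)
  carbon_uptake <- sum(-pmin(fl, 0) * cvec)   # imports are negative fluxes
  ch4_out <- fl[match("ch4", ex$metabolite)]
  expect_lte(ch4_out, carbon_uptake + 1e-6)
})

test_that("the toy medium is a mineral medium with dissolved CO2", {
  rec <- make_toy_medium()
  ids <- rec$components$compound_id
  expect_true(all(c("h2o", "co2") %in% ids))
  expect_false(any(c("glc", "glucose", "ac", "acetate") %in% ids))
  # concentrations span at least three orders of magnitude (water aside)
  conc <- rec$components$concentration[ids != "h2o"]
  expect_gte(log10(max(conc) / min(conc)), 3)
  expect_identical(make_toy_medium(), make_toy_medium())
})

test_that("planted coverage correlations are recovered at scale", {
  bp <- coverage_blueprint(n_mags = 8, n_experiments = 500, replicates = 1,
                           correlation_blocks = list(
                             list(members = c("mag01", "mag02"), r = 0.96)
                           ), seed = 11)
  cv <- make_coverage_matrix(bp)
  expect_true(all(cv$values >= 0))
  r <- pearson_matrix(cv)$r
  expect_gte(r["mag01", "mag02"], 0.91)
  expect_lte(r["mag01", "mag02"], 1.0)
  # unplanted pairs stay near zero at this sample size
  expect_lt(max(abs(r["mag05", c("mag06", "mag07", "mag08")])), 0.2)
})

test_that("coverage generation is seed-deterministic and rejects impossible targets", {
  expect_identical(make_coverage_matrix(), make_coverage_matrix())
  bp <- coverage_blueprint(correlation_blocks = list(
    list(members = c("mag01", "mag02"), r = -0.9)), noise_sd = 2)
  expect_error(make_coverage_matrix(bp), "infeasible")
  expect_error(coverage_blueprint(correlation_blocks = list(
    list(members = c("mag01", "mag02"), r = 1.2))), "target r")
})
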