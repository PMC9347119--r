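# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_toy <- function() {
  fixture("toy", function() make_toy_community())
}

# five-guild community under medium + reactor operating point
default_community <- function() {
  fixture("community", function() {
    toy <- default_toy()
    cm <- build_community(toy$models, toy$abundances)
    cm <- suppressWarnings(apply_medium(cm, recipe_to_bounds(make_toy_medium())))
    apply_operating_point(cm, operating_point())
  })
}

default_solution <- function() {
  fixture("solution", function() cooperative_tradeoff(default_community(),
                                                      f = 0.5))
}

# medium applied, VFA pinned, gases left free (sweep configuration)
sweep_community <- function() {
  fixture("sweep_community", function() {
    toy <- default_toy()
    cm <- build_community(toy$models, toy$abundances)
    cm <- suppressWarnings(apply_medium(cm, recipe_to_bounds(make_toy_medium())))
    apply_operating_point(cm, operating_point(co2_uptake = NULL,
                                              h2_uptake = NULL,
                                              ch4_min_export = NULL))
  })
}

# two substrate-capped species, the analytic tradeoff configuration
capped_pair <- function(a = c(spA = 0.3, spB = 0.7), cap = 1) {
  build_community(list(make_capped_toy("spA", cap = cap),
                       make_capped_toy("spB", cap = cap)), a)
}

# simple linear chain: src -> mid -> out with a capped sink
chain_model <- function(cap = 10) {
  mets <- data.frame(
    id = c("src", "mid", "out"),
    name = c("source", "intermediate", "product"),
    compartment = c("environment", "internal", "environment"),
    formula = NA_character_, stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    id = c("EX_src", "CONV1", "CONV2", "EX_out"),
    lb = c(-1000, 0, 0, 0), ub = c(0, 1000, 1000, cap),
    objective_coefficient = c(0, 0, 0, 1), stringsAsFactors = FALSE
  )
  rxns$stoich <- list(c(src = -1), c(src = -1, mid = 1),
                      c(mid = -1, out = 1), c(out = -1))
  species_model("chain", "linear chain toy", mets, rxns,
                biomass_reaction_id = "EX_out")
}
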