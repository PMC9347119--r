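## Synthetic community, medium and coverage generators.
##
## The toy species are lumped-stoichiometry caricatures of the five
## dominant biofilm guilds: a hydrogenotrophic methanogen (the only CH4
## exporter and the only formate importer), a versatile acetogen that fixes
## CO2 into acetate and formate and trades amino acids, an acetate/
## propionate-degrading bacterium that supplies the others with glutamate
## family amino acids, and two fermenters that turn acetate into propionate
## and butyrate. Carbon is conserved by every reaction; energy is tracked
## through a lumped ATP proxy and a reduced carrier regenerated from H2, so
## that every species must import H2 to grow. Catalytic capacity caps on
## the methanogen's direct hydrogenotrophic route make the formate shuttle
## obligatory at reactor-like CH4 demands, and modest fermentation caps
## route most surplus reducing power through the acetogen's acetate
## overflow -- the cross-feeding topology the community analysis probes.

TOY <- list(
  # biomass composition (per unit growth rate, i.e. per 1/h of biomass flux)
  atp_cost = 20, red_cost = 0.5, nh4_cost = 1.0, pi_cost = 0.1,
  aa_cost = 0.05,
  # ATP yields (mol ATP per unit pathway flux)
  y_mtg_h2 = 0.5, y_mtg_for = 0.4, y_wlp = 0.2, y_fdh = 0.05,
  y_acox = 0.4, y_ppox = 0.5, y_pfer = 0.25, y_bfer = 0.3, y_butox = 0.1,
  aa_atp = 0.25,
  # catalytic capacity caps (mmol/gDW/h)
  cap_mtg_h2 = 3.0, cap_mtg_for = 6.0, cap_wlp = 2.0, cap_fdh = 6.0,
  cap_pfer = 0.1, cap_bfer = 0.05
)

ENV_MET_NAMES <- c(
  h2 = "Hydrogen", co2 = "Carbon dioxide", ch4 = "Methane",
  "for" = "Formate", ac = "Acetate", ppa = "Propionate", but = "Butyrate",
  nh4 = "Ammonium", pi = "Phosphate", h2o = "Water",
  glu__L = "l-Glutamate", asp__L = "l-Aspartate", gln__L = "l-Glutamine",
  ser__L = "l-Serine", thr__L = "l-Threonine", ala__L = "l-Alanine",
  gly = "Glycine", trc = "Inert tracer"
)

#' Blueprint for a toy syntrophic community
#'
#' @param archetypes Character vector over
#'   `{"methanogen", "acetogen", "vfa_consumer", "fermenter"}`; the default
#'   is the five-guild biofilm core. Successive fermenters alternate
#'   between a butyrate-producing and a propionate-only variant.
#' @param abundances Relative abundances, same length as `archetypes`,
#'   non-negative and summing to one (tolerance `1e-9`). The default
#'   follows the dominance ordering observed in the biofilm reactors.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param stoichiometry_scale Positive multiplier on the growth energy
#'   requirement (ATP per unit biomass).
#' @param jitter_sd Log-normal jitter applied to the pathway ATP yields to
#'   emulate reconstruction-to-reconstruction variability (default 0.01;
#'   set 0 for fully canonical stoichiometry).
#' @param allow_multiple_methanogens Permit more than one methanogen
#'   archetype (default `FALSE`).
#' @return A `community_blueprint`.
#' @export
community_blueprint <- function(archetypes = c("acetogen", "methanogen",
                                               "vfa_consumer", "fermenter",
                                               "fermenter"),
                                abundances = c(0.33, 0.26, 0.20, 0.11, 0.10),
                                seed = 42L, stoichiometry_scale = 1,
                                jitter_sd = 0.01,
                                allow_multiple_methanogens = FALSE) {
  known <- c("methanogen", "acetogen", "vfa_consumer", "fermenter")
  if (!all(archetypes %in% known)) {
    stop("unknown archetype: ",
         paste(setdiff(archetypes, known), collapse = ", "), call. = FALSE)
  }
  if (length(abundances) != length(archetypes)) {
    stop("abundances must match archetypes in length", call. = FALSE)
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must be non-negative and sum to 1", call. = FALSE)
  }
  if (!allow_multiple_methanogens && sum(archetypes == "methanogen") > 1) {
    stop("at most one methanogen unless allow_multiple_methanogens",
         call. = FALSE)
  }
  if (stoichiometry_scale <= 0) {
    stop("stoichiometry_scale must be positive", call. = FALSE)
  }
  structure(list(archetypes = archetypes, abundances = abundances,
                 seed = as.integer(seed),
                 stoichiometry_scale = stoichiometry_scale,
                 jitter_sd = jitter_sd,
                 allow_multiple_methanogens = allow_multiple_methanogens),
            class = "community_blueprint")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a toy syntrophic community
#'
#' Builds one [species_model()] per blueprint archetype plus the matching
#' abundance table. Structural guarantees: the methanogen is the only
#' species with a CH4 export and the only one able to import formate;
#' formate is export-only for the bacteria; the acetogen carries exchanges
#' for the seven cross-fed amino acids (l-Glutamate, l-Aspartate,
#' l-Glutamine, l-Serine, l-Threonine, l-Alanine, glycine); fermenters
#' export propionate (and, for the first variant, butyrate); the VFA
#' degrader imports acetate and propionate. Every reaction conserves
#' carbon, so methane carbon export can never exceed the community's
#' carbon uptake.
#'
#' @param blueprint A [community_blueprint()].
#' @return List with `models` (list of `species_model`) and `abundances`
#'   (data frame `species_id`, `fraction`).
#' @export
make_toy_community <- function(blueprint = community_blueprint()) {
  stopifnot(inherits(blueprint, "community_blueprint"))
  with_seed(blueprint$seed, {
    n <- length(blueprint$archetypes)
    ids <- sprintf("sp%02d_%s", seq_len(n), blueprint$archetypes)
    ferm_variant <- cumsum(blueprint$archetypes == "fermenter")
    models <- vector("list", n)
    for (i in seq_len(n)) {
      models[[i]] <- switch(blueprint$archetypes[i],
        methanogen = toy_methanogen(ids[i], blueprint),
        acetogen = toy_acetogen(ids[i], blueprint),
        vfa_consumer = toy_vfa_consumer(ids[i], blueprint),
        fermenter = toy_fermenter(ids[i], blueprint,
                                  variant = if (ferm_variant[i] %% 2 == 1)
                                    "butyrate" else "propionate")
      )
    }
    list(
      models = models,
      abundances = data.frame(species_id = ids,
                              fraction = blueprint$abundances,
                              stringsAsFactors = FALSE)
    )
  })
}

jittered <- function(y, blueprint) {
  y * exp(stats::rnorm(length(y), 0, blueprint$jitter_sd))
}

toy_metabolites <- function(env_ids, internal_ids = c("atp", "red")) {
  rbind(
    data.frame(id = env_ids, name = unname(ENV_MET_NAMES[env_ids]),
               compartment = "environment", formula = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = internal_ids, name = c("ATP proxy", "Reduced carrier"),
               compartment = "internal", formula = NA_character_,
               stringsAsFactors = FALSE)
  )
}

toy_reactions <- function(defs) {
  df <- data.frame(
    id = vapply(defs, `[[`, character(1), "id"),
    lb = vapply(defs, function(d) d$lb %||% 0, numeric(1)),
    ub = vapply(defs, function(d) d$ub %||% DEFAULT_BOUND, numeric(1)),
    objective_coefficient = vapply(defs, function(d) d$obj %||% 0,
                                   numeric(1)),
    stringsAsFactors = FALSE
  )
  df$stoich <- lapply(defs, `[[`, "stoich")
  df
}

ex <- function(met, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND) {
  list(id = paste0("EX_", met), stoich = stats::setNames(-1, met),
       lb = lb, ub = ub)
}

toy_biomass <- function(bp, aa_reqs = character(0)) {
  s <- c(atp = -TOY$atp_cost * bp$stoichiometry_scale,
         red = -TOY$red_cost, nh4 = -TOY$nh4_cost, pi = -TOY$pi_cost)
  if (length(aa_reqs)) {
    s <- c(s, stats::setNames(rep(-TOY$aa_cost, length(aa_reqs)), aa_reqs))
  }
  list(id = "BIOMASS", stoich = s, lb = 0, ub = DEFAULT_BOUND, obj = 1)
}

toy_methanogen <- function(id, bp) {
  y <- jittered(c(TOY$y_mtg_h2, TOY$y_mtg_for), bp)
  env <- c("h2", "co2", "ch4", "for", "glu__L", "nh4", "pi", "h2o")
  defs <- list(
    ex("h2", ub = 0), ex("co2"), ex("ch4", lb = 0), ex("for", ub = 0),
    ex("glu__L", ub = 0), ex("nh4", ub = 0), ex("pi", ub = 0), ex("h2o"),
    list(id = "MTG_H2", ub = TOY$cap_mtg_h2,
         stoich = c(h2 = -4, co2 = -1, ch4 = 1, atp = y[1])),
    list(id = "MTG_FOR", ub = TOY$cap_mtg_for,
         stoich = c("for" = -4, ch4 = 1, co2 = 3, atp = y[2])),
    list(id = "H2RED", stoich = c(h2 = -1, red = 1)),
    list(id = "ATPM", stoich = c(atp = -1)),
    toy_biomass(bp, aa_reqs = "glu__L")
  )
  species_model(id, "Methanothermobacter-like hydrogenotrophic methanogen",
                toy_metabolites(env), toy_reactions(defs), "BIOMASS")
}

toy_acetogen <- function(id, bp) {
  y <- jittered(c(TOY$y_wlp, TOY$y_fdh, TOY$y_butox), bp)
  env <- c("h2", "co2", "ac", "for", "but", "nh4", "pi", "h2o", "trc",
           "glu__L", "asp__L", "gln__L", "ser__L", "thr__L", "ala__L", "gly")
  defs <- list(
    ex("h2", ub = 0), ex("co2"), ex("ac"), ex("for", lb = 0),
    ex("but", ub = 0), ex("nh4", ub = 0), ex("pi", ub = 0), ex("h2o"),
    ex("trc"),
    ex("thr__L", ub = 0), ex("glu__L", ub = 0),           # auxotrophies
    ex("ala__L", lb = 0), ex("gly", lb = 0), ex("ser__L", lb = 0),
    ex("gln__L", lb = 0), ex("asp__L", lb = 0),           # no synthesis: stay 0
    list(id = "WLP", ub = TOY$cap_wlp,
         stoich = c(h2 = -0.5, co2 = -2, ac = 1, atp = y[1])),
    list(id = "FDH", ub = TOY$cap_fdh,
         stoich = c(h2 = -1, co2 = -1, "for" = 1, atp = y[2])),
    list(id = "BUTOX", stoich = c(but = -1, ac = 2, atp = y[3])),
    list(id = "SYN_ALA",
         stoich = c(ac = -1.5, nh4 = -1, atp = -TOY$aa_atp, ala__L = 1)),
    list(id = "SYN_GLY",
         stoich = c(ac = -1, nh4 = -1, atp = -TOY$aa_atp, gly = 1)),
    list(id = "SYN_SER",
         stoich = c(ac = -1.5, nh4 = -1, atp = -TOY$aa_atp, ser__L = 1)),
    list(id = "H2RED", stoich = c(h2 = -1, red = 1)),
    list(id = "ATPM", stoich = c(atp = -1)),
    toy_biomass(bp, aa_reqs = c("thr__L", "glu__L"))
  )
  species_model(id, "Limnochordia-like versatile acetogen",
                toy_metabolites(env), toy_reactions(defs), "BIOMASS")
}

toy_vfa_consumer <- function(id, bp) {
  y <- jittered(c(TOY$y_acox, TOY$y_ppox), bp)
  env <- c("h2", "co2", "ac", "ppa", "nh4", "pi", "h2o",
           "glu__L", "gln__L", "asp__L", "gly")
  defs <- list(
    ex("h2", ub = 0), ex("co2"), ex("ac", ub = 0), ex("ppa", ub = 0),
    ex("nh4", ub = 0), ex("pi", ub = 0), ex("h2o"),
    ex("glu__L", lb = 0), ex("gln__L", lb = 0), ex("asp__L", lb = 0),
    ex("gly", ub = 0),
    list(id = "ACOX", stoich = c(ac = -1, co2 = 2, atp = y[1])),
    list(id = "PPOX", stoich = c(ppa = -1, co2 = 3, atp = y[2])),
    list(id = "SYN_GLU",
         stoich = c(ac = -2.5, nh4 = -1, atp = -TOY$aa_atp, glu__L = 1)),
    list(id = "SYN_GLN",
         stoich = c(ac = -2.5, nh4 = -2, atp = -TOY$aa_atp, gln__L = 1)),
    list(id = "SYN_ASP",
         stoich = c(ac = -2, nh4 = -1, atp = -TOY$aa_atp, asp__L = 1)),
    list(id = "H2RED", stoich = c(h2 = -1, red = 1)),
    list(id = "ATPM", stoich = c(atp = -1)),
    toy_biomass(bp, aa_reqs = "gly")
  )
  species_model(id, "Acetomicrobium-like acetate/propionate degrader",
                toy_metabolites(env), toy_reactions(defs), "BIOMASS")
}

toy_fermenter <- function(id, bp, variant = c("butyrate", "propionate")) {
  variant <- match.arg(variant)
  y <- jittered(c(TOY$y_pfer, TOY$y_bfer), bp)
  aa_reqs <- if (variant == "butyrate") "ser__L" else c("ala__L", "gln__L")
  env <- c("h2", "co2", "ac", "ppa", "nh4", "pi", "h2o", "thr__L",
           if (variant == "butyrate") c("but", "ser__L") else
             c("ala__L", "gln__L"))
  defs <- c(
    list(
      ex("h2", ub = 0), ex("co2"), ex("ac", ub = 0), ex("ppa", lb = 0),
      ex("nh4", ub = 0), ex("pi", ub = 0), ex("h2o"), ex("thr__L", lb = 0),
      list(id = "PFER", ub = TOY$cap_pfer,
           stoich = c(ac = -1, co2 = -1, h2 = -3, ppa = 1, atp = y[1])),
      list(id = "SYN_THR",
           stoich = c(ac = -2, nh4 = -1, atp = -TOY$aa_atp, thr__L = 1)),
      list(id = "H2RED", stoich = c(h2 = -1, red = 1)),
      list(id = "ATPM", stoich = c(atp = -1))
    ),
    if (variant == "butyrate") {
      list(ex("but", lb = 0), ex("ser__L", ub = 0),
           list(id = "BFER", ub = TOY$cap_bfer,
                stoich = c(ac = -2, h2 = -2, but = 1, atp = y[2])))
    } else {
      list(ex("ala__L", ub = 0), ex("gln__L", ub = 0))
    },
    list(toy_biomass(bp, aa_reqs = aa_reqs))
  )
  species_model(id, sprintf("Firmicutes-like %s fermenter", variant),
                toy_metabolites(env), toy_reactions(defs), "BIOMASS")
}

#' Minimal substrate-capped toy species
#'
#' A one-substrate organism whose growth rate is individually capped by its
#' own uptake bound: it imports an environment metabolite `substrate` (at
#' most `cap` mmol/gDW/h) and converts one unit into one unit of biomass
#' flux. Communities of such species have no shared limiting resource, so
#' the cooperative-tradeoff growth rates follow the closed form
#' \eqn{\mu_i = f \mu^* a_i / \lVert a \rVert^2} whenever no individual cap
#' binds -- the configuration used to validate the quadratic stage against
#' analytic solutions.
#'
#' @param species_id Model id.
#' @param cap Individual uptake cap (default 1).
#' @param substrate Environment metabolite id (default `"s"`).
#' @return A `species_model`.
#' @export
make_capped_toy <- function(species_id, cap = 1, substrate = "s") {
  mets <- data.frame(id = substrate, name = "Generic substrate",
                     compartment = "environment", formula = NA_character_,
                     stringsAsFactors = FALSE)
  defs <- list(
    list(id = paste0("EX_", substrate),
         stoich = stats::setNames(-1, substrate), lb = -cap, ub = 0),
    list(id = "BIOMASS", stoich = stats::setNames(-1, substrate),
         lb = 0, ub = DEFAULT_BOUND, obj = 1)
  )
  rxns <- toy_reactions(defs)
  # the biomass drain touches a single environment metabolite, so the
  # auto-detection rule would misread it as an exchange
  rxns$is_exchange <- c(TRUE, FALSE)
  species_model(species_id, paste0("capped toy (cap ", cap, ")"),
                mets, rxns, "BIOMASS")
}

#' Toy basal anaerobic medium
#'
#' A defined mineral medium without any organic carbon source: water,
#' dissolved CO2 and ~15 inorganic components (nitrogen, phosphorus,
#' sulfur, major cations and trace metals) whose concentrations span more
#' than three orders of magnitude. The inert tracer entry is a medium
#' component no toy pathway can use, which anchors the zero-elasticity
#' controls. The recipe is deterministic.
#'
#' @return A [medium_recipe()].
#' @export
make_toy_medium <- function() {
  comp <- data.frame(
    compound_id = c("h2o", "co2", "na1", "cl", "k1", "nh4", "pi", "mg2",
                    "so4", "ca2", "trc", "fe2", "mn2", "ni2", "zn2",
                    "cobalt2", "mo", "sel"),
    name = c("Water", "Dissolved carbon dioxide", "Sodium", "Chloride",
             "Potassium", "Ammonium", "Phosphate", "Magnesium", "Sulfate",
             "Calcium", "Inert tracer", "Iron(II)", "Manganese", "Nickel",
             "Zinc", "Cobalt", "Molybdate", "Selenite"),
    concentration = c(55000, 30, 100, 90, 10, 5.6, 2.2, 2.0, 1.0, 0.75,
                      0.5, 0.1, 0.05, 0.02, 0.01, 0.01, 0.005, 0.001),
    stringsAsFactors = FALSE
  )
  medium_recipe(comp, water_id = "h2o")
}

#' Blueprint for a synthetic coverage matrix
#'
#' @param n_mags Number of MAGs (rows; default 59).
#' @param n_experiments Number of experiment identifiers (default 67).
#' @param replicates Samples per experiment (default 2, giving 134 sample
#'   columns).
#' @param correlation_blocks List of `list(members =, r =)` planting a
#'   target pairwise Pearson correlation (on the coverage scale) within a
#'   member set. Defaults plant the two strongest co-occurring pairs seen
#'   among the dominant biofilm species (r = 0.96 and r = 0.71).
#' @param noise_sd Log-scale dispersion of the coverages (default 0.5).
#' @param replicate_sd Log-scale dispersion between replicates of the same
#'   experiment (default 0.05).
#' @param seed Integer seed.
#' @return A `coverage_blueprint`.
#' @export
coverage_blueprint <- function(n_mags = 59, n_experiments = 67,
                               replicates = 2,
                               correlation_blocks = list(
                                 list(members = c("mag01", "mag02"), r = 0.96),
                                 list(members = c("mag03", "mag04"), r = 0.71)
                               ),
                               noise_sd = 0.5, replicate_sd = 0.05,
                               seed = 42L) {
  if (n_experiments < 3) stop("need at least 3 experiments", call. = FALSE)
  for (b in correlation_blocks) {
    if (abs(b$r) > 1) stop("|target r| must be <= 1", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(list(n_mags = n_mags, n_experiments = n_experiments,
                 replicates = replicates,
                 correlation_blocks = correlation_blocks,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 seed = as.integer(seed)),
            class = "coverage_blueprint")
}

# Pearson correlation between equal-dispersion log-normals as a function of
# the correlation of the underlying normals (exact):
#   r_ln = (exp(r_z s^2) - 1) / (exp(s^2) - 1).
# Inverting it lets the generator plant a target on the coverage scale.
lognormal_rz <- function(r_target, s) {
  arg <- r_target * expm1(s^2)
  if (arg <= -1) {
    stop("target r ", r_target, " infeasible at noise_sd ", s, call. = FALSE)
  }
  rz <- log1p(arg) / s^2
  if (rz > 1 + 1e-12) {
    stop("target r ", r_target, " infeasible at noise_sd ", s, call. = FALSE)
  }
  min(rz, 1)
}

#' Generate a synthetic MAG coverage matrix
#'
#' Draws experiment-level coverages from a Gaussian copula with log-normal
#' margins: correlated normal scores (block structure per the blueprint,
#' independent elsewhere) are mapped through an exponential, giving
#' non-negative, right-skewed coverages; the normal-scale block
#' correlations are pre-corrected so the *coverage-scale* Pearson
#' correlation matches the planted target. Each experiment is then
#' expanded into `replicates` sample columns with small log-normal
#' replicate noise.
#'
#' @param blueprint A [coverage_blueprint()].
#' @return A [coverage_matrix()] with samples named
#'   `<experiment>_r<replicate>` and the matching replicate map.
#' @export
make_coverage_matrix <- function(blueprint = coverage_blueprint()) {
  stopifnot(inherits(blueprint, "coverage_blueprint"))
  bp <- blueprint
  mags <- sprintf("mag%02d", seq_len(bp$n_mags))
  for (b in bp$correlation_blocks) {
    if (!all(b$members %in% mags)) {
      stop("correlation block member outside mag01..mag",
           sprintf("%02d", bp$n_mags), call. = FALSE)
    }
  }
  with_seed(bp$seed, {
    z <- matrix(stats::rnorm(bp$n_mags * bp$n_experiments),
                nrow = bp$n_mags,
                dimnames = list(mags, NULL))
    for (b in bp$correlation_blocks) {
      rz <- lognormal_rz(b$r, bp$noise_sd)
      k <- length(b$members)
      sigma <- matrix(rz, k, k); diag(sigma) <- 1
      ch <- chol(sigma)
      z[b$members, ] <- t(ch) %*% z[b$members, , drop = FALSE]
    }
    base_log <- stats::rnorm(bp$n_mags, 1, 0.5)  # MAG-specific mean coverage
    exp_vals <- exp(base_log + bp$noise_sd * z)
    exps <- sprintf("exp%03d", seq_len(bp$n_experiments))
    samples <- as.vector(t(outer(exps, seq_len(bp$replicates),
                                 function(e, r) sprintf("%s_r%d", e, r))))
    vals <- matrix(0, bp$n_mags, length(samples),
                   dimnames = list(mags, samples))
    for (j in seq_len(bp$replicates)) {
      noise <- exp(stats::rnorm(bp$n_mags * bp$n_experiments,
                                0, bp$replicate_sd))
      vals[, seq(j, by = bp$replicates,
                 length.out = bp$n_experiments)] <- exp_vals * noise
    }
    coverage_matrix(vals, stats::setNames(rep(exps, each = bp$replicates),
                                          samples))
  })
}
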