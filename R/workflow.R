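#' Configuration of a community simulation run
#'
#' Bundles every tunable of the pipeline with defaults reproducing the
#' biofilm study conditions: tradeoff fraction 0.5, exchange plot
#' threshold 0.3 mmol/gDW/h, a nine-point 0--160 mmol/gDW/h gas sweep, a
#' doubling elasticity step, and the measured reactor operating point. In
#' synthetic mode (the default) models, abundances and medium come from
#' the toy generators under `seed`; otherwise `model_paths` and
#' `abundance_path` locate them on disk.
#'
#' @param out_dir Directory where every intermediate artifact is
#'   serialized; `NULL` disables serialization.
#' @param synthetic Use the toy generators (default `TRUE`).
#' @param model_paths,abundance_path,medium_path Input locations for
#'   non-synthetic runs (models readable by [read_model()], abundances and
#'   medium as TSV).
#' @param fraction Cooperative-tradeoff fraction (default 0.5).
#' @param exchange_threshold Edge threshold in mmol/gDW/h (default 0.3).
#' @param sweep_grid Thresholds for [growth_sweep()].
#' @param elasticity_step Multiplicative elasticity step (default 2).
#' @param op An [operating_point()].
#' @param seed Seed for the synthetic generators.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir = NULL, synthetic = TRUE,
                       model_paths = NULL, abundance_path = NULL,
                       medium_path = NULL, fraction = 0.5,
                       exchange_threshold = 0.3,
                       sweep_grid = seq(0, 160, length.out = 9),
                       elasticity_step = 2.0, op = operating_point(),
                       seed = 42L) {
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 model_paths = model_paths, abundance_path = abundance_path,
                 medium_path = medium_path, fraction = fraction,
                 exchange_threshold = exchange_threshold,
                 sweep_grid = sweep_grid, elasticity_step = elasticity_step,
                 op = op, seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (config$synthetic) {
    toy <- make_toy_community(community_blueprint(seed = config$seed))
    list(models = toy$models, abundances = toy$abundances,
         recipe = make_toy_medium())
  } else {
    if (is.null(config$model_paths) || is.null(config$abundance_path)) {
      stop("non-synthetic runs need model_paths and abundance_path",
           call. = FALSE)
    }
    ab <- utils::read.table(config$abundance_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    recipe <- if (is.null(config$medium_path)) make_toy_medium() else
      read_medium_recipe(config$medium_path)
    list(models = lapply(config$model_paths, read_model),
         abundances = ab, recipe = recipe)
  }
}

constrained_community <- function(config, with_op = TRUE) {
  inputs <- load_inputs(config)
  community <- build_community(inputs$models, inputs$abundances)
  community <- apply_medium(community, recipe_to_bounds(inputs$recipe))
  if (with_op) {
    community <- apply_operating_point(community, config$op)
  } else {
    # constrain VFA accumulation but leave the swept gases free
    op_free <- config$op
    op_free$co2_uptake <- NULL; op_free$h2_uptake <- NULL
    op_free$ch4_min_export <- NULL
    community <- apply_operating_point(community, op_free)
  }
  list(community = community, inputs = inputs)
}

serialize_artifact <- function(config, name, writer) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writer(file.path(config$out_dir, name))
}

write_manifest <- function(config, stage, paths) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  cfg <- config
  cfg$op <- unclass(cfg$op)
  manifest <- list(
    stage = stage,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("syntroflux")),
    artifacts = paths
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the constrained community simulation
#'
#' Chains medium construction, reactor operating point, community
#' assembly, the cooperative tradeoff and cross-feeding network
#' extraction. With an `out_dir` every intermediate (abundances, medium
#' bounds, member growth rates, exchange table, network edge list and a
#' reproducibility manifest) is written to disk.
#'
#' @param config A [run_config()].
#' @return List with `solution` (a `tradeoff_solution`), `exchanges` (the
#'   per-species exchange table) and `network` (an `exchange_network`).
#' @export
run_simulation <- function(config = run_config()) {
  cc <- constrained_community(config)
  solution <- cooperative_tradeoff(cc$community, f = config$fraction)
  if (solution$status != "optimal") {
    stop("simulation stage 'tradeoff': community solve returned status '",
         solution$status, "'", call. = FALSE)
  }
  exchanges <- extract_exchanges(solution, cc$community)
  network <- build_network(exchanges, threshold = config$exchange_threshold)

  serialize_artifact(config, "abundances.tsv", function(p) {
    utils::write.table(cc$inputs$abundances, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  serialize_artifact(config, "medium_bounds.tsv", function(p) {
    b <- recipe_to_bounds(cc$inputs$recipe)
    utils::write.table(data.frame(compound_id = names(b), max_uptake = b),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  serialize_artifact(config, "growth_rates.tsv", function(p) {
    utils::write.table(solution$members, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  serialize_artifact(config, "exchanges.tsv", function(p) {
    utils::write.table(exchanges, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  serialize_artifact(config, "network.tsv", function(p) write_network(network, p))
  write_manifest(config, "simulate",
                 c("abundances.tsv", "medium_bounds.tsv", "growth_rates.tsv",
                   "exchanges.tsv", "network.tsv"))
  list(solution = solution, exchanges = exchanges, network = network)
}

#' Run the gas-availability growth sweep
#'
#' Applies the medium and the zero-accumulation constraint on volatile
#' fatty acids but leaves the H2/CO2 exchanges free, then sweeps their
#' uptake bounds over the configured grid.
#'
#' @param config A [run_config()].
#' @return A `sweep_result`.
#' @export
run_sweep <- function(config = run_config()) {
  cc <- constrained_community(config, with_op = FALSE)
  gas <- unname(config$op$gas_ids[c("h2", "co2")])
  sweep <- growth_sweep(cc$community, gas_ids = gas,
                        grid = config$sweep_grid, f = config$fraction)
  serialize_artifact(config, "sweep.tsv", function(p) {
    utils::write.table(sweep$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  write_manifest(config, "sweep", "sweep.tsv")
  sweep
}

#' Run the univariate intervention (elasticity) scan
#'
#' Scans medium-availability and species-abundance interventions against
#' the configured responses, mirroring the effector-by-response elasticity
#' matrix of the community analysis.
#'
#' @param config A [run_config()].
#' @param effectors Optional data frame (`kind`, `id`); defaults to every
#'   medium component with a community exchange plus every species.
#' @param responses Optional response metabolite ids; defaults to the
#'   exported gases and amino acids.
#' @return Data frame of elasticity records.
#' @export
run_interventions <- function(config = run_config(), effectors = NULL,
                              responses = NULL) {
  cc <- constrained_community(config)
  community <- cc$community
  ex_mets <- community_exchanges(community)$metabolite
  if (is.null(effectors)) {
    med <- intersect(recipe_to_bounds(cc$inputs$recipe) |> names(), ex_mets)
    effectors <- rbind(
      data.frame(kind = "medium_metabolite", id = med,
                 stringsAsFactors = FALSE),
      data.frame(kind = "species_abundance",
                 id = community$species$species_id, stringsAsFactors = FALSE)
    )
  }
  if (is.null(responses)) {
    cats <- vapply(ex_mets, classify_metabolite, character(1))
    responses <- ex_mets[cats == "amino_acid" |
                           ex_mets %in% unname(config$op$gas_ids)]
  }
  baseline <- cooperative_tradeoff(community, f = config$fraction)
  if (baseline$status != "optimal") {
    stop("interventions stage 'baseline': solve returned '",
         baseline$status, "'", call. = FALSE)
  }
  records <- lapply(seq_len(nrow(effectors)), function(i) {
    elasticity(community,
               effector = list(kind = effectors$kind[i], id = effectors$id[i]),
               responses = responses,
               step_factor = config$elasticity_step,
               f = config$fraction, baseline = baseline)
  })
  out <- do.call(rbind, records)
  serialize_artifact(config, "elasticity.tsv", function(p) {
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  write_manifest(config, "interventions", "elasticity.tsv")
  out
}
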