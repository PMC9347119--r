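#' Per-species exchange fluxes of a community solution
#'
#' Tabulates every species-level exchange flux of an optimal tradeoff
#' solution, in the export-positive convention, both in the species' own
#' per-gDW units and abundance-weighted community units (the latter are
#' what the shared-pool mass balance couples).
#'
#' @param solution An optimal `tradeoff_solution`.
#' @param community The `community_model` it was solved on.
#' @param zero_tol Fluxes with magnitude below this are reported as zero
#'   (default `1e-9`).
#' @return A data frame with columns `species_id`, `metabolite`,
#'   `flux_species`, `flux_community`.
#' @export
extract_exchanges <- function(solution, community, zero_tol = 1e-9) {
  stopifnot(inherits(solution, "tradeoff_solution"))
  if (solution$status != "optimal") {
    stop("solution status is '", solution$status,
         "'; exchanges require an optimal solution", call. = FALSE)
  }
  rx <- community$reactions
  idx <- which(rx$kind == "exchange")
  ab <- stats::setNames(community$species$abundance,
                        community$species$species_id)
  # export-positive species flux: the exchange's pool contribution is
  # coupling * flux, with coupling = -stoich = +1 for the canonical
  # single-metabolite exchange.
  flux <- unname(solution$fluxes[rx$id[idx]]) * rx$coupling[idx]
  flux[abs(flux) < zero_tol] <- 0
  out <- data.frame(
    species_id = rx$species[idx],
    metabolite = rx$metabolite[idx],
    flux_species = flux,
    flux_community = flux * unname(ab[rx$species[idx]]),
    stringsAsFactors = FALSE
  )
  out[out$flux_species != 0, , drop = FALSE]
}

#' Build a thresholded cross-feeding network
#'
#' Flux balance analysis only defines species-to-pool fluxes; pairwise
#' arrows are attributed by proportional allocation through the shared
#' pool: for each metabolite with total export \eqn{E} and total import
#' \eqn{I} (community units), the edge from producer `p` to consumer `c`
#' carries \eqn{E_p I_c / \max(E, I)}, and the residual \eqn{|E - I|} flows
#' to (or from) a distinguished medium node. The allocation conserves flow
#' exactly and is deterministic. Edges are kept only when their flux is
#' strictly larger than `threshold` (default 0.3 mmol/gDW/h, the plotting
#' threshold used for the biofilm exchange figures).
#'
#' @param table Output of [extract_exchanges()].
#' @param threshold Minimum edge flux in community units (mmol/gDW/h).
#' @return An `exchange_network`: data frame of edges (`from`,
#'   `metabolite`, `to`, `flux`, `category`) with the threshold stored as
#'   an attribute. Node `"medium"` denotes the environment.
#' @export
build_network <- function(table, threshold = 0.3) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  edges <- list()
  for (m in unique(table$metabolite)) {
    tab <- table[table$metabolite == m, , drop = FALSE]
    prod <- tab[tab$flux_community > 0, , drop = FALSE]
    cons <- tab[tab$flux_community < 0, , drop = FALSE]
    E <- sum(prod$flux_community)
    I <- -sum(cons$flux_community)
    denom <- max(E, I)
    if (denom <= 0) next
    for (p in seq_len(nrow(prod))) {
      for (cc in seq_len(nrow(cons))) {
        edges[[length(edges) + 1]] <- data.frame(
          from = prod$species_id[p], metabolite = m,
          to = cons$species_id[cc],
          flux = prod$flux_community[p] * (-cons$flux_community[cc]) / denom,
          stringsAsFactors = FALSE
        )
      }
    }
    if (E > I) {        # surplus exported to the medium
      for (p in seq_len(nrow(prod))) {
        edges[[length(edges) + 1]] <- data.frame(
          from = prod$species_id[p], metabolite = m, to = "medium",
          flux = prod$flux_community[p] * (E - I) / E,
          stringsAsFactors = FALSE
        )
      }
    } else if (I > E) {  # deficit drawn from the medium
      for (cc in seq_len(nrow(cons))) {
        edges[[length(edges) + 1]] <- data.frame(
          from = "medium", metabolite = m, to = cons$species_id[cc],
          flux = -cons$flux_community[cc] * (I - E) / I,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  net <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), metabolite = character(0),
               to = character(0), flux = numeric(0),
               stringsAsFactors = FALSE)
  net <- net[net$flux > threshold, , drop = FALSE]
  net$category <- vapply(net$metabolite, classify_metabolite, character(1))
  rownames(net) <- NULL
  structure(net, class = c("exchange_network", "data.frame"),
            threshold = threshold)
}

# id normalization shared by the classifier: strip compartment suffixes and
# stereo tags, lower-case.
normalize_met_id <- function(id) {
  x <- tolower(id)
  x <- sub("_[ce]$", "", x)
  x <- sub("^ex_", "", x)
  x <- sub("__[ldm]$", "", x)
  x <- sub("^l-", "", x)
  x
}

METHANOGENESIS_SET <- c("co2", "h2", "ch4", "ac", "acetate", "pyr",
                        "pyruvate", "for", "formate")

AMINO_ACID_SET <- c(
  "ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
  "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val",
  "alanine", "arginine", "asparagine", "aspartate", "cysteine",
  "glutamine", "glutamate", "glycine", "histidine", "isoleucine",
  "leucine", "lysine", "methionine", "phenylalanine", "proline",
  "serine", "threonine", "tryptophan", "tyrosine", "valine"
)

#' Classify an exchanged metabolite
#'
#' Metabolites directly involved in methanogenesis (CO2, H2, CH4, acetate,
#' pyruvate, formate) form one category, the twenty proteinogenic amino
#' acids another; everything else is `"other"`. Ids are matched after
#' stripping compartment suffixes and stereo tags, so `"glu__L"`,
#' `"l-Glutamate"` and `"glu"` all classify alike.
#'
#' @param metabolite_id Character id or common name.
#' @return `"methanogenesis"`, `"amino_acid"` or `"other"`.
#' @export
classify_metabolite <- function(metabolite_id) {
  x <- normalize_met_id(metabolite_id)
  if (x %in% METHANOGENESIS_SET) "methanogenesis"
  else if (x %in% AMINO_ACID_SET) "amino_acid"
  else "other"
}

#' Write an exchange network as an edge-list TSV
#'
#' @param network An `exchange_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
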