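#' Construct a species-level metabolic model
#'
#' A `species_model` holds one organism's stoichiometric network in the form
#' used throughout this package: a metabolite table, a reaction table with a
#' stoichiometry list-column, and the id of the biomass reaction whose flux
#' is the specific growth rate (1/h). All fluxes are in mmol/gDW/h.
#'
#' Metabolites live either in the organism (`"internal"`) or in the shared
#' `"environment"` compartment. Environment metabolites use a common
#' namespace so that identical ids merge across species when a community is
#' assembled. Exchange reactions touch exactly one environment metabolite;
#' the sign convention is export-positive (negative flux = uptake).
#'
#' @param species_id Short unique identifier for the organism.
#' @param label Free-text taxon name.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`
#'   (`"internal"` or `"environment"`) and optionally `formula`.
#' @param reactions Data frame with columns `id`, `lb`, `ub`,
#'   `objective_coefficient` (optional, default 0) and a list-column
#'   `stoich` of named numeric vectors (metabolite id -> signed
#'   coefficient). An optional logical column `is_exchange` overrides the
#'   automatic single-environment-metabolite detection.
#' @param biomass_reaction_id Id of the biomass reaction.
#'
#' @return An object of class `species_model`.
#' @seealso [validate_model()], [read_model()], [write_model()]
#' @export
species_model <- function(species_id, label = species_id, metabolites,
                          reactions, biomass_reaction_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$objective_coefficient)) {
    reactions$objective_coefficient <- 0
  }
  stopifnot(is.list(reactions$stoich))
  # canonical stoichiometry: plain named double vector, ids sorted
  reactions$stoich <- lapply(reactions$stoich, function(s) {
    v <- unlist(s)
    v <- stats::setNames(as.numeric(v), names(v))
    v[order(names(v))]
  })
  model <- structure(
    list(
      species_id = as.character(species_id),
      label = as.character(label),
      metabolites = metabolites[, c("id", "name", "compartment", "formula")],
      reactions = reactions,
      biomass_reaction_id = as.character(biomass_reaction_id)
    ),
    class = "species_model"
  )
  model$reactions$is_exchange <- detect_exchanges(model, reactions$is_exchange)
  model
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf(
    "<species_model> %s (%s): %d metabolites, %d reactions (%d exchanges), biomass = %s\n",
    x$species_id, x$label, nrow(x$metabolites), nrow(x$reactions),
    sum(x$reactions$is_exchange), x$biomass_reaction_id
  ))
  invisible(x)
}

# Exchange reactions are auto-detected by the single-environment-metabolite
# rule; an explicit flag in the input file wins when present.
detect_exchanges <- function(model, explicit = NULL) {
  env_ids <- model$metabolites$id[model$metabolites$compartment == "environment"]
  auto <- vapply(model$reactions$stoich, function(s) {
    length(s) == 1L && names(s) %in% env_ids
  }, logical(1))
  if (!is.null(explicit)) {
    explicit <- as.logical(explicit)
    auto[!is.na(explicit)] <- explicit[!is.na(explicit)]
  }
  auto
}

#' Validate a species model
#'
#' Checks the structural invariants of a [species_model()]: unique non-empty
#' metabolite and reaction ids, stoichiometry keys that resolve to declared
#' metabolites, `lb <= ub` on every reaction, exchange reactions touching
#' exactly one environment metabolite, and a biomass reaction id that
#' resolves to exactly one reaction. Violations are returned as data, not
#' raised as conditions.
#'
#' @param model A `species_model`.
#' @return Character vector of human-readable violations; empty when the
#'   model is valid.
#' @export
validate_model <- function(model) {
  out <- character(0)
  mets <- model$metabolites
  rxns <- model$reactions
  if (any(!nzchar(mets$id))) out <- c(out, "metabolite with empty id")
  dup <- unique(mets$id[duplicated(mets$id)])
  if (length(dup)) {
    out <- c(out, sprintf("duplicate metabolite id '%s'", dup))
  }
  dupr <- unique(rxns$id[duplicated(rxns$id)])
  if (length(dupr)) out <- c(out, sprintf("duplicate reaction id '%s'", dupr))
  bad_bounds <- rxns$id[rxns$lb > rxns$ub]
  if (length(bad_bounds)) {
    out <- c(out, sprintf("reaction '%s': lower_bound > upper_bound", bad_bounds))
  }
  env_ids <- mets$id[mets$compartment == "environment"]
  for (i in seq_len(nrow(rxns))) {
    s <- rxns$stoich[[i]]
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown)) {
      out <- c(out, sprintf(
        "reaction '%s': stoichiometry references undeclared metabolite '%s'",
        rxns$id[i], unknown
      ))
    }
    if (isTRUE(rxns$is_exchange[i]) &&
        !(length(s) == 1L && all(names(s) %in% env_ids))) {
      out <- c(out, sprintf(
        "reaction '%s': exchange must touch exactly one environment metabolite",
        rxns$id[i]
      ))
    }
  }
  n_bio <- sum(rxns$id == model$biomass_reaction_id)
  if (n_bio != 1L) {
    out <- c(out, sprintf(
      "biomass_reaction_id '%s' resolves to %d reactions (expected 1)",
      model$biomass_reaction_id, n_bio
    ))
  }
  bad_comp <- mets$id[!mets$compartment %in% c("internal", "environment")]
  if (length(bad_comp)) {
    out <- c(out, sprintf("metabolite '%s': unknown compartment", bad_comp))
  }
  out
}

assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (length(v)) {
    stop("invalid model '", model$species_id, "': ",
         paste(v, collapse = "; "), call. = FALSE)
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `species_model` or `community_model`.
#' @return A sparse `dgCMatrix` with one row per metabolite and one column
#'   per reaction.
#' @export
stoichiometric_matrix <- function(model) {
  UseMethod("stoichiometric_matrix")
}

#' @export
stoichiometric_matrix.species_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    s <- model$reactions$stoich[[j]]
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(met_ids), length(rxn_ids)),
    dimnames = list(met_ids, rxn_ids)
  )
}

DEFAULT_BOUND <- 1000

#' Read a species model from disk
#'
#' Supports two dialects: a lightweight JSON format (`"toy-json"`) and the
#' constraint-based subset of SBML Level 3 with the flux-bounds extension
#' (`"sbml-subset"`): species, reactions, stoichiometry, flux bounds and the
#' active objective. Other SBML constructs (groups, annotations, rules) are
#' ignored with a message. Bounds absent from the file default to
#' (-1000, 1000) for reversible reactions and (0, 1000) otherwise.
#'
#' @param path File to read.
#' @param dialect `"toy-json"` or `"sbml-subset"`; `NULL` guesses from the
#'   file extension (`.json` vs `.xml`/`.sbml`).
#' @return A validated [species_model()].
#' @export
read_model <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  dialect <- dialect %||% guess_dialect(path)
  model <- switch(dialect,
    "toy-json" = read_model_json(path),
    "sbml-subset" = read_model_sbml(path),
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
  assert_valid_model(model)
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "toy-json"
  else if (ext %in% c("xml", "sbml")) "sbml-subset"
  else stop("cannot guess dialect from extension '.", ext, "'", call. = FALSE)
}

#' Write a species model to disk
#'
#' The written file round-trips through [read_model()] with full fidelity of
#' ids, stoichiometry, bounds and objective coefficients.
#'
#' @param model A valid `species_model`.
#' @param path Output file.
#' @param dialect `"toy-json"` or `"sbml-subset"`; `NULL` guesses from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = NULL) {
  assert_valid_model(model)
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
    "toy-json" = write_model_json(model, path),
    "sbml-subset" = write_model_sbml(model, path),
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
  invisible(path)
}

## ---- toy-json dialect -----------------------------------------------------
## One JSON document:
## {
##   "species_id": "...", "label": "...",
##   "metabolites": [{"id":, "name":, "compartment":, "formula":}, ...],
##   "reactions":   [{"id":, "stoich": {"met": coeff, ...},
##                    "lb":, "ub":, "obj":}, ...],
##   "biomass": "reaction id"
## }

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("parse error in '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  for (key in c("metabolites", "reactions", "biomass")) {
    if (is.null(doc[[key]])) {
      stop("parse error in '", path, "': missing element '", key, "'",
           call. = FALSE)
    }
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) {
      stop("parse error in '", path, "': metabolite without id", call. = FALSE)
    }
    data.frame(
      id = m$id, name = m$name %||% m$id,
      compartment = m$compartment %||% "internal",
      formula = m$formula %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoich)) {
      stop("parse error in '", path, "': reaction without id or stoich",
           call. = FALSE)
    }
    rev <- isTRUE(r$reversible)
    data.frame(
      id = r$id,
      lb = r$lb %||% if (rev) -DEFAULT_BOUND else 0,
      ub = r$ub %||% DEFAULT_BOUND,
      objective_coefficient = r$obj %||% 0,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rxns)) {
    rxns <- data.frame(id = character(0), lb = numeric(0), ub = numeric(0),
                       objective_coefficient = numeric(0))
    rxns$stoich <- list()
  } else {
    rxns$stoich <- lapply(doc$reactions, function(r) unlist(r$stoich))
  }
  species_model(
    species_id = doc$species_id %||% tools::file_path_sans_ext(basename(path)),
    label = doc$label %||% doc$species_id %||% "",
    metabolites = mets, reactions = rxns,
    biomass_reaction_id = doc$biomass
  )
}

write_model_json <- function(model, path) {
  rl <- model$reactions
  doc <- list(
    species_id = model$species_id,
    label = model$label,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out
    }),
    reactions = lapply(seq_len(nrow(rl)), function(i) {
      list(
        id = rl$id[i], stoich = as.list(rl$stoich[[i]]),
        lb = rl$lb[i], ub = rl$ub[i], obj = rl$objective_coefficient[i]
      )
    }),
    biomass = model$biomass_reaction_id
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- SBML Level 3 + fbc subset --------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("parse error in '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  sb_find <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  model_node <- sb_find(doc, "model")
  if (length(model_node) == 0) {
    stop("parse error in '", path, "': no <model> element", call. = FALSE)
  }
  model_node <- model_node[[1]]

  # compartments: anything whose id starts with "e" or is named environment
  comp_nodes <- sb_find(model_node, "compartment")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  env_comps <- comp_ids[comp_ids %in% c("e", "env", "environment", "extern")]

  sp_nodes <- sb_find(model_node, "species")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = ifelse(xml2::xml_attr(sp_nodes, "compartment") %in% env_comps,
                         "environment", "internal"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE
  )

  par_nodes <- sb_find(model_node, "parameter")
  pars <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id")
  )

  rxn_nodes <- sb_find(model_node, "reaction")
  stoich <- vector("list", length(rxn_nodes))
  lb <- ub <- numeric(length(rxn_nodes))
  ids <- character(length(rxn_nodes))
  for (i in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[i]]
    ids[i] <- xml2::xml_attr(rn, "id")
    if (is.na(ids[i])) {
      stop("parse error in '", path, "': reaction without id", call. = FALSE)
    }
    reac <- xml2::xml_find_all(
      rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(
      rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    s <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species"))
    )
    s[is.na(s)] <- ifelse(seq_along(s) <= length(reac), -1, 1)[is.na(s)]
    # collapse duplicated species references
    stoich[[i]] <- tapply(s, names(s), sum)
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb[i] <- if (!is.na(lb_ref) && lb_ref %in% names(pars)) pars[[lb_ref]]
             else if (rev) -DEFAULT_BOUND else 0
    ub[i] <- if (!is.na(ub_ref) && ub_ref %in% names(pars)) pars[[ub_ref]]
             else DEFAULT_BOUND
  }

  obj_coef <- stats::setNames(numeric(length(ids)), ids)
  fo_nodes <- sb_find(model_node, "fluxObjective")
  biomass <- NA_character_
  if (length(fo_nodes)) {
    for (fo in fo_nodes) {
      rid <- xml2::xml_attr(fo, "reaction")
      cf <- as.numeric(xml2::xml_attr(fo, "coefficient"))
      if (rid %in% ids) obj_coef[rid] <- ifelse(is.na(cf), 1, cf)
    }
    biomass <- names(obj_coef)[which.max(abs(obj_coef))]
  }

  ignored <- sb_find(model_node, "listOfGroups")
  if (length(ignored)) {
    message("read_model: ignoring SBML groups (constraint-based subset only)")
  }

  rxns <- data.frame(id = ids, lb = lb, ub = ub,
                     objective_coefficient = unname(obj_coef),
                     stringsAsFactors = FALSE)
  rxns$stoich <- stoich
  species_model(
    species_id = xml2::xml_attr(model_node, "id") %||%
      tools::file_path_sans_ext(basename(path)),
    label = xml2::xml_attr(model_node, "name") %||% "",
    metabolites = mets, reactions = rxns, biomass_reaction_id = biomass
  )
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  rl <- model$reactions
  bounds <- sort(unique(c(rl$lb, rl$ub)))
  par_id <- function(v) sprintf("fb_%d", match(v, bounds))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
      'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" name="%s" fbc:strict="true">',
            esc(model$species_id), esc(model$label)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>'
  )
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    frm <- if (!is.na(m$formula)) {
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    } else ""
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      esc(m$id), esc(m$name),
      if (m$compartment == "environment") "e" else "c", frm
    ))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(bounds)) {
    lines <- c(lines, sprintf(
      '      <parameter id="fb_%d" value="%s" constant="true"/>',
      k, num(bounds[k])
    ))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rl))) {
    s <- rl$stoich[[i]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(rl$id[i]), if (rl$lb[i] < 0) "true" else "false",
      par_id(rl$lb[i]), par_id(rl$ub[i])
    ))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                esc(names(reac)), num(-unname(reac))),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                esc(names(prod)), num(unname(prod))),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  obj <- rl[rl$objective_coefficient != 0, , drop = FALSE]
  if (nrow(obj) == 0) {
    obj <- rl[rl$id == model$biomass_reaction_id, , drop = FALSE]
    obj$objective_coefficient <- 1
  }
  lines <- c(lines, sprintf(
    paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
           'fbc:coefficient="%s"/>'),
    esc(obj$id), num(obj$objective_coefficient)
  ))
  lines <- c(lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
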