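#' Merge species models into an abundance-weighted community model
#'
#' Species networks are namespaced by `species_id` and joined through a
#' shared environment compartment, following the compartmentalized
#' community formulation used in community flux balance analysis. Each
#' species keeps a private copy of every environment metabolite it touches;
#' its exchange reaction moves the metabolite between that private copy and
#' the shared pool, contributing with weight `a_i` (the relative abundance)
#' to the pool's mass balance. One community-level exchange reaction per
#' pool metabolite connects the pool to the surrounding medium, so that at
#' any steady-state solution
#' \deqn{v_{EX}^{c,m} = \sum_i a_i \, v_{EX}^{i,m},}
#' i.e. community exchanges are in mmol per gram dry weight of *community*
#' per hour while species fluxes stay in per-gDW-of-that-species units.
#' Species internal fluxes are not rescaled. The community growth rate is
#' the abundance-weighted sum of the species biomass fluxes,
#' \eqn{\mu_c = \sum_i a_i \mu_i}.
#'
#' @param models List of validated [species_model()] objects.
#' @param abundances Named numeric vector (or data frame with columns
#'   `species_id` and `fraction`) of relative abundances covering exactly
#'   the model ids. Values are normalized to sum to one; species below
#'   `drop_threshold` are removed before renormalization.
#' @param drop_threshold Abundance below which a species is dropped
#'   (default `1e-6`).
#' @return An object of class `community_model`.
#' @export
build_community <- function(models, abundances, drop_threshold = 1e-6) {
  ids <- vapply(models, function(m) m$species_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate species_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  ab <- normalize_abundances(abundances, ids, drop_threshold)
  keep <- names(ab)
  models <- models[match(keep, ids)]
  ord <- order(keep)  # stable, deterministic construction
  models <- models[ord]
  ab <- ab[ord]

  met_rows <- list(); rxn_rows <- list()
  env_seen <- character(0)
  species_tab <- data.frame(
    species_id = names(ab),
    label = vapply(models, function(m) m$label, character(1)),
    abundance = unname(ab),
    biomass_reaction = paste0(names(ab), "__",
                              vapply(models, function(m) m$biomass_reaction_id,
                                     character(1))),
    stringsAsFactors = FALSE
  )

  for (k in seq_along(models)) {
    m <- models[[k]]
    sid <- m$species_id
    assert_valid_model(m)
    env_ids <- m$metabolites$id[m$metabolites$compartment == "environment"]
    ns <- function(x) paste0(sid, "__", x)
    met_rows[[length(met_rows) + 1]] <- data.frame(
      id = ns(m$metabolites$id),
      compartment = ifelse(m$metabolites$compartment == "environment",
                           "species_boundary", "internal"),
      species = sid, metabolite = m$metabolites$id,
      stringsAsFactors = FALSE
    )
    env_seen <- union(env_seen, env_ids)
    for (j in seq_len(nrow(m$reactions))) {
      s <- m$reactions$stoich[[j]]
      is_ex <- m$reactions$is_exchange[j]
      rxn_rows[[length(rxn_rows) + 1]] <- list(
        id = ns(m$reactions$id[j]),
        species = sid,
        kind = if (is_ex) "exchange"
               else if (m$reactions$id[j] == m$biomass_reaction_id) "biomass"
               else "internal",
        metabolite = if (is_ex) names(s) else NA_character_,
        lb = m$reactions$lb[j], ub = m$reactions$ub[j],
        # species-side stoichiometry on the namespaced private copies; the
        # abundance-weighted pool entry of exchanges is added when the
        # stoichiometric matrix is assembled, so abundances can be swapped
        # without reparsing models.
        stoich = stats::setNames(unname(s), ns(names(s))),
        coupling = if (is_ex) -unname(s) else NA_real_
      )
    }
  }

  env_seen <- sort(env_seen)
  for (m_id in env_seen) {
    rxn_rows[[length(rxn_rows) + 1]] <- list(
      id = paste0("EX_", m_id, "__medium"),
      species = NA_character_, kind = "community_exchange",
      metabolite = m_id, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND,
      stoich = stats::setNames(-1, m_id), coupling = NA_real_
    )
  }

  mets <- rbind(
    do.call(rbind, met_rows),
    data.frame(id = env_seen, compartment = "environment",
               species = NA_character_, metabolite = env_seen,
               stringsAsFactors = FALSE)
  )
  rxns <- data.frame(
    id = vapply(rxn_rows, `[[`, character(1), "id"),
    species = vapply(rxn_rows, `[[`, character(1), "species"),
    kind = vapply(rxn_rows, `[[`, character(1), "kind"),
    metabolite = vapply(rxn_rows, `[[`, character(1), "metabolite"),
    lb = vapply(rxn_rows, `[[`, numeric(1), "lb"),
    ub = vapply(rxn_rows, `[[`, numeric(1), "ub"),
    coupling = vapply(rxn_rows, `[[`, numeric(1), "coupling"),
    stringsAsFactors = FALSE
  )
  rxns$stoich <- lapply(rxn_rows, `[[`, "stoich")

  structure(
    list(species = species_tab, metabolites = mets, reactions = rxns),
    class = "community_model"
  )
}

normalize_abundances <- function(abundances, ids, drop_threshold) {
  if (is.data.frame(abundances)) {
    abundances <- stats::setNames(abundances$fraction, abundances$species_id)
  }
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    stop("abundances must be named by species_id", call. = FALSE)
  }
  unknown <- setdiff(names(abundances), ids)
  if (length(unknown)) {
    stop("abundance given for unknown species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ids, names(abundances))
  if (length(missing)) {
    stop("no abundance for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(abundances) <= 0) stop("abundances sum to zero", call. = FALSE)
  ab <- abundances / sum(abundances)
  ab <- ab[ab >= drop_threshold]
  ab / sum(ab)
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "<community_model> %d species, %d metabolites (%d shared), %d reactions\n",
    nrow(x$species), nrow(x$metabolites),
    sum(x$metabolites$compartment == "environment"), nrow(x$reactions)
  ))
  sp <- x$species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  %-18s a = %.4f  (%s)\n", sp$species_id[i],
                sp$abundance[i], sp$label[i]))
  }
  invisible(x)
}

#' Replace the abundance profile of a community model
#'
#' Rebuilds the abundance-dependent coupling weights and the community
#' growth objective without reconstructing the model. Used by the
#' elasticity analysis to probe abundance interventions.
#'
#' @param community A `community_model`.
#' @param abundances Named numeric vector over exactly the same species set
#'   (normalized internally).
#' @return A new `community_model`; the input is not modified.
#' @export
set_abundances <- function(community, abundances) {
  if (is.data.frame(abundances)) {
    abundances <- stats::setNames(abundances$fraction, abundances$species_id)
  }
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (!setequal(names(abundances), community$species$species_id)) {
    stop("abundances must cover exactly the community's species",
         call. = FALSE)
  }
  ab <- abundances[community$species$species_id]
  community$species$abundance <- unname(ab / sum(ab))
  community
}

#' @export
stoichiometric_matrix.community_model <- function(model) {
  met_ids <- model$metabolites$id
  rxns <- model$reactions
  ab <- stats::setNames(model$species$abundance, model$species$species_id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(rxns))) {
    s <- rxns$stoich[[j]]
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
    if (rxns$kind[j] == "exchange") {
      # abundance-weighted contribution to the shared pool
      ii <- c(ii, match(rxns$metabolite[j], met_ids))
      jj <- c(jj, j)
      xx <- c(xx, rxns$coupling[j] * ab[[rxns$species[j]]])
    }
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(length(met_ids), nrow(rxns)),
    dimnames = list(met_ids, rxns$id)
  )
}

# Community growth objective: abundance weights on the biomass fluxes.
community_objective <- function(community) {
  obj <- stats::setNames(numeric(nrow(community$reactions)),
                         community$reactions$id)
  obj[community$species$biomass_reaction] <- community$species$abundance
  obj
}

#' Community exchange reactions
#'
#' @param community A `community_model`.
#' @return Data frame of the community-level exchange reactions (one per
#'   shared environment metabolite) with their bounds.
#' @export
community_exchanges <- function(community) {
  community$reactions[community$reactions$kind == "community_exchange",
                      c("id", "metabolite", "lb", "ub")]
}

#' Set the bounds of a community exchange reaction
#'
#' Adjusts the community-level exchange of one environment metabolite;
#' `NULL` leaves a bound untouched. Uptake is negative, so e.g.
#' `lb = -20` allows import of up to 20 mmol/gDW/h.
#'
#' @param community A `community_model`.
#' @param metabolite Environment metabolite id.
#' @param lb,ub New bounds (mmol/gDW/h), or `NULL` to keep the current one.
#' @return A new `community_model`.
#' @export
set_community_exchange_bounds <- function(community, metabolite, lb = NULL,
                                          ub = NULL) {
  idx <- which(community$reactions$kind == "community_exchange" &
                 community$reactions$metabolite == metabolite)
  if (length(idx) != 1) {
    stop("no community exchange for metabolite '", metabolite,
         "'; candidates: ",
         paste(community_exchanges(community)$metabolite, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lb)) community$reactions$lb[idx] <- lb
  if (!is.null(ub)) community$reactions$ub[idx] <- ub
  community
}
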