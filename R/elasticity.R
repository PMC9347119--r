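#' Elasticity of exchange fluxes to univariate interventions
#'
#' Quantifies how strongly an intervention on the system -- increasing the
#' availability of a medium metabolite, or increasing the abundance of one
#' species -- changes selected community exchange fluxes. The coefficient
#' is a one-sided multiplicative finite difference on the log scale,
#' \deqn{\epsilon = \frac{\ln(|v'| + \varepsilon) - \ln(|v| + \varepsilon)}
#'                      {\ln(\theta'/\theta)},}
#' with \eqn{\varepsilon = 10^{-8}}, where \eqn{v} and \eqn{v'} are the
#' response fluxes of the baseline and perturbed cooperative-tradeoff
#' solutions and \eqn{\theta} the effector parameter. A positive
#' coefficient means the intervention increases production of the response
#' metabolite.
#'
#' For a `medium_metabolite` effector the community uptake bound of that
#' metabolite is multiplied by `step_factor` (a forced-uptake upper bound,
#' if present, is scaled along). For a `species_abundance` effector the
#' species' relative abundance is multiplied by `step_factor` and the
#' profile renormalized, abundances being compositional; the parameter
#' ratio entering the denominator is the effective post-normalization
#' ratio.
#'
#' @param community A constrained `community_model` (medium and operating
#'   point applied).
#' @param effector List with elements `kind` (`"medium_metabolite"` or
#'   `"species_abundance"`) and `id`.
#' @param responses Environment metabolite ids whose community exchange
#'   fluxes are the responses; default all community exchanges.
#' @param step_factor Multiplicative perturbation (default 2; values in
#'   (0, 1) probe the downward direction).
#' @param f Tradeoff fraction (default 0.5).
#' @param zero_tol Responses below this magnitude in both states get
#'   coefficient 0.
#' @param baseline Optional precomputed baseline `tradeoff_solution` to
#'   avoid re-solving when scanning many effectors.
#' @return Data frame with columns `effector_kind`, `effector_id`,
#'   `response`, `coefficient`, `direction`, `status`.
#' @export
elasticity <- function(community, effector, responses = NULL,
                       step_factor = 2.0, f = 0.5, zero_tol = 1e-6,
                       baseline = NULL) {
  stopifnot(inherits(community, "community_model"))
  if (step_factor <= 0 || step_factor == 1) {
    stop("step_factor must be positive and different from 1", call. = FALSE)
  }
  if (!is.list(effector) || is.null(effector$kind) || is.null(effector$id)) {
    stop("effector must be list(kind =, id =)", call. = FALSE)
  }
  ex <- community_exchanges(community)
  if (is.null(responses)) responses <- ex$metabolite

  if (is.null(baseline)) baseline <- cooperative_tradeoff(community, f = f)
  if (baseline$status != "optimal") {
    stop("baseline community is not solvable (status ", baseline$status, ")",
         call. = FALSE)
  }

  log_ratio <- log(step_factor)
  if (effector$kind == "medium_metabolite") {
    if (!effector$id %in% ex$metabolite) {
      stop("no community exchange for medium metabolite '", effector$id, "'",
           call. = FALSE)
    }
    i <- match(effector$id, ex$metabolite)
    new_lb <- step_factor * ex$lb[i]
    new_ub <- if (ex$ub[i] < 0) step_factor * ex$ub[i] else NULL
    perturbed <- set_community_exchange_bounds(community, effector$id,
                                               lb = new_lb, ub = new_ub)
  } else if (effector$kind == "species_abundance") {
    sp <- community$species
    if (!effector$id %in% sp$species_id) {
      stop("unknown species '", effector$id, "'", call. = FALSE)
    }
    ab <- stats::setNames(sp$abundance, sp$species_id)
    a0 <- ab[[effector$id]]
    ab[effector$id] <- ab[effector$id] * step_factor
    perturbed <- set_abundances(community, ab)
    a1 <- perturbed$species$abundance[
      perturbed$species$species_id == effector$id]
    log_ratio <- log(a1 / a0)  # effective ratio after renormalization
  } else {
    stop("unknown effector kind '", effector$kind, "'", call. = FALSE)
  }

  sol2 <- cooperative_tradeoff(perturbed, f = f)
  eps <- 1e-8
  records <- lapply(responses, function(m) {
    rid <- ex$id[match(m, ex$metabolite)]
    if (sol2$status != "optimal") {
      return(data.frame(effector_kind = effector$kind,
                        effector_id = effector$id, response = m,
                        coefficient = NA_real_, direction = NA_real_,
                        status = sol2$status, stringsAsFactors = FALSE))
    }
    v1 <- unname(baseline$fluxes[[rid]])
    v2 <- unname(sol2$fluxes[[rid]])
    coef <- if (abs(v1) < zero_tol && abs(v2) < zero_tol) 0 else
      (log(abs(v2) + eps) - log(abs(v1) + eps)) / log_ratio
    data.frame(effector_kind = effector$kind, effector_id = effector$id,
               response = m, coefficient = coef, direction = sign(coef),
               status = "optimal", stringsAsFactors = FALSE)
  })
  do.call(rbind, records)
}
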