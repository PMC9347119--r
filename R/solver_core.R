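## Linear and quadratic programming back ends.
##
## The flux polytope is {v : S v = 0, lb <= v <= ub}. Linear programs go
## through the bounded-variable simplex in lp.R; convex quadratic programs
## use the dual active-set method in quadprog. All bounds in this package
## are finite, which keeps both well posed.

FEASIBILITY_TOL <- 1e-6

solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  S <- as.matrix(S)
  lb <- pmax(lb, -1e6); ub <- pmin(ub, 1e6)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_))
  # drop all-zero rows (metabolites untouched by any reaction)
  live <- rowSums(abs(S)) > 0
  res <- lp_simplex(S[live, , drop = FALSE], numeric(sum(live)),
                    lb, ub, obj, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = if (res$status == "infeasible") "infeasible"
                else "numerical_failure",
                objective = NA_real_))
  }
  v <- res$v
  names(v) <- colnames(S)
  list(status = "optimal", objective = res$objective, v = v)
}

# Drop linearly dependent rows so the equality system passed to quadprog has
# full row rank (community matrices carry redundant conservation rows).
independent_rows <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) == 0) return(S)
  qrt <- qr(t(S))
  S[sort(qrt$pivot[seq_len(qrt$rank)]), , drop = FALSE]
}

# min v' diag(w) v  s.t.  S v = 0, ineqA v >= ineqb, lb <= v <= ub.
# Variables with lb == ub are pinned through equality rows, which the dual
# active-set method handles much more gracefully than paired inequalities.
solve_qp <- function(S, lb, ub, w, ineqA = NULL, ineqb = NULL) {
  n <- length(lb)
  S <- as.matrix(S)
  fixed <- which(lb == ub)
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    S <- rbind(S, E)
    b_eq <- c(numeric(nrow(S) - length(fixed)), lb[fixed])
  } else {
    b_eq <- numeric(nrow(S))
  }
  # reduce [S | b] jointly to keep the right-hand side aligned
  aug <- cbind(S, b_eq)
  qrt <- qr(t(aug[, seq_len(n), drop = FALSE]))
  keep <- sort(qrt$pivot[seq_len(qrt$rank)])
  Sr <- aug[keep, seq_len(n), drop = FALSE]
  br <- aug[keep, n + 1]

  free <- setdiff(seq_len(n), fixed)
  I_lb <- diag(n)[, free, drop = FALSE]
  Amat <- cbind(t(Sr), if (!is.null(ineqA)) t(ineqA),
                I_lb, -I_lb)
  bvec <- c(br, ineqb, lb[free], -ub[free])
  Dmat <- diag(2 * pmax(w, 1e-10), n)
  res <- tryCatch(
    quadprog::solve.QP(Dmat, rep(0, n), Amat, bvec, meq = nrow(Sr)),
    error = function(e) NULL
  )
  if (is.null(res)) return(list(status = "infeasible"))
  v <- res$solution
  names(v) <- colnames(S)
  list(status = "optimal", v = v)
}

model_lp_parts <- function(model, objective_reaction = NULL) {
  S <- stoichiometric_matrix(model)
  if (inherits(model, "community_model")) {
    rx <- model$reactions
    obj <- community_objective(model)
  } else {
    rx <- model$reactions
    obj <- stats::setNames(rx$objective_coefficient, rx$id)
    if (all(obj == 0)) obj[model$biomass_reaction_id] <- 1
  }
  if (!is.null(objective_reaction)) {
    if (!objective_reaction %in% rx$id) {
      stop("unknown objective reaction: ", objective_reaction, call. = FALSE)
    }
    obj <- stats::setNames(numeric(nrow(rx)), rx$id)
    obj[objective_reaction] <- 1
  }
  list(S = S, lb = rx$lb, ub = rx$ub, obj = unname(obj), ids = rx$id)
}

#' Flux balance analysis
#'
#' Maximizes the objective flux (the biomass reaction unless
#' `objective_reaction` says otherwise) over the steady-state flux polytope
#' \eqn{\{v : S v = 0,\; lb \le v \le ub\}}. For a `community_model` the
#' default objective is the community growth rate
#' \eqn{\mu_c = \sum_i a_i \mu_i}.
#'
#' @param model A `species_model` or `community_model`.
#' @param objective_reaction Optional reaction id to maximize instead of the
#'   model's own objective.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"numerical_failure"`), `objective`, and a named
#'   `fluxes` vector (mmol/gDW/h; biomass fluxes in 1/h).
#' @export
fba <- function(model, objective_reaction = NULL) {
  p <- model_lp_parts(model, objective_reaction)
  res <- solve_lp(p$S, p$lb, p$ub, p$obj)
  if (res$status == "optimal") {
    resid <- max(abs(p$S %*% res$v))
    if (resid > FEASIBILITY_TOL) {
      warning("mass-balance residual ", format(resid), " exceeds tolerance")
    }
    structure(list(status = "optimal", objective = res$objective,
                   fluxes = stats::setNames(res$v, p$ids)),
              class = "flux_solution")
  } else {
    structure(list(status = res$status, objective = NA_real_,
                   fluxes = NULL), class = "flux_solution")
  }
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s, objective: %s\n", x$status,
              format(x$objective, digits = 6)))
  invisible(x)
}

#' Two-stage cooperative-tradeoff community optimization
#'
#' Stage 1 maximizes the community growth rate \eqn{\mu_c = \sum_i a_i
#' \mu_i} by linear programming. Stage 2 fixes a fraction `f` of that
#' optimum as a floor and minimizes \eqn{\sum_i \mu_i^2} over the same
#' polytope; the strict convexity of the quadratic in the growth rates
#' makes the per-species growth rates unique and, in the regime where no
#' species is individually limited, proportional to the relative
#' abundances. Stage 3 pins the stage-2 growth rates and minimizes the
#' squared Euclidean norm of all exchange fluxes, which makes the reported
#' cross-feeding fluxes reproducible in the face of flux degeneracy.
#'
#' @param community A `community_model`.
#' @param f Enforced fraction of the maximal community growth rate,
#'   `0 < f <= 1` (default 0.5).
#' @param delta Ridge weight placed on the fluxes outside each stage's
#'   quadratic objective; keeps the programs strictly convex (default
#'   `1e-8`).
#' @param regularize_fluxes Run stage 3 (default `TRUE`).
#' @return A `tradeoff_solution`: `status`, `mu_c_max`, `fraction`,
#'   `community_growth`, a `members` data frame (`species_id`, `abundance`,
#'   `mu`), and the full named `fluxes` vector.
#' @export
cooperative_tradeoff <- function(community, f = 0.5, delta = 1e-8,
                                 regularize_fluxes = TRUE) {
  stopifnot(inherits(community, "community_model"))
  if (!(f > 0 && f <= 1)) stop("f must lie in (0, 1]", call. = FALSE)
  p <- model_lp_parts(community)
  stage1 <- solve_lp(p$S, p$lb, p$ub, p$obj)
  if (stage1$status != "optimal") {
    return(structure(list(status = stage1$status), class = "tradeoff_solution"))
  }
  mu_c_max <- stage1$objective

  bio_idx <- match(community$species$biomass_reaction, p$ids)
  w2 <- rep(delta, length(p$ids))
  w2[bio_idx] <- 1
  # small absolute slack keeps the floor feasible at f = 1 and when the
  # stage-1 optimum is numerically zero
  stage2 <- solve_qp(p$S, p$lb, p$ub, w2,
                     ineqA = matrix(p$obj, nrow = 1),
                     ineqb = f * mu_c_max - 1e-9)
  if (stage2$status != "optimal") {
    return(structure(list(status = "infeasible", mu_c_max = mu_c_max),
                     class = "tradeoff_solution"))
  }
  mu <- pmax(stage2$v[bio_idx], 0)
  fluxes <- stage2$v

  if (regularize_fluxes) {
    lb3 <- p$lb; ub3 <- p$ub
    lb3[bio_idx] <- ub3[bio_idx] <- mu
    w3 <- rep(delta, length(p$ids))
    w3[community$reactions$kind %in% c("exchange", "community_exchange")] <- 1
    stage3 <- solve_qp(p$S, lb3, ub3, w3)
    if (stage3$status == "optimal") fluxes <- stage3$v
  }
  names(fluxes) <- p$ids
  resid <- max(abs(p$S %*% fluxes))
  if (resid > FEASIBILITY_TOL) {
    warning("mass-balance residual ", format(resid), " exceeds tolerance")
  }

  structure(list(
    status = "optimal",
    mu_c_max = mu_c_max,
    fraction = f,
    community_growth = sum(community$species$abundance * mu),
    members = data.frame(
      species_id = community$species$species_id,
      abundance = community$species$abundance,
      mu = unname(mu),
      stringsAsFactors = FALSE
    ),
    fluxes = fluxes
  ), class = "tradeoff_solution")
}

#' @export
print.tradeoff_solution <- function(x, ...) {
  cat(sprintf("<tradeoff_solution> status: %s\n", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  mu_c_max: %.6f 1/h, fraction: %.2f, achieved mu_c: %.6f\n",
                x$mu_c_max, x$fraction, x$community_growth))
    print(x$members, row.names = FALSE)
  }
  invisible(x)
}

#' Growth response to increasing gas availability
#'
#' Re-solves the cooperative tradeoff over a grid of uptake upper bounds
#' for the supplied gases (hydrogen and carbon dioxide by default): at each
#' threshold `t` the community exchange of every listed gas is allowed to
#' import up to `t` mmol/gDW/h (lower bound `-t`, export bound untouched).
#' A plateau is flagged where the relative change of the community growth
#' rate between consecutive grid points first drops below `plateau_tol`.
#'
#' @param community A `community_model`, typically with the growth medium
#'   already applied but without pinned gas uptakes.
#' @param gas_ids Environment metabolite ids whose uptake is swept.
#' @param grid Ascending numeric vector of thresholds (mmol/gDW/h); default
#'   nine evenly spaced points from 0 to 160.
#' @param f Tradeoff fraction passed to [cooperative_tradeoff()].
#' @param gas_scale Optional named multipliers applied to the threshold per
#'   gas (e.g. `c(h2 = 1, co2 = 0.25)` to sweep at a fixed uptake ratio);
#'   default 1 for every gas.
#' @param plateau_tol Relative-change criterion for the plateau flag
#'   (default `1e-3`).
#' @return A `sweep_result`: long data frame `table` (`threshold`,
#'   `species_id`, `mu`, `mu_c`), the community growth trace `mu_c`, and a
#'   `plateau` list (`value`, `onset`, `reached`).
#' @export
growth_sweep <- function(community, gas_ids = c("h2", "co2"),
                         grid = seq(0, 160, length.out = 9), f = 0.5,
                         gas_scale = NULL, plateau_tol = 1e-3) {
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  if (is.unsorted(grid)) stop("grid must be sorted ascending", call. = FALSE)
  scale <- stats::setNames(rep(1, length(gas_ids)), gas_ids)
  if (!is.null(gas_scale)) scale[names(gas_scale)] <- gas_scale

  rows <- list(); mu_c <- numeric(length(grid))
  for (k in seq_along(grid)) {
    cm <- community
    for (g in gas_ids) {
      cm <- set_community_exchange_bounds(cm, g, lb = -grid[k] * scale[[g]])
    }
    sol <- cooperative_tradeoff(cm, f = f)
    mu_k <- if (sol$status == "optimal") sol$members$mu else
      rep(NA_real_, nrow(community$species))
    mu_c[k] <- if (sol$status == "optimal") sol$community_growth else NA_real_
    rows[[k]] <- data.frame(
      threshold = grid[k],
      species_id = community$species$species_id,
      mu = mu_k, mu_c = mu_c[k], stringsAsFactors = FALSE
    )
  }

  onset <- NA_integer_; reached <- FALSE
  if (length(grid) > 1 && !anyNA(mu_c)) {
    rel <- abs(diff(mu_c)) / pmax(abs(mu_c[-1]), 1e-12)
    hit <- which(rel < plateau_tol)
    if (length(hit)) onset <- hit[1] + 1L
    reached <- length(rel) > 0 && rel[length(rel)] < plateau_tol
  }
  structure(list(
    table = do.call(rbind, rows),
    thresholds = grid,
    mu_c = mu_c,
    plateau = list(value = mu_c[length(mu_c)], onset = onset,
                   reached = reached)
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(data.frame(threshold = x$thresholds, mu_c = x$mu_c),
        row.names = FALSE)
  cat(sprintf("  plateau: value %.6f, onset index %s, reached: %s\n",
              x$plateau$value, x$plateau$onset, x$plateau$reached))
  invisible(x)
}
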