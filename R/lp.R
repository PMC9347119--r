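## Bounded-variable two-phase primal simplex.
##
## Solves   max / min  c'v   s.t.  A v = b,  lb <= v <= ub  (all bounds
## finite). Nonbasic variables sit at one of their bounds; Bland's smallest-
## index rule governs both the entering and the leaving choice, which rules
## out cycling on the degenerate, highly redundant stoichiometric systems
## this package produces. Phase 1 drives a full set of artificial columns
## to zero; phase 2 optimizes the true objective with the artificials
## clamped. Problem sizes here are tiny (tens to a couple of hundred
## variables), so dense solves per iteration are perfectly adequate.

lp_simplex <- function(A, b, lb, ub, cvec, maximize = TRUE,
                       tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (any(lb > ub + tol)) return(list(status = "infeasible"))
  if (m == 0L) {
    v <- ifelse((if (maximize) cvec else -cvec) > 0, ub, lb)
    return(list(status = "optimal", v = v, objective = sum(cvec * v)))
  }

  r <- as.numeric(b - A %*% lb)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  big <- sum(abs(r)) + 1
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(big, m))

  state <- list(
    basis = n + seq_len(m),
    at_ub = rep(FALSE, n + m),   # meaningful for nonbasic columns only
    xB = abs(r)
  )

  core <- function(state, cost, iter_budget) {
    nb_all <- seq_len(n + m)
    for (it in seq_len(iter_budget)) {
      B <- Aext[, state$basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[state$basis]),
                    error = function(e) NULL)
      if (is.null(y)) return(list(state = state, status = "numerical_failure"))
      nonbasic <- setdiff(nb_all, state$basis)
      d <- cost[nonbasic] - as.numeric(crossprod(Aext[, nonbasic, drop = FALSE], y))
      enter_lb <- nonbasic[!state$at_ub[nonbasic] & d > tol]
      enter_ub <- nonbasic[state$at_ub[nonbasic] & d < -tol]
      cand <- c(enter_lb, enter_ub)
      if (!length(cand)) return(list(state = state, status = "optimal"))
      j <- min(cand)                      # Bland
      increasing <- !state$at_ub[j]
      w <- tryCatch(solve(B, Aext[, j]), error = function(e) NULL)
      if (is.null(w)) return(list(state = state, status = "numerical_failure"))
      dirB <- if (increasing) -w else w   # d xB / d t
      lbB <- lbe[state$basis]; ubB <- ube[state$basis]
      flip_t <- ube[j] - lbe[j]           # bound flip distance
      ratios <- rep(Inf, m)
      dec <- dirB < -tol; inc <- dirB > tol
      ratios[dec] <- (state$xB[dec] - lbB[dec]) / (-dirB[dec])
      ratios[inc] <- (ubB[inc] - state$xB[inc]) / dirB[inc]
      ratios[ratios < 0] <- 0             # degeneracy guard
      t_star <- min(flip_t, ratios)
      if (min(ratios) < flip_t - 1e-12) {
        # basis change: Bland's rule among the blocking rows
        block <- which(ratios <= t_star + 1e-12)
        leave <- block[which.min(state$basis[block])]
        state$xB <- state$xB + dirB * t_star
        out <- state$basis[leave]
        state$at_ub[out] <- dirB[leave] > 0  # hit its upper bound?
        state$xB[leave] <- if (increasing) lbe[j] + t_star else ube[j] - t_star
        state$basis[leave] <- j
        # clamp against round-off
        state$xB <- pmin(pmax(state$xB, lbe[state$basis]),
                         ube[state$basis])
      } else {
        state$xB <- state$xB + dirB * flip_t
        state$at_ub[j] <- !state$at_ub[j]    # flip, basis unchanged
      }
    }
    list(state = state, status = "iteration_limit")
  }

  full_solution <- function(state) {
    v <- ifelse(state$at_ub[seq_len(n + m)], ube, lbe)
    v[state$basis] <- state$xB
    v
  }

  # Phase 1: minimize the artificial mass
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- core(state, c1, max_iter)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  v1 <- full_solution(ph1$state)
  if (sum(v1[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))

  # Phase 2: clamp artificials, optimize the true objective
  ube[n + seq_len(m)] <- 0
  state <- ph1$state
  state$xB <- pmin(state$xB, ube[state$basis])
  c2 <- c(if (maximize) cvec else -cvec, rep(0, m))
  ph2 <- core(state, c2, max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  v <- full_solution(ph2$state)[seq_len(n)]
  list(status = "optimal", v = v, objective = sum(cvec * v))
}
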