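# Independent oracles, deliberately naive.

# Exhaustive vertex enumeration for max c'v s.t. A v = b, lb <= v <= ub:
# every basic solution (basis columns + nonbasic variables pinned at either
# bound) is enumerated and checked for feasibility.
brute_lp_max <- function(A, b, lb, ub, cvec, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  best <- -Inf
  if (m == 0) {
    return(sum(ifelse(cvec > 0, ub, lb) * cvec))
  }
  combs <- utils::combn(n, m)
  for (k in seq_len(ncol(combs))) {
    Bidx <- combs[, k]
    Nidx <- setdiff(seq_len(n), Bidx)
    B <- A[, Bidx, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    for (mask in 0:(2^length(Nidx) - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_along(Nidx) - 1)) > 0
      xN <- ifelse(at_ub, ub[Nidx], lb[Nidx])
      rhs <- b - if (length(Nidx)) A[, Nidx, drop = FALSE] %*% xN else 0
      xB <- solve(B, rhs)
      if (all(xB >= lb[Bidx] - tol) && all(xB <= ub[Bidx] + tol)) {
        v <- numeric(n); v[Bidx] <- xB; v[Nidx] <- xN
        best <- max(best, sum(cvec * v))
      }
    }
  }
  best
}

# Dense grid search for the stage-2 quadratic on a two-capped-species
# community: minimize mu1^2 + mu2^2 s.t. a'mu >= f*mu_max, 0 <= mu <= cap.
grid_qp_mu <- function(a, caps, f, mu_max, step = 5e-4) {
  g1 <- seq(0, caps[1], by = step)
  g2 <- seq(0, caps[2], by = step)
  grid <- expand.grid(mu1 = g1, mu2 = g2)
  feas <- grid$mu1 * a[1] + grid$mu2 * a[2] >= f * mu_max - 1e-12
  grid <- grid[feas, ]
  obj <- grid$mu1^2 + grid$mu2^2
  as.numeric(grid[which.min(obj), ])
}
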