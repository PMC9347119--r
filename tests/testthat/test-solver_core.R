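test_that("fba solves simple hand-checked programs", {
  chain <- chain_model(cap = 10)
  f <- fba(chain)
  expect_identical(f$status, "optimal")
  expect_equal(f$objective, 10, tolerance = 1e-9)
  # clamping the objective reaction to zero gives a zero optimum
  chain0 <- chain
  j <- match("EX_out", chain0$reactions$id)
  chain0$reactions$lb[j] <- chain0$reactions$ub[j] <- 0
  expect_equal(fba(chain0)$objective, 0)
})

test_that("the LP stage agrees with exhaustive vertex enumeration", {
  # (a) randomized small flux polytopes
  set.seed(101)
  for (trial in 1:12) {
    n <- sample(3:6, 1)
    m <- sample(1:(n - 1), 1)
    A <- matrix(round(rnorm(m * n), 1), m)
    lb <- round(runif(n, -3, 0), 1)
    ub <- round(runif(n, 0.5, 3), 1)
    cvec <- round(rnorm(n), 1)
    v0 <- runif(n) * (ub - lb) + lb
    b <- as.numeric(A %*% v0)
    got <- syntroflux:::lp_simplex(A, b, lb, ub, cvec, maximize = TRUE)
    expect_identical(got$status, "optimal")
    expect_equal(got$objective, brute_lp_max(A, b, lb, ub, cvec),
                 tolerance = 1e-6)
  }
  # (b) an actual community polytope (two capped species, 5 reactions)
  cm <- capped_pair()
  S <- as.matrix(stoichiometric_matrix(cm))
  live <- rowSums(abs(S)) > 0
  obj <- unname(syntroflux:::community_objective(cm))
  brute <- brute_lp_max(S[live, , drop = FALSE], numeric(sum(live)),
                        cm$reactions$lb, cm$reactions$ub, obj)
  expect_equal(fba(cm)$objective, brute, tolerance = 1e-9)
})

test_that("the cooperative tradeoff matches its closed form", {
  # two identical species with individual caps mu* = 1 and no shared
  # limiting resource: mu_i = f mu* a_i / ||a||^2
  cm <- capped_pair(a = c(spA = 0.3, spB = 0.7), cap = 1)
  sol <- cooperative_tradeoff(cm, f = 0.5)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$mu_c_max, 1, tolerance = 1e-8)
  expect_equal(sol$members$mu, 0.5 * c(0.3, 0.7) / (0.3^2 + 0.7^2),
               tolerance = 1e-5)
  # f = 1 recovers the full community optimum
  sol1 <- cooperative_tradeoff(cm, f = 1)
  expect_equal(sol1$community_growth, sol1$mu_c_max, tolerance = 1e-6)
  expect_error(cooperative_tradeoff(cm, f = 0), "lie in")
})

test_that("stage-2 growth rates are proportional to abundances when unconstrained", {
  for (n in 2:5) {
    set.seed(n)
    a <- runif(n)
    a <- a / sum(a)
    models <- lapply(seq_len(n), function(i) {
      make_capped_toy(sprintf("s%02d", i), cap = 10)
    })
    cm <- build_community(models, stats::setNames(a, sprintf("s%02d",
                                                             seq_len(n))))
    sol <- cooperative_tradeoff(cm, f = 0.5)
    ratio <- sol$members$mu / sol$members$abundance
    expect_lt(max(ratio) - min(ratio), 1e-5)
  }
})

test_that("the stage-2 quadratic agrees with a dense grid search", {
  a <- c(0.4, 0.6)
  cm <- capped_pair(a = c(spA = a[1], spB = a[2]), cap = 1)
  sol <- cooperative_tradeoff(cm, f = 0.5)
  ref <- grid_qp_mu(a, caps = c(1, 1), f = 0.5, mu_max = sol$mu_c_max)
  expect_lt(max(abs(sol$members$mu - ref)), 1e-3)
})

test_that("repeated solves are reproducible", {
  cm <- default_community()
  s1 <- cooperative_tradeoff(cm)
  s2 <- cooperative_tradeoff(cm)
  expect_equal(s1$members$mu, s2$members$mu, tolerance = 1e-12)
  expect_equal(s1$fluxes, s2$fluxes, tolerance = 1e-12)
})

test_that("relaxing a bound never decreases the community optimum", {
  cm <- sweep_community()
  cm20 <- set_community_exchange_bounds(cm, "h2", lb = -20)
  cm40 <- set_community_exchange_bounds(cm, "h2", lb = -40)
  expect_gte(fba(cm40)$objective, fba(cm20)$objective - 1e-9)
})

test_that("the gas sweep is monotone and saturates at the unconstrained optimum", {
  cm <- sweep_community()
  sw <- growth_sweep(cm, grid = seq(0, 160, length.out = 9))
  expect_equal(sw$thresholds, seq(0, 160, by = 20))
  # threshold 0: no electron donor, no growth
  expect_equal(sw$mu_c[1], 0, tolerance = 1e-9)
  expect_true(all(sw$table$mu[sw$table$threshold == 0] < 1e-9))
  expect_true(all(diff(sw$mu_c) > -1e-9))
  cmu <- set_community_exchange_bounds(cm, "h2", lb = -1000)
  cmu <- set_community_exchange_bounds(cmu, "co2", lb = -1000)
  free <- cooperative_tradeoff(cmu)
  expect_equal(sw$plateau$value, free$community_growth, tolerance = 1e-3)
  expect_true(sw$plateau$reached)
  expect_lte(sw$plateau$onset, length(sw$thresholds))
})

test_that("sweep input validation and degenerate grids", {
  cm <- sweep_community()
  expect_error(growth_sweep(cm, grid = numeric(0)), "empty")
  expect_error(growth_sweep(cm, grid = c(10, 5)), "sorted")
  one <- growth_sweep(cm, grid = 40)
  expect_equal(nrow(one$table), nrow(cm$species))
  expect_false(one$plateau$reached)
  expect_true(is.na(one$plateau$onset))
})

test_that("infeasible communities are reported, not mis-solved", {
  # force more methane than carbon allows
  cm <- default_community()
  cm <- set_community_exchange_bounds(cm, "ch4", lb = 10)
  sol <- cooperative_tradeoff(cm)
  expect_identical(sol$status, "infeasible")
  expect_identical(fba(cm)$status, "infeasible")
})
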