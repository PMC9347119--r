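make_cov <- function(values, samples = NULL, mags = NULL, map = NULL) {
  if (is.null(mags)) mags <- sprintf("mag%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(mags, samples)
  coverage_matrix(values, map)
}

test_that("replicate averaging is the arithmetic mean per experiment", {
  vals <- matrix(c(0.2, 0.4, 0.1, 0.1, 0.5, 0.5), nrow = 1,
                 dimnames = list("mag01", paste0("s", 1:6)))
  map <- stats::setNames(c("e1", "e1", "e2", "e2", "e3", "e3"),
                         paste0("s", 1:6))
  avg <- average_replicates(coverage_matrix(vals, map))
  expect_equal(unname(avg$values["mag01", ]), c(0.3, 0.1, 0.5))
  # identical replicates average to themselves; singleton passes through
  vals2 <- matrix(c(1, 1, 7), nrow = 1,
                  dimnames = list("mag01", c("a1", "a2", "b1")))
  map2 <- c(a1 = "A", a2 = "A", b1 = "B")
  avg2 <- average_replicates(coverage_matrix(vals2, map2))
  expect_equal(unname(avg2$values["mag01", ]), c(1, 7))
})

test_that("the dominance filter keeps experiments at the inclusive 1% boundary", {
  vals <- rbind(
    mag01 = c(0.005, 0.010, 0.200, 0),
    mag02 = c(0.995, 0.990, 0.800, 1)
  )
  colnames(vals) <- paste0("e", 1:4)
  cv <- coverage_matrix(vals)
  kept <- filter_dominant(cv, "mag01", min_fraction = 0.01)
  expect_identical(colnames(kept$values), c("e2", "e3"))
  expect_warning(
    empty <- filter_dominant(cv, "mag01", min_fraction = 0.5),
    "empty matrix"
  )
  expect_equal(ncol(empty$values), 0)
  expect_error(filter_dominant(cv, "magXX"), "not in matrix")
})

test_that("pearson_matrix matches cor.test and masks by significance", {
  set.seed(5)
  x <- matrix(rnorm(4 * 30), nrow = 4,
              dimnames = list(paste0("m", 1:4), paste0("e", 1:30)))
  x[2, ] <- x[1, ] + rnorm(30, sd = 0.1)
  x <- abs(x)
  cv <- coverage_matrix(x)
  res <- pearson_matrix(cv)
  ct <- stats::cor.test(x[1, ], x[2, ])
  expect_equal(res$r["m1", "m2"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p["m1", "m2"], ct$p.value, tolerance = 1e-9)
  expect_true(res$significant["m1", "m2"])
  expect_equal(diag(res$r), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(res$r))
  expect_true(isSymmetric(res$significant))
  expect_error(pearson_matrix(make_cov(matrix(1:4, 2))), "at least 3")
})

test_that("constant rows are reported as missing, with a warning", {
  vals <- rbind(flat = rep(1, 5), vary = c(1, 2, 3, 4, 5))
  colnames(vals) <- paste0("e", 1:5)
  expect_warning(res <- pearson_matrix(coverage_matrix(vals)), "constant")
  expect_true(is.na(res$r["flat", "vary"]))
  expect_false(res$significant["flat", "vary"])
})

test_that("column permutation leaves the correlation matrix unchanged", {
  cv <- average_replicates(make_coverage_matrix(
    coverage_blueprint(n_mags = 6, n_experiments = 40, seed = 3)))
  perm <- sample(ncol(cv$values))
  r1 <- pearson_matrix(cv)$r
  r2 <- pearson_matrix(coverage_matrix(cv$values[, perm]))$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("planted correlations converge towards their target with sample size", {
  target <- 0.96
  r_at <- function(n) {
    bp <- coverage_blueprint(
      n_mags = 4, n_experiments = n, replicates = 1,
      correlation_blocks = list(list(members = c("mag01", "mag02"),
                                     r = target)),
      seed = 21
    )
    pearson_matrix(make_coverage_matrix(bp))$r["mag01", "mag02"]
  }
  expect_lt(abs(r_at(50) - target), 0.1)
  expect_lt(abs(r_at(500) - target), 0.05)
})

test_that("full pipeline: average, filter, correlate on generated data", {
  cv <- make_coverage_matrix(coverage_blueprint(seed = 8))
  expect_equal(ncol(cv$values), 134)
  avg <- average_replicates(cv)
  expect_equal(ncol(avg$values), 67)
  dom <- sprintf("mag%02d", 1:5)
  kept <- filter_dominant(avg, dom, min_fraction = 0.01)
  res <- pearson_matrix(kept)
  expect_gt(res$r["mag01", "mag02"], 0.8)  # planted 0.96 pair still strong
  expect_true(res$significant["mag01", "mag02"])
})
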