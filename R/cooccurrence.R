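#' Construct a coverage matrix
#'
#' Rows are metagenome-assembled genomes (MAGs), columns are sequencing
#' samples; values are non-negative coverages or relative abundances. The
#' replicate map assigns each sample to an experiment identifier, so that
#' technical or biological replicates can be averaged before correlation.
#'
#' @param values Non-negative numeric matrix with row and column names.
#' @param replicate_map Named character vector: sample id -> experiment id.
#'   Defaults to one experiment per sample.
#' @return A `coverage_matrix`.
#' @export
coverage_matrix <- function(values, replicate_map = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("coverage values must be non-negative",
                            call. = FALSE)
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("coverage matrix needs row (MAG) and column (sample) names",
         call. = FALSE)
  }
  if (is.null(replicate_map)) {
    replicate_map <- stats::setNames(colnames(values), colnames(values))
  }
  if (!all(colnames(values) %in% names(replicate_map))) {
    stop("replicate map must cover all samples", call. = FALSE)
  }
  structure(list(values = values,
                 replicate_map = replicate_map[colnames(values)]),
            class = "coverage_matrix")
}

#' Average replicate samples into experiment-level profiles
#'
#' Collapses the sample columns of a coverage matrix into one column per
#' experiment identifier by arithmetic mean across that experiment's
#' replicates.
#'
#' @param matrix A [coverage_matrix()].
#' @return A `coverage_matrix` with one column per experiment (each mapped
#'   to itself).
#' @export
average_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  groups <- matrix$replicate_map
  exps <- unique(unname(groups))
  if (any(!nzchar(exps))) stop("experiment with empty identifier",
                               call. = FALSE)
  cols <- lapply(exps, function(e) {
    idx <- which(groups == e)
    if (length(idx) == 0) stop("experiment '", e, "' has zero samples",
                               call. = FALSE)
    rowMeans(matrix$values[, idx, drop = FALSE])
  })
  out <- matrix(unlist(cols), nrow = nrow(matrix$values),
                dimnames = list(rownames(matrix$values), exps))
  coverage_matrix(out)
}

#' Retain experiments dominated by a core species set
#'
#' Keeps the experiments (columns) in which the dominant species together
#' make up at least `min_fraction` of the column total (inclusive
#' boundary). Columns are normalized by their sum before the comparison,
#' so the filter works identically on raw coverages and on relative
#' abundances.
#'
#' @param matrix A [coverage_matrix()].
#' @param dominant_ids Row (MAG) ids of the dominant species.
#' @param min_fraction Retention threshold (default 0.01, i.e. 1%).
#' @return A filtered `coverage_matrix`; empty (zero columns) with a
#'   warning when no experiment qualifies.
#' @export
filter_dominant <- function(matrix, dominant_ids, min_fraction = 0.01) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  missing <- setdiff(dominant_ids, rownames(matrix$values))
  if (length(missing)) {
    stop("dominant ids not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  totals <- colSums(matrix$values)
  frac <- colSums(matrix$values[dominant_ids, , drop = FALSE]) /
    ifelse(totals > 0, totals, 1)
  keep <- frac >= min_fraction
  if (!any(keep)) {
    warning("no experiment retains >= ", min_fraction,
            " of the dominant species; returning an empty matrix",
            call. = FALSE)
  }
  coverage_matrix(matrix$values[, keep, drop = FALSE],
                  matrix$replicate_map[keep])
}

#' Pairwise Pearson correlation of coverage profiles
#'
#' Computes the MAG-by-MAG Pearson correlation matrix across experiments,
#' with two-sided p-values from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and a significance mask at
#' `alpha` (pairs with `p >= alpha` are masked). Constant rows have
#' undefined correlations and are reported as `NA`.
#'
#' @param matrix A `coverage_matrix` with at least three columns.
#' @param alpha Significance level for the mask (default 0.05).
#' @return A `correlation_result`: list with symmetric matrices `r`, `p`,
#'   logical `significant`, and the number of experiments `n`.
#' @export
pearson_matrix <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  x <- matrix$values
  n <- ncol(x)
  if (n < 3) stop("need at least 3 experiments, got ", n, call. = FALSE)
  constant <- apply(x, 1, stats::sd) == 0
  if (any(constant)) {
    warning("constant coverage rows reported as NA: ",
            paste(rownames(x)[constant], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(x)))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r) <- ifelse(constant, NA, 1)
  rr <- pmin(pmax(r, -1), 1)
  tval <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  diag(p) <- 0
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d MAGs over %d experiments; %d significant pairs\n",
              nrow(x$r), x$n,
              sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)))
  invisible(x)
}

#' Read/write coverage matrices as TSV
#'
#' The coverage TSV has MAGs as rows and samples as columns; the optional
#' replicate map TSV has columns `sample` and `experiment`.
#'
#' @param path Coverage TSV.
#' @param replicate_path Optional replicate map TSV.
#' @return A `coverage_matrix`.
#' @export
read_coverage <- function(path, replicate_path = NULL) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  rep_map <- NULL
  if (!is.null(replicate_path)) {
    rm <- utils::read.table(replicate_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    rep_map <- stats::setNames(as.character(rm$experiment), rm$sample)
  }
  coverage_matrix(vals, rep_map)
}

#' @rdname read_coverage
#' @param matrix A `coverage_matrix` to write.
#' @export
write_coverage <- function(matrix, path) {
  utils::write.table(matrix$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
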