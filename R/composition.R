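# Genus-composition processing: coverage filter -> relative abundance ->
# host averaging -> top-N collapse -> Euclidean hierarchical clustering.
# The clustering step is shared with KO paralog matrices.

#' Remove low-coverage samples
#'
#' Drops samples whose total alignment count is strictly below
#' `min_total` (default 1,000), preserving the order of survivors.
#'
#' @param counts Sample x genus count matrix (non-negative).
#' @param min_total Minimum total count for a sample to be retained.
#' @return The filtered count matrix.
#' @export
filter_low_coverage <- function(counts, min_total = 1000L) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) stop("all samples fall below the coverage threshold of ",
                       min_total)
  counts[keep, , drop = FALSE]
}

#' Per-sample relative abundances
#'
#' @param counts Sample x genus count matrix; every row total must be
#'   positive (low-coverage samples should already be filtered).
#' @return A matrix of per-sample fractions; each row sums to 1.
#' @export
relative_abundance <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 1L, totals, "/")
}

#' Average relative abundances within host categories
#'
#' Unweighted arithmetic mean of per-sample relative-abundance rows within
#' each host; every host row of the result sums to 1.
#'
#' @param rel Sample x genus relative-abundance matrix.
#' @param hosts Named character vector mapping every sample (row name) to
#'   a host label.
#' @return Host x genus matrix of mean relative abundances.
#' @export
host_mean_composition <- function(rel, hosts) {
  stopifnot(is.matrix(rel), !is.null(rownames(rel)))
  missing <- setdiff(rownames(rel), names(hosts))
  if (length(missing))
    stop("sample(s) without a host label: ", paste(missing, collapse = ", "))
  h <- hosts[rownames(rel)]
  sums <- rowsum(rel, h)
  sweep(sums, 1L, as.vector(table(h)[rownames(sums)]), "/")
}

#' Collapse to the top-N genera plus "others"
#'
#' Keeps the `n` genera with the largest mean abundance across host rows
#' (in decreasing order of that mean) and sums all remaining genera into
#' an `"others"` column; row sums are preserved. With `n` at or above the
#' genus count the matrix is returned unchanged (no `"others"` column).
#'
#' @param host_matrix Host x genus abundance matrix.
#' @param n Number of genera to keep (default 10).
#' @return Host x (n + 1) matrix.
#' @export
top_n_collapse <- function(host_matrix, n = 10L) {
  stopifnot(is.matrix(host_matrix), n >= 1L)
  if (ncol(host_matrix) <= n) return(host_matrix)
  ord <- order(colMeans(host_matrix), decreasing = TRUE)
  top <- ord[seq_len(n)]
  rest <- ord[-seq_len(n)]
  cbind(host_matrix[, top, drop = FALSE],
        others = rowSums(host_matrix[, rest, drop = FALSE]))
}

#' Hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering of matrix rows on pairwise Euclidean
#' distances, used both for host composition profiles and for KO paralog
#' median matrices.
#'
#' @param m Numeric matrix (rows are the objects to cluster); at least 2
#'   rows, no missing values.
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"` (Ward's D2).
#' @return An object of class `hclust`.
#' @export
hclust_euclidean <- function(m, linkage = c("average", "single",
                                            "complete", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("clustering needs at least 2 rows")
  if (anyNA(m)) stop("matrix contains missing values")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)
}
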