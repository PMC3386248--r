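# Per-subject dwell-time profiles over modular configurations and the
# cohort-level meta-modular consensus clustering.

#' Module counts across a subject's windows
#'
#' @param partitions ordered list of [detect_modules()] partitions, one per
#'   window.
#' @return integer vector of per-window module counts (order preserved).
#' @export
module_count_series <- function(partitions) {
  if (length(partitions) == 0) stop("partitions must be non-empty")
  vapply(partitions, function(p) as.integer(p$n_modules), integer(1))
}

#' Modular dwell time
#'
#' Percentage of a subject's windows spent in configurations with each
#' observed module count. Percentages sum to 100 exactly (module counts
#' partition the windows).
#'
#' @param series integer vector of per-window module counts.
#' @param subject_id optional subject label.
#' @return object of class `dwell_profile`: `subject_id` and `percentages`
#'   (named numeric, names = module counts).
#' @export
modular_dwell_time <- function(series, subject_id = NA_character_) {
  if (length(series) == 0) stop("series must be non-empty")
  tab <- table(series)
  pct <- 100 * as.numeric(tab) / length(series)
  names(pct) <- names(tab)
  structure(
    list(subject_id = subject_id, percentages = pct),
    class = "dwell_profile"
  )
}

#' @export
print.dwell_profile <- function(x, ...) {
  cat(sprintf("dwell_profile '%s':\n", x$subject_id))
  print(round(x$percentages, 2))
  invisible(x)
}

#' Co-assignment frequencies across pooled windowed graphs
#'
#' Because module label numbers are arbitrary from graph to graph, nodes are
#' compared by whether they share a label within each graph: entry (i, j) is
#' the fraction of pooled graphs in which nodes i and j are assigned to the
#' same module. Invariant under any per-graph relabelling.
#'
#' @param partitions list of partitions pooled over all windows and
#'   subjects; all must share the node count.
#' @return object of class `coassignment`: `frequencies` (N x N symmetric,
#'   diagonal 1) and `n_graphs_pooled`.
#' @export
coassignment <- function(partitions) {
  if (length(partitions) == 0) stop("partitions must be non-empty")
  ns <- vapply(partitions, function(p) length(p$labels), integer(1))
  if (length(unique(ns)) != 1) stop("all partitions must share node count")
  N <- ns[1]
  acc <- matrix(0, N, N)
  for (p in partitions) {
    acc <- acc + outer(p$labels, p$labels, "==")
  }
  freq <- acc / length(partitions)
  diag(freq) <- 1
  structure(
    list(frequencies = freq, n_graphs_pooled = length(partitions)),
    class = "coassignment"
  )
}

#' Meta-modular consensus clustering
#'
#' Ward agglomerative hierarchical clustering of the co-assignment
#' dissimilarity `d(i, j) = 1 - frequency(i, j)` (Lance-Williams Ward update
#' applied to the dissimilarity as given, no embedding), cut at `k`
#' clusters. Deterministic given its input. With `k = N` every node is its
#' own cluster.
#'
#' @param coassign a [coassignment()].
#' @param k number of meta-modules (default 5, the maximum module count
#'   observed per windowed graph).
#' @return object of class `meta_modules`: `labels` (canonical 1..k), `k`,
#'   and `linkage` (the `hclust` merge history; heights non-decreasing).
#' @export
meta_modules <- function(coassign, k = 5) {
  stopifnot(inherits(coassign, "coassignment"))
  N <- nrow(coassign$frequencies)
  k <- as.integer(k)
  if (k < 1 || k > N) stop(sprintf("k must lie in 1..%d", N))
  d <- stats::as.dist(1 - coassign$frequencies)
  hc <- stats::hclust(d, method = "ward.D")
  labels <- canonicalize_labels(stats::cutree(hc, k = k))
  structure(
    list(labels = labels, k = k, linkage = hc),
    class = "meta_modules"
  )
}

#' @export
print.meta_modules <- function(x, ...) {
  cat(sprintf(
    "meta_modules: %d clusters over %d nodes (sizes %s)\n",
    x$k, length(x$labels),
    paste(tabulate(x$labels, x$k), collapse = ", ")
  ))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance; 1 for identical partitions
#' (up to relabelling), ~0 for independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return numeric adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
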