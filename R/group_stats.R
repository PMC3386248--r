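# Sub-network dwell time under the fixed final module assignment, and
# two-group statistical comparison.

#' Composite within-module degree Z-score of a sub-network
#'
#' Within-module degree Z-scores are computed under a *fixed* module
#' assignment (by default the atlas final assignment, not the window's own
#' detected partition) and averaged over the sub-network's four nodes.
#'
#' @param graph a [correlation_graph()] result or symmetric matrix.
#' @param fixed_partition integer module labels covering all nodes.
#' @param subnet a sub-network definition: `list(name, node_ids)` as from
#'   [dmn_subnetworks()].
#' @param weight_mode passed to [within_module_degree_z()].
#' @return composite Z-score (single numeric).
#' @export
subnetwork_composite_z <- function(graph, fixed_partition, subnet,
                                   weight_mode = c("signed", "positive")) {
  weight_mode <- match.arg(weight_mode)
  W <- as_weights(graph)
  fixed_partition <- check_labels(fixed_partition, nrow(W))
  ids <- subnet$node_ids
  if (any(ids < 1 | ids > nrow(W))) {
    stop(sprintf("sub-network '%s' has nodes outside the partition", subnet$name))
  }
  z <- within_module_degree_z(W, fixed_partition, weight_mode = weight_mode)
  mean(z[ids])
}

#' Sub-network dwell time across a subject's windows
#'
#' A sub-network "strongly contributes" to a window's brain state when its
#' composite within-module degree Z-score is strictly positive; its dwell
#' time is the percentage of windows in which that holds. Ties at exactly
#' zero count as not strong.
#'
#' @param dyn a [dynamic_graphs()] result.
#' @param fixed_partition integer module labels covering all nodes.
#' @param subnets named list of sub-network definitions
#'   (default [dmn_subnetworks()]).
#' @param weight_mode passed to [within_module_degree_z()].
#' @return `dwell_profile` whose `percentages` are named by sub-network.
#'   (Sub-network states are not mutually exclusive, so these do not sum
#'   to 100.)
#' @export
subnetwork_dwell_time <- function(dyn, fixed_partition,
                                  subnets = dmn_subnetworks(),
                                  weight_mode = c("signed", "positive")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(dyn, "dynamic_connectivity"))
  n_win <- length(dyn$graphs)
  comp <- vapply(dyn$graphs, function(g) {
    vapply(subnets, function(sn) {
      subnetwork_composite_z(g, fixed_partition, sn, weight_mode = weight_mode)
    }, numeric(1))
  }, numeric(length(subnets)))
  comp <- matrix(comp, nrow = length(subnets))  # subnets x windows
  pct <- 100 * rowMeans(comp > 0)
  names(pct) <- vapply(subnets, `[[`, character(1), "name")
  structure(
    list(subject_id = dyn$subject_id, percentages = pct),
    class = "dwell_profile"
  )
}

#' Two-group comparison by Wilcoxon rank-sum
#'
#' Two-sided rank-sum test: exact enumeration when the combined sample size
#' is at most 20 and there are no ties, normal approximation with tie
#' correction otherwise. Medians and linear-interpolation quartiles are
#' reported per group.
#'
#' @param values_a,values_b per-subject values for the two groups (each of
#'   length >= 2).
#' @param label_a,label_b group labels for reporting.
#' @return object of class `group_comparison`: `group_medians_iqr` (per
#'   group: median, q1, q3, n), `p_value`, `test_name`.
#' @export
compare_groups <- function(values_a, values_b,
                           label_a = "A", label_b = "B") {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 subjects")
  }
  n_tot <- length(values_a) + length(values_b)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- n_tot <= 20 && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  summ <- function(x, lab) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = lab, n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  structure(
    list(
      group_medians_iqr = rbind(summ(values_a, label_a),
                                summ(values_b, label_b)),
      p_value = ht$p.value,
      test_name = if (exact) {
        "Wilcoxon rank-sum (exact)"
      } else {
        "Wilcoxon rank-sum (normal approximation, tie-corrected)"
      }
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g\n", x$test_name, x$p_value))
  print(x$group_medians_iqr, row.names = FALSE)
  invisible(x)
}

#' Two-group comparison of proportions by chi-squared test
#'
#' 2 x 2 chi-squared test without continuity correction (configurable).
#'
#' @param success_a,total_a successes and total for group A.
#' @param success_b,total_b successes and total for group B.
#' @param correct apply Yates continuity correction (default FALSE).
#' @param label_a,label_b group labels.
#' @return object of class `group_comparison` (medians slot carries the
#'   proportions).
#' @export
compare_proportions <- function(success_a, total_a, success_b, total_b,
                                correct = FALSE,
                                label_a = "A", label_b = "B") {
  if (total_a < 1 || total_b < 1) stop("totals must be >= 1")
  if (success_a < 0 || success_a > total_a ||
      success_b < 0 || success_b > total_b) {
    stop("successes must lie in [0, total]")
  }
  tab <- matrix(c(success_a, total_a - success_a,
                  success_b, total_b - success_b), 2, 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  props <- data.frame(
    group = c(label_a, label_b),
    n = c(total_a, total_b),
    median = c(success_a / total_a, success_b / total_b),
    q1 = NA_real_, q3 = NA_real_
  )
  structure(
    list(
      group_medians_iqr = props,
      p_value = ht$p.value,
      test_name = sprintf("chi-squared (2x2%s)",
                          if (correct) ", continuity-corrected" else ""),
      statistic = unname(ht$statistic)
    ),
    class = "group_comparison"
  )
}
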