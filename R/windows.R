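# Sliding-window construction of fully connected signed connectivity graphs.

#' Sliding-window configuration
#'
#' Window lengths are odd so that each windowed graph can be centred on a
#' single volume; even lengths are permitted only for internal reference
#' computations (the variance-curve reference uses half the scan).
#'
#' @param length_volumes window length L in volumes (odd positive integer).
#' @param stride_volumes advance per window (default 1 volume).
#' @param allow_even permit an even length (internal use).
#' @return object of class `window_config`.
#' @export
window_config <- function(length_volumes, stride_volumes = 1,
                          allow_even = FALSE) {
  L <- as.integer(length_volumes)
  s <- as.integer(stride_volumes)
  if (is.na(L) || L < 2) stop("length_volumes must be a positive integer >= 2")
  if (!allow_even && L %% 2 == 0) {
    stop("length_volumes must be odd (windows are centred on a volume)")
  }
  if (is.na(s) || s < 1) stop("stride_volumes must be a positive integer")
  structure(
    list(length_volumes = L, stride_volumes = s),
    class = "window_config"
  )
}

#' Number of sliding windows in a scan
#'
#' `floor((T - L) / stride) + 1`; with the default unit stride a 100-volume
#' scan and an 11-volume window give 90 windowed graphs.
#'
#' @param n_volumes scan length T in volumes.
#' @param config a [window_config()].
#' @return integer window count.
#' @export
window_count <- function(n_volumes, config) {
  T_ <- as.integer(n_volumes)
  if (config$length_volumes > T_) {
    stop(sprintf(
      "window length %d exceeds scan length %d",
      config$length_volumes, T_
    ))
  }
  (T_ - config$length_volumes) %/% config$stride_volumes + 1L
}

#' Windowed Pearson connectivity graph
#'
#' Off-diagonal entry (i, j) is the Pearson correlation of regions i and j
#' over the half-open volume range `[start_volume, start_volume + L)`
#' (0-based). The diagonal is stored as 1 but excluded from all modularity
#' and degree computations downstream.
#'
#' @param ts an [roi_timeseries()].
#' @param start_volume 0-based first volume of the window.
#' @param config a [window_config()].
#' @param window_index optional 0-based window index recorded on the graph.
#' @param variance_mode `"strict"` errors on a zero-variance region inside
#'   the window; `"lenient"` sets that region's weights to 0 with a warning.
#' @return object of class `connectivity_matrix` with fields `weights`
#'   (N x N, symmetric, in \[-1, 1\]), `window_index`, `center_volume`.
#' @export
correlation_graph <- function(ts, start_volume, config,
                              window_index = NA_integer_,
                              variance_mode = c("strict", "lenient")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(ts, "roi_timeseries"))
  L <- config$length_volumes
  T_ <- nrow(ts$data)
  start_volume <- as.integer(start_volume)
  if (start_volume < 0 || start_volume + L > T_) {
    stop(sprintf(
      "window [%d, %d) does not fit in %d volumes", start_volume,
      start_volume + L, T_
    ))
  }
  block <- ts$data[(start_volume + 1):(start_volume + L), , drop = FALSE]
  v <- apply(block, 2, stats::var)
  zero_var <- which(v <= 0 | !is.finite(v))
  if (length(zero_var) > 0) {
    msg <- sprintf(
      "zero-variance region(s) %s in window starting at volume %d",
      paste(ts$region_ids[zero_var], collapse = ", "), start_volume
    )
    if (variance_mode == "strict") stop(msg)
    warning(msg)
  }
  if (length(zero_var) > 0) {
    keep <- setdiff(seq_len(ncol(block)), zero_var)
    W <- matrix(0, ncol(block), ncol(block))
    if (length(keep) >= 2) {
      W[keep, keep] <- stats::cor(block[, keep, drop = FALSE])
    }
    diag(W) <- 1
  } else {
    W <- stats::cor(block)
  }
  # clamp tiny numerical overshoot
  W[W > 1] <- 1
  W[W < -1] <- -1
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ts$region_ids, ts$region_ids)
  structure(
    list(
      weights = W,
      window_index = as.integer(window_index),
      center_volume = start_volume + (L - 1L) %/% 2L
    ),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "connectivity_matrix: %d nodes, window %s, centre volume %s\n",
    nrow(x$weights),
    ifelse(is.na(x$window_index), "?", x$window_index),
    x$center_volume
  ))
  invisible(x)
}

#' All sliding-window graphs for one subject
#'
#' @inheritParams correlation_graph
#' @return object of class `dynamic_connectivity`: ordered list `graphs`
#'   (length equal to [window_count()]), the `config`, and `subject_id`.
#' @export
dynamic_graphs <- function(ts, config,
                           variance_mode = c("strict", "lenient")) {
  variance_mode <- match.arg(variance_mode)
  n_win <- window_count(nrow(ts$data), config)
  starts <- (seq_len(n_win) - 1L) * config$stride_volumes
  graphs <- lapply(seq_len(n_win), function(k) {
    correlation_graph(ts, starts[k], config,
                      window_index = k - 1L, variance_mode = variance_mode)
  })
  structure(
    list(graphs = graphs, config = config, subject_id = ts$subject_id),
    class = "dynamic_connectivity"
  )
}

#' @export
print.dynamic_connectivity <- function(x, ...) {
  cat(sprintf(
    "dynamic_connectivity '%s': %d windows of length %d (stride %d)\n",
    x$subject_id, length(x$graphs), x$config$length_volumes,
    x$config$stride_volumes
  ))
  invisible(x)
}
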