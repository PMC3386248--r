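# Data-driven window-length selection via Q* variability, module-count
# curves across window lengths, and power-law extrapolation of the
# instantaneous modular configuration.

#' Standard deviation of Q* across window lengths
#'
#' For each candidate length, every window of every subject is graphed and
#' its modules detected; the standard deviation of Q* over all pooled graphs
#' is recorded. Variability is reported relative to a reference length of
#' half the scan (`floor(T/2)`, added automatically if absent):
#' `relative_variance_pct(L) = 100 * (sd(L) / sd(reference) - 1)`.
#'
#' @param cohort list of [roi_timeseries()] (or records with a `ts` field).
#' @param lengths candidate window lengths in volumes.
#' @param seed integer seed for the module detections.
#' @param n_restarts optimizer restarts per graph.
#' @param stride window stride (default 1).
#' @return object of class `qstar_variance_curve`: data frame with columns
#'   `length`, `sd_qstar`, `relative_variance_pct`; attribute
#'   `reference_length`.
#' @export
qstar_variance_curve <- function(cohort, lengths, seed = 1, n_restarts = 10,
                                 stride = 1) {
  cohort <- normalize_cohort(cohort)
  T_ <- nrow(cohort[[1]]$data)
  ref <- T_ %/% 2L
  lengths <- sort(unique(as.integer(c(lengths, ref))))
  if (any(lengths > T_)) stop("window lengths must not exceed scan length")
  sd_q <- vapply(lengths, function(L) {
    qs <- cohort_qstars(cohort, L, stride, seed, n_restarts)
    stats::sd(qs)
  }, numeric(1))
  sd_q[sd_q < 1e-12] <- 0  # constant-Q* cohorts: rounding noise is not signal
  ref_sd <- sd_q[lengths == ref]
  rel <- if (ref_sd > 0) 100 * (sd_q / ref_sd - 1) else ifelse(sd_q > 0, Inf, 0)
  out <- data.frame(
    length = lengths,
    sd_qstar = sd_q,
    relative_variance_pct = rel
  )
  structure(out,
    reference_length = ref,
    class = c("qstar_variance_curve", "data.frame")
  )
}

# Pool Q* values over all windows of all subjects at one window length.
cohort_qstars <- function(cohort, L, stride, seed, n_restarts) {
  unlist(lapply(seq_along(cohort), function(si) {
    cfg <- window_config(L, stride, allow_even = TRUE)
    dyn <- dynamic_graphs(cohort[[si]], cfg)
    vapply(seq_along(dyn$graphs), function(wi) {
      detect_modules(dyn$graphs[[wi]], n_restarts = n_restarts,
                     seed = derive_seed(seed, si, L, wi))$qstar
    }, numeric(1))
  }))
}

# Accept either a list of roi_timeseries or generate_cohort() records.
normalize_cohort <- function(cohort) {
  if (inherits(cohort, "roi_timeseries")) return(list(cohort))
  lapply(cohort, function(x) {
    if (inherits(x, "roi_timeseries")) x else x$ts
  })
}

#' Select the smallest reliable odd window length
#'
#' Returns the smallest odd length whose Q* variability is no more than
#' `cutoff_pct` percent above the half-scan reference.
#'
#' @param curve a [qstar_variance_curve()].
#' @param cutoff_pct relative-variance cutoff in percent (default 10).
#' @param parity currently only `"odd"` windows are selectable.
#' @return window length in volumes.
#' @export
select_window <- function(curve, cutoff_pct = 10, parity = "odd") {
  stopifnot(inherits(curve, "qstar_variance_curve"))
  parity <- match.arg(parity, "odd")
  ok <- curve$relative_variance_pct <= cutoff_pct & curve$length %% 2 == 1
  if (!any(ok)) {
    stop(sprintf(
      "no reliable window: no odd length has relative Q* variance <= %g%%",
      cutoff_pct
    ))
  }
  min(curve$length[ok])
}

#' Proportion of module counts across window lengths
#'
#' Pools all windows of all subjects at each length and tallies the number
#' of detected modules, binned as 1, 2, 3, 4, 5 and "6+".
#'
#' @inheritParams qstar_variance_curve
#' @return object of class `module_count_curve`: data frame with columns
#'   `length`, `n_modules` (character bin) and `proportion` (summing to 1
#'   within each length).
#' @export
module_count_curve <- function(cohort, lengths, seed = 1, n_restarts = 10,
                               stride = 1) {
  cohort <- normalize_cohort(cohort)
  T_ <- nrow(cohort[[1]]$data)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths > T_)) stop("window lengths must not exceed scan length")
  bins <- c("1", "2", "3", "4", "5", "6+")
  rows <- lapply(lengths, function(L) {
    counts <- unlist(lapply(seq_along(cohort), function(si) {
      cfg <- window_config(L, stride, allow_even = TRUE)
      dyn <- dynamic_graphs(cohort[[si]], cfg)
      vapply(seq_along(dyn$graphs), function(wi) {
        detect_modules(dyn$graphs[[wi]], n_restarts = n_restarts,
                       seed = derive_seed(seed, si, L, wi))$n_modules
      }, integer(1))
    }))
    binned <- ifelse(counts >= 6, "6+", as.character(counts))
    tab <- table(factor(binned, levels = bins))
    data.frame(
      length = L,
      n_modules = bins,
      proportion = as.numeric(tab) / length(counts)
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("module_count_curve", "data.frame"))
}

#' Power-law extrapolation of the instantaneous modular configuration
#'
#' Fits ordinary least squares to (log10 L, log10 p(L)) over the given fit
#' range for the proportion p of windows with `target_count` modules, and
#' returns `100 * 10^intercept` — the extrapolated percentage at
#' log10(L) = 0, i.e. a window of a single volume, operationalizing the
#' "instantaneous" configuration.
#'
#' @param curve a [module_count_curve()].
#' @param fit_range window lengths to fit (all must be present in the curve
#'   with nonzero proportion).
#' @param target_count module count whose proportion is extrapolated
#'   (default 2).
#' @return extrapolated percentage.
#' @export
powerlaw_intercept <- function(curve, fit_range, target_count = 2) {
  stopifnot(inherits(curve, "module_count_curve"))
  key <- as.character(target_count)
  sub <- curve[curve$n_modules == key & curve$length %in% fit_range, ]
  missing_l <- setdiff(fit_range, sub$length)
  if (length(missing_l) > 0) {
    stop(sprintf(
      "fit_range lengths absent from curve: %s",
      paste(missing_l, collapse = ", ")
    ))
  }
  if (any(sub$proportion <= 0)) {
    stop(sprintf(
      "zero proportion of %s-module windows at length(s) %s: log-log fit undefined",
      key, paste(sub$length[sub$proportion <= 0], collapse = ", ")
    ))
  }
  fit <- stats::lm(log10(proportion) ~ log10(length), data = sub)
  100 * 10^unname(coef(fit)[1])
}
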