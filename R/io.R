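# Delimited-text readers/writers, pipeline configuration and the
# end-to-end pipeline driver.

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop(sprintf("%s: empty file", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read an ROI time-series file
#'
#' Tab- or comma-delimited (auto-detected), volumes as rows, regions as
#' columns, header row of region ids.
#'
#' @param path file path.
#' @param tr_seconds repetition time to attach (seconds).
#' @param subject_id subject label; defaults to the file name sans extension.
#' @return an [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr_seconds = 3, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- detect_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop(sprintf("%s: duplicate region ids in header", path))
  }
  n_col <- length(header)
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  n_fields <- lengths(body)
  ragged <- which(n_fields != n_col)
  if (length(ragged) > 0) {
    stop(sprintf(
      "%s: line %d has %d fields, expected %d",
      path, ragged[1] + 1L, n_fields[ragged[1]], n_col
    ))
  }
  suppressWarnings(
    vals <- vapply(body, function(r) as.numeric(r), numeric(n_col))
  )
  vals <- matrix(vals, nrow = n_col)
  bad <- which(apply(is.na(vals), 2, any))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric value on line %d", path, bad[1] + 1L))
  }
  data <- t(vals)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  roi_timeseries(data, tr_seconds = tr_seconds, region_ids = header,
                 subject_id = subject_id)
}

#' Write an ROI time-series file
#'
#' Tab-delimited, full double precision (`%.17g`), so that
#' [read_timeseries()] round-trips the values bit-exactly.
#'
#' @param ts an [roi_timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$region_ids, collapse = "\t"), con)
  body <- apply(ts$data, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

#' Write / read a switching ground truth as a JSON sidecar
#' @param truth a [switching_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "switching_truth"))
  payload <- list(
    state_sequence = truth$state_sequence,
    occupancy = as.list(truth$occupancy),
    specs = lapply(truth$specs, function(s) {
      list(
        state_id = s$state_id,
        community_map = s$community_map,
        rho_in = s$rho_in,
        rho_out = s$rho_out
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(payload$specs)), function(i) {
    s <- payload$specs[i, ]
    state_spec(s$state_id, unlist(s$community_map), s$rho_in, s$rho_out)
  })
  switching_truth(unlist(payload$state_sequence), specs)
}

#' Write a synthetic cohort to disk with its manifest
#'
#' One tab-delimited time-series file and one JSON ground-truth sidecar per
#' subject, plus a manifest (`subject_id`, `group`, `path`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly; also written to
#'   `dir/manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    f <- file.path(dir, paste0(rec$ts$subject_id, ".tsv"))
    write_timeseries(rec$ts, f)
    write_ground_truth(rec$truth,
                       file.path(dir, paste0(rec$ts$subject_id, "_truth.json")))
    data.frame(subject_id = rec$ts$subject_id, group = rec$group, path = f,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest
#' @param path manifest path (tab-delimited: subject_id, group, path).
#' @return data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns subject_id, group, path")
  }
  if (nrow(m) == 0) stop("manifest is empty")
  m
}

#' Serialize windowed graphs
#'
#' `write_graphs()` emits one tab-delimited N x N block per window preceded
#' by a `# window <index>` header line; `write_graphs_long()` emits a single
#' flattened table (window, i, j, weight) over the upper triangle.
#'
#' @param dyn a [dynamic_graphs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphs <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_connectivity"))
  con <- file(path, "w")
  on.exit(close(con))
  for (g in dyn$graphs) {
    writeLines(sprintf("# window %d", g$window_index), con)
    writeLines(apply(g$weights, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' @rdname write_graphs
#' @export
write_graphs_long <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_connectivity"))
  rows <- lapply(dyn$graphs, function(g) {
    ut <- which(upper.tri(g$weights), arr.ind = TRUE)
    data.frame(window = g$window_index, i = ut[, 1], j = ut[, 2],
               weight = g$weights[upper.tri(g$weights)])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param window window length in volumes (odd integer), or `"auto"` to
#'   select it from the cohort's Q* variance curve.
#' @param stride window stride (volumes).
#' @param n_restarts optimizer restarts per graph.
#' @param null_passes strength-matching passes for [null_model()].
#' @param seed master seed; all stage seeds derive from it.
#' @param weight_mode `"signed"` or `"positive"` Z-score weights.
#' @param variance_mode `"strict"` or `"lenient"` zero-variance handling.
#' @param k_meta number of meta-modules.
#' @param cutoff_pct window-selection cutoff (percent).
#' @param lengths candidate lengths for `"auto"` selection (default odd
#'   9..T/2).
#' @param tr_seconds repetition time of the input files.
#' @param max_fail_frac abort when more than this fraction of subjects fails.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window = "auto", stride = 1, n_restarts = 10,
                            null_passes = 10, seed = 1,
                            weight_mode = c("signed", "positive"),
                            variance_mode = c("strict", "lenient"),
                            k_meta = 5, cutoff_pct = 10, lengths = NULL,
                            tr_seconds = 3, max_fail_frac = 0) {
  weight_mode <- match.arg(weight_mode)
  variance_mode <- match.arg(variance_mode)
  if (!identical(window, "auto")) {
    window <- as.integer(window)
    if (is.na(window) || window < 2) stop("window must be 'auto' or >= 2")
  }
  for (nm in c("stride", "n_restarts", "null_passes", "k_meta")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1) stop(sprintf("%s must be positive", nm))
  }
  structure(
    list(
      window = window, stride = as.integer(stride),
      n_restarts = as.integer(n_restarts),
      null_passes = as.integer(null_passes), seed = as.integer(seed),
      weight_mode = weight_mode, variance_mode = variance_mode,
      k_meta = as.integer(k_meta), cutoff_pct = cutoff_pct,
      lengths = lengths, tr_seconds = tr_seconds,
      max_fail_frac = max_fail_frac
    ),
    class = "pipeline_config"
  )
}

#' Run the full dynamic-modularity pipeline over a cohort
#'
#' Reads every subject in the manifest, optionally selects the window
#' length, builds sliding-window graphs, detects modules per window,
#' computes modular dwell times, pools partitions into the co-assignment
#' matrix and meta-modules, computes DMN sub-network dwell times when the
#' cohort has 68 regions, and compares groups when two are present.
#' Identical (manifest, config) input yields identical output.
#'
#' @param manifest data frame from [read_manifest()], or a path to one.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for serialized result tables.
#' @return a result bundle (list) with elements `window`, `subjects`
#'   (per-subject partitions, dwell profiles), `summary` (per-window
#'   table), `coassignment`, `meta_modules`, `subnetwork_dwell`,
#'   `group_comparisons`, `log`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stop("manifest is empty")
  failures <- character(0)
  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch(
      read_timeseries(manifest$path[i], tr_seconds = config$tr_seconds,
                      subject_id = manifest$subject_id[i]),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      failures <- c(failures, sprintf("%s: %s", manifest$subject_id[i],
                                      conditionMessage(rec)))
      subjects[i] <- list(NULL)
    } else {
      subjects[[i]] <- rec
    }
  }
  if (length(failures) > nrow(manifest) * config$max_fail_frac) {
    stop(sprintf("pipeline aborted, %d subject(s) failed:\n%s",
                 length(failures), paste(failures, collapse = "\n")))
  }
  keep <- !vapply(subjects, is.null, logical(1))
  manifest <- manifest[keep, , drop = FALSE]
  subjects <- subjects[keep]
  T_ <- nrow(subjects[[1]]$data)
  N <- ncol(subjects[[1]]$data)

  # window selection
  if (identical(config$window, "auto")) {
    lengths <- config$lengths
    if (is.null(lengths)) lengths <- seq(9, T_ %/% 2, by = 2)
    curve <- qstar_variance_curve(subjects, lengths,
                                  seed = derive_seed(config$seed, 101),
                                  n_restarts = config$n_restarts,
                                  stride = config$stride)
    L <- select_window(curve, cutoff_pct = config$cutoff_pct)
  } else {
    curve <- NULL
    L <- config$window
  }
  cfg <- window_config(L, config$stride)

  summary_rows <- list()
  all_partitions <- list()
  dwell <- list()
  subnet_dwell <- list()
  fixed <- if (N == 68) final_partition() else NULL
  for (si in seq_along(subjects)) {
    ts <- subjects[[si]]
    dyn <- dynamic_graphs(ts, cfg, variance_mode = config$variance_mode)
    parts <- lapply(seq_along(dyn$graphs), function(wi) {
      detect_modules(dyn$graphs[[wi]], n_restarts = config$n_restarts,
                     seed = derive_seed(config$seed, si, wi))
    })
    all_partitions <- c(all_partitions, parts)
    dwell[[si]] <- modular_dwell_time(module_count_series(parts),
                                      subject_id = ts$subject_id)
    if (!is.null(fixed)) {
      subnet_dwell[[si]] <- subnetwork_dwell_time(
        dyn, fixed, weight_mode = config$weight_mode
      )
    }
    summary_rows[[si]] <- data.frame(
      subject = ts$subject_id,
      window = seq_along(parts) - 1L,
      n_modules = vapply(parts, `[[`, integer(1), "n_modules"),
      qstar = vapply(parts, `[[`, numeric(1), "qstar")
    )
  }
  summary <- do.call(rbind, summary_rows)

  coa <- coassignment(all_partitions)
  meta <- meta_modules(coa, k = min(config$k_meta, N))

  comparisons <- list()
  groups <- unique(manifest$group)
  if (length(groups) == 2 && !is.null(fixed)) {
    ga <- which(manifest$group == groups[1])
    gb <- which(manifest$group == groups[2])
    if (length(ga) >= 2 && length(gb) >= 2) {
      for (sn in names(dmn_subnetworks())) {
        va <- vapply(subnet_dwell[ga], function(d) d$percentages[[sn]],
                     numeric(1))
        vb <- vapply(subnet_dwell[gb], function(d) d$percentages[[sn]],
                     numeric(1))
        comparisons[[sn]] <- compare_groups(va, vb, groups[1], groups[2])
      }
    }
  }

  log <- list(
    package_version = as.character(utils::packageVersion("dynmod")),
    seed = config$seed,
    window = L,
    stride = config$stride,
    n_restarts = config$n_restarts,
    weight_mode = config$weight_mode,
    k_meta = config$k_meta,
    n_subjects = length(subjects),
    n_regions = N,
    n_volumes = T_,
    failures = failures
  )

  bundle <- list(
    window = L,
    variance_curve = curve,
    subjects = manifest,
    dwell = dwell,
    subnetwork_dwell = subnet_dwell,
    summary = summary,
    coassignment = coa,
    meta_modules = meta,
    group_comparisons = comparisons,
    log = log
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Serialize the main pipeline tables under out_dir.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$summary, file.path(out_dir, "window_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dw <- do.call(rbind, lapply(bundle$dwell, function(d) {
    data.frame(subject = d$subject_id, key = names(d$percentages),
               percentage = unname(d$percentages))
  }))
  utils::write.table(dw, file.path(out_dir, "modular_dwell.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(bundle$subnetwork_dwell) > 0) {
    sd_tab <- do.call(rbind, lapply(bundle$subnetwork_dwell, function(d) {
      data.frame(subject = d$subject_id, key = names(d$percentages),
                 percentage = unname(d$percentages))
    }))
    utils::write.table(sd_tab, file.path(out_dir, "subnetwork_dwell.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(node = seq_along(bundle$meta_modules$labels),
               meta_module = bundle$meta_modules$labels),
    file.path(out_dir, "meta_modules.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(
    round(bundle$coassignment$frequencies, 6),
    file.path(out_dir, "coassignment.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  if (length(bundle$group_comparisons) > 0) {
    comp <- do.call(rbind, lapply(names(bundle$group_comparisons), function(nm) {
      gc <- bundle$group_comparisons[[nm]]
      g <- gc$group_medians_iqr
      data.frame(
        metric = nm,
        group_a = g$group[1], median_a = g$median[1],
        q1_a = g$q1[1], q3_a = g$q3[1],
        group_b = g$group[2], median_b = g$median[2],
        q1_b = g$q1[2], q3_b = g$q3[2],
        p_value = gc$p_value
      )
    }))
    utils::write.table(comp, file.path(out_dir, "group_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
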