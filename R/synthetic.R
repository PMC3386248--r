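# Synthetic switching-state BOLD generator.
#
# Emits ROI time series whose cross-sectional correlation structure switches
# among a small set of modular "brain states", each a block-equicorrelated
# signed correlation matrix. Every downstream stage of the pipeline can be
# validated against the planted state sequence and community maps.

#' Specify one latent modular brain state
#'
#' A state is a block-constant correlation structure over `N` regions:
#' correlation `rho_in` between regions sharing a community label and
#' `rho_out` between regions in different communities. The implied N x N
#' correlation matrix is checked for positive semi-definiteness at
#' construction; infeasible (`rho_in`, `rho_out`) combinations are rejected.
#'
#' @param state_id integer identifier of the state.
#' @param community_map integer vector of per-node community labels;
#'   contiguous integers starting at 1.
#' @param rho_in within-community correlation, in (0, 1).
#' @param rho_out between-community correlation, in (-1, 0].
#' @return an object of class `state_spec` carrying the correlation matrix.
#' @export
state_spec <- function(state_id, community_map, rho_in, rho_out) {
  state_id <- as.integer(state_id)
  community_map <- as.integer(community_map)
  n <- length(community_map)
  if (n < 2) stop("community_map must cover at least 2 regions")
  if (anyNA(community_map)) stop("community_map must not contain NA")
  u <- sort(unique(community_map))
  if (!identical(u, seq_along(u))) {
    stop("community labels must be contiguous integers starting at 1")
  }
  if (!(rho_in > 0 && rho_in < 1)) stop("rho_in must lie in (0, 1)")
  if (!(rho_out > -1 && rho_out <= 0)) stop("rho_out must lie in (-1, 0]")
  same <- outer(community_map, community_map, "==")
  C <- ifelse(same, rho_in, rho_out)
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "state %d: correlation structure is not positive semi-definite (min eigenvalue %.3g); reduce |rho_out| or rho_in",
      state_id, min(ev)
    ))
  }
  structure(
    list(
      state_id = state_id,
      community_map = community_map,
      rho_in = rho_in,
      rho_out = rho_out,
      correlation = C
    ),
    class = "state_spec"
  )
}

#' @export
print.state_spec <- function(x, ...) {
  cat(sprintf(
    "state_spec %d: %d regions, %d communities, rho_in = %.3g, rho_out = %.3g\n",
    x$state_id, length(x$community_map), max(x$community_map),
    x$rho_in, x$rho_out
  ))
  invisible(x)
}

#' Bundle a latent state sequence with its state specifications
#'
#' @param state_sequence integer vector of per-volume state ids (length T).
#' @param specs list of [state_spec()] objects; every id appearing in
#'   `state_sequence` must be present.
#' @return an object of class `switching_truth` with fields `state_sequence`,
#'   `specs` and `occupancy` (per-state fraction of volumes, summing to 1,
#'   tallied exactly from the sequence).
#' @export
switching_truth <- function(state_sequence, specs) {
  state_sequence <- as.integer(state_sequence)
  if (length(state_sequence) < 1) stop("state_sequence must be non-empty")
  ids <- vapply(specs, function(s) s$state_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate state ids in specs")
  if (!all(state_sequence %in% ids)) {
    stop("state_sequence contains ids with no matching state_spec")
  }
  ns <- vapply(specs, function(s) length(s$community_map), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all states must share the same region count")
  }
  occ <- vapply(ids, function(i) mean(state_sequence == i), numeric(1))
  names(occ) <- as.character(ids)
  structure(
    list(state_sequence = state_sequence, specs = specs, occupancy = occ),
    class = "switching_truth"
  )
}

#' Sample a Markov latent state sequence
#'
#' The first state is drawn from `initial`; each subsequent state is drawn
#' from the transition row of the current state. Dwell in a state is induced
#' by its self-transition probability.
#'
#' @param n_volumes number of volumes T (>= 1).
#' @param transition K x K row-stochastic transition matrix; rows must sum to
#'   1 within 1e-9. Row/state k indexes state id k.
#' @param initial length-K initial distribution.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return integer vector of length `n_volumes` with values in 1..K.
#' @export
generate_state_sequence <- function(n_volumes, transition, initial, seed) {
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (ncol(transition) != K) stop("transition must be square")
  rs <- rowSums(transition)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad) > 0) {
    stop(sprintf(
      "transition row %d is not stochastic (sums to %.12g)", bad[1], rs[bad[1]]
    ))
  }
  if (any(transition < 0)) stop("transition probabilities must be non-negative")
  if (length(initial) != K) stop("initial must have length K")
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("initial must be a probability distribution")
  }
  local_seed(seed, {
    seq_out <- integer(n_volumes)
    seq_out[1] <- sample.int(K, 1, prob = initial)
    if (n_volumes > 1) {
      for (t in 2:n_volumes) {
        seq_out[t] <- sample.int(K, 1, prob = transition[seq_out[t - 1], ])
      }
    }
    seq_out
  })
}

#' Construct an ROI time-series object
#'
#' @param data numeric matrix, volumes (rows) x regions (columns).
#' @param tr_seconds repetition time in seconds (> 0).
#' @param region_ids character vector of unique region labels; defaults to
#'   `roi01 ...`.
#' @param subject_id subject identifier string.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds = 3,
                           region_ids = NULL, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop("data must not contain missing or non-finite values")
  }
  if (nrow(data) < 2) stop("need at least 2 volumes")
  if (ncol(data) < 2) stop("need at least 2 regions")
  if (!(tr_seconds > 0)) stop("tr_seconds must be positive")
  if (is.null(region_ids)) {
    region_ids <- colnames(data)
    if (is.null(region_ids)) {
      region_ids <- sprintf("roi%02d", seq_len(ncol(data)))
    }
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != ncol(data)) {
    stop("region_ids must match the number of regions")
  }
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  colnames(data) <- region_ids
  structure(
    list(
      data = data,
      tr_seconds = tr_seconds,
      region_ids = region_ids,
      subject_id = as.character(subject_id)
    ),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "roi_timeseries '%s': %d volumes x %d regions, TR = %g s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds
  ))
  invisible(x)
}

# Symmetric moving average with truncated (renormalized) edges.
moving_average <- function(x, halfwidth) {
  h <- as.integer(halfwidth)
  if (h <= 0) return(x)
  n <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Generate BOLD-like signals from a switching ground truth
#'
#' At each volume a zero-mean multivariate normal sample is drawn whose
#' correlation matrix is the active state's block structure; white noise of
#' standard deviation `noise_sd` is added, and a symmetric moving average of
#' the given halfwidth emulates the temporal smoothness of band-limited BOLD.
#'
#' @param truth a [switching_truth()].
#' @param noise_sd non-negative white-noise standard deviation.
#' @param smoothing_halfwidth moving-average halfwidth in volumes (0 = none).
#' @param seed integer seed; output is bit-identical under identical inputs.
#' @param tr_seconds repetition time (seconds).
#' @param subject_id subject label.
#' @param region_ids optional region labels.
#' @return an [roi_timeseries()].
#' @export
generate_bold <- function(truth, noise_sd = 0.25, smoothing_halfwidth = 1,
                          seed = 1, tr_seconds = 3, subject_id = "sim",
                          region_ids = NULL) {
  stopifnot(inherits(truth, "switching_truth"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n_vol <- length(truth$state_sequence)
  N <- length(truth$specs[[1]]$community_map)
  ids <- vapply(truth$specs, function(s) s$state_id, integer(1))
  # Cholesky factors; tiny ridge guards exactly semi-definite structures.
  chols <- lapply(truth$specs, function(s) {
    chol(s$correlation + diag(1e-9, N))
  })
  X <- local_seed(seed, {
    Z <- matrix(rnorm(n_vol * N), n_vol, N)
    E <- if (noise_sd > 0) {
      noise_sd * matrix(rnorm(n_vol * N), n_vol, N)
    } else {
      0
    }
    out <- matrix(0, n_vol, N)
    for (k in seq_along(ids)) {
      rows <- which(truth$state_sequence == ids[k])
      if (length(rows) > 0) {
        out[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]]
      }
    }
    out + E
  })
  X <- moving_average(X, smoothing_halfwidth)
  roi_timeseries(X, tr_seconds = tr_seconds,
                 region_ids = region_ids, subject_id = subject_id)
}

#' Default switching states: a 2-block and a 3-block modular state
#'
#' The default study conditions: regions split into three contiguous groups
#' (sizes as equal as possible); state 1 is 2-modular (groups 1 and 2 fused
#' against group 3), state 2 is 3-modular (each group its own community).
#' The finest common refinement of the two maps is the 3-group map, which is
#' what consensus meta-modular clustering should recover.
#'
#' @param n_regions number of regions (default 68).
#' @param rho_in within-community correlation (default 0.7).
#' @param rho_out between-community correlation (default -0.2).
#' @return list of two [state_spec()] objects, plus attribute
#'   `refinement` holding the planted 3-group map.
#' @export
default_switching_states <- function(n_regions = 68, rho_in = 0.7,
                                     rho_out = -0.2) {
  sizes <- diff(round(seq(0, n_regions, length.out = 4)))
  groups <- rep(seq_len(3), times = sizes)
  map2 <- ifelse(groups <= 2, 1L, 2L)
  specs <- list(
    state_spec(1L, map2, rho_in, rho_out),
    state_spec(2L, groups, rho_in, rho_out)
  )
  attr(specs, "refinement") <- groups
  specs
}

#' DMN-contrast states: anterior-strong versus posterior-strong
#'
#' Two 2-modular states over the 68-region atlas expressing the reciprocal
#' anterior/posterior default-mode configuration: in the anterior-strong
#' state the pDMN nodes are exiled from the dominant community that carries
#' the rest of the task-negative module (so their within-TNN strength drops),
#' and vice versa in the posterior-strong state. Under the fixed final module
#' assignment, the aDMN composite within-module degree Z-score is positive in
#' the anterior-strong state and negative in the posterior-strong state.
#'
#' @param rho_in,rho_out block correlations as in [state_spec()].
#' @return list of two [state_spec()]s: id 1 = posterior-strong,
#'   id 2 = anterior-strong.
#' @export
dmn_switching_states <- function(rho_in = 0.7, rho_out = -0.2) {
  atlas <- node_atlas()
  n <- nrow(atlas)
  tnn <- which(atlas$final_assignment == 4)
  subnets <- dmn_subnetworks()
  a_nodes <- subnets[["aDMN"]]$node_ids
  p_nodes <- subnets[["pDMN"]]$node_ids
  # posterior-strong: TNN minus aDMN forms the coherent community
  map_post <- rep(2L, n)
  map_post[setdiff(tnn, a_nodes)] <- 1L
  # anterior-strong: TNN minus pDMN forms the coherent community
  map_ant <- rep(2L, n)
  map_ant[setdiff(tnn, p_nodes)] <- 1L
  list(
    state_spec(1L, map_post, rho_in, rho_out),
    state_spec(2L, map_ant, rho_in, rho_out)
  )
}

#' Default two-state transition matrix
#'
#' Self-transitions chosen so that dwell episodes are long relative to an
#' 11-volume window (mean dwell ~83 and ~36 volumes) with stationary
#' occupancy `occupancy_1` of state 1.
#'
#' @param occupancy_1 stationary occupancy of state 1 (default 0.7).
#' @param p_leave_1 probability of leaving state 1 per volume (default 0.012).
#' @return 2 x 2 row-stochastic matrix.
#' @export
default_transition <- function(occupancy_1 = 0.7, p_leave_1 = 0.012) {
  stopifnot(occupancy_1 > 0, occupancy_1 < 1, p_leave_1 > 0, p_leave_1 < 1)
  # pi_1 = p21 / (p12 + p21)  =>  p21 = p12 * pi_1 / (1 - pi_1)
  p12 <- p_leave_1
  p21 <- p12 * occupancy_1 / (1 - occupancy_1)
  if (p21 >= 1) stop("infeasible occupancy/leave-rate combination")
  matrix(c(1 - p12, p12, p21, 1 - p21), 2, 2, byrow = TRUE)
}

#' Generate a cohort of subjects with known switching structure
#'
#' @param n_per_group named integer vector: subjects per group label.
#' @param specs shared list of [state_spec()]s (same regions for all groups).
#' @param transition_by_group named list of K x K transition matrices, one
#'   per group (names matching `n_per_group`).
#' @param initial_by_group optional named list of initial distributions;
#'   default uniform over states.
#' @param n_volumes volumes per subject (default 100).
#' @param tr_seconds repetition time (default 3).
#' @param noise_sd,smoothing_halfwidth passed to [generate_bold()].
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @param region_ids optional region labels.
#' @return list of records, each `list(ts, group, truth)`; the ground truth
#'   retains the subject's exact state occupancy for recovery tests.
#' @export
generate_cohort <- function(n_per_group, specs, transition_by_group,
                            initial_by_group = NULL,
                            n_volumes = 100, tr_seconds = 3,
                            noise_sd = 0.25, smoothing_halfwidth = 1,
                            seed = 1, region_ids = NULL) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(groups == "")) {
    stop("n_per_group must be a named vector of group sizes")
  }
  if (!all(groups %in% names(transition_by_group))) {
    stop("transition_by_group must name every group")
  }
  K <- length(specs)
  ns <- vapply(specs, function(s) length(s$community_map), integer(1))
  if (length(unique(ns)) != 1) stop("states disagree on region count")
  if (is.null(initial_by_group)) {
    initial_by_group <- stats::setNames(
      rep(list(rep(1 / K, K)), length(groups)), groups
    )
  }
  cohort <- list()
  idx <- 0
  for (g in groups) {
    for (s in seq_len(n_per_group[[g]])) {
      idx <- idx + 1
      sid <- sprintf("%s%02d", g, s)
      seed_seq <- derive_seed(seed, idx, 1)
      seed_bold <- derive_seed(seed, idx, 2)
      st_seq <- generate_state_sequence(
        n_volumes, transition_by_group[[g]], initial_by_group[[g]], seed_seq
      )
      truth <- switching_truth(st_seq, specs)
      ts <- generate_bold(
        truth, noise_sd = noise_sd,
        smoothing_halfwidth = smoothing_halfwidth,
        seed = seed_bold, tr_seconds = tr_seconds,
        subject_id = sid, region_ids = region_ids
      )
      cohort[[idx]] <- list(ts = ts, group = g, truth = truth)
    }
  }
  cohort
}

#' Extract just the time series from a cohort
#' @param cohort result of [generate_cohort()].
#' @return list of [roi_timeseries()].
#' @export
cohort_timeseries <- function(cohort) lapply(cohort, `[[`, "ts")
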