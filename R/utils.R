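# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so that seeded generation never perturbs an enclosing
#' simulation.
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed for sub-tasks, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed)
  for (k in idx) h <- (h * 7919 + as.double(k) * 104729 + 1) %% 2147483629
  as.integer(h)
}

#' Canonicalize module labels
#'
#' Relabels an integer label vector so that the module of the first node is 1,
#' the next previously unseen module is 2, and so on. Idempotent, and
#' preserves the partition (hence any modularity value) exactly.
#'
#' @param labels integer vector of module labels.
#' @return integer vector of contiguous labels starting at 1.
#' @export
canonicalize_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  first <- unique(labels)
  match(labels, first)
}

# Extract the raw N x N weight matrix from a connectivity_matrix or matrix.
as_weights <- function(graph) {
  w <- if (inherits(graph, "connectivity_matrix")) graph$weights else graph
  if (!is.matrix(w) || !is.numeric(w)) {
    stop("graph must be a numeric matrix or a connectivity_matrix")
  }
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  w
}

check_symmetric <- function(w, tol = 1e-10) {
  if (max(abs(w - t(w))) > tol) stop("weight matrix must be symmetric")
  invisible(w)
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop(sprintf("labels must have length %d (one per node)", n))
  }
  if (anyNA(labels) || any(labels < 1)) stop("labels must be positive integers")
  labels
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
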