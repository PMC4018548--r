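#' Ground truth for synthetic connectivity data
#'
#' Describes the generating process for a synthetic multi-subject,
#' multi-condition correlation dataset: a baseline correlation matrix, a set
#' of affected edges whose Fisher-z values drift linearly across conditions
#' by a total amount `delta`, a set of affected nodes with linearly drifting
#' signal means, and independent Gaussian noise. Effects are planted on the
#' Fisher-z scale, where the inference model is additive and the
#' back-transformed correlations are automatically confined to `(-1, 1)`.
#'
#' @param base_r baseline correlation matrix (a [weight_matrix()] with all
#'   `|r| < 1`).
#' @param edge_effects NULL or a data frame with columns `i`, `j` (vertex
#'   indices, `i < j`) and `delta`: the total z-scale change of that edge
#'   from the first to the last condition (negative = declining edge).
#' @param node_effects NULL or a data frame with columns `node` and `delta`:
#'   total signal change from first to last condition.
#' @param noise_sd edge noise standard deviation on the z scale.
#' @param node_baseline baseline node signal level.
#' @param node_noise_sd node signal noise standard deviation.
#' @return an object of class `ground_truth`.
#' @seealso [default_ground_truth()] for a ready-made block-structured truth.
#' @export
ground_truth <- function(base_r, edge_effects = NULL, node_effects = NULL,
                         noise_sd = 0.1, node_baseline = 100,
                         node_noise_sd = 1) {
  base_r <- as_weight_matrix(base_r)
  if (any(abs(base_r) >= 1)) {
    stop("baseline correlations must satisfy |r| < 1", call. = FALSE)
  }
  n_v <- nrow(base_r)
  if (!is.null(edge_effects)) {
    edge_effects <- as.data.frame(edge_effects)
    need <- c("i", "j", "delta")
    if (!all(need %in% names(edge_effects))) {
      stop("`edge_effects` needs columns i, j, delta", call. = FALSE)
    }
    ii <- as.integer(edge_effects$i)
    jj <- as.integer(edge_effects$j)
    if (anyNA(ii) || anyNA(jj) || any(ii >= jj) || any(ii < 1L) ||
      any(jj > n_v)) {
      stop("affected edges must be pairs i < j within the node set",
        call. = FALSE
      )
    }
    if (anyDuplicated(cbind(ii, jj))) {
      stop("duplicate affected edges", call. = FALSE)
    }
    if (any(!is.finite(edge_effects$delta))) {
      stop("edge effect sizes must be finite", call. = FALSE)
    }
    edge_effects <- data.frame(i = ii, j = jj, delta = as.numeric(edge_effects$delta))
  }
  if (!is.null(node_effects)) {
    node_effects <- as.data.frame(node_effects)
    if (!all(c("node", "delta") %in% names(node_effects))) {
      stop("`node_effects` needs columns node, delta", call. = FALSE)
    }
    vv <- as.integer(node_effects$node)
    if (anyNA(vv) || any(vv < 1L) || any(vv > n_v) || anyDuplicated(vv)) {
      stop("affected nodes must be distinct indices within the node set",
        call. = FALSE
      )
    }
    if (any(!is.finite(node_effects$delta))) {
      stop("node effect sizes must be finite", call. = FALSE)
    }
    node_effects <- data.frame(node = vv, delta = as.numeric(node_effects$delta))
  }
  if (!is.numeric(noise_sd) || noise_sd < 0 || !is.finite(noise_sd)) {
    stop("`noise_sd` must be a nonnegative number", call. = FALSE)
  }
  structure(
    list(
      base_r = base_r, edge_effects = edge_effects,
      node_effects = node_effects, noise_sd = noise_sd,
      node_baseline = node_baseline, node_noise_sd = node_noise_sd
    ),
    class = "ground_truth"
  )
}

#' Block-structured default ground truth
#'
#' Builds a [ground_truth()] whose baseline correlation matrix has a modular
#' block structure (`n_blocks` equally sized communities with higher
#' within-block than between-block correlation), so that density and
#' modularity metrics computed on the synthetic data are non-trivial. By
#' default 8 disjoint edges decline across conditions by 3 noise standard
#' deviations in total, and 5 nodes gain signal -- the canonical recovery
#' regime used in the package's own validation.
#'
#' @param n_nodes number of nodes.
#' @param n_blocks number of baseline communities (default 4).
#' @param within_r,between_r baseline correlation inside / between blocks.
#' @param n_affected_edges number of planted edges (disjoint pairs
#'   `(1,2), (3,4), ...`); the default of 8 shrinks automatically when the
#'   node set is too small for 8 disjoint pairs.
#' @param edge_delta total z-scale drift of each planted edge; the default
#'   `-3 * noise_sd` is a strong, clearly recoverable decline.
#' @param noise_sd z-scale noise standard deviation (default 0.1).
#' @param n_affected_nodes number of planted nodes (`1..n_affected_nodes`).
#' @param node_delta total signal drift of planted nodes, in units of the
#'   node noise standard deviation (default 3).
#' @return a `ground_truth`.
#' @export
default_ground_truth <- function(n_nodes, n_blocks = 4, within_r = 0.5,
                                 between_r = 0.1,
                                 n_affected_edges = min(8L, n_nodes %/% 2L),
                                 edge_delta = -3 * noise_sd, noise_sd = 0.1,
                                 n_affected_nodes = min(5L, n_nodes),
                                 node_delta = 3) {
  n_nodes <- as.integer(n_nodes)
  if (2L * n_affected_edges > n_nodes) {
    stop("not enough nodes for the requested number of disjoint planted edges",
      call. = FALSE
    )
  }
  if (n_affected_nodes > n_nodes) {
    stop("more planted nodes than nodes", call. = FALSE)
  }
  block <- ((seq_len(n_nodes) - 1L) %% n_blocks) + 1L
  base <- matrix(between_r, n_nodes, n_nodes)
  base[outer(block, block, "==")] <- within_r
  diag(base) <- 0
  edge_effects <- if (n_affected_edges > 0) {
    k <- seq_len(n_affected_edges)
    data.frame(i = 2L * k - 1L, j = 2L * k, delta = edge_delta)
  }
  node_effects <- if (n_affected_nodes > 0) {
    data.frame(node = seq_len(n_affected_nodes), delta = node_delta)
  }
  ground_truth(
    base,
    edge_effects = edge_effects, node_effects = node_effects,
    noise_sd = noise_sd, node_noise_sd = 1
  )
}

# Linear per-condition fraction of the total effect: 0 at the first
# condition, 1 at the last.
.effect_profile <- function(n_conditions) {
  if (n_conditions < 2L) {
    return(rep(0, n_conditions))
  }
  (seq_len(n_conditions) - 1) / (n_conditions - 1)
}

#' Generate a synthetic correlation dataset with planted effects
#'
#' For every subject and condition, each edge's Fisher-z value is drawn as
#' `base z + effect(condition) + Normal(0, noise_sd)` and back-transformed to
#' a correlation, yielding symmetric zero-diagonal matrices whose entries are
#' guaranteed inside `(-1, 1)`. Affected edges drift linearly from 0 (first
#' condition) to their full `delta` (last condition). Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param n_subjects number of subjects (rows of the data array).
#' @param n_conditions number of experimental conditions.
#' @param truth a [ground_truth()]; default [default_ground_truth()] on 30
#'   nodes.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return list with `data` (a [correlation_dataset()]) and `truth`.
#' @examples
#' sim <- generate_dataset(20, 4, seed = 1)
#' sim$data
#' @export
generate_dataset <- function(n_subjects, n_conditions,
                             truth = default_ground_truth(30), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- as.integer(n_subjects)
  J <- as.integer(n_conditions)
  if (is.na(n) || n < 1L || is.na(J) || J < 1L) {
    stop("`n_subjects` and `n_conditions` must be positive integers",
      call. = FALSE
    )
  }
  n_v <- nrow(truth$base_r)
  ep <- edge_pairs(n_v)
  e_n <- nrow(ep)
  base_z <- fisher_z(truth$base_r[ep])
  delta <- numeric(e_n)
  if (!is.null(truth$edge_effects)) {
    key <- (ep[, 1L] - 1) * n_v + ep[, 2L]
    eff_key <- (truth$edge_effects$i - 1) * n_v + truth$edge_effects$j
    delta[match(eff_key, key)] <- truth$edge_effects$delta
  }
  profile <- .effect_profile(J)
  z <- with_seed(seed, {
    noise <- array(stats::rnorm(e_n * n * J, 0, truth$noise_sd), c(e_n, n, J))
    mean_arr <- outer(delta, profile) # E x J
    noise + base_z + aperm(array(mean_arr, c(e_n, J, n)), c(1L, 3L, 2L))
  })
  r <- tanh(z)
  flat <- matrix(0, n_v * n_v, n * J)
  lower <- (ep[, 1L] - 1L) * n_v + ep[, 2L]
  upper <- (ep[, 2L] - 1L) * n_v + ep[, 1L]
  rflat <- matrix(r, e_n, n * J)
  flat[lower, ] <- rflat
  flat[upper, ] <- rflat
  arr <- array(flat, c(n_v, n_v, n, J))
  list(
    data = correlation_dataset(arr, labels = wm_labels(truth$base_r)),
    truth = truth
  )
}

#' Generate synthetic node signals with planted effects
#'
#' Node-level analogue of [generate_dataset()], on the raw signal scale:
#' `y = baseline + effect(condition) + Normal(0, node_noise_sd)`, with
#' affected nodes drifting linearly from 0 to their full `delta` across the
#' condition gradient.
#'
#' @inheritParams generate_dataset
#' @return list with `signals` (a [node_signal_table()]) and `truth`.
#' @export
generate_node_signals <- function(n_subjects, n_conditions,
                                  truth = default_ground_truth(30),
                                  seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- as.integer(n_subjects)
  J <- as.integer(n_conditions)
  if (is.na(n) || n < 1L || is.na(J) || J < 1L) {
    stop("`n_subjects` and `n_conditions` must be positive integers",
      call. = FALSE
    )
  }
  n_v <- nrow(truth$base_r)
  delta <- numeric(n_v)
  if (!is.null(truth$node_effects)) {
    delta[truth$node_effects$node] <- truth$node_effects$delta
  }
  profile <- .effect_profile(J)
  y <- with_seed(seed, {
    noise <- array(stats::rnorm(n_v * n * J, 0, truth$node_noise_sd), c(n_v, n, J))
    mean_arr <- outer(delta, profile) # N_V x J
    noise + truth$node_baseline +
      aperm(array(mean_arr, c(n_v, J, n)), c(1L, 3L, 2L))
  })
  list(
    signals = node_signal_table(y, labels = wm_labels(truth$base_r)),
    truth = truth
  )
}
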