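#' Threshold a weight matrix at a fixed cut-off
#'
#' Binarizes an association matrix: edge `{i, j}` is present iff
#' `w_ij > tau` (`mode = "signed"`) or `|w_ij| > tau` (`mode = "absolute"`).
#' The inequality is strict, so thresholding correlations at `tau = 1` always
#' yields an empty graph. Note that thresholding is non-linear: the average of
#' thresholded matrices is generally not the thresholded average matrix, which
#' is the basic motivation for inferential (SPN) summaries over naive
#' averaging.
#'
#' @param W a [weight_matrix()] (or coercible matrix).
#' @param tau finite numeric cut-off.
#' @param mode `"signed"` compares weights directly; `"absolute"` compares
#'   their absolute values (useful when negative correlations should count as
#'   connections).
#' @return an undirected simple `igraph` graph on the nodes of `W`.
#' @examples
#' W <- weight_matrix(matrix(c(0, .8, .8, 0), 2))
#' igraph::ecount(threshold_by_value(W, 0.5))
#' @seealso [threshold_by_density()] for rank-based thresholding.
#' @export
threshold_by_value <- function(W, tau, mode = c("signed", "absolute")) {
  W <- as_weight_matrix(W)
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau)) {
    stop("`tau` must be a single finite number", call. = FALSE)
  }
  ep <- edge_pairs(nrow(W))
  w <- W[ep]
  keep <- if (mode == "signed") w > tau else abs(w) > tau
  binary_graph(nrow(W), ep[keep, , drop = FALSE], labels = wm_labels(W))
}

#' Threshold a weight matrix at a wiring density
#'
#' Retains the `floor(k * E_max)` top-ranked edges of the saturated graph,
#' with `E_max = N_V (N_V - 1) / 2`, ranking by weight (descending) in signed
#' mode or by absolute weight in absolute mode. Ties are broken by the
#' lexicographic edge order of [edge_pairs()], so the result is deterministic.
#' Using `floor` guarantees the realized density never exceeds `k`.
#'
#' @inheritParams threshold_by_value
#' @param k target wiring density in `[0, 1]`.
#' @return an undirected simple `igraph` graph with exactly
#'   `floor(k * E_max)` edges.
#' @examples
#' W <- weight_matrix(matrix(runif(16), 4) |> (\(m) (m + t(m)) / 2)())
#' igraph::ecount(threshold_by_density(W, 1 / 3))
#' @export
threshold_by_density <- function(W, k, mode = c("signed", "absolute")) {
  W <- as_weight_matrix(W)
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > 1) {
    stop("`k` must be a density in [0, 1]", call. = FALSE)
  }
  ep <- edge_pairs(nrow(W))
  w <- W[ep]
  key <- if (mode == "signed") -w else -abs(w)
  ord <- order(key, ep[, 1L], ep[, 2L])
  m <- floor(k * nrow(ep))
  keep <- ord[seq_len(m)]
  binary_graph(nrow(W), ep[keep, , drop = FALSE], labels = wm_labels(W))
}

#' Hop-count shortest path lengths
#'
#' Breadth-first-search distances between every pair of vertices; unreachable
#' pairs get `Inf`.
#'
#' @param G an undirected `igraph` graph.
#' @return symmetric numeric matrix of hop counts with zero diagonal and
#'   attribute `flavor = "hop-count"`.
#' @export
shortest_path_lengths <- function(G) {
  d <- igraph::distances(G, weights = NA)
  dimnames(d) <- NULL
  attr(d, "flavor") <- "hop-count"
  d
}

#' Weighted shortest path lengths
#'
#' Each positive weight `w_ij` defines an edge of length `1 / w_ij` (the
#' Latora-Marchiori convention: stronger association means shorter effective
#' distance); zero weights mean "no edge". Distances are minimal path lengths
#' under this metric, computed by Dijkstra's algorithm; unreachable pairs get
#' `Inf`. Negative weights are rejected -- take absolute values or truncate at
#' zero explicitly before calling if negative correlations should be used.
#'
#' @param W a [weight_matrix()] with nonnegative weights.
#' @return symmetric numeric matrix of weighted distances, attribute
#'   `flavor = "weighted-length"`.
#' @export
weighted_shortest_path_lengths <- function(W) {
  W <- as_weight_matrix(W)
  if (any(W < 0)) {
    stop(
      "negative weights are not allowed in weighted path metrics; ",
      "preprocess the matrix explicitly (absolute value or truncation at 0)",
      call. = FALSE
    )
  }
  n <- nrow(W)
  ep <- edge_pairs(n)
  w <- W[ep]
  keep <- w > 0
  g <- binary_graph(n, ep[keep, , drop = FALSE])
  d <- igraph::distances(g, weights = 1 / w[keep])
  dimnames(d) <- NULL
  attr(d, "flavor") <- "weighted-length"
  d
}

# Mean inverse distance over ordered vertex pairs, with 1/Inf = 0.
.efficiency_from_distances <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency of an unweighted graph
#'
#' `E(G) = 1 / (N_V (N_V - 1)) * sum_{i != j} 1 / d_ij`, the mean inverse
#' shortest-path length over ordered vertex pairs (equivalently the inverse
#' harmonic mean of path lengths), with `1 / Inf = 0` so the measure is
#' defined for disconnected graphs. Values lie in `[0, 1]`: the complete graph
#' attains 1 and the empty graph 0.
#'
#' @param G an undirected `igraph` graph with at least 2 vertices.
#' @return efficiency in `[0, 1]`.
#' @examples
#' global_efficiency(binary_graph(3, rbind(c(1, 2), c(2, 3)))) # path: 5/6
#' @export
global_efficiency <- function(G) {
  if (igraph::vcount(G) < 2L) {
    stop("global efficiency requires at least 2 vertices", call. = FALSE)
  }
  .efficiency_from_distances(shortest_path_lengths(G))
}

#' Weighted global efficiency
#'
#' Same averaging as [global_efficiency()] but with weighted shortest path
#' lengths `d^W_ij` (see [weighted_shortest_path_lengths()]) in place of hop
#' counts. For a two-node graph this reduces to the edge weight itself, and
#' whenever every direct edge is itself a weighted shortest path (see
#' [direct_path_condition_holds()]) on a complete graph, the weighted
#' efficiency collapses to the weighted density [weighted_density()].
#'
#' @inheritParams weighted_shortest_path_lengths
#' @return weighted efficiency (nonnegative real).
#' @export
weighted_global_efficiency <- function(W) {
  W <- as_weight_matrix(W)
  if (nrow(W) < 2L) {
    stop("weighted efficiency requires at least 2 vertices", call. = FALSE)
  }
  .efficiency_from_distances(weighted_shortest_path_lengths(W))
}

#' Weighted density (weighted cost)
#'
#' `K_W = 1 / (N_V (N_V - 1)) * sum_{i != j} w_ij`, the mean off-diagonal
#' weight of the association matrix. This is the "connectivity strength" that
#' should be reported alongside any topological comparison, since most
#' topological metrics are strongly driven by it.
#'
#' @param W a [weight_matrix()].
#' @return mean off-diagonal weight.
#' @export
weighted_density <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  sum(W) / (n * (n - 1))
}

#' Does every edge realize its own weighted shortest path?
#'
#' Checks the degeneracy condition under which weighted global efficiency
#' carries no information beyond weighted density: for every positive-weight
#' edge `{i, j}`, the direct edge length `1 / w_ij` equals the weighted
#' shortest-path distance `d^W_ij` (no detour is shorter). When this holds on
#' a complete positive matrix, `E_W == K_W`. A simple sufficient condition is
#' `w_max <= 2 * w_min` on a complete graph: any two-hop detour has length at
#' least `2 / w_max >= 1 / w_min`, so no direct edge can be beaten.
#'
#' @inheritParams weighted_shortest_path_lengths
#' @param tol relative tolerance for the distance comparison.
#' @return TRUE iff the condition holds for every positive-weight edge.
#' @export
direct_path_condition_holds <- function(W, tol = 1e-12) {
  W <- as_weight_matrix(W)
  d <- weighted_shortest_path_lengths(W)
  ep <- edge_pairs(nrow(W))
  w <- W[ep]
  pos <- w > 0
  if (!any(pos)) {
    return(TRUE)
  }
  direct <- 1 / w[pos]
  dist <- d[ep[pos, , drop = FALSE]]
  # dist <= direct always (the direct edge is one candidate path)
  all(dist >= direct - tol * pmax(1, direct))
}
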