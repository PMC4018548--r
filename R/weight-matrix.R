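#' Weighted association matrix
#'
#' Validates and normalizes a symmetric real-valued association matrix (for
#' example a matrix of inter-regional correlations) into a `weight_matrix`.
#' The diagonal is forced to zero -- self-association carries no edge
#' information. Small numerical asymmetries are repaired by averaging the
#' matrix with its transpose: asymmetries up to `1e-8` are repaired silently,
#' asymmetries up to `1e-4` are repaired with a warning, and anything larger
#' is an error.
#'
#' @param values square numeric matrix of association weights `w_ij`
#'   (typically correlations in `[-1, 1]`), at least 2 x 2.
#' @param labels optional character vector of node names; defaults to the
#'   dimnames of `values` when present.
#' @return a numeric matrix of class `weight_matrix` with zero diagonal and
#'   exact symmetry.
#' @examples
#' w <- weight_matrix(matrix(c(0, .8, .8, 0), 2), labels = c("a", "b"))
#' weighted_density(w)
#' @export
weight_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("weight matrix must be numeric", call. = FALSE)
  }
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (ncol(values) != n) {
    stop(sprintf("weight matrix must be square; got %d x %d", n, ncol(values)),
      call. = FALSE
    )
  }
  if (n < 2L) {
    stop("a weight matrix needs at least 2 nodes", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite weight at row %d, column %d", bad[1L], bad[2L]
    ), call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-4) {
    bad <- which(abs(values - t(values)) == asym, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is asymmetric beyond tolerance at row %d, column %d (max |w_ij - w_ji| = %.3g)",
      bad[1L], bad[2L], asym
    ), call. = FALSE)
  }
  if (asym > 1e-8) {
    warning(sprintf(
      "matrix asymmetric by up to %.3g; symmetrized by averaging", asym
    ), call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- colnames(values)
  }
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("`labels` must have one entry per node", call. = FALSE)
    }
    dimnames(values) <- list(labels, labels)
  } else {
    dimnames(values) <- NULL
  }
  structure(values, class = c("weight_matrix", "matrix", "array"))
}

#' @rdname weight_matrix
#' @param x object to coerce.
#' @export
as_weight_matrix <- function(x) {
  if (inherits(x, "weight_matrix")) x else weight_matrix(x)
}

# Node labels of a weight matrix (or NULL).
wm_labels <- function(W) rownames(W)

#' Build an undirected simple graph from an edge list
#'
#' Thin constructor around an [igraph::graph] object: `n_vertices` isolated
#' vertices plus the given unordered edges. Self-loops and duplicate edges are
#' rejected, so the result is always a simple graph.
#'
#' @param n_vertices number of vertices.
#' @param edges two-column integer matrix of vertex pairs (1-based), or NULL
#'   for an edgeless graph.
#' @param labels optional node names.
#' @return an undirected simple `igraph` graph.
#' @examples
#' g <- binary_graph(3, rbind(c(1, 2), c(2, 3)))
#' global_efficiency(g)
#' @export
binary_graph <- function(n_vertices, edges = NULL, labels = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 1L) {
    stop("`n_vertices` must be a positive integer", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n_vertices, directed = FALSE)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_vertices)) {
      stop("edge endpoints must be vertex indices in 1..n_vertices", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    key <- pmin(edges[, 1L], edges[, 2L]) * (n_vertices + 1) +
      pmax(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key)) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  if (!is.null(labels)) {
    if (length(labels) != n_vertices) {
      stop("`labels` must have one entry per vertex", call. = FALSE)
    }
    igraph::V(g)$name <- as.character(labels)
  }
  g
}
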