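#' Newman modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)`, where `e_cc` is the fraction of edges falling
#' inside module `c` and `a_c` the fraction of edge endpoints attached to
#' `c`. Unweighted, unsigned version; `Q` lies in `[-0.5, 1)`.
#'
#' @param G an undirected simple `igraph` graph with at least one edge.
#' @param partition a `graph_partition` (see
#'   [greedy_modularity_partition()]) or an integer membership vector with one
#'   module id per vertex.
#' @return the modularity score.
#' @examples
#' g <- binary_graph(6, rbind(
#'   c(1, 2), c(2, 3), c(1, 3),
#'   c(4, 5), c(5, 6), c(4, 6)
#' ))
#' newman_modularity(g, c(1, 1, 1, 2, 2, 2)) # 0.5
#' @export
newman_modularity <- function(G, partition) {
  if (igraph::ecount(G) == 0L) {
    stop("modularity is undefined for an edgeless graph", call. = FALSE)
  }
  membership <- if (inherits(partition, "graph_partition")) {
    partition$membership
  } else {
    as.integer(partition)
  }
  if (length(membership) != igraph::vcount(G) || anyNA(membership)) {
    stop("`partition` must assign every vertex to a module", call. = FALSE)
  }
  igraph::modularity(G, membership)
}

#' Greedy modularity maximization (Clauset-Newman-Moore)
#'
#' Agglomerative modularity optimization: starting from singleton modules,
#' repeatedly merge the pair of modules giving the largest modularity
#' increase, and return the partition at the maximal modularity encountered.
#' Isolated vertices remain singleton modules and are counted. Greedy
#' agglomeration is a lower bound on the true modularity optimum.
#'
#' @param G an undirected simple `igraph` graph with at least one edge.
#' @return an object of class `graph_partition`: a list with `membership`
#'   (integer module ids `1..n_modules`, one per vertex), `n_modules` and
#'   `modularity`.
#' @export
greedy_modularity_partition <- function(G) {
  if (igraph::ecount(G) == 0L) {
    stop("modularity is undefined for an edgeless graph", call. = FALSE)
  }
  cl <- igraph::cluster_fast_greedy(G)
  # cut the agglomeration dendrogram at the maximal modularity encountered
  best_step <- which.max(cl$modularity) - 1L
  membership <- as.integer(igraph::cut_at(cl, steps = best_step))
  membership <- match(membership, unique(membership)) # contiguous ids
  structure(
    list(
      membership = membership,
      n_modules = max(membership),
      modularity = igraph::modularity(G, membership)
    ),
    class = "graph_partition"
  )
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf(
    "Partition into %d modules (Q = %.4f)\n", x$n_modules, x$modularity
  ))
  invisible(x)
}

#' Ring lattice
#'
#' Regular graph in which every vertex is connected to its `degree / 2`
#' nearest neighbors on each side of a ring; `N_E = n * degree / 2`.
#'
#' @param n number of vertices.
#' @param degree even vertex degree, strictly less than `n`.
#' @return an undirected simple `igraph` graph.
#' @examples
#' igraph::ecount(ring_lattice(112, 4)) # 224
#' @export
ring_lattice <- function(n, degree) {
  n <- as.integer(n)
  degree <- as.integer(degree)
  if (is.na(degree) || degree %% 2L != 0L || degree < 0L) {
    stop("`degree` must be a nonnegative even integer", call. = FALSE)
  }
  if (degree >= n) stop("`degree` must be smaller than `n`", call. = FALSE)
  if (degree == 0L) {
    return(binary_graph(n))
  }
  edges <- do.call(rbind, lapply(seq_len(degree %/% 2L), function(d) {
    i <- seq_len(n)
    cbind(i, (i + d - 1L) %% n + 1L)
  }))
  binary_graph(n, edges)
}

#' Nearest-neighbor lattice with an exact edge count
#'
#' Generalizes [ring_lattice()] to arbitrary edge counts: the `m` edges of
#' the saturated graph with the smallest ring distance
#' `min(|i - j|, n - |i - j|)` are retained (ties broken lexicographically).
#' When `m = n * d / 2` for an even `d < n` this is exactly the ring lattice
#' of degree `d`; intermediate `m` fill in the next neighbor ring partially,
#' keeping the graph as regular as the edge budget allows. Used by the
#' modularity experiment so lattice and random ensembles can be matched
#' edge-for-edge.
#'
#' @param n number of vertices.
#' @param m number of edges, at most `n (n - 1) / 2`.
#' @return an undirected simple `igraph` graph with exactly `m` edges.
#' @export
nearest_neighbor_graph <- function(n, m) {
  n <- as.integer(n)
  m <- as.integer(m)
  e_max <- n_saturated_edges(n)
  if (is.na(m) || m < 0L || m > e_max) {
    stop(sprintf("`m` must lie in 0..%d", as.integer(e_max)), call. = FALSE)
  }
  ep <- edge_pairs(n)
  span <- ep[, 2L] - ep[, 1L]
  ring_dist <- pmin(span, n - span)
  ord <- order(ring_dist, ep[, 1L], ep[, 2L])
  binary_graph(n, ep[ord[seq_len(m)], , drop = FALSE])
}

#' Randomly rewire edges, conserving the edge count
#'
#' Repeats `n_rewires` times: pick a uniformly random edge, detach one of its
#' endpoints (chosen uniformly), and reattach it to a uniformly random
#' vertex; proposals creating self-loops or duplicate edges are resampled
#' (bounded retries). The edge count is invariant by construction; the degree
#' sequence is not.
#'
#' @param G an undirected simple `igraph` graph.
#' @param n_rewires number of rewiring steps.
#' @param max_retries retry budget per step before giving up (a complete
#'   graph, for instance, cannot be rewired).
#' @return the rewired graph.
#' @export
rewire_edges <- function(G, n_rewires, max_retries = 1000L) {
  n_rewires <- as.integer(n_rewires)
  if (is.na(n_rewires) || n_rewires < 0L) {
    stop("`n_rewires` must be a nonnegative integer", call. = FALSE)
  }
  if (n_rewires == 0L) {
    return(G)
  }
  n <- igraph::vcount(G)
  el <- igraph::as_edgelist(G, names = FALSE)
  m <- nrow(el)
  if (m == 0L) stop("cannot rewire a graph with no edges", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  adj[el[, 2L:1L]] <- TRUE
  for (step in seq_len(n_rewires)) {
    done <- FALSE
    for (try in seq_len(max_retries)) {
      e <- sample.int(m, 1L)
      side <- sample.int(2L, 1L)
      keep <- el[e, side]
      old <- el[e, 3L - side]
      new <- sample.int(n, 1L)
      if (new == keep || adj[keep, new]) next
      adj[keep, old] <- adj[old, keep] <- FALSE
      adj[keep, new] <- adj[new, keep] <- TRUE
      el[e, ] <- c(keep, new)
      done <- TRUE
      break
    }
    if (!done) {
      stop("rewiring failed: graph too dense to rewire within the retry budget",
        call. = FALSE
      )
    }
  }
  labels <- if ("name" %in% igraph::vertex_attr_names(G)) igraph::V(G)$name
  binary_graph(n, el, labels = labels)
}

#' Uniform random graph with a fixed number of edges
#'
#' Erdos-Renyi `G(n, m)`: `m` distinct edges sampled uniformly without
#' replacement from the saturated edge set.
#'
#' @param n number of vertices.
#' @param m number of edges, at most `n (n - 1) / 2`.
#' @return an undirected simple `igraph` graph with exactly `m` edges.
#' @export
random_graph <- function(n, m) {
  n <- as.integer(n)
  m <- as.integer(m)
  e_max <- n_saturated_edges(n)
  if (is.na(m) || m < 0L || m > e_max) {
    stop(sprintf("`m` must lie in 0..%d", as.integer(e_max)), call. = FALSE)
  }
  ep <- edge_pairs(n)
  idx <- sample.int(e_max, m)
  binary_graph(n, ep[idx, , drop = FALSE])
}

#' Configuration of a modularity-versus-density experiment
#'
#' @param n_vertices number of vertices per graph (default 112, a typical
#'   cortical parcellation size).
#' @param edge_counts edge counts to sweep over; defaults to
#'   `n_vertices * lattice_degree / 2`.
#' @param rewire_counts rewiring counts to sweep over (default 0).
#' @param ensembles graph ensembles: `"lattice"` (nearest-neighbor ring,
#'   optionally rewired) and/or `"random"` (uniform `G(n, m)`).
#' @param replicates independent graphs per cell (default 1000).
#' @param lattice_degree ring-lattice degree used for the default edge count
#'   (default 4, the standard small-world baseline).
#' @param seed master seed; every (ensemble, edges, rewires) cell derives its
#'   own substream from it, so cells are independently reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_vertices = 112, edge_counts = NULL,
                              rewire_counts = 0,
                              ensembles = c("lattice", "random"),
                              replicates = 1000, lattice_degree = 4,
                              seed = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (is.null(edge_counts)) edge_counts <- n_vertices * lattice_degree / 2
  edge_counts <- as.integer(edge_counts)
  rewire_counts <- as.integer(rewire_counts)
  replicates <- as.integer(replicates)
  ensembles <- match.arg(ensembles, several.ok = TRUE)
  e_max <- n_saturated_edges(n_vertices)
  if (any(edge_counts < 1L) || any(edge_counts > e_max)) {
    stop(sprintf("edge counts must lie in 1..%d", as.integer(e_max)),
      call. = FALSE
    )
  }
  if (any(rewire_counts < 0L)) {
    stop("rewire counts must be nonnegative", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(
      n_vertices = n_vertices, edge_counts = edge_counts,
      rewire_counts = rewire_counts, ensembles = ensembles,
      replicates = replicates, lattice_degree = lattice_degree, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Run a modularity-versus-density experiment
#'
#' For every cell (ensemble x edge count x rewire count) of the
#' configuration, generates `replicates` independent graphs -- nearest-
#' neighbor lattices subsequently rewired, or uniform random graphs,
#' optionally rewired too -- detects modules by greedy modularity
#' maximization, and records the module count and modularity of each graph.
#' This reproduces the confound the metric work warns about: module counts
#' rise with topological randomness and fall as edges are added, so
#' modularity comparisons between network families that differ in density
#' mostly reflect the density difference.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `ensemble`, `n_edges`, `n_rewires`,
#'   `replicate`, `n_modules`, `modularity`; fully reproducible from the
#'   config seed.
#' @seealso [summarize_modularity_experiment()] for per-cell means.
#' @export
run_modularity_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- expand.grid(
    ensemble = config$ensembles,
    n_edges = config$edge_counts,
    n_rewires = config$rewire_counts,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  runner <- function() {
    cell_seeds <- sample.int(2147483646L, nrow(cells))
    out <- vector("list", nrow(cells))
    for (c_i in seq_len(nrow(cells))) {
      set.seed(cell_seeds[c_i])
      ens <- cells$ensemble[c_i]
      m <- cells$n_edges[c_i]
      r <- cells$n_rewires[c_i]
      n_mod <- integer(config$replicates)
      q <- numeric(config$replicates)
      for (rep_i in seq_len(config$replicates)) {
        g <- if (ens == "lattice") {
          nearest_neighbor_graph(config$n_vertices, m)
        } else {
          random_graph(config$n_vertices, m)
        }
        if (r > 0L) g <- rewire_edges(g, r)
        part <- greedy_modularity_partition(g)
        n_mod[rep_i] <- part$n_modules
        q[rep_i] <- part$modularity
      }
      out[[c_i]] <- data.frame(
        ensemble = ens, n_edges = m, n_rewires = r,
        replicate = seq_len(config$replicates),
        n_modules = n_mod, modularity = q,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }
  if (is.null(config$seed)) runner() else with_seed(config$seed, runner())
}

#' Per-cell summary of a modularity experiment
#'
#' @param results the data frame returned by [run_modularity_experiment()].
#' @return data frame with per-cell mean and standard deviation of the module
#'   count and modularity.
#' @export
summarize_modularity_experiment <- function(results) {
  agg <- stats::aggregate(
    cbind(n_modules, modularity) ~ ensemble + n_edges + n_rewires,
    data = results,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x))
  )
  data.frame(
    ensemble = agg$ensemble, n_edges = agg$n_edges,
    n_rewires = agg$n_rewires,
    mean_modules = agg$n_modules[, "mean"],
    sd_modules = agg$n_modules[, "sd"],
    mean_modularity = agg$modularity[, "mean"],
    sd_modularity = agg$modularity[, "sd"],
    stringsAsFactors = FALSE
  )
}
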