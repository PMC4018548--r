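# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify:
# distances via Floyd-Warshall instead of BFS/Dijkstra, modularity via a
# double loop over edges and degrees instead of igraph, ANOVA via explicit
# sums of squares instead of the vectorized fit.

# Floyd-Warshall all-pairs shortest paths from a matrix of edge lengths
# (Inf = no edge). Works for hop counts (length 1) and weighted lengths.
fw_distances <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Edge-length matrix of an igraph graph: 1 for present edges, Inf otherwise.
hop_length_matrix <- function(g) {
  n <- igraph::vcount(g)
  len <- matrix(Inf, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  len[el] <- 1
  len[el[, 2:1, drop = FALSE]] <- 1
  len
}

# Edge-length matrix of a weight matrix under the 1/w convention.
inverse_weight_length_matrix <- function(W) {
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- Inf
  len
}

# Efficiency straight from a distance matrix.
efficiency_from_d <- function(d) {
  n <- nrow(d)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

# Newman modularity by explicit counting: within-module edge fractions and
# endpoint fractions accumulated edge by edge.
brute_modularity <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  mods <- sort(unique(membership))
  q <- 0
  for (c_id in mods) {
    e_cc <- 0
    ends <- 0
    for (e in seq_len(m)) {
      in1 <- membership[el[e, 1]] == c_id
      in2 <- membership[el[e, 2]] == c_id
      if (in1 && in2) e_cc <- e_cc + 1
      ends <- ends + in1 + in2
    }
    q <- q + e_cc / m - (ends / (2 * m))^2
  }
  q
}

# All set partitions of n elements as membership vectors (restricted growth
# strings); Bell(8) = 4140 so this is feasible for n <= 8.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k_max) {
    pos <- length(prefix) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(k_max + 1L)) {
      rec(c(prefix, v), max(k_max, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# Maximal modularity over all partitions (exhaustive search).
brute_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  parts <- all_partitions(n)
  best <- -Inf
  for (p in parts) {
    q <- igraph::modularity(g, p)
    if (q > best) best <- q
  }
  best
}

# Two-way balanced ANOVA (subject + condition) from first-principles sums of
# squares, one n x J response matrix at a time.
anova_oracle <- function(z) {
  n <- nrow(z)
  J <- ncol(z)
  grand <- mean(z)
  ss_cond <- 0
  for (j in seq_len(J)) ss_cond <- ss_cond + n * (mean(z[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      fit <- mean(z[i, ]) + mean(z[, j]) - grand
      ss_err <- ss_err + (z[i, j] - fit)^2
    }
  }
  f <- (ss_cond / (J - 1)) / (ss_err / ((n - 1) * (J - 1)))
  list(
    statistic = f,
    p_value = pf(f, J - 1, (n - 1) * (J - 1), lower.tail = FALSE)
  )
}

# Random simple graph helper for oracle sweeps (edge presence by coin flips,
# independent of the package's generators).
random_oracle_graph <- function(n, p_edge = 0.3) {
  ep <- edge_pairs(n)
  keep <- runif(nrow(ep)) < p_edge
  binary_graph(n, ep[keep, , drop = FALSE])
}

# Random symmetric positive tie-free weight matrix.
random_weight_matrix <- function(n, lo = 0.1, hi = 0.9) {
  ep <- edge_pairs(n)
  w <- runif(nrow(ep), lo, hi)
  m <- matrix(0, n, n)
  m[ep] <- w
  m[ep[, 2:1]] <- w
  weight_matrix(m)
}
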