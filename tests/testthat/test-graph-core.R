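test_that("value thresholding follows the strict cut-off in both modes", {
  w2 <- weight_matrix(matrix(c(0, 0.8, 0.8, 0), 2))
  expect_equal(igraph::ecount(threshold_by_value(w2, 0.5)), 1)
  expect_equal(igraph::ecount(threshold_by_value(w2, 0.8)), 0) # strict

  w3 <- weight_matrix(matrix(c(
    0, 0.4, 0.8,
    0.4, 0, -0.7,
    0.8, -0.7, 0
  ), 3))
  expect_equal(igraph::ecount(threshold_by_value(w3, 0.5, "signed")), 1)
  g_abs <- threshold_by_value(w3, 0.5, "absolute")
  expect_equal(igraph::ecount(g_abs), 2)
  el <- igraph::as_edgelist(g_abs, names = FALSE)
  expect_setequal(paste(el[, 1], el[, 2]), c("1 3", "2 3"))
  expect_error(threshold_by_value(w3, Inf), "finite")
})

test_that("thresholding is non-linear: mean of thresholded != thresholded mean", {
  w1 <- weight_matrix(matrix(c(0, 0.4, 0.4, 0), 2))
  w2 <- weight_matrix(matrix(c(0, 0.8, 0.8, 0), 2))
  tau <- 0.5
  indicator <- function(W) as.numeric(igraph::ecount(threshold_by_value(W, tau)))
  mean_of_thresholded <- (indicator(w1) + indicator(w2)) / 2
  thresholded_mean <- indicator(weight_matrix((unclass(w1) + unclass(w2)) / 2))
  expect_equal(mean_of_thresholded, 0.5)
  expect_equal(thresholded_mean, 1)
  expect_false(mean_of_thresholded == thresholded_mean)
})

test_that("density thresholding keeps floor(k * E_max) top-ranked edges", {
  set.seed(42)
  W <- random_weight_matrix(6)
  e_max <- 15
  expect_equal(igraph::ecount(threshold_by_density(W, 0)), 0)
  expect_equal(igraph::ecount(threshold_by_density(W, 1)), e_max)
  for (k in c(0.2, 0.5, 0.8)) {
    expect_equal(igraph::ecount(threshold_by_density(W, k)), floor(k * e_max))
  }

  # 4-node case: exactly the top-2 weighted edges at k = 1/3
  ep <- edge_pairs(4)
  w <- c(0.1, 0.9, 0.3, 0.7, 0.2, 0.5)
  m <- matrix(0, 4, 4)
  m[ep] <- w
  m[ep[, 2:1]] <- w
  g <- threshold_by_density(weight_matrix(m), 1 / 3)
  el <- igraph::as_edgelist(g, names = FALSE)
  top2 <- ep[order(-w)[1:2], , drop = FALSE]
  expect_setequal(
    paste(el[, 1], el[, 2]),
    paste(top2[, 1], top2[, 2])
  )
  expect_error(threshold_by_density(W, 1.2), "density")

  # absolute mode ranks by magnitude
  m_neg <- matrix(0, 3, 3)
  m_neg[1, 2] <- m_neg[2, 1] <- -0.9
  m_neg[1, 3] <- m_neg[3, 1] <- 0.2
  m_neg[2, 3] <- m_neg[3, 2] <- 0.5
  g1 <- threshold_by_density(weight_matrix(m_neg), 1 / 3, "absolute")
  el1 <- igraph::as_edgelist(g1, names = FALSE)
  expect_equal(as.vector(el1), c(1, 2))
})

test_that("hop distances match the Floyd-Warshall oracle on random graphs", {
  set.seed(7)
  for (trial in 1:30) {
    n <- sample(4:30, 1)
    g <- random_oracle_graph(n, runif(1, 0.05, 0.5))
    d <- shortest_path_lengths(g)
    expect_equal(unclass(d)[seq_along(d)], fw_distances(hop_length_matrix(g))[seq_along(d)],
      tolerance = 1e-12
    )
  }
  # named cases
  tri <- binary_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_true(all(shortest_path_lengths(tri)[upper.tri(diag(3))] == 1))
  p3 <- binary_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(shortest_path_lengths(p3)[1, 3], 2)
  iso <- binary_graph(2)
  expect_equal(shortest_path_lengths(iso)[1, 2], Inf)
})

test_that("weighted distances use 1/w edge lengths and reject negatives", {
  w2 <- weight_matrix(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(weighted_shortest_path_lengths(w2)[1, 2], 2)

  wk3 <- weight_matrix(matrix(0.5, 3, 3))
  d <- weighted_shortest_path_lengths(wk3)
  expect_true(all(d[upper.tri(d)] == 2)) # direct edge (2) beats 2-hop (4)

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(weighted_shortest_path_lengths(weight_matrix(chain))[1, 3], 2)

  neg <- matrix(0, 3, 3)
  neg[1, 2] <- neg[2, 1] <- -0.2
  expect_error(
    weighted_shortest_path_lengths(weight_matrix(neg)),
    "negative"
  )
})

test_that("weighted distances match the Floyd-Warshall oracle", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(4:25, 1)
    W <- random_weight_matrix(n)
    # sparsify some entries to exercise disconnection
    mask <- matrix(runif(n * n) < 0.4, n, n)
    mask <- mask & t(mask)
    Wm <- unclass(W)
    Wm[mask] <- 0
    W <- weight_matrix(Wm)
    d <- weighted_shortest_path_lengths(W)
    d_oracle <- fw_distances(inverse_weight_length_matrix(unclass(W)))
    expect_equal(unclass(d)[seq_along(d)], d_oracle[seq_along(d)], tolerance = 1e-12)
  }
})

test_that("global efficiency closed forms and bounds hold", {
  for (n in c(3, 5, 8)) {
    kn <- binary_graph(n, edge_pairs(n))
    expect_identical(global_efficiency(kn), 1)
    expect_identical(global_efficiency(binary_graph(n)), 0)
  }
  p3 <- binary_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(p3), 5 / 6, tolerance = 1e-15)
  expect_error(global_efficiency(binary_graph(1)), "2 vertices")
})

test_that("efficiency is monotone non-decreasing under edge addition", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(5:15, 1)
    ep <- edge_pairs(n)
    keep <- runif(nrow(ep)) < 0.3
    g <- binary_graph(n, ep[keep, , drop = FALSE])
    e_before <- global_efficiency(g)
    missing <- which(!keep)
    if (!length(missing)) next
    add <- ep[sample(missing, 1), , drop = FALSE]
    g2 <- igraph::add_edges(g, as.vector(t(add)))
    expect_gte(global_efficiency(g2), e_before)
    expect_lte(global_efficiency(g2), 1)
  }
})

test_that("weighted efficiency, weighted density, and the degeneracy condition", {
  w2 <- weight_matrix(matrix(c(0, 0.7, 0.7, 0), 2))
  expect_equal(weighted_global_efficiency(w2), 0.7, tolerance = 1e-15)

  wk3 <- weight_matrix(matrix(0.5, 3, 3))
  expect_equal(weighted_global_efficiency(wk3), 0.5, tolerance = 1e-15)
  expect_equal(weighted_density(wk3), 0.5, tolerance = 1e-15)

  # K_3 with weights {0.2, 0.4, 0.6}: K_W = mean = 0.4
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(weighted_density(weight_matrix(m)), 0.4, tolerance = 1e-15)
  expect_equal(weighted_density(weight_matrix(2 * m)), 0.8, tolerance = 1e-15)
  expect_equal(weighted_density(weight_matrix(matrix(0, 4, 4))), 0)

  # spread condition w_max <= 2 w_min forces E_W == K_W on complete graphs
  set.seed(31)
  W <- random_weight_matrix(10, lo = 0.4, hi = 0.6)
  expect_true(direct_path_condition_holds(W))
  expect_equal(weighted_global_efficiency(W), weighted_density(W),
    tolerance = 1e-12
  )

  # counterexample: strong 2-hop detour beats a weak direct edge
  bad <- matrix(0, 3, 3)
  bad[1, 2] <- bad[2, 1] <- 1
  bad[2, 3] <- bad[3, 2] <- 1
  bad[1, 3] <- bad[3, 1] <- 0.2
  Wb <- weight_matrix(bad)
  expect_false(direct_path_condition_holds(Wb))
  expect_false(isTRUE(all.equal(
    weighted_global_efficiency(Wb),
    weighted_density(Wb)
  )))

  # uniform complete weights trivially satisfy the condition
  expect_true(direct_path_condition_holds(weight_matrix(matrix(0.3, 4, 4))))
})

test_that("weight matrix invariants are enforced", {
  expect_error(weight_matrix(matrix(0, 1, 1)), "at least 2")
  expect_error(weight_matrix(matrix(1:6, 2, 3)), "square")
  m <- matrix(c(0, 1, NA, 0), 2)
  expect_error(weight_matrix(m), "non-finite")
  asym <- matrix(c(0, 0.5, 0.5 + 1e-6, 0), 2)
  expect_warning(W <- weight_matrix(asym), "symmetrized")
  expect_equal(W[1, 2], 0.5 + 5e-7)
  asym_big <- matrix(c(0, 0.5, 0.51, 0), 2)
  expect_error(weight_matrix(asym_big), "asymmetric")
  # diagonal is forced to zero
  expect_equal(diag(unclass(weight_matrix(diag(3) + 0.2))), rep(0, 3))
})
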