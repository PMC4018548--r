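test_that("Fisher z matches its closed form and round-trips", {
  expect_identical(fisher_z(0), 0)
  # independent log-based evaluation of atanh
  expect_equal(fisher_z(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)),
    tolerance = 1e-15
  )
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(c(0.2, -1)), "position 2")

  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0)) # strictly increasing
})

test_that("Benjamini-Hochberg step-up matches the hand-applied rule", {
  res <- fdr_bh(c(0.001, 0.01, 0.02, 0.04, 0.9), 0.05)
  expect_equal(sum(res$reject), 4)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(res$q >= c(0.001, 0.01, 0.02, 0.04, 0.9)))

  expect_equal(sum(fdr_bh(rep(1, 10), 0.05)$reject), 0)
  expect_true(fdr_bh(0.04, 0.05)$reject) # m = 1: threshold is alpha0
  expect_false(fdr_bh(0.06, 0.05)$reject)

  empty <- fdr_bh(numeric(0), 0.05)
  expect_length(empty$reject, 0)
  expect_length(empty$q, 0)
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
  expect_error(fdr_bh(0.5, alpha0 = 0), "alpha0")
})

test_that("edge linear model handles degenerate and exact-effect inputs", {
  # constant responses: no condition effect at all
  fit <- edge_linear_model(matrix(0.37, 6, 3))
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)
  expect_equal(fit$sign, 0L)

  # exact additive effect on condition 2, no noise
  z <- matrix(0.1, 8, 2)
  z[, 2] <- z[, 2] + 0.25
  fit2 <- edge_linear_model(z)
  expect_equal(fit2$p_value, 0)
  expect_equal(fit2$sign, 1L)
  expect_equal(unname(fit2$beta), 0.25, tolerance = 1e-12)

  # subject-only variation is not a condition effect
  z3 <- matrix(rep(c(1, 2, 3), 4), nrow = 3)
  fit3 <- edge_linear_model(z3)
  expect_equal(fit3$statistic, 0)
  expect_equal(fit3$sign, 0L)

  expect_error(edge_linear_model(matrix(1:6, 6, 1)), "2 conditions")
  expect_error(edge_linear_model(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("edge linear model F matches the sums-of-squares oracle and aov", {
  set.seed(101)
  for (trial in 1:8) {
    n <- sample(4:8, 1)
    J <- sample(2:4, 1)
    z <- matrix(rnorm(n * J), n, J)
    fit <- edge_linear_model(z)
    oracle <- anova_oracle(z)
    expect_equal(fit$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)

    # second independent route: R's own aov on the long layout
    long <- data.frame(
      y = as.vector(z),
      subject = factor(rep(seq_len(n), J)),
      condition = factor(rep(seq_len(J), each = n))
    )
    aov_tab <- summary(stats::aov(y ~ subject + condition, data = long))[[1]]
    expect_equal(fit$statistic, aov_tab["condition", "F value"],
      tolerance = 1e-8
    )
  }
})

test_that("mean SPN recovers planted strong edges and flags degeneracy", {
  # 10 nodes -> 45 edges; plant 10 strong edges in an otherwise weak matrix
  n_v <- 10
  base <- matrix(fisher_z_inverse(0.2), n_v, n_v)
  ep <- edge_pairs(n_v)
  planted <- ep[seq(1, 45, length.out = 10), , drop = FALSE]
  base[planted] <- fisher_z_inverse(1.0)
  base[planted[, 2:1]] <- fisher_z_inverse(1.0)
  diag(base) <- 0
  truth <- ground_truth(base, noise_sd = 0.1)
  sim <- generate_dataset(20, 1, truth = truth, seed = 99)
  res <- mean_spn(sim$data, 1)
  inc <- included_edges(res)
  expect_equal(nrow(inc), 10)
  expect_setequal(
    paste(inc$i, inc$j),
    paste(planted[, 1], planted[, 2])
  )
  expect_true(all(inc$q_value <= res$alpha0))

  # identical correlations everywhere -> zero grand sd
  flat <- ground_truth(matrix(0.3, 4, 4) - diag(0.3, 4), noise_sd = 0)
  sim_flat <- generate_dataset(5, 1, truth = flat)
  expect_error(mean_spn(sim_flat$data, 1), "degenerate")

  expect_error(mean_spn(generate_dataset(1, 1)$data, 1), "2 subjects")
  expect_error(mean_spn(sim$data, "nope"), "unknown condition")
})

test_that("mean SPN false positives under a global null are controlled", {
  truth <- ground_truth(matrix(0, 10, 10), noise_sd = 0.2)
  n_rep <- 200
  any_hit <- logical(n_rep)
  set.seed(500)
  for (r in seq_len(n_rep)) {
    sim <- generate_dataset(20, 1, truth = truth)
    any_hit[r] <- nrow(included_edges(mean_spn(sim$data, 1))) > 0
  }
  prop <- mean(any_hit)
  se <- sd(any_hit) / sqrt(n_rep)
  expect_lte(prop, 0.05 + 2 * max(se, sqrt(0.05 * 0.95 / n_rep)))
})

test_that("differential SPN recovers planted declining edges with correct sign", {
  truth <- default_ground_truth(30, n_affected_edges = 8, edge_delta = -0.3)
  sim <- generate_dataset(20, 4, truth = truth, seed = 7)
  res <- differential_spn(sim$data)
  inc <- included_edges(res)
  planted_keys <- paste(truth$edge_effects$i, truth$edge_effects$j)
  found_minus <- paste(inc$minus$i, inc$minus$j)
  expect_gte(sum(planted_keys %in% found_minus), 7)
  expect_equal(nrow(inc$plus), 0)
  # plus and minus sets are disjoint by construction
  expect_length(intersect(found_minus, paste(inc$plus$i, inc$plus$j)), 0)
  expect_true(all(res$table$q_value >= res$table$p_value))
})

test_that("differential SPN is invariant under subject relabeling", {
  sim <- generate_dataset(12, 3, truth = default_ground_truth(12), seed = 13)
  # the gradient diagnostic may fire on noisy coefficients; irrelevant here
  res1 <- suppressWarnings(differential_spn(sim$data))
  perm <- sample(12)
  permuted <- correlation_dataset(
    sim$data$r[, , perm, ],
    subject_ids = sim$data$subject_ids[perm],
    condition_ids = sim$data$condition_ids
  )
  res2 <- suppressWarnings(differential_spn(permuted))
  expect_equal(res2$table$statistic, res1$table$statistic, tolerance = 1e-12)
  expect_identical(res2$table$included, res1$table$included)
})

test_that("duplicating a condition column behaves like a null contrast", {
  truth <- ground_truth(matrix(0.2, 14, 14) - diag(0.2, 14), noise_sd = 0.15)
  sim <- generate_dataset(10, 2, truth = truth, seed = 71)
  arr <- sim$data$r
  arr[, , , 2] <- arr[, , , 1] # duplicated column: no condition signal left
  ds <- correlation_dataset(arr)
  res <- differential_spn(ds)
  # identical columns give zero condition and error SS: every F is 0
  expect_true(all(res$table$statistic == 0))
  expect_equal(sum(res$table$included), 0)
})

test_that("node differential SPN recovers planted node shifts", {
  truth <- default_ground_truth(30, n_affected_nodes = 5, node_delta = 3)
  sim <- generate_node_signals(20, 4, truth = truth, seed = 17)
  res <- node_differential_spn(sim$signals)
  inc <- included_edges(res)
  expect_setequal(inc$plus$v, 1:5)
  expect_equal(nrow(inc$minus), 0)

  # per-node F values match the brute-force oracle
  y <- sim$signals$y
  for (v in c(1, 10, 30)) {
    oracle <- anova_oracle(y[v, , ]) # y[v, , ] is already subjects x conditions
    expect_equal(res$table$statistic[v], oracle$statistic, tolerance = 1e-10)
  }

  # constant signals include nothing
  const <- node_signal_table(array(5, c(4, 6, 3)))
  res0 <- node_differential_spn(const)
  expect_equal(sum(res0$table$included), 0)
  expect_true(all(res0$table$sign == 0))
})

test_that("uncorrected and Bonferroni thresholds are supported", {
  sim <- generate_dataset(10, 3, truth = default_ground_truth(12), seed = 23)
  res_none <- differential_spn(sim$data, alpha0 = 0.01, correction = "none")
  expect_true(all(res_none$table$q_value == res_none$table$p_value))
  expect_identical(
    res_none$table$included,
    res_none$table$p_value <= 0.01
  )
  res_bonf <- differential_spn(sim$data, correction = "bonferroni")
  res_bh <- differential_spn(sim$data, correction = "BH")
  expect_lte(sum(res_bonf$table$included), sum(res_bh$table$included))
})

test_that("non-monotone condition profiles trigger the gradient warning", {
  # edge (1,2) goes strongly up at condition 2 and strongly down at 3:
  # significant, but its coefficients point both ways
  n <- 12
  arr <- array(0, c(4, 4, n, 3))
  set.seed(3)
  for (i in seq_len(n)) {
    shift <- c(0, 0.6, -0.6)
    for (j in 1:3) {
      m <- matrix(0.1, 4, 4)
      m[1, 2] <- m[2, 1] <- tanh(atanh(0.1) + shift[j] + rnorm(1, 0, 0.05))
      diag(m) <- 0
      arr[, , i, j] <- m + matrix(rnorm(16, 0, 1e-3), 4) |> (\(x) (x + t(x)) / 2)()
    }
  }
  diag_zero <- function(a) {
    for (i in seq_len(dim(a)[3])) for (j in seq_len(dim(a)[4])) diag(a[, , i, j]) <- 0
    a
  }
  ds <- correlation_dataset(diag_zero(arr))
  expect_warning(differential_spn(ds), "mixed sign")
})
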