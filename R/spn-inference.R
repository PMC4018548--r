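#' Fisher z-transform of correlations
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform applied to correlations before edge-level testing so that normal
#' theory applies. Strictly increasing on `(-1, 1)`; [fisher_z_inverse()]
#' (`tanh`) undoes it.
#'
#' @param r numeric vector of correlations with `|r| < 1`.
#' @return the transformed values.
#' @examples
#' fisher_z(0.5) # 0.5493061
#' fisher_z_inverse(fisher_z(0.5))
#' @export
fisher_z <- function(r) {
  bad <- which(is.na(r) | abs(r) >= 1)
  if (length(bad)) {
    stop(sprintf(
      "correlation at position %d is %s; Fisher z requires |r| < 1",
      bad[1L], format(r[bad[1L]])
    ), call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z numeric vector on the Fisher z scale.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: rejects all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= (k / m) * alpha0}`. Returned q-values are the
#' monotone-corrected step-up adjusted p-values, so the rejection set is
#' exactly `{q <= alpha0}`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha0 FDR base rate in `(0, 1)`.
#' @return list with `reject` (logical mask) and `q` (adjusted p-values).
#' @examples
#' fdr_bh(c(0.001, 0.01, 0.02, 0.04, 0.9), 0.05)$reject # 4 rejections
#' @export
fdr_bh <- function(p_values, alpha0 = 0.05) {
  if (!is.numeric(alpha0) || length(alpha0) != 1L || is.na(alpha0) ||
    alpha0 <= 0 || alpha0 >= 1) {
    stop("`alpha0` must lie in (0, 1)", call. = FALSE)
  }
  if (length(p_values) == 0L) {
    return(list(reject = logical(0), q = numeric(0)))
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(reject = q <= alpha0, q = q)
}

# Map a correction name to adjusted p-values.
.adjust_p <- function(p, correction) {
  switch(correction,
    BH = stats::p.adjust(p, method = "BH"),
    bonferroni = stats::p.adjust(p, method = "bonferroni"),
    none = p,
    stop(sprintf("unknown correction '%s'", correction), call. = FALSE)
  )
}

# Balanced complete two-way (subject + condition) fixed-effects ANOVA, fitted
# simultaneously for E responses. `z` is an E x n x J array. For a balanced
# complete design this is the Laird-Ware random-intercept model with the
# subject effects profiled out: the F test for the condition factor has
# (J - 1, (n - 1)(J - 1)) degrees of freedom either way.
.balanced_anova <- function(z) {
  d <- dim(z)
  e_n <- d[1L]
  n <- d[2L]
  J <- d[3L]
  if (n < 2L) stop("at least 2 subjects required", call. = FALSE)
  if (J < 2L) stop("at least 2 conditions required", call. = FALSE)
  if (anyNA(z) || any(!is.finite(z))) {
    stop("model input must be complete and finite", call. = FALSE)
  }
  m_subj <- rowMeans(z, dims = 2L) # E x n
  m_cond <- colMeans(aperm(z, c(2L, 1L, 3L))) # E x J
  m_all <- rowMeans(m_cond) # E
  ss_cond <- n * rowSums((m_cond - m_all)^2)
  ms_arr <- array(m_subj, dim = d)
  mc_arr <- aperm(array(m_cond, dim = c(e_n, J, n)), c(1L, 3L, 2L))
  resid <- z - ms_arr - mc_arr + m_all
  ss_err <- rowSums(resid^2, dims = 1L)
  ss_tot <- rowSums((z - m_all)^2, dims = 1L)
  df1 <- J - 1L
  df2 <- (n - 1L) * (J - 1L)
  f <- (ss_cond / df1) / (ss_err / df2)
  # degenerate cases: constant responses, or zero condition and error SS
  f[ss_tot <= 1e-20 * pmax(1, m_all^2)] <- 0
  f[is.nan(f)] <- 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  beta <- m_cond[, -1L, drop = FALSE] - m_cond[, 1L]
  colnames(beta) <- paste0("beta_", 2L:J)
  pick <- max.col(abs(beta), ties.method = "first")
  b_sel <- beta[cbind(seq_len(e_n), pick)]
  sgn <- sign(b_sel)
  sgn[abs(b_sel) <= 1e-12 * pmax(1, abs(m_all))] <- 0
  sgn[f == 0] <- 0
  list(
    statistic = f, p_value = p, beta = beta, sign = as.integer(sgn),
    df1 = df1, df2 = df2
  )
}

#' Within-subject linear model for one edge (or node)
#'
#' Fits the repeated-measures model `z_ij = mu + subject_i + condition_j +
#' eps_ij` to an `n x J` matrix of responses (Fisher-z correlations for an
#' edge, or time-averaged signals for a node) and returns the omnibus F test
#' for the condition factor, with `(J - 1, (n - 1)(J - 1))` degrees of
#' freedom. For the balanced complete designs accepted here this
#' fixed-effects fit is the random-intercept mixed model with the subject
#' intercepts profiled out, so the F statistic matches the mixed-model test.
#' The coefficient vector is reference-coded (condition means minus the first
#' condition mean) and the reported effect sign is the sign of the
#' largest-magnitude coefficient -- meaningful when the conditions form an
#' experimental gradient.
#'
#' @param edge_values `n x J` numeric matrix: subjects in rows, conditions in
#'   columns, complete and finite.
#' @return list with `statistic` (F), `p_value`, `beta` (named length `J - 1`
#'   vector), `sign` in `{-1, 0, 1}`, and degrees of freedom `df1`, `df2`.
#' @examples
#' z <- matrix(rnorm(24), 6, 4)
#' edge_linear_model(z)$statistic
#' @export
edge_linear_model <- function(edge_values) {
  edge_values <- as.matrix(edge_values)
  n <- nrow(edge_values)
  J <- ncol(edge_values)
  fit <- .balanced_anova(array(edge_values, c(1L, n, J)))
  list(
    statistic = fit$statistic[1L], p_value = fit$p_value[1L],
    beta = fit$beta[1L, ], sign = fit$sign[1L],
    df1 = fit$df1, df2 = fit$df2
  )
}

# Shared constructor for SPN results.
spn_result <- function(kind, table, alpha0, correction, n_vertices,
                       labels = NULL, condition = NULL) {
  structure(
    list(
      kind = kind, table = table, alpha0 = alpha0, correction = correction,
      n_vertices = n_vertices, labels = labels, condition = condition
    ),
    class = "spn_result"
  )
}

#' @export
print.spn_result <- function(x, ...) {
  n_inc <- sum(x$table$included)
  cat(sprintf(
    "%s SPN (%s, alpha0 = %g): %d of %d %s included\n",
    x$kind, x$correction, x$alpha0, n_inc, nrow(x$table),
    if (x$kind == "differential-node") "nodes" else "edges"
  ))
  if (x$kind %in% c("differential-edge", "differential-node")) {
    cat(sprintf(
      "  upweighted (SPN+): %d   downweighted (SPN-): %d\n",
      sum(x$table$included & x$table$sign > 0),
      sum(x$table$included & x$table$sign < 0)
    ))
  }
  invisible(x)
}

#' Included elements of an SPN
#'
#' For a mean SPN, the significant edges; for differential SPNs, a list with
#' the upweighted (`plus`, SPN+) and downweighted (`minus`, SPN-) components,
#' which are disjoint by construction.
#'
#' @param result an `spn_result`.
#' @return data frame of included rows, or a list `plus`/`minus` of such.
#' @export
included_edges <- function(result) {
  stopifnot(inherits(result, "spn_result"))
  tab <- result$table
  if (result$kind == "mean") {
    return(tab[tab$included, , drop = FALSE])
  }
  list(
    plus = tab[tab$included & tab$sign > 0, , drop = FALSE],
    minus = tab[tab$included & tab$sign < 0, , drop = FALSE]
  )
}

# Shared head of the edge test table.
.edge_table_head <- function(n_v, labels) {
  ep <- edge_pairs(n_v)
  if (is.null(labels)) labels <- as.character(seq_len(n_v))
  data.frame(
    node_i = labels[ep[, 1L]], node_j = labels[ep[, 2L]],
    i = ep[, 1L], j = ep[, 2L],
    stringsAsFactors = FALSE
  )
}

#' Mean statistical parametric network for one condition
#'
#' Summarizes one condition's average connectivity by mass-univariate
#' inference: each edge's correlations are Fisher z-transformed, and the edge
#' statistic compares the edge's mean to the grand sample mean by a z test,
#' `(mean_i z^e_i - zbar) / (sd / sqrt(n))`, where the grand mean and grand
#' standard deviation are computed over all edges and subjects within the
#' condition (`sd_scope = "values"`, the default) or over the edge-wise means
#' (`sd_scope = "edge_means"`). The test is one-sided (upper tail): an edge is
#' included when its correlation significantly exceeds the grand mean after
#' multiple-testing correction.
#'
#' @param data a [correlation_dataset()] with at least 2 subjects.
#' @param condition condition label (or index) to summarize.
#' @param alpha0 base rate for the correction (default 0.05).
#' @param correction `"BH"` (FDR, default), `"bonferroni"`, or `"none"`.
#' @param sd_scope scale of the grand standard deviation; see above.
#' @return an `spn_result` of kind `"mean"` whose table has one row per edge
#'   of the saturated graph (statistic, p, q, included).
#' @export
mean_spn <- function(data, condition, alpha0 = 0.05,
                     correction = c("BH", "none", "bonferroni"),
                     sd_scope = c("values", "edge_means")) {
  stopifnot(inherits(data, "correlation_dataset"))
  correction <- match.arg(correction)
  sd_scope <- match.arg(sd_scope)
  d <- dim(data$r)
  n <- d[3L]
  if (n < 2L) stop("mean SPN requires at least 2 subjects", call. = FALSE)
  if (is.character(condition)) {
    j <- match(condition, data$condition_ids)
    if (is.na(j)) {
      stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
    }
  } else {
    j <- as.integer(condition)
    if (is.na(j) || j < 1L || j > d[4L]) {
      stop("condition index out of range", call. = FALSE)
    }
  }
  z <- fisher_z(edge_value_array(data)[, , j, drop = FALSE][, , 1L])
  z <- matrix(z, ncol = n) # E x n
  grand_mean <- mean(z)
  edge_means <- rowMeans(z)
  grand_sd <- switch(sd_scope,
    values = stats::sd(as.vector(z)),
    edge_means = stats::sd(edge_means)
  )
  if (!is.finite(grand_sd) || grand_sd <= 0) {
    stop("degenerate dataset: zero grand standard deviation", call. = FALSE)
  }
  statistic <- (edge_means - grand_mean) / (grand_sd / sqrt(n))
  p <- stats::pnorm(statistic, lower.tail = FALSE)
  q <- .adjust_p(p, correction)
  tab <- .edge_table_head(d[1L], data$labels)
  tab$statistic <- statistic
  tab$p_value <- p
  tab$q_value <- q
  tab$sign <- as.integer(sign(statistic))
  tab$included <- q <= alpha0
  spn_result("mean", tab, alpha0, correction, d[1L],
    labels = data$labels, condition = data$condition_ids[j]
  )
}

#' Differential statistical parametric network over edges
#'
#' Tests every edge of the saturated graph for a condition effect: the
#' Fisher-z correlations of each edge are fitted with the within-subject
#' model of [edge_linear_model()] and the per-edge condition F tests are
#' corrected jointly across all `N_E` edges. Significant edges are assigned
#' to the upweighted network SPN+ or the downweighted network SPN- according
#' to the sign of their largest-magnitude condition coefficient.
#'
#' @inheritParams mean_spn
#' @return an `spn_result` of kind `"differential-edge"`; its table carries
#'   the F statistics, p/q-values, signs, inclusion flags, and the
#'   reference-coded coefficient columns `beta_2 .. beta_J`.
#' @export
differential_spn <- function(data, alpha0 = 0.05,
                             correction = c("BH", "none", "bonferroni")) {
  stopifnot(inherits(data, "correlation_dataset"))
  correction <- match.arg(correction)
  d <- dim(data$r)
  if (d[4L] < 2L) {
    stop("differential SPN requires at least 2 conditions", call. = FALSE)
  }
  z <- fisher_z(edge_value_array(data))
  dim(z) <- c(n_saturated_edges(d[1L]), d[3L], d[4L])
  fit <- .balanced_anova(z)
  q <- .adjust_p(fit$p_value, correction)
  tab <- .edge_table_head(d[1L], data$labels)
  tab$statistic <- fit$statistic
  tab$p_value <- fit$p_value
  tab$q_value <- q
  tab$sign <- fit$sign
  tab$included <- q <= alpha0
  tab <- cbind(tab, as.data.frame(fit$beta))
  .warn_mixed_signs(fit$beta, tab$included)
  spn_result("differential-edge", tab, alpha0, correction, d[1L],
    labels = data$labels
  )
}

# Sign assignment presumes an experimental gradient; warn when a significant
# element has condition coefficients pointing both ways.
.warn_mixed_signs <- function(beta, included) {
  if (!any(included)) {
    return(invisible())
  }
  b <- beta[included, , drop = FALSE]
  tol <- 1e-8 * pmax(1, apply(abs(b), 1L, max))
  mixed <- rowSums(b > tol) > 0 & rowSums(b < -tol) > 0
  if (any(mixed)) {
    warning(sprintf(
      "%d significant element(s) have condition coefficients of mixed sign; ",
      sum(mixed)
    ), "the SPN+/SPN- assignment assumes a monotone experimental gradient",
    call. = FALSE
    )
  }
  invisible()
}

#' Differential statistical parametric network over nodes
#'
#' Node-level analogue of [differential_spn()]: one within-subject linear
#' model per region, on the raw time-averaged signals (no Fisher transform),
#' with joint correction across the `N_V` nodes. Significant nodes are split
#' into upweighted and downweighted sets by the sign of the
#' largest-magnitude condition coefficient.
#'
#' @param signals a [node_signal_table()].
#' @inheritParams mean_spn
#' @return an `spn_result` of kind `"differential-node"` with one table row
#'   per node.
#' @export
node_differential_spn <- function(signals, alpha0 = 0.05,
                                  correction = c("BH", "none", "bonferroni")) {
  stopifnot(inherits(signals, "node_signal_table"))
  correction <- match.arg(correction)
  fit <- .balanced_anova(signals$y)
  q <- .adjust_p(fit$p_value, correction)
  labels <- signals$labels
  if (is.null(labels)) labels <- as.character(seq_len(dim(signals$y)[1L]))
  tab <- data.frame(node = labels, v = seq_along(labels), stringsAsFactors = FALSE)
  tab$statistic <- fit$statistic
  tab$p_value <- fit$p_value
  tab$q_value <- q
  tab$sign <- fit$sign
  tab$included <- q <= alpha0
  tab <- cbind(tab, as.data.frame(fit$beta))
  .warn_mixed_signs(fit$beta, tab$included)
  spn_result("differential-node", tab, alpha0, correction,
    dim(signals$y)[1L],
    labels = labels
  )
}
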