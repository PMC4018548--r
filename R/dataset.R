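#' Multi-subject, multi-condition array of correlation matrices
#'
#' The full dataset of a one-way repeated-measures connectivity experiment:
#' one symmetric `N_V x N_V` association matrix per subject and condition.
#' Internally stored as a 4-d array `[node, node, subject, condition]` with
#' zero diagonals; every slice must satisfy the [weight_matrix()] invariants
#' and all slices must share node labels. The order of `condition_ids` is
#' meaningful: it encodes the experimental gradient used when reporting signed
#' effects.
#'
#' @param matrices either a 4-d numeric array `[N_V, N_V, n, J]`, or a nested
#'   list `matrices[[i]][[j]]` of `N_V x N_V` matrices (subject `i`,
#'   condition `j`).
#' @param subject_ids length-`n` labels (default `S1..Sn`).
#' @param condition_ids length-`J` ordered labels (default `C1..CJ`).
#' @param labels optional node names shared by all matrices.
#' @return an object of class `correlation_dataset` with elements `r`
#'   (the 4-d array), `subject_ids`, `condition_ids`, `labels`.
#' @export
correlation_dataset <- function(matrices, subject_ids = NULL,
                                condition_ids = NULL, labels = NULL) {
  if (is.list(matrices)) {
    n <- length(matrices)
    if (n == 0L) stop("empty dataset", call. = FALSE)
    J <- length(matrices[[1L]])
    if (J == 0L || !all(vapply(matrices, length, 0L) == J)) {
      stop("every subject needs the same number of condition matrices",
        call. = FALSE
      )
    }
    n_v <- nrow(as.matrix(matrices[[1L]][[1L]]))
    r <- array(NA_real_, c(n_v, n_v, n, J))
    for (i in seq_len(n)) {
      for (j in seq_len(J)) {
        r[, , i, j] <- as.matrix(matrices[[i]][[j]])
      }
    }
    if (is.null(labels)) labels <- rownames(as.matrix(matrices[[1L]][[1L]]))
  } else if (is.array(matrices) && length(dim(matrices)) == 4L) {
    r <- matrices
    storage.mode(r) <- "double"
    if (is.null(labels)) labels <- dimnames(matrices)[[1L]]
  } else {
    stop("`matrices` must be a 4-d array or a nested list of matrices",
      call. = FALSE
    )
  }
  d <- dim(r)
  if (d[1L] != d[2L]) stop("matrices must be square", call. = FALSE)
  n_v <- d[1L]
  n <- d[3L]
  J <- d[4L]
  if (n_v < 2L) stop("need at least 2 nodes", call. = FALSE)
  # validate and normalize every slice through the weight_matrix invariants
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      wm <- tryCatch(weight_matrix(r[, , i, j]), error = function(e) {
        stop(sprintf(
          "matrix for subject %d, condition %d is invalid: %s",
          i, j, conditionMessage(e)
        ), call. = FALSE)
      })
      r[, , i, j] <- unclass(wm)
    }
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  if (is.null(condition_ids)) condition_ids <- paste0("C", seq_len(J))
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop("`subject_ids` must be unique and match the number of subjects",
      call. = FALSE
    )
  }
  if (length(condition_ids) != J || anyDuplicated(condition_ids)) {
    stop("`condition_ids` must be unique and match the number of conditions",
      call. = FALSE
    )
  }
  dimnames(r) <- list(labels, labels, subject_ids, condition_ids)
  structure(
    list(
      r = r,
      subject_ids = as.character(subject_ids),
      condition_ids = as.character(condition_ids),
      labels = labels
    ),
    class = "correlation_dataset"
  )
}

#' @export
print.correlation_dataset <- function(x, ...) {
  d <- dim(x$r)
  cat(sprintf(
    "Correlation dataset: %d nodes, %d subjects x %d conditions (%s)\n",
    d[1L], d[3L], d[4L], paste(x$condition_ids, collapse = " < ")
  ))
  invisible(x)
}

#' @export
dim.correlation_dataset <- function(x) dim(x$r)

# Edge-major view of a correlation_dataset: E x n x J array of the
# upper-triangular correlations, edges ordered as edge_pairs().
edge_value_array <- function(data) {
  stopifnot(inherits(data, "correlation_dataset"))
  d <- dim(data$r)
  n_v <- d[1L]
  ep <- edge_pairs(n_v)
  flat <- matrix(data$r, nrow = n_v * n_v)
  idx <- (ep[, 2L] - 1L) * n_v + ep[, 1L]
  array(flat[idx, , drop = FALSE], c(nrow(ep), d[3L], d[4L]))
}

#' Per-node time-averaged signal table
#'
#' Node-level analogue of [correlation_dataset()]: one time-averaged
#' intensity value per region, subject and condition, stored as a complete
#' finite `[N_V, n, J]` array.
#'
#' @param values 3-d numeric array `[node, subject, condition]`.
#' @param subject_ids,condition_ids,labels as in [correlation_dataset()];
#'   `labels` names the nodes/regions.
#' @return an object of class `node_signal_table`.
#' @export
node_signal_table <- function(values, subject_ids = NULL,
                              condition_ids = NULL, labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-d array [node, subject, condition]",
      call. = FALSE
    )
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("node signals must be complete and finite", call. = FALSE)
  }
  d <- dim(values)
  if (is.null(labels)) labels <- dimnames(values)[[1L]]
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(d[2L]))
  if (is.null(condition_ids)) condition_ids <- paste0("C", seq_len(d[3L]))
  if (length(subject_ids) != d[2L] || length(condition_ids) != d[3L]) {
    stop("id lengths must match the array dimensions", call. = FALSE)
  }
  dimnames(values) <- list(labels, subject_ids, condition_ids)
  structure(
    list(
      y = values,
      subject_ids = as.character(subject_ids),
      condition_ids = as.character(condition_ids),
      labels = labels
    ),
    class = "node_signal_table"
  )
}

#' @export
print.node_signal_table <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf(
    "Node signal table: %d nodes, %d subjects x %d conditions\n",
    d[1L], d[2L], d[3L]
  ))
  invisible(x)
}
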