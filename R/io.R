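#' Read / write an association matrix
#'
#' Plain-text square numeric tables, tab- or comma-separated (auto-detected,
#' overridable), with an optional single header row of node labels. On read,
#' the matrix is passed through the [weight_matrix()] invariants: asymmetries
#' up to `1e-8` are repaired silently, up to `1e-4` with a warning, and
#' larger asymmetries are an error. Values are written with 17 significant
#' digits so a write/read round trip reproduces the matrix to machine
#' precision.
#'
#' @param path file path.
#' @param sep field separator; NULL (default) auto-detects tab vs comma.
#' @return `read_matrix` returns a [weight_matrix()].
#' @export
read_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path,
    sep = sep, header = header,
    check.names = FALSE, colClasses = "numeric",
    comment.char = ""
  )
  values <- as.matrix(df)
  if (nrow(values) != ncol(values)) {
    stop(sprintf(
      "matrix in %s is not square: %d rows x %d columns",
      path, nrow(values), ncol(values)
    ), call. = FALSE)
  }
  labels <- if (header) colnames(values) else NULL
  dimnames(values) <- NULL
  weight_matrix(values, labels = labels)
}

#' @rdname read_matrix
#' @param W a [weight_matrix()] (or coercible matrix) to write.
#' @export
write_matrix <- function(W, path, sep = "\t") {
  W <- as_weight_matrix(W)
  lines <- apply(unclass(W), 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = sep)
  })
  labels <- wm_labels(W)
  if (!is.null(labels)) {
    lines <- c(paste(labels, collapse = sep), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a correlation dataset from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `condition_id`, `path`
#' (matrix file, relative paths resolved against the manifest's directory):
#' one row per subject-by-condition cell. The design must be complete --
#' every subject must have a matrix for every condition -- and all matrices
#' must agree in size and node labels. Condition order is the order of first
#' appearance in the manifest, which encodes the experimental gradient.
#'
#' @param path manifest CSV path.
#' @return a [correlation_dataset()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition_id", "path")
  if (!all(need %in% names(man))) {
    stop("manifest needs columns subject_id, condition_id, path",
      call. = FALSE
    )
  }
  if (anyDuplicated(man[, c("subject_id", "condition_id")])) {
    dup <- man[duplicated(man[, c("subject_id", "condition_id")]), ][1L, ]
    stop(sprintf(
      "duplicate manifest row for subject '%s', condition '%s'",
      dup$subject_id, dup$condition_id
    ), call. = FALSE)
  }
  subjects <- unique(man$subject_id)
  conditions <- unique(man$condition_id)
  for (s in subjects) {
    for (cond in conditions) {
      if (!any(man$subject_id == s & man$condition_id == cond)) {
        stop(sprintf(
          "incomplete design: no matrix for subject '%s', condition '%s'",
          s, cond
        ), call. = FALSE)
      }
    }
  }
  base_dir <- dirname(path)
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  ref <- NULL
  arr <- NULL
  for (row in seq_len(nrow(man))) {
    W <- read_matrix(resolve(man$path[row]))
    if (is.null(ref)) {
      ref <- W
      arr <- array(
        NA_real_,
        c(nrow(W), nrow(W), length(subjects), length(conditions))
      )
    } else {
      if (nrow(W) != nrow(ref)) {
        stop(sprintf(
          "matrix %s has %d nodes; expected %d",
          man$path[row], nrow(W), nrow(ref)
        ), call. = FALSE)
      }
      if (!identical(wm_labels(W), wm_labels(ref))) {
        stop(sprintf(
          "node labels in %s differ from those of the first matrix",
          man$path[row]
        ), call. = FALSE)
      }
    }
    i <- match(man$subject_id[row], subjects)
    j <- match(man$condition_id[row], conditions)
    arr[, , i, j] <- unclass(W)
  }
  correlation_dataset(arr,
    subject_ids = subjects, condition_ids = conditions,
    labels = wm_labels(ref)
  )
}

#' Write a correlation dataset (plus optional ground truth) to a directory
#'
#' Writes one matrix file per subject-by-condition cell, a `manifest.csv`
#' pointing at them, and -- when the dataset comes from the synthetic
#' generator -- a `truth.json` describing the planted effects. The directory
#' round-trips through [read_manifest()].
#'
#' @param data a [correlation_dataset()], or the list returned by
#'   [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  truth <- NULL
  if (!inherits(data, "correlation_dataset") && is.list(data) &&
    inherits(data$data, "correlation_dataset")) {
    truth <- data$truth
    data <- data$data
  }
  stopifnot(inherits(data, "correlation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(data$r)
  rows <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (i in seq_len(d[3L])) {
    for (j in seq_len(d[4L])) {
      k <- k + 1L
      fn <- sprintf("%s_%s.tsv", data$subject_ids[i], data$condition_ids[j])
      write_matrix(
        weight_matrix(data$r[, , i, j], labels = data$labels),
        file.path(dir, fn)
      )
      rows[[k]] <- data.frame(
        subject_id = data$subject_ids[i],
        condition_id = data$condition_ids[j],
        path = fn, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(
        edge_effects = truth$edge_effects,
        node_effects = truth$node_effects,
        noise_sd = truth$noise_sd
      ),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(manifest)
}

#' Read / write node signal tables
#'
#' Long-format CSV with columns `subject_id`, `condition_id`, `node`,
#' `value`; the design must be complete (every node for every subject and
#' condition). Condition order is first-appearance order.
#'
#' @param path CSV path.
#' @return `read_node_signals` returns a [node_signal_table()].
#' @export
read_node_signals <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("signal file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition_id", "node", "value")
  if (!all(need %in% names(df))) {
    stop("node signal file needs columns subject_id, condition_id, node, value",
      call. = FALSE
    )
  }
  subjects <- unique(df$subject_id)
  conditions <- unique(df$condition_id)
  nodes <- unique(df$node)
  arr <- array(
    NA_real_,
    c(length(nodes), length(subjects), length(conditions))
  )
  idx <- cbind(
    match(df$node, nodes),
    match(df$subject_id, subjects),
    match(df$condition_id, conditions)
  )
  if (anyDuplicated(idx)) {
    stop("duplicate (subject, condition, node) rows in signal file",
      call. = FALSE
    )
  }
  arr[idx] <- df$value
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "incomplete design: missing value for node '%s', subject '%s', condition '%s'",
      nodes[miss[1L]], subjects[miss[2L]], conditions[miss[3L]]
    ), call. = FALSE)
  }
  node_signal_table(arr,
    subject_ids = subjects, condition_ids = conditions,
    labels = as.character(nodes)
  )
}

#' @rdname read_node_signals
#' @param signals a [node_signal_table()] (or the list returned by
#'   [generate_node_signals()]).
#' @export
write_node_signals <- function(signals, path) {
  if (!inherits(signals, "node_signal_table") && is.list(signals) &&
    inherits(signals$signals, "node_signal_table")) {
    signals <- signals$signals
  }
  stopifnot(inherits(signals, "node_signal_table"))
  d <- dim(signals$y)
  grid <- expand.grid(
    node = seq_len(d[1L]), subject = seq_len(d[2L]),
    condition = seq_len(d[3L])
  )
  labels <- signals$labels
  if (is.null(labels)) labels <- as.character(seq_len(d[1L]))
  df <- data.frame(
    subject_id = signals$subject_ids[grid$subject],
    condition_id = signals$condition_ids[grid$condition],
    node = labels[grid$node],
    value = signals$y[as.matrix(grid)],
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an SPN to GraphML, edge-list TSV, or JSON
#'
#' GraphML output carries node labels (and, if supplied, 2-d layout
#' coordinates) as vertex attributes and the statistic, p, q and sign as
#' edge attributes, so downstream viewers can style the plus/minus
#' components. The edge-list format is a TSV of the included elements with
#' the same statistics; JSON is a run summary (settings, counts, included
#' elements).
#'
#' @param result an `spn_result`.
#' @param path output file path.
#' @param format `"graphml"`, `"edgelist"`, or `"json"`.
#' @param coordinates optional `N_V x 2` matrix of node coordinates for the
#'   GraphML export.
#' @return `path`, invisibly.
#' @export
export_spn <- function(result, path,
                       format = c("graphml", "edgelist", "json"),
                       coordinates = NULL) {
  stopifnot(inherits(result, "spn_result"))
  format <- match.arg(format)
  tab <- result$table
  inc <- tab[tab$included, , drop = FALSE]
  node_kind <- result$kind == "differential-node"
  if (format == "graphml") {
    labels <- result$labels
    if (is.null(labels)) labels <- as.character(seq_len(result$n_vertices))
    g <- if (node_kind) {
      binary_graph(result$n_vertices, labels = labels)
    } else {
      binary_graph(result$n_vertices, as.matrix(inc[, c("i", "j")]),
        labels = labels
      )
    }
    if (!is.null(coordinates)) {
      coordinates <- as.matrix(coordinates)
      if (nrow(coordinates) != result$n_vertices || ncol(coordinates) < 2L) {
        stop("`coordinates` must be an N_V x 2 matrix", call. = FALSE)
      }
      igraph::V(g)$x <- coordinates[, 1L]
      igraph::V(g)$y <- coordinates[, 2L]
    }
    if (node_kind) {
      igraph::V(g)$statistic <- tab$statistic
      igraph::V(g)$q_value <- tab$q_value
      igraph::V(g)$sign <- tab$sign
      igraph::V(g)$included <- tab$included
    } else if (nrow(inc)) {
      igraph::E(g)$statistic <- inc$statistic
      igraph::E(g)$p_value <- inc$p_value
      igraph::E(g)$q_value <- inc$q_value
      igraph::E(g)$sign <- inc$sign
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    cols <- intersect(
      c(
        "node_i", "node_j", "node", "statistic", "p_value", "q_value",
        "sign"
      ),
      names(inc)
    )
    utils::write.table(inc[, cols, drop = FALSE], path,
      sep = "\t",
      quote = FALSE, row.names = FALSE
    )
  } else {
    jsonlite::write_json(
      list(
        kind = result$kind, alpha0 = result$alpha0,
        correction = result$correction, condition = result$condition,
        n_vertices = result$n_vertices,
        n_tested = nrow(tab), n_included = nrow(inc),
        n_plus = sum(inc$sign > 0), n_minus = sum(inc$sign < 0),
        included = inc
      ),
      path,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records the configuration, seed and result counts of an analysis run so
#' it can be re-executed exactly.
#'
#' @param path output JSON path.
#' @param config named list of settings (serialized verbatim).
#' @param counts named list of result counts.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, config, counts = list()) {
  jsonlite::write_json(
    list(
      package = "spnet",
      version = as.character(utils::packageVersion("spnet")),
      config = config,
      counts = counts
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
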