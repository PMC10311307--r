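#' Construct an expression matrix object
#'
#' Container for a cell-by-marker expression table. Row order defines the
#' canonical cell index used by every other function in the package: node
#' indices in neighbour graphs, label vectors and traces all refer to rows
#' of this object in their original order.
#'
#' @param values Numeric matrix, cells in rows, markers in columns.
#' @param cell_ids Character vector of unique cell identifiers (one per row).
#' @param sample_ids Character vector of sample labels (one per row).
#' @param marker_names Character vector of unique marker names (one per
#'   column). Defaults to the column names of `values`.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `cell_ids`, `sample_ids` and `marker_names`.
#' @export
expression_matrix <- function(values, cell_ids, sample_ids,
                              marker_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one cell and one marker")
  }
  if (anyNA(values)) stop("expression values contain missing entries")
  cell_ids <- as.character(cell_ids)
  sample_ids <- as.character(sample_ids)
  if (length(cell_ids) != nrow(values) || length(sample_ids) != nrow(values)) {
    stop("cell_ids and sample_ids must have one entry per row")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                       collapse = ", "))
  }
  if (is.null(marker_names)) marker_names <- paste0("marker_", seq_len(ncol(values)))
  marker_names <- as.character(marker_names)
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  dimnames(values) <- list(NULL, marker_names)
  structure(list(values = values, cell_ids = cell_ids,
                 sample_ids = sample_ids, marker_names = marker_names),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d markers, %d sample(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$sample_ids))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a cell-by-marker expression table from CSV
#'
#' Expects a header row with `cell_id`, `sample_id` and at least one marker
#' column; every other column is parsed as a numeric marker. File row order
#' is preserved and becomes the canonical cell index.
#'
#' @param path Path to a CSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("cell_id", "sample_id")
  if (!all(req %in% names(df))) {
    stop("expression CSV must contain columns: ", paste(req, collapse = ", "))
  }
  marker_cols <- setdiff(names(df), req)
  if (length(marker_cols) == 0L) stop("no marker columns found")
  vals <- matrix(NA_real_, nrow(df), length(marker_cols),
                 dimnames = list(NULL, marker_cols))
  for (j in seq_along(marker_cols)) {
    col <- df[[marker_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   marker_cols[j], bad[1L], col[bad[1L]]))
    }
    if (anyNA(num)) {
      stop(sprintf("missing value in column '%s', row %d",
                   marker_cols[j], which(is.na(num))[1L]))
    }
    vals[, j] <- num
  }
  expression_matrix(vals, df$cell_id, df$sample_id, marker_cols)
}

#' Write an expression matrix to CSV
#'
#' Inverse of [read_expression_csv()]: the written file round-trips through
#' the reader reproducing values exactly (full double precision).
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(cell_id = expr$cell_ids, sample_id = expr$sample_ids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- expr$values
  for (j in seq_len(ncol(vals))) {
    df[[expr$marker_names[j]]] <- sprintf("%.17g", vals[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cell spatial coordinates from CSV
#'
#' @param path CSV with columns `cell_id`, `sample_id`, `x`, `y`
#'   (coordinates in pixels).
#' @return A data.frame of class `cell_locations`.
#' @export
read_locations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "sample_id", "x", "y")
  if (!all(req %in% names(df))) {
    stop("locations CSV must contain columns: ", paste(req, collapse = ", "))
  }
  cell_locations(df$cell_id, df$sample_id, df$x, df$y)
}

#' Construct a cell-locations table
#'
#' @param cell_id,sample_id,x,y Parallel vectors; coordinates in pixels.
#' @return A data.frame of class `cell_locations`.
#' @export
cell_locations <- function(cell_id, sample_id, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("coordinates must be finite")
  df <- data.frame(cell_id = as.character(cell_id),
                   sample_id = as.character(sample_id),
                   x = x, y = y, stringsAsFactors = FALSE)
  class(df) <- c("cell_locations", "data.frame")
  df
}

#' Construct a neighbour graph object
#'
#' The undirected multi-sample cell adjacency graph on which the Markov
#' random field label prior is defined. Samples form disconnected
#' components; node indices refer to rows of the companion expression
#' matrix.
#'
#' @param n_nodes Number of nodes.
#' @param edges Two-column integer matrix of unordered node pairs (1-based).
#' @param sample_of Character vector mapping each node to its sample label.
#' @return An object of class `neighbour_graph` with fields `n_nodes`,
#'   `edges` (canonicalized: u < v, unique, sorted) and `sample_of`.
#' @export
neighbour_graph <- function(n_nodes, edges, sample_of) {
  n_nodes <- as.integer(n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2L)
  sample_of <- as.character(sample_of)
  if (length(sample_of) != n_nodes) stop("sample_of must have one entry per node")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (any(sample_of[edges[, 1L]] != sample_of[edges[, 2L]])) {
      stop("edges may only join nodes within the same sample")
    }
  }
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges, sample_of = sample_of),
            class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("neighbour_graph: %d nodes, %d edges, %d sample(s)\n",
              x$n_nodes, nrow(x$edges), length(unique(x$sample_of))))
  invisible(x)
}

#' Adjacency list of a neighbour graph
#'
#' @param graph A [neighbour_graph()].
#' @return List of integer vectors; element `n` holds the (1-based)
#'   neighbours of node `n`.
#' @export
adjacency_list <- function(graph) {
  stopifnot(inherits(graph, "neighbour_graph"))
  adj <- vector("list", graph$n_nodes)
  for (i in seq_len(graph$n_nodes)) adj[[i]] <- integer(0)
  if (nrow(graph$edges) > 0L) {
    u <- graph$edges[, 1L]; v <- graph$edges[, 2L]
    nb <- split(c(v, u), c(u, v))
    for (key in names(nb)) adj[[as.integer(key)]] <- sort(nb[[key]])
  }
  adj
}

#' Build the neighbour graph from cell locations
#'
#' Cells of the same sample are joined by an edge when their
#' centroid-to-centroid Euclidean distance is strictly below `threshold`
#' (in pixels); ties at the threshold are excluded. Samples are never
#' connected to each other.
#'
#' @param locations A `cell_locations` table whose `cell_id`s match the
#'   companion expression matrix; if `expr` is given, rows are aligned to
#'   its canonical cell order first.
#' @param threshold Positive distance threshold in pixels.
#' @param expr Optional [expression_matrix()] used to fix node order.
#' @return A [neighbour_graph()].
#' @export
build_neighbour_graph <- function(locations, threshold, expr = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number of pixels")
  }
  if (!is.null(expr)) {
    idx <- match(expr$cell_ids, locations$cell_id)
    if (anyNA(idx)) stop("locations missing for some cells in the expression matrix")
    locations <- locations[idx, , drop = FALSE]
  }
  sample_codes <- as.integer(factor(locations$sample_id))
  edges <- cpp_threshold_edges(locations$x, locations$y, sample_codes, threshold)
  neighbour_graph(nrow(locations), edges, locations$sample_id)
}

#' Build a neighbour graph from an explicit edge list
#'
#' Alternative input dialect for upstream pipelines that already computed
#' neighbour relations.
#'
#' @param edge_df Data frame with columns `cell_id_a`, `cell_id_b`,
#'   `sample_id`.
#' @param expr The companion [expression_matrix()] defining node order.
#' @return A [neighbour_graph()].
#' @export
graph_from_edge_list <- function(edge_df, expr) {
  req <- c("cell_id_a", "cell_id_b", "sample_id")
  if (!all(req %in% names(edge_df))) {
    stop("edge list must contain columns: ", paste(req, collapse = ", "))
  }
  a <- match(as.character(edge_df$cell_id_a), expr$cell_ids)
  b <- match(as.character(edge_df$cell_id_b), expr$cell_ids)
  if (anyNA(a) || anyNA(b)) stop("edge list references unknown cell_ids")
  neighbour_graph(length(expr$cell_ids), cbind(a, b), expr$sample_ids)
}

#' Read an edge-list CSV
#'
#' @param path CSV with columns `cell_id_a`, `cell_id_b`, `sample_id`.
#' @param expr The companion [expression_matrix()].
#' @return A [neighbour_graph()].
#' @export
read_edge_list_csv <- function(path, expr) {
  graph_from_edge_list(utils::read.csv(path, stringsAsFactors = FALSE), expr)
}

#' Spatially aware downsampling by breadth-first search
#'
#' Within each sample, a start node is drawn uniformly at random and a
#' breadth-first traversal collects nodes until `target_per_sample` are
#' taken (or the start node's connected component is exhausted). Frontier
#' ties are broken by ascending node index so the traversal is
#' deterministic given the seed. Keeping BFS balls rather than uniform
#' subsets preserves local spatial structure in the retained subgraph.
#'
#' @param graph A [neighbour_graph()].
#' @param target_per_sample Number of nodes to keep per sample.
#' @param seed Integer RNG seed for the start-node draws.
#' @return List with `nodes` (kept node indices, ascending) and `graph`
#'   (the induced subgraph, nodes re-indexed in that order).
#' @export
bfs_downsample <- function(graph, target_per_sample, seed = NULL) {
  stopifnot(inherits(graph, "neighbour_graph"))
  if (graph$n_nodes < 1L) stop("graph is empty")
  if (target_per_sample < 1L) stop("target_per_sample must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_list(graph)
  keep <- integer(0)
  for (s in unique(graph$sample_of)) {
    nodes <- which(graph$sample_of == s)
    start <- nodes[sample.int(length(nodes), 1L)]
    visited <- logical(graph$n_nodes)
    visited[start] <- TRUE
    queue <- start
    got <- start
    while (length(queue) > 0L && length(got) < target_per_sample) {
      n <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[n]]) {  # adjacency lists are sorted: ascending-index ties
        if (!visited[nb]) {
          visited[nb] <- TRUE
          got <- c(got, nb)
          queue <- c(queue, nb)
          if (length(got) >= target_per_sample) break
        }
      }
    }
    keep <- c(keep, got)
  }
  keep <- sort(keep)
  list(nodes = keep, graph = induced_subgraph(graph, keep))
}

#' Induced subgraph on a node subset
#'
#' @param graph A [neighbour_graph()].
#' @param nodes Node indices to keep (re-indexed 1..length(nodes) in the
#'   given order).
#' @return A [neighbour_graph()].
#' @export
induced_subgraph <- function(graph, nodes) {
  nodes <- as.integer(nodes)
  newid <- rep(NA_integer_, graph$n_nodes)
  newid[nodes] <- seq_along(nodes)
  e <- graph$edges
  keep <- !is.na(newid[e[, 1L]]) & !is.na(newid[e[, 2L]])
  neighbour_graph(length(nodes),
                  cbind(newid[e[keep, 1L]], newid[e[keep, 2L]]),
                  graph$sample_of[nodes])
}

#' Inverse hyperbolic sine transform
#'
#' Standard variance-stabilizing normalization for mass cytometry
#' intensities: each value becomes `asinh(value / cofactor)`. The default
#' cofactor of 5 is the usual CyTOF convention.
#'
#' @param expr An [expression_matrix()].
#' @param cofactor Positive scale divisor applied before `asinh`.
#' @return A transformed [expression_matrix()] of the same shape.
#' @export
arcsinh_transform <- function(expr, cofactor = 5) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a positive number")
  }
  expression_matrix(asinh(expr$values / cofactor), expr$cell_ids,
                    expr$sample_ids, expr$marker_names)
}

#' Project expression onto leading principal components
#'
#' Scores on the top principal components of the mean-centred (not scaled)
#' marker matrix, ordered by decreasing explained variance.
#'
#' @param expr An [expression_matrix()].
#' @param n_components Number of components to keep (at most the number of
#'   markers).
#' @return An [expression_matrix()] whose columns `PC1..PCn` are component
#'   scores; explained variances are attached as attribute
#'   `"explained_variance"`.
#' @export
pca_project <- function(expr, n_components) {
  stopifnot(inherits(expr, "expression_matrix"))
  M <- ncol(expr$values)
  if (n_components < 1L || n_components > M) {
    stop("n_components must be between 1 and the number of markers (", M, ")")
  }
  pc <- stats::prcomp(expr$values, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- expression_matrix(scores, expr$cell_ids, expr$sample_ids,
                           paste0("PC", seq_len(n_components)))
  attr(out, "explained_variance") <- pc$sdev[seq_len(n_components)]^2
  out
}
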