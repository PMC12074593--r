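#' Residue contact graph
#'
#' Nodes are residues in chain order; an undirected edge joins residues i
#' and j whenever their C-alpha distance is strictly below the threshold.
#' Edges are stored once as a two-column integer matrix with `i < j`
#' (1-based node indices).
#'
#' @param features numeric L x D matrix of per-residue features.
#' @param edges two-column integer matrix of undirected edges, `i < j`.
#' @param labels integer 0/1 vector of length L.
#' @param node_ids integer residue indices (from the structure file).
#' @param train_mask logical vector of length L; nodes contributing to the
#'   training loss. Defaults to all `TRUE`.
#' @param chain_id character tag(s) recording provenance.
#'
#' @return An object of class `protein_graph`.
#' @export
protein_graph <- function(features, edges, labels, node_ids = seq_len(nrow(features)),
                          train_mask = rep(TRUE, nrow(features)),
                          chain_id = "chain") {
  features <- as.matrix(features)
  n <- nrow(features)
  edges <- normalize_edges(edges, n)
  assert_that(length(labels) == n,
              "label vector length must equal feature row count",
              "bindgraph_shape_error")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0 or 1",
              "bindgraph_label_error")
  assert_that(length(train_mask) == n && is.logical(train_mask),
              "train_mask must be a logical vector matching node count",
              "bindgraph_shape_error")
  assert_that(all(is.finite(features)), "node features must be finite")
  structure(
    list(features = unname(features), edges = edges,
         labels = as.integer(labels), node_ids = as.integer(node_ids),
         train_mask = train_mask, chain_id = chain_id),
    class = "protein_graph")
}

# canonicalize an edge matrix: integer, i < j, unique, no self-edges
normalize_edges <- function(edges, n) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  edges <- matrix(as.integer(edges), ncol = 2L)
  assert_that(all(edges >= 1L & edges <= n), "edge endpoint out of range",
              "bindgraph_shape_error")
  assert_that(all(edges[, 1L] != edges[, 2L]), "self-edges are not allowed",
              "bindgraph_shape_error")
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph> %d nodes, %d edges, %d (%.2f%%) binding, D=%d\n",
              nrow(x$features), nrow(x$edges), sum(x$labels),
              100 * mean(x$labels), ncol(x$features)))
  invisible(x)
}

#' Contact-graph construction parameters
#'
#' @param distance_threshold C-alpha distance cutoff in Angstroms
#'   (default 8). Residue pairs strictly closer than this are connected.
#' @return A `graph_config` list.
#' @export
graph_config <- function(distance_threshold = 8.0) {
  assert_that(is.numeric(distance_threshold) && distance_threshold > 0,
              "distance_threshold must be positive")
  structure(list(distance_threshold = distance_threshold),
            class = "graph_config")
}

#' Build the residue contact graph of a chain
#'
#' Connects residues i != j when `||ca_i - ca_j|| < distance_threshold`
#' (strict less-than). Sequence-adjacent residues get no special treatment:
#' consecutive C-alphas sit ~3.8 Angstroms apart, so they satisfy the
#' distance rule in practice anyway.
#'
#' @param chain a labelled [residue_chain()].
#' @param features numeric matrix with one row per retained residue (see
#'   [embed_sequence()] / [synthetic_features_for_labels()]).
#' @param cfg a [graph_config()].
#' @param train_mask optional logical vector; defaults to all `TRUE`.
#'
#' @return A [protein_graph()] whose node order equals chain order.
#' @export
build_contact_graph <- function(chain, features, cfg = graph_config(),
                                train_mask = NULL) {
  assert_that(inherits(chain, "residue_chain"), "chain must be a residue_chain")
  assert_that(!is.null(chain$label),
              "chain must carry labels (see attach_labels)",
              "bindgraph_label_error")
  features <- as.matrix(features)
  n <- length(chain)
  if (nrow(features) != n)
    stop_bindgraph(sprintf(
      "feature matrix has %d rows but chain has %d residues",
      nrow(features), n), "bindgraph_shape_error")
  assert_that(all(is.finite(chain$ca_xyz)), "coordinates must be finite")
  d <- as.matrix(stats::dist(chain$ca_xyz))
  adj <- d < cfg$distance_threshold
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  protein_graph(features = features, edges = idx, labels = chain$label,
                node_ids = chain$residue_index,
                train_mask = train_mask %||% rep(TRUE, n),
                chain_id = chain$chain_id)
}

#' Merge several protein graphs into one disjoint union
#'
#' Node ids are offset per graph; no edges cross chain boundaries. The
#' offsets are recorded in the result (`attr(, "offsets")`) so the union
#' can be split back with [split_batched_graph()].
#'
#' @param graphs list of [protein_graph()]s sharing the feature dimension.
#' @return A single [protein_graph()] with an `offsets` attribute.
#' @export
batch_graphs <- function(graphs) {
  assert_that(is.list(graphs) && length(graphs) >= 1L,
              "graphs must be a non-empty list")
  dims <- vapply(graphs, function(g) ncol(g$features), integer(1))
  if (length(unique(dims)) != 1L)
    stop_bindgraph(sprintf("feature dimensions differ across graphs: %s",
                           paste(unique(dims), collapse = ", ")),
                   "bindgraph_shape_error")
  sizes <- vapply(graphs, function(g) nrow(g$features), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]$edges
    if (nrow(e) == 0L) return(e)
    e + offsets[[k]]
  }))
  out <- protein_graph(
    features = do.call(rbind, lapply(graphs, `[[`, "features")),
    edges = edges,
    labels = unlist(lapply(graphs, `[[`, "labels")),
    node_ids = unlist(lapply(graphs, `[[`, "node_ids")),
    train_mask = unlist(lapply(graphs, `[[`, "train_mask")),
    chain_id = vapply(graphs, function(g) g$chain_id[[1L]], character(1)))
  attr(out, "offsets") <- stats::setNames(offsets, out$chain_id)
  attr(out, "sizes") <- sizes
  out
}

#' Split a batched graph back into its component graphs
#'
#' Inverts [batch_graphs()] using the recorded offsets.
#'
#' @param batched a graph produced by [batch_graphs()].
#' @return List of [protein_graph()]s in the original order.
#' @export
split_batched_graph <- function(batched) {
  offsets <- attr(batched, "offsets")
  sizes <- attr(batched, "sizes")
  assert_that(!is.null(offsets) && !is.null(sizes),
              "graph was not produced by batch_graphs (no offsets recorded)")
  lapply(seq_along(sizes), function(k) {
    rng <- (offsets[[k]] + 1L):(offsets[[k]] + sizes[[k]])
    e <- batched$edges
    keep <- e[, 1L] >= rng[[1L]] & e[, 1L] <= rng[[length(rng)]]
    protein_graph(
      features = batched$features[rng, , drop = FALSE],
      edges = e[keep, , drop = FALSE] - offsets[[k]],
      labels = batched$labels[rng],
      node_ids = batched$node_ids[rng],
      train_mask = batched$train_mask[rng],
      chain_id = batched$chain_id[[k]])
  })
}

# sparse symmetric 0/1 adjacency of a protein_graph
graph_adjacency <- function(graph) {
  n <- nrow(graph$features)
  e <- graph$edges
  if (nrow(e) == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                 dims = c(n, n)))
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(n, n))
}

# neighbour list of one node (1-based ids)
node_neighbors <- function(graph, node) {
  e <- graph$edges
  sort(unique(c(e[e[, 1L] == node, 2L], e[e[, 2L] == node, 1L])))
}

# neighbour lists for all nodes at once
adjacency_list <- function(graph) {
  n <- nrow(graph$features)
  e <- graph$edges
  ends <- c(e[, 2L], e[, 1L])
  starts <- factor(c(e[, 1L], e[, 2L]), levels = seq_len(n))
  lapply(split(ends, starts), function(v) sort(unique(v)))
}

#' Export a graph's edge list as text
#'
#' Writes one `i j` pair per line using 0-based node indices, the common
#' interchange convention for graph tools.
#'
#' @param graph a [protein_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges - 1L
  writeLines(sprintf("%d %d", e[, 1L], e[, 2L]), path)
  invisible(path)
}
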