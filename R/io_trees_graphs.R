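#' Write a phylogenetic tree to Newick
#'
#' Trees are `ape::phylo` objects; bootstrap supports, when present as
#' `node.label`, are emitted as internal-node labels. The emitted string
#' re-parses to an isomorphic tree with branch lengths preserved.
#'
#' @param tree an `ape::phylo` tree with non-negative branch lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  # a valid phylo object is acyclic/connected by construction; check counts
  n_edge <- nrow(tree$edge)
  n_node <- length(tree$tip.label) + tree$Nnode
  if (n_edge != n_node - 1L) stop("input is not a tree (cycle or disconnected)")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path a Newick file.
#' @return An `ape::phylo` tree; internal-node labels (e.g. bootstrap
#'   supports) are kept in `node.label`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Similarity-graph edge tables
#'
#' An `edge_table` holds an undirected simple graph over sequence identifiers
#' with per-edge scores (\eqn{-\log_{10}} E-values) and per-node attributes
#' (taxon label, cluster-type label). Edges are canonicalised so that
#' `node_a < node_b` lexicographically.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @param nodes data.frame with columns `id`, `taxon`, `cluster_type` (extra
#'   columns are preserved).
#' @return An object of class `edge_table`.
#' @export
edge_table <- function(edges = data.frame(node_a = character(),
                                          node_b = character(),
                                          score = numeric()),
                       nodes = NULL) {
  stopifnot(all(c("node_a", "node_b", "score") %in% names(edges)))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  flip <- edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  if (any(edges$node_a == edges$node_b)) stop("self-loop in edge table")
  if (anyDuplicated(edges[, c("node_a", "node_b")])) stop("duplicate edge")
  if (any(!is.finite(edges$score)) || any(edges$score < 0))
    stop("edge scores must be finite and >= 0")
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$node_a, edges$node_b)))
    nodes <- data.frame(id = ids, taxon = rep(NA_character_, length(ids)),
                        cluster_type = rep(NA_character_, length(ids)),
                        stringsAsFactors = FALSE)
  }
  stopifnot("id" %in% names(nodes))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "edge_table")
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("edge_table: %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

nodes_path <- function(path) {
  sub("(\\.[^./]+)?$", "_nodes\\1", path)
}

#' Write an `edge_table` as Cytoscape-importable TSVs
#'
#' Writes the edge list to `path` and the node attributes to a sidecar file
#' (`<path stem>_nodes.<ext>`), both with deterministic row order.
#'
#' @param graph an [edge_table()].
#' @param path output edge TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  stopifnot(inherits(graph, "edge_table"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$nodes, nodes_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an `edge_table` written by [write_edge_table()]
#'
#' @param path edge TSV path (the node sidecar is located automatically).
#' @return An [edge_table()].
#' @export
read_edge_table <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(node_a = "character",
                                            node_b = "character"))
  np <- nodes_path(path)
  nodes <- if (file.exists(np))
    utils::read.delim(np, stringsAsFactors = FALSE,
                      colClasses = c(id = "character"))
  else NULL
  edge_table(edges, nodes)
}
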