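#' Interrogate a learned or averaged network
#'
#' Queries operate on a directed edge list: either a [dag()] or a data
#' frame with `from`/`to` columns (e.g. the output of
#' [threshold_network()] or [read_edge_table()]), in which case strength
#' and direction columns are carried through where applicable.
#'
#' `markov_blanket()` returns the variables needed to predict a node
#' and its children: its parents, its children, and the other parents
#' of those children.
#'
#' @param edges a [dag()] or a data frame with columns `from`, `to`.
#' @param node a node name.
#' @return `markov_blanket()`: character vector of node names (sorted,
#'   excluding `node`).
#' @export
markov_blanket <- function(edges, node) {
  e <- edge_pairs(edges)
  known <- unique(c(e))
  nodes <- attr(edges, "nodes")
  if (is.null(nodes) && inherits(edges, "mixbn_dag")) nodes <- edges$nodes
  if (!(node %in% c(known, nodes)))
    stop("unknown node: ", node)
  pa <- e[e[, 2] == node, 1]
  ch <- e[e[, 1] == node, 2]
  sp <- e[e[, 2] %in% ch, 1]
  sort(setdiff(unique(c(pa, ch, sp)), node))
}

#' @rdname markov_blanket
#' @param node_set character vector of node names.
#' @return `subnetwork()`: the induced subgraph — all edges with both
#'   endpoints in `node_set` (no path contraction), same columns as the
#'   input edge list.
#' @export
subnetwork <- function(edges, node_set) {
  if (inherits(edges, "mixbn_dag")) {
    stopifnot(all(node_set %in% edges$nodes))
    e <- edges(edges)
    keep <- e[, 1] %in% node_set & e[, 2] %in% node_set
    return(dag(intersect(edges$nodes, node_set), e[keep, , drop = FALSE]))
  }
  keep <- edges$from %in% node_set & edges$to %in% node_set
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname markov_blanket
#' @return `degree_summary()`: list with `mean_out_per_parent` (edges
#'   per node having at least one outgoing edge) and `mean_in_per_child`
#'   (edges per node having at least one incoming edge).
#' @export
degree_summary <- function(edges) {
  e <- edge_pairs(edges)
  if (!nrow(e)) stop("degree_summary needs at least one edge")
  list(mean_out_per_parent = nrow(e) / length(unique(e[, 1])),
       mean_in_per_child = nrow(e) / length(unique(e[, 2])))
}

#' Percentage of edges between variable classes
#'
#' Row-normalised percentages of directed edges by (from-class,
#' to-class).  Allele-score nodes are excluded from the matrix by
#' default — their edges are structural (anchor to target) rather than
#' learned relationships among measured variables — and reported
#' separately in the `"allele_score_edges"` attribute.
#'
#' @param edges a [dag()] or edge-list data frame.
#' @param meta a [variable_meta()] table assigning every endpoint a
#'   class.
#' @param exclude_classes classes dropped from the matrix (default
#'   `"allele_score"`).
#' @return A k x k matrix of row percentages (rows with no outgoing
#'   edges are `NA`); attribute `"n_edges"` holds the count matrix.
#' @export
class_edge_matrix <- function(edges, meta, exclude_classes = "allele_score") {
  e <- edge_pairs(edges)
  cls <- stats::setNames(meta$vclass, meta$name)
  if (any(!c(e) %in% names(cls)))
    stop("edge endpoint(s) missing from metadata")
  classes <- setdiff(c("clinical", "metabolite", "protein", "expression",
                       "allele_score"), exclude_classes)
  classes <- intersect(classes, unique(meta$vclass))
  fc <- cls[e[, 1]]; tc <- cls[e[, 2]]
  keep <- fc %in% classes & tc %in% classes
  counts <- table(factor(fc[keep], classes), factor(tc[keep], classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(from = classes, to = classes))
  pct <- 100 * counts / rowSums(counts)
  pct[rowSums(counts) == 0, ] <- NA_real_
  attr(pct, "n_edges") <- counts
  attr(pct, "allele_score_edges") <-
    e[!keep, , drop = FALSE]
  pct
}

#' Structural Hamming distance
#'
#' Number of edge insertions, deletions and reversals needed to turn
#' one DAG into another over the same node set: skeleton differences
#' count one each, and a shared skeleton edge with opposite orientation
#' counts one reversal.
#'
#' @param true_dag,learned [dag()] objects over the same nodes.
#' @return Integer distance.
#' @export
shd <- function(true_dag, learned) {
  if (!setequal(true_dag$nodes, learned$nodes))
    stop("shd requires identical node sets")
  A <- true_dag$A
  Bm <- learned$A[true_dag$nodes, true_dag$nodes]
  skel_a <- A | t(A)
  skel_b <- Bm | t(Bm)
  diff_skel <- sum((skel_a != skel_b)[upper.tri(skel_a)])
  shared <- skel_a & skel_b
  reversed <- sum((A & t(Bm) & shared)[upper.tri(shared) | lower.tri(shared)])
  as.integer(diff_skel + reversed)
}

# Normalise edge input to a 2-column character matrix.
edge_pairs <- function(edges) {
  if (inherits(edges, "mixbn_dag")) return(edges(edges))
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  cbind(from = as.character(edges$from), to = as.character(edges$to))
}
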