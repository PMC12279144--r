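#' Directed graphs over named nodes
#'
#' A light container for the directed (acyclic) graphs that structure
#' search, averaging and querying operate on.  Construction checks
#' endpoints and self-edges but not acyclicity, so that [is_acyclic()]
#' can be asked of any edge set; operations that require a DAG
#' (topological order, scoring, search) reject cyclic input.
#'
#' @param nodes character vector of node names (unique).
#' @param edges edges as a 2-column matrix/data frame of (parent, child)
#'   names, or `NULL` for the empty graph.
#' @return An object of class `mixbn_dag` holding the node names and a
#'   logical adjacency matrix `A` (`A[i, j]` is the edge i -> j).
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' is_acyclic(g)
#' topological_order(g)
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as_edge_matrix(edges)
    unknown <- setdiff(c(edges), nodes)
    if (length(unknown))
      stop("edge endpoint(s) not declared as nodes: ",
           paste(unique(unknown), collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    A[edges] <- TRUE
  }
  structure(list(nodes = nodes, A = A), class = "mixbn_dag")
}

# Coerce data frame / matrix / vector input to a 2-column character matrix.
as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  edges <- matrix(as.character(edges), ncol = 2)
  colnames(edges) <- c("from", "to")
  edges
}

#' @rdname dag
#' @param x a `mixbn_dag`.
#' @export
edges <- function(x) {
  idx <- which(x$A, arr.ind = TRUE)
  e <- cbind(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' @rdname dag
#' @export
n_edges <- function(x) sum(x$A)

#' @rdname dag
#' @param node a node name.
#' @export
parents <- function(x, node) x$nodes[x$A[, node]]

#' @rdname dag
#' @export
children <- function(x, node) x$nodes[x$A[node, ]]

#' @export
print.mixbn_dag <- function(x, ...) {
  cat(sprintf("mixbn_dag: %d nodes, %d edges\n", length(x$nodes), n_edges(x)))
  invisible(x)
}

#' Acyclicity test
#'
#' Kahn peeling: repeatedly remove nodes with no remaining parents; the
#' graph is acyclic iff all nodes are removed.
#'
#' @param x a [dag()].
#' @return `TRUE` iff the edge set contains no directed cycle.
#' @export
is_acyclic <- function(x) {
  A <- x$A
  indeg <- colSums(A)
  alive <- rep(TRUE, length(indeg))
  repeat {
    free <- which(alive & indeg == 0)
    if (!length(free)) break
    alive[free] <- FALSE
    for (i in free) indeg <- indeg - A[i, ]
    A[free, ] <- FALSE
  }
  !any(alive)
}

#' Topological ordering
#'
#' Every parent precedes all of its children.  Ties (several nodes
#' simultaneously parentless) are broken by lexicographic node name so
#' the output is reproducible.
#'
#' @param x an acyclic [dag()].
#' @return Character vector of node names in topological order.
#' @export
topological_order <- function(x) {
  A <- x$A
  indeg <- colSums(A)
  alive <- rep(TRUE, length(indeg))
  names(alive) <- x$nodes
  out <- character(0)
  while (any(alive)) {
    free <- x$nodes[alive & indeg == 0]
    if (!length(free)) stop("graph is cyclic: no topological order exists")
    nxt <- sort(free)[1]
    out <- c(out, nxt)
    alive[nxt] <- FALSE
    indeg <- indeg - A[nxt, ]
  }
  out
}

# TRUE if a directed path from `from` to `to` exists (integer node
# indices; used to veto cycle-creating moves: adding u -> v is illegal
# iff v already reaches u).
has_path <- function(A, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(ncol(A))
  seen[from] <- TRUE
  stack <- from
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nxt <- which(A[i, ] & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  FALSE
}
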