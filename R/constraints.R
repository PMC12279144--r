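#' Edge and role constraints for structure search
#'
#' Constraints mirror those used when fitting networks to cohort data:
#' required and forbidden directed edges, `parent_only` nodes that may
#' not receive any incoming edge (genetic allele scores, which make
#' causal sense only as parents), and `no_parents` nodes (e.g. sex).
#' A typing rule is enforced automatically at search time rather than
#' stored per-edge: a discrete child may not have a continuous parent.
#'
#' @param required,forbidden 2-column matrices/data frames of directed
#'   (parent, child) name pairs, or `NULL`.
#' @param parent_only,no_parents character vectors of node names.
#' @param meta optional [variable_meta()] table; when supplied, required
#'   edges are checked against the typing rule at construction.
#' @return An object of class `mixbn_constraints`.
#' @export
constraint_set <- function(required = NULL, forbidden = NULL,
                           parent_only = character(0),
                           no_parents = character(0), meta = NULL) {
  required <- if (is.null(required) || !NROW(required))
    matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  else as_edge_matrix(required)
  forbidden <- if (is.null(forbidden) || !NROW(forbidden))
    matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  else as_edge_matrix(forbidden)
  key <- function(e) paste(e[, 1], e[, 2], sep = "\r")
  if (length(intersect(key(required), key(forbidden))))
    stop("an edge cannot be both required and forbidden")
  if (any(required[, 2] %in% parent_only))
    stop("required edge into a parent_only node")
  if (any(required[, 2] %in% no_parents))
    stop("required edge into a no_parents node")
  if (!is.null(meta)) {
    disc <- meta$name[is_discrete(meta)]
    cont <- setdiff(meta$name, disc)
    bad <- required[, 2] %in% disc & required[, 1] %in% cont
    if (any(bad))
      stop("required edge gives a discrete child a continuous parent")
  }
  structure(list(required = required, forbidden = forbidden,
                 parent_only = unique(as.character(parent_only)),
                 no_parents = unique(as.character(no_parents))),
            class = "mixbn_constraints")
}

#' @export
print.mixbn_constraints <- function(x, ...) {
  cat(sprintf("mixbn_constraints: %d required, %d forbidden, %d parent-only, %d no-parents\n",
              nrow(x$required), nrow(x$forbidden),
              length(x$parent_only), length(x$no_parents)))
  invisible(x)
}

#' Check a graph against a constraint set
#'
#' Returns one row per violation: missing required edges, present
#' forbidden edges, edges into `parent_only` or `no_parents` nodes, and
#' continuous parents of discrete children.
#'
#' @param dag a [dag()].
#' @param constraints a [constraint_set()].
#' @param meta a [variable_meta()] table covering the dag's nodes.
#' @return Data frame with columns `from`, `to`, `rule`; zero rows iff
#'   the graph satisfies every constraint.
#' @export
check_constraints <- function(dag, constraints, meta) {
  stopifnot(inherits(dag, "mixbn_dag"))
  if (!all(dag$nodes %in% meta$name))
    stop("dag nodes missing from metadata: ",
         paste(setdiff(dag$nodes, meta$name), collapse = ", "))
  e <- edges(dag)
  viol <- list()
  add <- function(from, to, rule) {
    if (length(from))
      viol[[length(viol) + 1]] <<- data.frame(from = from, to = to, rule = rule,
                                              stringsAsFactors = FALSE)
  }
  req <- constraints$required
  if (nrow(req)) {
    present <- dag$A[req]
    add(req[!present, 1], req[!present, 2], "required_missing")
  }
  if (nrow(e)) {
    key <- paste(e[, 1], e[, 2], sep = "\r")
    fkey <- paste(constraints$forbidden[, 1], constraints$forbidden[, 2], sep = "\r")
    hit <- key %in% fkey
    add(e[hit, 1], e[hit, 2], "forbidden_edge")
    hit <- e[, 2] %in% constraints$parent_only
    add(e[hit, 1], e[hit, 2], "edge_into_parent_only")
    hit <- e[, 2] %in% constraints$no_parents
    add(e[hit, 1], e[hit, 2], "edge_into_no_parents")
    disc <- meta$name[is_discrete(meta)]
    cont <- setdiff(meta$name, disc)
    hit <- e[, 2] %in% disc & e[, 1] %in% cont
    add(e[hit, 1], e[hit, 2], "continuous_parent_of_discrete")
  }
  if (!length(viol))
    return(data.frame(from = character(0), to = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

#' Constraints anchoring allele scores to their target variables
#'
#' Each allele score is built for exactly one target variable, and the
#' only edge it may take part in is the one towards that target: no
#' edges into an allele score, and no edges from it to anything else.
#' Presence of the anchor edge itself is left to the search unless
#' `require_anchor_edge = TRUE`.
#'
#' @param meta a [variable_meta()] table.
#' @param anchors named character vector mapping allele-score node name
#'   to its target variable name.
#' @param require_anchor_edge force the score -> target edge into every
#'   searched graph (default `FALSE`: permitted, not required).
#' @return A [constraint_set()].
#' @export
allele_score_constraints <- function(meta, anchors,
                                     require_anchor_edge = FALSE) {
  stopifnot(!is.null(names(anchors)), all(names(anchors) %in% meta$name),
            all(anchors %in% meta$name))
  as.nodes <- names(anchors)
  forb <- do.call(rbind, lapply(as.nodes, function(a) {
    others <- setdiff(meta$name, c(a, anchors[[a]]))
    cbind(from = rep(a, length(others)), to = others)
  }))
  required <- if (require_anchor_edge)
    cbind(from = as.nodes, to = unname(anchors)) else NULL
  constraint_set(required = required, forbidden = forb,
                 parent_only = as.nodes, meta = meta)
}

#' Read and write constraint files
#'
#' One rule per line, whitespace/tab-delimited with a header:
#' `kind from to`, where `kind` is `require`, `forbid`, `parent_only`
#' or `no_parents`; role rules use only the `from` field.
#'
#' @param path file path.
#' @param meta optional metadata passed to [constraint_set()].
#' @return `read_constraints()` returns a [constraint_set()].
#' @export
read_constraints <- function(path, meta = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", fill = TRUE,
                           na.strings = NULL)
  stopifnot(all(c("kind", "from") %in% names(raw)))
  if (is.null(raw$to)) raw$to <- ""
  pick <- function(kind) raw[raw$kind == kind, , drop = FALSE]
  req <- pick("require"); forb <- pick("forbid")
  constraint_set(
    required = if (nrow(req)) req[c("from", "to")] else NULL,
    forbidden = if (nrow(forb)) forb[c("from", "to")] else NULL,
    parent_only = pick("parent_only")$from,
    no_parents = pick("no_parents")$from,
    meta = meta)
}

#' @rdname read_constraints
#' @param constraints a [constraint_set()].
#' @export
write_constraints <- function(constraints, path) {
  rows <- rbind(
    if (nrow(constraints$required))
      data.frame(kind = "require", from = constraints$required[, 1],
                 to = constraints$required[, 2]),
    if (nrow(constraints$forbidden))
      data.frame(kind = "forbid", from = constraints$forbidden[, 1],
                 to = constraints$forbidden[, 2]),
    if (length(constraints$parent_only))
      data.frame(kind = "parent_only", from = constraints$parent_only, to = ""),
    if (length(constraints$no_parents))
      data.frame(kind = "no_parents", from = constraints$no_parents, to = ""))
  if (is.null(rows))
    rows <- data.frame(kind = character(0), from = character(0),
                       to = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
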