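#' Search parameters for hill-climbing
#'
#' @param max_iterations maximum number of accepted moves (>= 1).
#' @param random_restarts number of additional climbs from random
#'   constraint-respecting starting graphs (default 0: a single
#'   deterministic climb from the empty graph plus required edges).
#' @param seed integer seed controlling restarts (and nothing else; the
#'   base climb is deterministic).
#' @param move_set subset of `c("add", "delete", "reverse")`.
#' @param eps convergence guard: a move must improve the score by more
#'   than `eps` (absolute) to be accepted.
#' @return A list of class `mixbn_search_params`.
#' @export
search_params <- function(max_iterations = 500L, random_restarts = 0L,
                          seed = 1L, move_set = c("add", "delete", "reverse"),
                          eps = 1e-9) {
  stopifnot(max_iterations >= 1, random_restarts >= 0,
            all(move_set %in% c("add", "delete", "reverse")))
  structure(list(max_iterations = as.integer(max_iterations),
                 random_restarts = as.integer(random_restarts),
                 seed = as.integer(seed), move_set = move_set, eps = eps),
            class = "mixbn_search_params")
}

# Logical p x p matrix of edges that may never be present: forbidden
# list, edges into parent_only / no_parents nodes, continuous parents
# of discrete children, self-edges.
blocked_matrix <- function(nodes, constraints, meta) {
  p <- length(nodes)
  B <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(constraints$forbidden)) {
    keep <- constraints$forbidden[, 1] %in% nodes &
      constraints$forbidden[, 2] %in% nodes
    B[constraints$forbidden[keep, , drop = FALSE]] <- TRUE
  }
  B[, intersect(constraints$parent_only, nodes)] <- TRUE
  B[, intersect(constraints$no_parents, nodes)] <- TRUE
  disc <- intersect(meta$name[is_discrete(meta)], nodes)
  cont <- setdiff(nodes, disc)
  B[cont, disc] <- TRUE
  diag(B) <- TRUE
  B
}

#' Enumerate legal single-edge moves
#'
#' All additions, deletions and reversals that keep the graph acyclic
#' and respect the constraint set and the discrete/continuous typing
#' rule.  Required edges cannot be deleted or reversed.
#'
#' @param dag a [dag()].
#' @param constraints a [constraint_set()] (or `NULL` for none).
#' @param meta a [variable_meta()] table covering the nodes.
#' @param move_set subset of `c("add", "delete", "reverse")`.
#' @return Data frame with columns `kind`, `from`, `to`, sorted by
#'   (child, parent, kind).
#' @export
legal_moves <- function(dag, constraints = NULL, meta,
                        move_set = c("add", "delete", "reverse")) {
  if (is.null(constraints)) constraints <- constraint_set()
  nodes <- dag$nodes
  A <- dag$A
  B <- blocked_matrix(nodes, constraints, meta)
  R <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(constraints$required)) {
    keep <- constraints$required[, 1] %in% nodes &
      constraints$required[, 2] %in% nodes
    R[constraints$required[keep, , drop = FALSE]] <- TRUE
  }
  mv <- enumerate_moves(A, B, R, move_set)
  out <- data.frame(kind = mv$kind, from = nodes[mv$u], to = nodes[mv$v],
                    stringsAsFactors = FALSE)
  out[order(out$to, out$from, out$kind), , drop = FALSE]
}

# Boolean transitive closure (reach[i, j] = directed path i ~> j).
reachability <- function(A) {
  Rm <- A
  repeat {
    Rn <- Rm | (Rm %*% A > 0)
    if (identical(Rn, Rm)) return(Rm)
    Rm <- Rn
  }
}

# Shared move enumeration on index matrices; returns parallel vectors
# kind/u/v where the move concerns the directed edge u -> v as present
# (delete/reverse) or proposed (add).
enumerate_moves <- function(A, B, R, move_set) {
  kind <- character(0); u <- integer(0); v <- integer(0)
  reach <- reachability(A)
  if ("add" %in% move_set) {
    cand <- which(!A & !B & !t(reach), arr.ind = TRUE)  # v must not reach u
    if (nrow(cand)) {
      kind <- c(kind, rep("add", nrow(cand)))
      u <- c(u, cand[, 1]); v <- c(v, cand[, 2])
    }
  }
  if ("delete" %in% move_set) {
    cand <- which(A & !R, arr.ind = TRUE)
    if (nrow(cand)) {
      kind <- c(kind, rep("delete", nrow(cand)))
      u <- c(u, cand[, 1]); v <- c(v, cand[, 2])
    }
  }
  if ("reverse" %in% move_set) {
    cand <- which(A & !R, arr.ind = TRUE)
    if (nrow(cand)) {
      ok <- vapply(seq_len(nrow(cand)), function(i) {
        ui <- cand[i, 1]; vi <- cand[i, 2]
        if (B[vi, ui]) return(FALSE)
        A2 <- A; A2[ui, vi] <- FALSE       # reversal is legal iff no
        !has_path(A2, ui, vi)              # second u ~> v path remains
      }, logical(1))
      kind <- c(kind, rep("reverse", sum(ok)))
      u <- c(u, cand[ok, 1]); v <- c(v, cand[ok, 2])
    }
  }
  list(kind = kind, u = u, v = v)
}

#' Greedy hill-climbing structure search
#'
#' Steepest-descent hill climbing on the BIC network score: starting
#' from the empty graph plus any required edges, repeatedly apply the
#' single legal add/delete/reverse move that most improves (lowers) the
#' score, stopping at a local optimum.  Ties are broken by lexicographic
#' (child, parent, move-kind), so the result is deterministic; with
#' `random_restarts > 0` additional climbs start from random
#' constraint-respecting graphs drawn from the seed and the best final
#' score wins.
#'
#' @param data a complete [mixbn_data()] object.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param params a [search_params()] object.
#' @return The learned [dag()], with the final score in attribute
#'   `"score"`.
#' @export
best_fit_network <- function(data, constraints = NULL,
                             params = search_params()) {
  if (is.null(constraints)) constraints <- constraint_set()
  meta <- data$meta
  nodes <- meta$name
  p <- length(nodes)
  B <- blocked_matrix(nodes, constraints, meta)
  R <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(constraints$required)) R[constraints$required] <- TRUE
  if (any(R & B)) stop("a required edge is forbidden by role or typing rules")
  start <- dag(nodes, which_edges(R, nodes))
  if (!is_acyclic(start)) stop("required edges form a directed cycle")
  scorer <- make_scorer(data)
  best <- climb(start$A, B, R, nodes, scorer, params)
  if (params$random_restarts > 0) {
    set.seed(params$seed)
    for (r in seq_len(params$random_restarts)) {
      A0 <- random_start(R, B, nodes)
      cand <- climb(A0, B, R, nodes, scorer, params)
      if (attr(cand, "score") < attr(best, "score")) best <- cand
    }
  }
  out <- dag(nodes, which_edges(best, nodes))
  attr(out, "score") <- attr(best, "score")
  out
}

which_edges <- function(A, nodes) {
  idx <- which(A, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(nodes[idx[, 1]], nodes[idx[, 2]])
}

# One steepest-descent climb from adjacency matrix A.  Per-move score
# deltas are cached in matrices and only the families touched by the
# last accepted move are re-evaluated; legality (acyclicity) is
# re-derived each iteration from the reachability closure.
climb <- function(A, B, R, nodes, scorer, params) {
  p <- length(nodes)
  use <- c(add = "add" %in% params$move_set,
           delete = "delete" %in% params$move_set,
           reverse = "reverse" %in% params$move_set)
  delta_of <- function(new, old)
    if (is.infinite(new) && is.infinite(old)) Inf else new - old
  fam <- vapply(seq_len(p), function(j) scorer$bic_idx(j, which(A[, j])),
                numeric(1))
  # Dadd[u, v]: delta of adding u -> v given v's current parents;
  # Ddel[u, v]: delta of deleting the present edge u -> v.
  Dadd <- matrix(NA_real_, p, p)
  Ddel <- matrix(NA_real_, p, p)
  dirty <- seq_len(p)
  for (iter in seq_len(params$max_iterations)) {
    for (v in dirty) {
      pav <- which(A[, v])
      for (u in seq_len(p)) {
        if (u == v) next
        if (A[u, v]) {
          Ddel[u, v] <- delta_of(scorer$bic_idx(v, pav[pav != u]), fam[v])
          Dadd[u, v] <- NA_real_
        } else if (!B[u, v]) {
          Dadd[u, v] <- delta_of(scorer$bic_idx(v, c(pav, u)), fam[v])
          Ddel[u, v] <- NA_real_
        }
      }
    }
    reach <- reachability(A)
    ku <- integer(0); kv <- integer(0); kk <- character(0); kd <- numeric(0)
    if (use["add"]) {
      idx <- which(!A & !B & !t(reach), arr.ind = TRUE)
      if (nrow(idx)) {
        ku <- c(ku, idx[, 1]); kv <- c(kv, idx[, 2])
        kk <- c(kk, rep("add", nrow(idx))); kd <- c(kd, Dadd[idx])
      }
    }
    if (use["delete"]) {
      idx <- which(A & !R, arr.ind = TRUE)
      if (nrow(idx)) {
        ku <- c(ku, idx[, 1]); kv <- c(kv, idx[, 2])
        kk <- c(kk, rep("delete", nrow(idx))); kd <- c(kd, Ddel[idx])
      }
    }
    if (use["reverse"]) {
      idx <- which(A & !R & !t(B), arr.ind = TRUE)
      if (nrow(idx)) {
        ok <- vapply(seq_len(nrow(idx)), function(i) {
          A2 <- A; A2[idx[i, 1], idx[i, 2]] <- FALSE
          !has_path(A2, idx[i, 1], idx[i, 2])
        }, logical(1))
        idx <- idx[ok, , drop = FALSE]
      }
      if (nrow(idx)) {
        # reversal = delete u -> v plus add v -> u (u's family gains v)
        ku <- c(ku, idx[, 1]); kv <- c(kv, idx[, 2])
        kk <- c(kk, rep("reverse", nrow(idx)))
        kd <- c(kd, Ddel[idx] + Dadd[idx[, c(2, 1), drop = FALSE]])
      }
    }
    if (!length(ku)) break
    ord <- order(nodes[kv], nodes[ku], kk)
    kd <- kd[ord]; ku <- ku[ord]; kv <- kv[ord]; kk <- kk[ord]
    best <- which.min(kd)                  # first index attaining the min
    if (!length(best) || !(kd[best] < -params$eps)) break
    ui <- ku[best]; vi <- kv[best]
    if (kk[best] == "add") {
      A[ui, vi] <- TRUE
      fam[vi] <- scorer$bic_idx(vi, which(A[, vi]))
      dirty <- vi
    } else if (kk[best] == "delete") {
      A[ui, vi] <- FALSE
      fam[vi] <- scorer$bic_idx(vi, which(A[, vi]))
      dirty <- vi
    } else {
      A[ui, vi] <- FALSE; A[vi, ui] <- TRUE
      fam[vi] <- scorer$bic_idx(vi, which(A[, vi]))
      fam[ui] <- scorer$bic_idx(ui, which(A[, ui]))
      dirty <- c(ui, vi)
    }
  }
  attr(A, "score") <- sum(fam)
  A
}

# Random constraint-respecting acyclic start for restarts: a random
# node order, edges added forward along it with probability 0.5.  Dense
# starts matter: they let restarts escape the orientation traps (e.g.
# around collider structures) that greedy moves from sparse graphs
# cannot undo.
random_start <- function(R, B, nodes) {
  p <- length(nodes)
  A <- R
  ord <- sample.int(p)
  for (a in seq_len(p - 1)) for (b in seq(a + 1, p)) {
    ui <- ord[a]; vi <- ord[b]
    if (!A[ui, vi] && !B[ui, vi] && stats::runif(1) < 0.5 &&
        !has_path(A, vi, ui))
      A[ui, vi] <- TRUE
  }
  A
}
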