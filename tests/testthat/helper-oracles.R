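# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive re-implementations straight from the
# definitions, kept free of any package internals they are checking.

# brute-force cycle detection: depth-first search from every node
oracle_has_cycle <- function(nodes, edge_mat) {
  adj <- lapply(nodes, function(v)
    edge_mat[edge_mat[, 1] == v, 2])
  names(adj) <- nodes
  visit <- function(v, trail) {
    if (v %in% trail) return(TRUE)
    for (w in adj[[v]]) if (visit(w, c(trail, v))) return(TRUE)
    FALSE
  }
  any(vapply(nodes, function(v) visit(v, character(0)), logical(1)))
}

# Markov blanket straight from the definition
oracle_blanket <- function(edge_mat, node) {
  pa <- edge_mat[edge_mat[, 2] == node, 1]
  ch <- edge_mat[edge_mat[, 1] == node, 2]
  sp <- unlist(lapply(ch, function(c) edge_mat[edge_mat[, 2] == c, 1]))
  sort(setdiff(unique(c(pa, ch, sp)), node))
}

# Gaussian-regression family log-likelihood via lm(), with the same
# variance floor contract the scorer documents
oracle_gauss_family <- function(y, X = NULL, n_total = length(y)) {
  df <- data.frame(y = y)
  form <- if (is.null(X) || ncol(X) == 0) y ~ 1 else {
    for (k in seq_len(ncol(X))) df[[paste0("x", k)]] <- X[, k]
    stats::as.formula(paste("y ~", paste(paste0("x", seq_len(ncol(X))),
                                         collapse = " + ")))
  }
  fit <- stats::lm(form, df)
  m <- length(y)
  rss <- sum(stats::residuals(fit)^2)
  s2 <- max(rss / m, 1e-12 * stats::var(y), 1e-300)
  ll <- -m / 2 * log(2 * pi * s2) - rss / (2 * s2)
  k <- length(stats::coef(fit)) + 1
  list(loglik = ll, n_params = k)
}

# multinomial family log-likelihood from counts
oracle_multinomial_ll <- function(codes, n_levels) {
  counts <- tabulate(codes, n_levels)
  nz <- counts[counts > 0]
  sum(nz * log(nz / length(codes)))
}

# grid search for the CDF level minimising the L1 threshold objective
oracle_threshold_level <- function(strengths, grid = seq(0, 1, by = 1e-4)) {
  xs <- seq(0, 1 - 1e-6, length.out = 2000)
  Fx <- vapply(xs, function(x) mean(strengths <= x), numeric(1))
  obj <- vapply(grid, function(c) mean(abs(Fx - c)), numeric(1))
  grid[which.min(obj)]
}

# all 25 DAGs on three named nodes
all_dags_3 <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  arcs <- rbind(pairs, pairs[, 2:1])
  out <- list()
  for (mask in 0:63) {
    sel <- as.logical(intToBits(mask))[1:6]
    g <- tryCatch(dag(nodes, arcs[sel, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(g) && is_acyclic(g)) out[[length(out) + 1]] <- g
  }
  out
}

# random edge set over p nodes (cyclic allowed)
random_edge_set <- function(p, n_edges) {
  nodes <- sprintf("n%02d", seq_len(p))
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  e <- unique(cbind(from[keep], to[keep]))
  list(nodes = nodes, edges = e)
}

# random DAG: forward edges along a random node order
random_dag <- function(p, edge_prob = 0.3) {
  nodes <- sprintf("n%02d", seq_len(p))
  ord <- sample(nodes)
  e <- NULL
  if (p > 1)
    for (b in 2:p) for (a in seq_len(b - 1))
      if (stats::runif(1) < edge_prob) e <- rbind(e, c(ord[a], ord[b]))
  dag(nodes, e)
}

# all-continuous metadata + data for quick scoring fixtures
cont_meta <- function(names, vclass = "metabolite")
  variable_meta(names, rep("continuous", length(names)),
                rep(vclass, length(names)))

cont_data <- function(df, vclass = "metabolite")
  mixbn_data(df, cont_meta(names(df), vclass))

# linear-chain model X1 -> X2 -> ... with given coefficients
chain_data <- function(n, betas, seed, sd = 1) {
  set.seed(seed)
  p <- length(betas) + 1
  x <- matrix(0, n, p)
  x[, 1] <- stats::rnorm(n)
  for (j in 2:p) x[, j] <- betas[j - 1] * x[, j - 1] + stats::rnorm(n, 0, sd)
  df <- as.data.frame(x)
  names(df) <- sprintf("V%d", seq_len(p))
  cont_data(df)
}

# strength of the undirected pair (a, b) in an average network
pair_strength <- function(avg, a, b) {
  hit <- (avg$from == a & avg$to == b) | (avg$from == b & avg$to == a)
  if (any(hit)) avg$strength[hit][1] else 0
}

# direction value for orientation a -> b (NA if the pair never appears)
pair_direction <- function(avg, a, b) {
  if (any(hit <- avg$from == a & avg$to == b)) return(avg$direction[hit][1])
  if (any(hit <- avg$from == b & avg$to == a)) return(1 - avg$direction[hit][1])
  NA_real_
}

# count of true edges scoring strength > thr in an average network
detected_true_edges <- function(avg, true_dag, thr = 0.5) {
  te <- edges(true_dag)
  if (!nrow(te)) return(0L)
  sum(vapply(seq_len(nrow(te)), function(i)
    pair_strength(avg, te[i, 1], te[i, 2]) > thr, logical(1)))
}
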