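#' Bootstrap model averaging: edge strength and direction
#'
#' The data are resampled with replacement (whole individuals) and the
#' best-fit network re-learned on every replicate.  For each unordered
#' node pair, the *strength* is the proportion of replicates in which an
#' edge appears between the two nodes (either direction), and the
#' *direction* is the proportion of those replicates in which it points
#' a given way.  These are often loosely called posterior probabilities
#' of the edge existing / of its orientation, though they are bootstrap
#' proportions, not samples from a posterior.
#'
#' Reproducibility: one master seed spawns an independent seed per
#' replicate, so replicates can be computed in any order (or in
#' parallel) with identical results.
#'
#' @param data a complete [mixbn_data()] object.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param params a [search_params()] object for the per-replicate fits.
#' @param n_replicates number of bootstrap replicates (the analyses this
#'   package is designed for use 1000).
#' @param seed master seed for the resampling.
#' @return An object of class `mixbn_avgnet`: a data frame with one row
#'   per unordered pair seen in any replicate, columns `from`, `to`,
#'   `strength`, `direction` (the proportion for the `from -> to`
#'   orientation, always >= 0.5; exact 0.5 ties are oriented towards the
#'   lexicographically larger name), plus attributes `n_replicates` and
#'   `seed`.
#' @export
bootstrap_average <- function(data, constraints = NULL,
                              params = search_params(),
                              n_replicates = 1000L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  n <- n_samples(data)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  fits <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    rows <- sample.int(n, n, replace = TRUE)
    fits[[r]] <- best_fit_network(subset_rows(data, rows), constraints, params)
  }
  avg <- tally_replicates(fits, nodes = data$meta$name)
  attr(avg, "seed") <- seed
  avg
}

#' @rdname bootstrap_average
#' @param dags list of [dag()] objects (one best-fit network per
#'   replicate) to tally directly; exposed so the counting step can be
#'   exercised and audited independently of the search.
#' @param nodes node name vector (defaults to the first dag's nodes).
#' @export
tally_replicates <- function(dags, nodes = NULL) {
  stopifnot(length(dags) >= 1)
  if (is.null(nodes)) nodes <- dags[[1]]$nodes
  p <- length(nodes)
  count <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (g in dags) {
    stopifnot(setequal(g$nodes, nodes))
    count[g$nodes, g$nodes] <- count[g$nodes, g$nodes] + g$A
  }
  R <- length(dags)
  idx <- which(count + t(count) > 0 & upper.tri(count), arr.ind = TRUE)
  if (nrow(idx)) {
    a <- nodes[idx[, 1]]; b <- nodes[idx[, 2]]
    n_ab <- count[idx]; n_ba <- t(count)[idx]
    either <- n_ab + n_ba
    # orient towards the majority; an exact tie points at the
    # lexicographically larger of the two names
    fwd <- n_ab > n_ba | (n_ab == n_ba & a < b)
    out <- data.frame(from = ifelse(fwd, a, b), to = ifelse(fwd, b, a),
                      strength = either / R,
                      direction = pmax(n_ab, n_ba) / either,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction = numeric(0))
  }
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_replicates = R, nodes = nodes,
            class = c("mixbn_avgnet", "data.frame"))
}

#' Analytic significance threshold for edge strengths
#'
#' An ideal average network would have strengths of exactly 0 (noise
#' edges) and 1 (real edges); its strength CDF is flat at some level
#' `c` on `[0, 1)`.  The level `c` minimising the L1 distance between
#' that ideal CDF and the empirical CDF of the observed strengths is
#' found, and the threshold
#' returned is the corresponding `c`-quantile of the strengths.  Edges
#' with strength strictly above the threshold are deemed significant.
#'
#' @param strengths numeric vector of strengths in `[0, 1]`.
#' @return The threshold, with the estimated CDF level in attribute
#'   `"level"`.
#' @export
estimate_strength_threshold <- function(strengths) {
  if (!length(strengths)) stop("no strengths supplied")
  stopifnot(all(strengths >= 0 & strengths <= 1))
  s <- sort(strengths)
  # empirical CDF is a step function; the L1 objective
  # integral |F(x) - c| dx on [0, 1) is piecewise linear in c and is
  # minimised at a length-weighted median of the step heights
  xs <- unique(c(0, s[s < 1], 1))
  heights <- vapply(xs[-length(xs)], function(x) mean(s <= x), numeric(1))
  widths <- diff(xs)
  o <- order(heights)
  heights <- heights[o]; widths <- widths[o]
  cum <- cumsum(widths)
  level <- heights[which(cum >= sum(widths) / 2)[1]]
  # level 0 means no noise mass below the true edges: nothing should be
  # cut, so the threshold sits below every positive strength
  thr <- if (level == 0) 0
    else as.numeric(stats::quantile(s, probs = level, names = FALSE))
  attr(thr, "level") <- level
  thr
}

#' Threshold an average network into a directed edge list
#'
#' Pairs with strength strictly greater than `strength_thr` are kept
#' and oriented in their majority direction.  When `direction_thr`
#' exceeds 0.5, pairs whose majority direction falls below it
#' (strictly) are also dropped; a pair at exactly the threshold is
#' retained.  Exact 0.5 direction ties are flagged as unresolved.
#'
#' @param avg a `mixbn_avgnet` from [bootstrap_average()] /
#'   [tally_replicates()].
#' @param strength_thr strength threshold in `[0, 1]`; defaults to the
#'   analytic estimate from [estimate_strength_threshold()].
#' @param direction_thr direction threshold in `[0, 1]` (default 0.5,
#'   i.e. no extra filtering beyond majority orientation).
#' @return Data frame of class `mixbn_edges` with columns `from`, `to`,
#'   `strength`, `direction`, `direction_unresolved`; the thresholds
#'   used are stored in attributes.
#' @export
threshold_network <- function(avg, strength_thr = NULL, direction_thr = 0.5) {
  stopifnot(inherits(avg, "mixbn_avgnet"))
  if (is.null(strength_thr))
    strength_thr <- estimate_strength_threshold(avg$strength)
  stopifnot(strength_thr >= 0, strength_thr <= 1,
            direction_thr >= 0, direction_thr <= 1)
  keep <- avg$strength > strength_thr
  if (direction_thr > 0.5)
    keep <- keep & avg$direction >= direction_thr
  out <- as.data.frame(avg)[keep, , drop = FALSE]
  out$direction_unresolved <- out$direction == 0.5
  rownames(out) <- NULL
  structure(out, strength_thr = as.numeric(strength_thr),
            direction_thr = direction_thr, nodes = attr(avg, "nodes"),
            class = c("mixbn_edges", "data.frame"))
}

#' Edge-table files
#'
#' CSV with columns `from`, `to`, `strength`, `direction`, sorted by
#' (from, to) — the same layout as published average-network edge
#' tables, so such tables can be read back for querying.
#'
#' @param edges a `mixbn_avgnet`, `mixbn_edges` or compatible data
#'   frame.
#' @param path file path.
#' @return `read_edge_table()` returns a data frame with those four
#'   columns (extra columns are preserved).
#' @export
write_edge_table <- function(edges, path) {
  stopifnot(all(c("from", "to", "strength", "direction") %in% names(edges)))
  out <- as.data.frame(edges)[c("from", "to", "strength", "direction")]
  out <- out[order(out$from, out$to), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "strength", "direction") %in% names(out)))
  out
}
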