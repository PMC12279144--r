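#' Conditional linear-Gaussian BIC scoring
#'
#' The network score is the sum over nodes of a family score: each
#' continuous node is modelled as a Gaussian linear regression on its
#' continuous parents, fitted separately within every observed
#' configuration of its discrete parents; each discrete node is
#' multinomial within every observed configuration of its (necessarily
#' discrete) parents.  The score is the BIC on the natural-log scale,
#'
#'   BIC = -2 logL + k log(n),
#'
#' a penalised negative log-likelihood: lower is better.  Parameters are
#' counted only for parent configurations actually observed in the data
#' (unobserved cells contribute neither likelihood nor parameters), and
#' a residual-variance floor of `max(1e-12 * var(child), 1e-300)` keeps
#' degenerate (perfect-fit) families finite.
#'
#' `family_loglik()` returns the maximised log-likelihood and parameter
#' count for one family; `family_score()` additionally reports the BIC;
#' `network_score()` sums family BICs over a DAG.  A family whose MLE is
#' undefined (some observed configuration has fewer observations than
#' regression coefficients) is flagged invalid and scores `+Inf`.
#'
#' @param node child variable name.
#' @param parents character vector of parent variable names.
#' @param data a complete [mixbn_data()] object.
#' @return `family_loglik()`: list with `loglik`, `n_params`, `valid`.
#'   `family_score()`: list with additionally `node`, `parents`,
#'   `n_obs` and `bic`.  `network_score()`: a single number (`+Inf` if
#'   any family is invalid).
#' @examples
#' meta <- variable_meta(c("x", "y"), rep("continuous", 2),
#'                       rep("clinical", 2))
#' d <- mixbn_data(data.frame(x = rnorm(50), y = rnorm(50)), meta)
#' family_score("y", "x", d)
#' @export
family_loglik <- function(node, parents, data) {
  sc <- make_scorer(data)
  fam <- sc$family(node, parents)
  list(loglik = fam$loglik, n_params = fam$n_params, valid = fam$valid)
}

#' @rdname family_loglik
#' @export
family_score <- function(node, parents, data) {
  sc <- make_scorer(data)
  fam <- sc$family(node, parents)
  list(node = node, parents = parents, loglik = fam$loglik,
       n_params = fam$n_params, n_obs = n_samples(data), bic = fam$bic,
       valid = fam$valid)
}

#' @rdname family_loglik
#' @param dag an acyclic [dag()] over the data's variables.
#' @export
network_score <- function(dag, data) {
  stopifnot(inherits(dag, "mixbn_dag"))
  if (!is_acyclic(dag)) stop("network_score requires an acyclic graph")
  sc <- make_scorer(data)
  total <- 0
  for (v in dag$nodes) {
    b <- sc$bic(v, parents(dag, v))
    if (!is.finite(b)) return(Inf)
    total <- total + b
  }
  total
}

#' Family-score evaluator with caching
#'
#' Precomputes the Gram matrix of the data once and serves family
#' scores keyed by (node, sorted parent set).  The cache is private to
#' the returned object, so a new scorer must be made whenever the data
#' change (e.g. per bootstrap replicate); cached values are by
#' construction identical to uncached ones.
#'
#' @param data a complete [mixbn_data()] object.
#' @return A list of functions: `family(node, parents)` returning the
#'   full family record, and `bic(node, parents)` returning just the
#'   BIC value.
#' @export
make_scorer <- function(data) {
  if (!is_complete(data))
    stop("scoring requires complete data; impute first")
  x <- data$x
  n <- nrow(x)
  meta <- data$meta
  disc <- is_discrete(meta)
  names(disc) <- meta$name
  nlev <- vapply(seq_len(nrow(meta)), function(j)
    if (disc[j]) length(meta$levels[[j]]) else 0L, integer(1))
  names(nlev) <- meta$name
  # Gram matrix of [1, data]; regressions on continuous parents with no
  # discrete parents reduce to solves on its submatrices.
  M <- cbind(`(intercept)` = 1, x)
  G <- crossprod(M)
  cmeans <- colMeans(x)
  cvars <- (diag(G)[-1] - n * cmeans^2) / max(n - 1, 1)
  var_floor <- function(j) max(1e-12 * cvars[j], 1e-300)
  cache <- new.env(hash = TRUE, parent = emptyenv())

  gauss_ll <- function(rss, m, floor) {
    s2 <- max(rss / m, floor)
    -m / 2 * log(2 * pi * s2) - rss / (2 * s2)
  }
  # residual sum of squares of y ~ 1 + X, Gram fast path with QR fallback
  rss_full <- function(j, cp) {
    idx <- c(1L, cp + 1L)
    S <- G[idx, idx, drop = FALSE]
    xty <- G[idx, j + 1L]
    b <- tryCatch(solve(S, xty), error = function(e) NULL)
    if (is.null(b)) {
      q <- qr(M[, idx, drop = FALSE])
      return(sum(qr.resid(q, x[, j])^2))
    }
    max(G[j + 1L, j + 1L] - sum(b * xty), 0)
  }
  rss_rows <- function(j, cp, rows) {
    X <- M[rows, c(1L, cp + 1L), drop = FALSE]
    y <- x[rows, j]
    q <- qr(X)
    sum(qr.resid(q, y)^2)
  }

  compute <- function(jname, pnames) {
    j <- match(jname, meta$name)
    pj <- match(pnames, meta$name)
    if (anyNA(c(j, pj))) stop("unknown variable name in family")
    dp <- pj[disc[pj]]
    cp <- pj[!disc[pj]]
    invalid <- list(loglik = -Inf, n_params = 1L, bic = Inf, valid = FALSE)
    if (length(dp)) {
      cfg <- rep(0, n)
      for (d in dp) cfg <- cfg * nlev[d] + (x[, d] - 1)
      groups <- split.default(seq_len(n), cfg)
    } else groups <- NULL
    if (disc[j]) {
      if (length(cp)) return(invalid)     # CLG typing: no continuous parents
      L <- nlev[j]
      ll <- 0
      if (is.null(groups)) {
        counts <- tabulate(x[, j], L)
        nz <- counts[counts > 0]
        ll <- sum(nz * log(nz / n))
        k <- (L - 1)
      } else {
        for (rows in groups) {
          counts <- tabulate(x[rows, j], L)
          nz <- counts[counts > 0]
          ll <- ll + sum(nz * log(nz / length(rows)))
        }
        k <- (L - 1) * length(groups)
      }
    } else {
      floor <- var_floor(j)
      p1 <- length(cp) + 1L                 # intercept + slopes
      if (is.null(groups)) {
        if (n < p1) return(invalid)
        ll <- gauss_ll(rss_full(j, cp), n, floor)
        k <- p1 + 1L                        # + variance
      } else {
        ll <- 0
        for (rows in groups) {
          m <- length(rows)
          if (m < p1) return(invalid)
          ll <- ll + gauss_ll(rss_rows(j, cp, rows), m, floor)
        }
        k <- (p1 + 1L) * length(groups)
      }
    }
    list(loglik = as.numeric(ll), n_params = as.integer(k),
         bic = as.numeric(-2 * ll + k * log(n)), valid = TRUE)
  }

  family_idx <- function(j, pa) {
    key <- paste(j, paste(sort.int(pa, method = "radix"), collapse = ","),
                 sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- compute(meta$name[j], meta$name[pa])
    assign(key, val, envir = cache)
    val
  }
  family <- function(node, parents)
    family_idx(match(node, meta$name), match(parents, meta$name))
  list(family = family,
       bic = function(node, parents) family(node, parents)$bic,
       bic_idx = function(j, pa) family_idx(j, pa)$bic,
       n_obs = n)
}
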