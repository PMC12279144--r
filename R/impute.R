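#' Imputation parameters
#'
#' @param seed integer seed for the random fill (and for any fallback
#'   random draws).
#' @param discrete_mismatch_cost distance contribution of one unequal
#'   discrete value (default 1; continuous contributions are squared
#'   z-score differences, so this is in standard-deviation units).
#' @param fallback what to do when no eligible donor exists:
#'   `"drop_sparsest_nearby"` drops the nearby variable with the most
#'   missing data and retries, falling back to a random draw from the
#'   variable's observed values once the nearby set is empty;
#'   `"global_random"` draws randomly straight away.
#' @param iterate re-run the donor pass until the filled values
#'   stabilise; default `FALSE` (a single pass, the intended use).
#' @return A list of class `mixbn_impute_params`.
#' @export
imputation_params <- function(seed = 1L, discrete_mismatch_cost = 1,
                              fallback = c("drop_sparsest_nearby",
                                           "global_random"),
                              iterate = FALSE) {
  stopifnot(discrete_mismatch_cost >= 0)
  structure(list(seed = as.integer(seed),
                 discrete_mismatch_cost = discrete_mismatch_cost,
                 fallback = match.arg(fallback), iterate = iterate),
            class = "mixbn_impute_params")
}

#' Random fill of missing values
#'
#' Every missing cell is replaced with a value sampled uniformly with
#' replacement from that variable's non-missing values.  Used to build
#' the provisional complete dataset on which the initial network is
#' fitted.
#'
#' @param data a [mixbn_data()] object (every variable must have at
#'   least one observed value).
#' @param seed integer seed; the fill is deterministic given it.
#' @return A complete `mixbn_data`; observed cells are unchanged.
#' @export
random_fill <- function(data, seed = 1L) {
  if (is_complete(data)) return(data)
  set.seed(seed)
  x <- data$x
  for (j in seq_len(ncol(x))) {
    miss <- data$missing[, j]
    if (!any(miss)) next
    obs <- x[!miss, j]
    x[miss, j] <- obs[sample.int(length(obs), sum(miss), replace = TRUE)]
  }
  with_values(data, x)
}

#' Variables informing a nearest-neighbour search
#'
#' The variables adjacent (in either direction — edge orientation is
#' ignored) to the missing variable in the initial network, restricted
#' to those observed for the index individual.
#'
#' @param initial_dag a [dag()] over the data's variables.
#' @param index row index of the individual being imputed.
#' @param missing_var name of the variable to impute.
#' @param data the original [mixbn_data()] (with its missingness mask).
#' @return Character vector of variable names (possibly empty).
#' @export
nearby_variables <- function(initial_dag, index, missing_var, data) {
  nb <- unique(c(parents(initial_dag, missing_var),
                 children(initial_dag, missing_var)))
  nb[!data$missing[index, nb]]
}

#' Nearest-neighbour donor selection
#'
#' Distance between the index individual and each candidate donor over
#' the nearby variables: squared differences of z-scored continuous
#' values (mean/SD from each variable's observed values) plus the
#' squared `discrete_mismatch_cost` per unequal discrete value, square
#' rooted.  Candidates must have observed values for every nearby
#' variable and for the missing variable itself.  Ties go to the
#' smallest row index.
#'
#' @param index row index of the individual being imputed.
#' @param missing_var variable to impute.
#' @param nearby_vars character vector from [nearby_variables()].
#' @param data the original [mixbn_data()].
#' @param params an [imputation_params()] object.
#' @return The donor's row index, with the distance in attribute
#'   `"distance"`; `NA` if no eligible donor exists.
#' @export
nearest_neighbour <- function(index, missing_var, nearby_vars, data,
                              params = imputation_params()) {
  cand <- which(!data$missing[, missing_var] &
                  rowSums(data$missing[, nearby_vars, drop = FALSE]) == 0)
  cand <- cand[cand != index]
  if (!length(cand)) return(NA_integer_)
  disc <- is_discrete(data$meta)
  names(disc) <- data$meta$name
  d2 <- numeric(length(cand))
  for (v in nearby_vars) {
    if (disc[v]) {
      d2 <- d2 + params$discrete_mismatch_cost^2 *
        (data$x[cand, v] != data$x[index, v])
    } else {
      obs <- data$x[!data$missing[, v], v]
      s <- stats::sd(obs)
      if (!is.finite(s) || s == 0) s <- 1
      d2 <- d2 + ((data$x[cand, v] - data$x[index, v]) / s)^2
    }
  }
  best <- which.min(d2)                    # first minimum = smallest index
  structure(cand[best], distance = sqrt(d2[best]))
}

#' Network-guided nearest-neighbour imputation
#'
#' The two-stage scheme: (1) missing values are filled by random
#' sampling from each variable's observed values and a best-fit network
#' is learned on the filled data; (2) for each individual with missing
#' data and each of its missing variables in turn, the variables
#' adjacent to the missing variable in that initial network (and
#' observed for the individual) define a distance, and the nearest
#' individual observed for those variables and the missing one donates
#' its observed value.  Each missing variable gets its own donor; the
#' goal is a completed dataset that supports network learning, not
#' minimal per-cell error.
#'
#' @param data a [mixbn_data()] with missing values.
#' @param constraints a [constraint_set()] or `NULL`, passed to the
#'   initial network fit.
#' @param search_params a [search_params()] for the initial fit.
#' @param params an [imputation_params()].
#' @return A complete `mixbn_data`; observed cells are bit-identical to
#'   the input.  The initial network is attached as attribute
#'   `"initial_dag"` and the donor log (one row per imputed cell:
#'   `sample`, `variable`, `donor`, `method`) as attribute
#'   `"donor_log"`.
#' @export
impute <- function(data, constraints = NULL,
                   search_params = mixbn::search_params(),
                   params = imputation_params()) {
  if (is_complete(data)) {
    g0 <- best_fit_network(data, constraints, search_params)
    attr(data, "initial_dag") <- g0
    attr(data, "donor_log") <- data.frame(sample = character(0),
                                          variable = character(0),
                                          donor = character(0),
                                          method = character(0))
    return(data)
  }
  filled <- random_fill(data, params$seed)
  g0 <- best_fit_network(filled, constraints, search_params)
  x <- filled$x
  log <- list()
  miss_per_var <- colSums(data$missing)
  todo <- which(rowSums(data$missing) > 0)
  for (i in todo) {
    for (v in data$meta$name[data$missing[i, ]]) {
      nb <- if (params$fallback == "global_random") character(0)
        else nearby_variables(g0, i, v, data)
      donor <- NA_integer_
      repeat {
        if (!length(nb)) break
        donor <- nearest_neighbour(i, v, nb, data, params)
        if (!is.na(donor)) break
        # no donor observed for this nearby set: drop its sparsest
        # member and retry with the remainder
        nb <- nb[-which.max(miss_per_var[nb])]
      }
      if (!is.na(donor)) {
        x[i, v] <- data$x[donor, v]
        method <- "nearest_neighbour"
        donor_id <- data$sample_ids[donor]
      } else {
        obs <- data$x[!data$missing[, v], v]
        x[i, v] <- obs[sample.int(length(obs), 1)]
        method <- "random"
        donor_id <- NA_character_
      }
      log[[length(log) + 1]] <- data.frame(sample = data$sample_ids[i],
                                           variable = v, donor = donor_id,
                                           method = method,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- with_values(data, x)
  if (params$iterate) {
    # optional extra passes: re-learn the network on the completed data
    # and redo the donor step until the filled cells stop changing
    for (pass in 1:10) {
      g0 <- best_fit_network(out, constraints, search_params)
      prev <- out$x
      x <- out$x
      for (i in todo) for (v in data$meta$name[data$missing[i, ]]) {
        nb <- nearby_variables(g0, i, v, data)
        donor <- if (length(nb)) nearest_neighbour(i, v, nb, data, params)
          else NA_integer_
        if (!is.na(donor)) x[i, v] <- data$x[donor, v]
      }
      out <- with_values(out, x)
      if (identical(prev, out$x)) break
    }
  }
  attr(out, "initial_dag") <- g0
  attr(out, "donor_log") <- do.call(rbind, c(log, make.row.names = FALSE))
  out
}
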