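#' Simulate a ground-truth mixed network
#'
#' Draws a random conditional linear-Gaussian network whose variables
#' fall into the classes of a multi-omics cohort (clinical, metabolite,
#' protein, expression, allele score).  Edges between measured
#' variables prefer same-class pairs (class assortativity, the dominant
#' pattern in such data), discrete nodes never get continuous parents,
#' and every allele score is a root with exactly one child — its target
#' variable — anchored by a simulated SNP set.
#'
#' @param n_per_class named counts for classes `clinical`, `metabolite`,
#'   `protein`, `expression`, `allele_score` (missing entries are 0).
#' @param max_in_degree cap on the number of parents per node.
#' @param edge_density marginal probability that an ordered candidate
#'   pair becomes an edge (before assortativity reweighting).
#' @param effect_range range of absolute regression coefficients; signs
#'   are random.
#' @param prob_same_class share of edge probability given to same-class
#'   pairs (default 0.8, mirroring the diagonal dominance seen in
#'   cohort-scale class-edge tables).
#' @param n_discrete number of clinical variables made discrete (2-3
#'   levels each); the rest are continuous.
#' @param n_snps_per_score SNPs underlying each allele score.
#' @param residual_sd residual standard deviation of continuous nodes.
#' @param seed integer seed; the model is reproducible given it.
#' @return An object of class `mixbn_model`: list with `dag`, `meta`,
#'   `parameters` (per-node CLG parameters), `snp_effects` (per
#'   allele score: SNP ids, minor-allele frequencies, weights, map) and
#'   `seed`.
#' @export
simulate_model <- function(n_per_class = c(clinical = 5, metabolite = 5,
                                           protein = 5, expression = 5,
                                           allele_score = 3),
                           max_in_degree = 4L, edge_density = 0.1,
                           effect_range = c(0.5, 1.5),
                           prob_same_class = 0.8, n_discrete = 2L,
                           n_snps_per_score = 10L, residual_sd = 1,
                           seed = 1L) {
  classes <- c("clinical", "metabolite", "protein", "expression",
               "allele_score")
  counts <- stats::setNames(rep(0L, 5), classes)
  counts[names(n_per_class)] <- as.integer(n_per_class)
  stopifnot(all(counts >= 0), max_in_degree >= 1, edge_density >= 0)
  set.seed(seed)
  mk <- function(prefix, k) if (k) sprintf("%s%02d", prefix, seq_len(k))
    else character(0)
  nm <- list(clinical = mk("clin", counts["clinical"]),
             metabolite = mk("met", counts["metabolite"]),
             protein = mk("pro", counts["protein"]),
             expression = mk("expr", counts["expression"]))
  measured <- unlist(nm, use.names = FALSE)
  vclass <- rep(names(nm), lengths(nm))
  n_discrete <- min(n_discrete, counts["clinical"])
  dtype <- rep("continuous", length(measured))
  levels <- vector("list", length(measured))
  if (n_discrete > 0) {
    disc.idx <- seq_len(n_discrete)        # leading clinical variables
    dtype[disc.idx] <- "discrete"
    lev.sizes <- rep(c(2L, 3L), length.out = n_discrete)
    levels[disc.idx] <- lapply(lev.sizes, function(L) LETTERS[seq_len(L)])
  }
  # allele scores anchor to molecular targets first, then continuous
  # clinical ones
  eligible <- c(nm$metabolite, nm$protein, nm$expression,
                setdiff(nm$clinical, measured[dtype == "discrete"]))
  kAS <- counts["allele_score"]
  if (kAS > length(eligible))
    stop("more allele scores requested than eligible target variables")
  targets <- eligible[seq_len(kAS)]
  as.names <- if (kAS > 0) paste0("AS_", targets) else character(0)
  meta <- variable_meta(c(measured, as.names),
                        c(dtype, rep("continuous", kAS)),
                        c(vclass, rep("allele_score", kAS)),
                        c(levels, vector("list", kAS)))
  # random DAG over measured nodes: edges forward along a random order
  ord <- sample(measured)
  cls <- stats::setNames(vclass, measured)
  is.disc <- stats::setNames(dtype == "discrete", measured)
  p_same <- min(1, 2 * edge_density * prob_same_class)
  p_diff <- min(1, 2 * edge_density * (1 - prob_same_class))
  edge_list <- list()
  indeg <- stats::setNames(integer(length(measured)), measured)
  for (b in seq_along(ord)[-1]) for (a in seq_len(b - 1)) {
    u <- ord[a]; v <- ord[b]
    if (is.disc[v] && !is.disc[u]) next
    if (indeg[v] >= max_in_degree) next
    pr <- if (cls[u] == cls[v]) p_same else p_diff
    if (stats::runif(1) < pr) {
      edge_list[[length(edge_list) + 1]] <- c(u, v)
      indeg[v] <- indeg[v] + 1L
    }
  }
  edge_mat <- if (length(edge_list)) do.call(rbind, edge_list) else NULL
  edge_mat <- rbind(edge_mat, cbind(as.names, targets))
  g <- dag(meta$name, edge_mat)
  # CLG parameters, in a fixed draw order (node by node)
  nlev <- stats::setNames(vapply(meta$levels, length, integer(1)), meta$name)
  draw_effect <- function(k) sample(c(-1, 1), k, replace = TRUE) *
    stats::runif(k, effect_range[1], effect_range[2])
  parameters <- list()
  for (v in meta$name) {
    pa <- parents(g, v)
    dp <- pa[is_discrete(meta)[match(pa, meta$name)]]
    cp <- setdiff(pa, dp)
    n_cfg <- if (length(dp)) prod(nlev[dp]) else 1L
    if (is_discrete(meta)[match(v, meta$name)]) {
      # rotate a common base distribution across parent configurations
      # so discrete -> discrete edges carry real dependence
      base <- stats::rgamma(nlev[v], shape = 5) + 0.5
      cpt <- vapply(seq_len(n_cfg), function(cf)
        base[(seq_len(nlev[v]) + cf - 2) %% nlev[v] + 1], numeric(nlev[v]))
      cpt <- matrix(cpt, nrow = nlev[v])
      cpt <- sweep(cpt, 2, colSums(cpt), "/")
      parameters[[v]] <- list(type = "discrete", parents_discrete = dp,
                              cpt = cpt)
    } else {
      # per-configuration intercepts on an equally spaced grid scaled by
      # a drawn effect, so discrete parents shift the mean by at least
      # the lower end of effect_range between adjacent configurations
      intercepts <- if (n_cfg > 1)
        draw_effect(1) * (seq_len(n_cfg) - (n_cfg + 1) / 2) else 0
      coef <- if (length(cp)) stats::setNames(draw_effect(length(cp)), cp)
        else stats::setNames(numeric(0), character(0))
      parameters[[v]] <- list(type = "continuous", parents_discrete = dp,
                              parents_continuous = cp,
                              intercepts = intercepts, coef = coef,
                              sd = residual_sd)
    }
  }
  snp_effects <- list()
  for (i in seq_along(as.names)) {
    a <- as.names[i]
    maf <- stats::runif(n_snps_per_score, 0.1, 0.5)
    w <- stats::runif(n_snps_per_score, 0.2, 0.8)
    snp_effects[[a]] <- list(
      target = targets[i],
      snp_ids = sprintf("%s_snp%02d", a, seq_len(n_snps_per_score)),
      maf = maf, weights = w, chromosome = i,
      position = 1e6 + (seq_len(n_snps_per_score) - 1) * 1e4)
  }
  structure(list(dag = g, meta = meta, parameters = parameters,
                 snp_effects = snp_effects, seed = seed),
            class = "mixbn_model")
}

#' Hand-specified ground-truth models
#'
#' Assembles a `mixbn_model` from explicit parts, for simulation
#' studies that need a known structure rather than a random draw.
#' Validates the CLG rules: acyclic graph, no continuous parents of
#' discrete nodes, allele scores as roots with exactly one child, and
#' parameter sets consistent with each node's parents.
#'
#' @param dag a [dag()] over `meta$name`.
#' @param meta a [variable_meta()] table.
#' @param parameters named list, one entry per node: continuous nodes
#'   `list(type = "continuous", parents_discrete, parents_continuous,
#'   intercepts, coef, sd)`; discrete nodes `list(type = "discrete",
#'   parents_discrete, cpt)` with `cpt` levels x configurations.
#' @param snp_effects named list per allele-score node:
#'   `list(target, snp_ids, maf, weights, chromosome, position)`.
#' @return A `mixbn_model`.
#' @export
clg_model <- function(dag, meta, parameters, snp_effects = list()) {
  validate_meta(meta)
  stopifnot(setequal(dag$nodes, meta$name), is_acyclic(dag))
  disc <- meta$name[is_discrete(meta)]
  for (v in meta$name) {
    if (meta$vclass[match(v, meta$name)] == "allele_score") next
    pa <- parents(dag, v)
    par <- parameters[[v]]
    if (is.null(par)) stop("no parameters for node ", v)
    if (v %in% disc) {
      if (any(!pa %in% disc))
        stop("discrete node ", v, " has continuous parent(s)")
      stopifnot(identical(par$type, "discrete"),
                setequal(par$parents_discrete, pa))
    } else if (!(meta$vclass[match(v, meta$name)] == "allele_score")) {
      stopifnot(identical(par$type, "continuous"),
                setequal(c(par$parents_discrete, par$parents_continuous), pa))
    }
  }
  as.nodes <- meta$name[meta$vclass == "allele_score"]
  if (!setequal(as.nodes, names(snp_effects)))
    stop("snp_effects must have one entry per allele-score node")
  for (a in names(snp_effects)) {
    se <- snp_effects[[a]]
    stopifnot(length(parents(dag, a)) == 0,
              identical(children(dag, a), se$target),
              length(se$maf) == length(se$snp_ids),
              length(se$weights) == length(se$snp_ids))
  }
  structure(list(dag = dag, meta = meta, parameters = parameters,
                 snp_effects = snp_effects, seed = NA_integer_),
            class = "mixbn_model")
}

#' @export
print.mixbn_model <- function(x, ...) {
  cat(sprintf("mixbn_model: %d nodes (%d allele scores), %d edges\n",
              length(x$dag$nodes), length(x$snp_effects), n_edges(x$dag)))
  invisible(x)
}

#' Simulate SNP dosage matrices
#'
#' Dosages are Binomial(2, MAF) per SNP; with `ld_r2 > 0`, each SNP
#' copies the previous SNP's genotype with probability `sqrt(ld_r2)`
#' (first-order block structure giving adjacent-pair squared
#' correlations near `ld_r2` when MAFs are similar).
#'
#' @param n number of individuals.
#' @param maf vector of minor-allele frequencies.
#' @param ld_r2 target adjacent-pair squared correlation (0 = none).
#' @param snp_ids,chromosome,position optional map fields.
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, maf, ld_r2 = 0, snp_ids = NULL,
                               chromosome = NULL, position = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(maf)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(m))
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  if (is.null(position)) position <- 1e6 + (seq_len(m) - 1) * 1e4
  D <- matrix(0, n, m)
  copy_p <- sqrt(ld_r2)
  for (j in seq_len(m)) {
    fresh <- stats::rbinom(n, 2, maf[j])
    if (j > 1 && copy_p > 0 && chromosome[j] == chromosome[j - 1]) {
      take <- stats::runif(n) < copy_p
      D[, j] <- ifelse(take, D[, j - 1], fresh)
    } else D[, j] <- fresh
  }
  genotype_matrix(D, snp_ids, chromosome, position)
}

#' Sample a dataset from a ground-truth model
#'
#' Ancestral sampling in topological order: SNP dosages first, allele
#' scores as standardised weighted dosage sums, then each measured node
#' from its conditional distribution given its sampled parents.
#'
#' @param model a [simulate_model()] object.
#' @param n number of individuals.
#' @param seed integer seed.
#' @param ld_r2 LD between adjacent SNPs within each score's block.
#' @return List with `data` (a complete [mixbn_data()]) and `genotypes`
#'   (a [genotype_matrix()], or `NULL` when the model has no allele
#'   scores).
#' @export
simulate_dataset <- function(model, n, seed = 1L, ld_r2 = 0) {
  stopifnot(inherits(model, "mixbn_model"), n >= 1)
  set.seed(seed)
  meta <- model$meta
  x <- matrix(NA_real_, n, nrow(meta), dimnames = list(NULL, meta$name))
  genotypes <- NULL
  if (length(model$snp_effects)) {
    blocks <- lapply(names(model$snp_effects), function(a) {
      se <- model$snp_effects[[a]]
      G <- simulate_genotypes(n, se$maf, ld_r2 = ld_r2, snp_ids = se$snp_ids,
                              chromosome = rep(se$chromosome, length(se$maf)),
                              position = se$position)
      # standardise the raw weighted sum by its theoretical moments so
      # anchor effect sizes are on the same scale as other coefficients
      raw <- as.numeric(G$dosages %*% se$weights)
      mu <- sum(se$weights * 2 * se$maf)
      sdv <- sqrt(sum(se$weights^2 * 2 * se$maf * (1 - se$maf)))
      x[, a] <<- (raw - mu) / sdv
      G
    })
    genotypes <- genotype_matrix(
      do.call(cbind, lapply(blocks, function(G) G$dosages)),
      unlist(lapply(blocks, function(G) G$snp_ids)),
      unlist(lapply(blocks, function(G) G$chromosome)),
      unlist(lapply(blocks, function(G) G$position)))
  }
  nlev <- stats::setNames(vapply(meta$levels, length, integer(1)), meta$name)
  for (v in topological_order(model$dag)) {
    if (!is.na(x[1, v])) next               # allele scores already drawn
    par <- model$parameters[[v]]
    cfg <- rep(1L, n)
    for (d in par$parents_discrete) cfg <- (cfg - 1L) * nlev[d] + x[, d]
    if (par$type == "discrete") {
      L <- nrow(par$cpt)
      u <- stats::runif(n)
      cum <- apply(par$cpt, 2, cumsum)
      x[, v] <- vapply(seq_len(n), function(i)
        findInterval(u[i], cum[, cfg[i]], left.open = TRUE) + 1, numeric(1))
    } else {
      mu <- par$intercepts[cfg]
      for (cp in names(par$coef)) mu <- mu + par$coef[[cp]] * x[, cp]
      x[, v] <- mu + stats::rnorm(n, 0, par$sd)
    }
  }
  df <- as.data.frame(x)
  for (j in which(is_discrete(meta)))
    df[[j]] <- meta$levels[[j]][x[, j]]
  list(data = mixbn_data(df, meta), genotypes = genotypes)
}

#' Missingness specifications
#'
#' Describes block missingness of the kind seen in multi-centre cohort
#' data: whole (sample group x variable set) blocks absent (fraction
#' 1), or partially missing at a given rate.
#'
#' @param blocks list of blocks, each a list with `rows` (integer or
#'   logical sample selector, or `"all"`), `vars` (variable names) and
#'   `fraction` in `[0, 1]`.
#' @param ensure_no_complete_row if `TRUE`, every sample left complete
#'   after the blocks are applied gets one extra missing cell among the
#'   blocks' variables.
#' @param seed integer seed for the partial-fraction draws.
#' @return A list of class `mixbn_missingness_spec`.
#' @export
missingness_spec <- function(blocks, ensure_no_complete_row = FALSE,
                             seed = 1L) {
  for (b in blocks)
    stopifnot(all(c("rows", "vars", "fraction") %in% names(b)),
              b$fraction >= 0, b$fraction <= 1)
  structure(list(blocks = blocks,
                 ensure_no_complete_row = ensure_no_complete_row,
                 seed = as.integer(seed)),
            class = "mixbn_missingness_spec")
}

#' Mask cells of a dataset according to a missingness specification
#'
#' Observed (unmasked) values are never altered.  A specification that
#' would leave some variable with no observed values at all is
#' rejected, since downstream imputation requires at least one observed
#' value per variable.
#'
#' @param data a [mixbn_data()].
#' @param spec a [missingness_spec()].
#' @return A `mixbn_data` with the mask applied.
#' @export
inject_missingness <- function(data, spec) {
  stopifnot(inherits(spec, "mixbn_missingness_spec"))
  set.seed(spec$seed)
  x <- data$x
  n <- nrow(x)
  touched <- character(0)
  for (b in spec$blocks) {
    rows <- if (identical(b$rows, "all")) seq_len(n)
      else if (is.logical(b$rows)) which(b$rows) else as.integer(b$rows)
    stopifnot(all(b$vars %in% colnames(x)))
    touched <- union(touched, b$vars)
    for (v in b$vars) {
      hit <- if (b$fraction >= 1) rows
        else rows[stats::runif(length(rows)) < b$fraction]
      x[hit, v] <- NA_real_
    }
  }
  if (spec$ensure_no_complete_row && length(touched)) {
    complete <- which(rowSums(is.na(x)) == 0)
    if (length(complete)) {
      pick <- sample(touched, length(complete), replace = TRUE)
      x[cbind(complete, match(pick, colnames(x)))] <- NA_real_
    }
  }
  if (any(colSums(!is.na(x)) == 0))
    stop("specification would leave a variable with no observed values")
  with_values(data, x)
}

#' Cohort-style synthetic preset
#'
#' Generates a model and dataset emulating the structure of a large
#' multi-centre type-2-diabetes cohort: 3029 individuals of whom 795
#' are cases, 260 mixed variables in class counts (65 clinical, 34
#' metabolite, 27 protein, 33 expression, 101 allele scores), clinical
#' variables with block missingness such that no individual is
#' complete, and omics variables complete except 14 individuals
#' missing every protein.  A disease indicator (`clin03`) is binarised
#' by thresholding so that `n_cases` individuals are cases, and — like
#' T2D treated as a continuous trait so that continuous parents are
#' allowed — stays declared continuous.  `scale` shrinks every count
#' proportionally for desk-scale runs.
#'
#' @param seed integer seed.
#' @param n number of individuals (default 3029).
#' @param n_cases number of cases (default 795).
#' @param scale multiplier on the class counts (default 1; use e.g.
#'   0.1 for quick runs).
#' @param n_protein_missing individuals missing every protein variable
#'   (default 14).
#' @param edge_density passed to [simulate_model()].
#' @return List with `model`, `data` (mask applied), `complete_data`
#'   (before masking), `genotypes`, `case_rows` and `constraints` (the
#'   allele-score anchoring plus no-parents sex and discrete-centre
#'   typing that such an analysis uses).
#' @export
direct_like <- function(seed = 1L, n = 3029L, n_cases = 795L, scale = 1,
                        n_protein_missing = 14L, edge_density = 0.05) {
  counts <- ceiling(c(clinical = 65, metabolite = 34, protein = 27,
                      expression = 33, allele_score = 101) * scale)
  counts["allele_score"] <- min(counts["allele_score"],
                                sum(counts[c("metabolite", "protein",
                                             "expression")]) +
                                  counts["clinical"] - 2)
  model <- simulate_model(n_per_class = counts, edge_density = edge_density,
                          n_discrete = min(2L, counts[["clinical"]]),
                          seed = seed)
  sim <- simulate_dataset(model, n, seed = seed + 1L)
  data <- sim$data
  # binary disease indicator, declared continuous: threshold the third
  # clinical variable (the first two are the discrete sex/centre-like
  # variables when present) at the case rate
  clin <- model$meta$name[model$meta$vclass == "clinical" &
                            model$meta$dtype == "continuous"]
  t2d_var <- clin[1]
  cut <- stats::quantile(data$x[, t2d_var], 1 - n_cases / n)
  case_rows <- which(data$x[, t2d_var] > cut)
  x <- data$x
  x[, t2d_var] <- as.numeric(data$x[, t2d_var] > cut)
  data <- with_values(data, x)
  complete_data <- data
  # block missingness on the continuous clinical variables (sparing the
  # disease indicator): some missing for all cases, some for all
  # controls, the rest partially missing
  blockable <- setdiff(clin, t2d_var)
  k <- length(blockable)
  thirds <- split(blockable, factor(rep(1:3, length.out = k), levels = 1:3))
  control_rows <- setdiff(seq_len(n), case_rows)
  prot <- model$meta$name[model$meta$vclass == "protein"]
  blocks <- list(
    list(rows = case_rows, vars = thirds[[1]], fraction = 1),
    list(rows = control_rows, vars = thirds[[2]], fraction = 1),
    list(rows = "all", vars = thirds[[3]], fraction = 0.2))
  if (n_protein_missing > 0 && length(prot)) {
    prot_rows <- sample.int(n, min(n_protein_missing, n))
    blocks <- c(blocks, list(list(rows = prot_rows, vars = prot,
                                  fraction = 1)))
  }
  spec <- missingness_spec(blocks, ensure_no_complete_row = TRUE,
                           seed = seed + 2L)
  data <- inject_missingness(data, spec)
  anchors <- vapply(model$snp_effects, function(se) se$target, character(1))
  constraints <- allele_score_constraints(model$meta, anchors)
  disc <- model$meta$name[is_discrete(model$meta)]
  if (length(disc))                        # sex-like variable: no parents
    constraints$no_parents <- disc[1]
  list(model = model, data = data, complete_data = complete_data,
       genotypes = sim$genotypes, case_rows = case_rows,
       t2d_var = t2d_var, constraints = constraints)
}
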