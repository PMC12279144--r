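#' SNP dosage matrices
#'
#' Desk-scale container for additively coded genotypes: dosages in
#' \{0, 1, 2\} (missing allowed) with a SNP map giving chromosome and
#' base-pair position.  Columns are stored sorted by (chromosome,
#' position).
#'
#' @param dosages numeric matrix, samples x SNPs, values 0/1/2 or `NA`.
#' @param snp_ids character vector of SNP identifiers (unique).
#' @param chromosome,position per-SNP map vectors.
#' @param sample_ids optional row identifiers.
#' @return An object of class `mixbn_genotypes` with elements
#'   `dosages`, `snp_ids`, `chromosome`, `position`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snp_ids, chromosome, position,
                            sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  stopifnot(length(snp_ids) == m, length(chromosome) == m,
            length(position) == m, !anyDuplicated(snp_ids))
  vals <- dosages[!is.na(dosages)]
  if (any(!vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or missing")
  o <- order(chromosome, position)
  dosages <- dosages[, o, drop = FALSE]
  snp_ids <- as.character(snp_ids)[o]
  colnames(dosages) <- snp_ids
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 chromosome = chromosome[o], position = as.integer(position[o]),
                 sample_ids = as.character(sample_ids)),
            class = "mixbn_genotypes")
}

#' @export
print.mixbn_genotypes <- function(x, ...) {
  cat(sprintf("mixbn_genotypes: %d samples x %d SNPs\n",
              nrow(x$dosages), length(x$snp_ids)))
  invisible(x)
}

# per-SNP mean imputation of missing dosages
mean_impute_dosages <- function(D) {
  for (j in seq_len(ncol(D))) {
    miss <- is.na(D[, j])
    if (any(miss)) D[miss, j] <- mean(D[!miss, j])
  }
  D
}

#' Per-SNP association scan
#'
#' Linear regression of a continuous trait on each SNP dosage plus
#' covariates (an intercept is always included; genetic principal
#' components are the typical covariates, supplied precomputed).
#' Missing dosages are mean-imputed per SNP.  P-values are Wald tests
#' of the dosage coefficient.
#'
#' @param y complete numeric trait vector.
#' @param G a [genotype_matrix()] with matching rows.
#' @param covariates optional numeric matrix of covariates (no
#'   intercept column needed).
#' @return Data frame with columns `snp_id`, `beta`, `se`, `pvalue`;
#'   monomorphic SNPs get `NA` coefficients and `pvalue = 1`.
#' @export
association_scan <- function(y, G, covariates = NULL) {
  stopifnot(inherits(G, "mixbn_genotypes"), length(y) == nrow(G$dosages),
            !anyNA(y))
  n <- length(y)
  Z <- cbind(`(intercept)` = rep(1, n), covariates)
  m <- length(G$snp_ids)
  beta <- se <- rep(NA_real_, m)
  pval <- rep(1, m)
  for (j in seq_len(m)) {
    g <- G$dosages[, j]
    miss <- is.na(g)
    if (any(miss)) g[miss] <- mean(g[!miss])
    if (stats::var(g) == 0) next
    X <- cbind(g, Z)
    XtX <- crossprod(X)
    XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
    if (is.null(XtXinv)) next               # collinear design
    b <- XtXinv %*% crossprod(X, y)
    res <- y - X %*% b
    df <- n - ncol(X)
    if (df <= 0) next
    s2 <- sum(res^2) / df
    beta[j] <- b[1]
    se[j] <- sqrt(s2 * XtXinv[1, 1])
    tval <- beta[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tval), df)
  }
  data.frame(snp_id = G$snp_ids, beta = beta, se = se, pvalue = pval,
             stringsAsFactors = FALSE)
}

#' Filter parameters for genetics-based variable selection
#'
#' @param alpha significance level before Bonferroni correction for
#'   metabolite/protein (and expression) scans (default 0.01).
#' @param min_snps minimum number of significant SNPs for a metabolite
#'   or protein variable to be retained (default 20).
#' @param expression_min_snps minimum for expression variables, which
#'   are retained with more than one significant SNP (default 2).
#' @param clinical_alpha significance level for clinical-variable scans
#'   (default 0.05).
#' @return A list of class `mixbn_filter_params`.
#' @export
filter_params <- function(alpha = 0.01, min_snps = 20L,
                          expression_min_snps = 2L, clinical_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, clinical_alpha > 0, clinical_alpha < 1,
            min_snps >= 1, expression_min_snps >= 1)
  structure(list(alpha = alpha, min_snps = as.integer(min_snps),
                 expression_min_snps = as.integer(expression_min_snps),
                 clinical_alpha = clinical_alpha),
            class = "mixbn_filter_params")
}

#' Bonferroni-based variable retention
#'
#' The significance threshold is `alpha` divided by the total number of
#' tests in the scan (rows x columns of the p-value matrix).  Under the
#' default rule a variable is retained when at least `min_snps` SNPs
#' pass; under the `"expression"` rule when at least
#' `expression_min_snps` pass (i.e. more than one significant SNP).
#'
#' @param pvalues numeric matrix of p-values, variables x SNPs (row and
#'   column names identify them).
#' @param params a [filter_params()] object.
#' @param rule `"min_snps"` or `"expression"`.
#' @param alpha optionally override the level (e.g. `clinical_alpha`).
#' @return List with `retained` (variable names), `significant_snps`
#'   (named list of SNP id vectors for retained variables) and
#'   `threshold` (the per-test threshold used).
#' @export
bonferroni_retain <- function(pvalues, params = filter_params(),
                              rule = c("min_snps", "expression"),
                              alpha = NULL) {
  rule <- match.arg(rule)
  pvalues <- as.matrix(pvalues)
  if (is.null(alpha)) alpha <- params$alpha
  thr <- alpha / length(pvalues)
  need <- if (rule == "expression") params$expression_min_snps else
    params$min_snps
  sig <- pvalues < thr
  n_sig <- rowSums(sig)
  retained <- rownames(pvalues)[n_sig >= need]
  snps <- lapply(retained, function(v) colnames(pvalues)[sig[v, ]])
  names(snps) <- retained
  list(retained = retained, significant_snps = snps, threshold = thr)
}

#' Greedy LD clumping
#'
#' Repeatedly take the unclaimed SNP with the smallest p-value as an
#' index SNP and discard unclaimed SNPs on the same chromosome within
#' `window_bp` whose squared dosage correlation with it exceeds
#' `r2_max`.  The returned index SNPs are independent predictors,
#' ordered by ascending p-value.
#'
#' @param assoc data frame from [association_scan()] (needs `snp_id`
#'   and `pvalue`).
#' @param G a [genotype_matrix()] containing all `assoc` SNPs.
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_bp clumping window in base pairs (default 250 kb).
#' @return Character vector of index SNP ids, p-ascending.
#' @export
clump <- function(assoc, G, r2_max = 0.1, window_bp = 250000L) {
  stopifnot(all(assoc$snp_id %in% G$snp_ids))
  D <- mean_impute_dosages(G$dosages[, assoc$snp_id, drop = FALSE])
  chr <- G$chromosome[match(assoc$snp_id, G$snp_ids)]
  pos <- G$position[match(assoc$snp_id, G$snp_ids)]
  ord <- order(assoc$pvalue, assoc$snp_id)
  claimed <- rep(FALSE, nrow(assoc))
  keep <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    keep <- c(keep, assoc$snp_id[i])
    near <- which(!claimed & chr == chr[i] & abs(pos - pos[i]) <= window_bp)
    if (length(near)) {
      r2 <- suppressWarnings(stats::cor(D[, i], D[, near]))^2
      r2[is.na(r2)] <- 0
      claimed[near[r2 > r2_max]] <- TRUE
    }
  }
  keep
}

#' Weighted allele scores
#'
#' Per-individual sum of risk-allele dosages over the selected SNPs,
#' weighted by their estimated allelic effects; missing dosages
#' contribute the SNP's mean dosage.
#'
#' @param G a [genotype_matrix()].
#' @param snps character vector of SNP ids (all must be in `G`).
#' @param weights numeric effect sizes, one per SNP (recycled by name if
#'   named).
#' @return Numeric vector of scores, one per individual.
#' @export
allele_score <- function(G, snps, weights) {
  missing_snps <- setdiff(snps, G$snp_ids)
  if (length(missing_snps))
    stop("SNP(s) absent from genotypes: ", paste(missing_snps, collapse = ", "))
  if (!is.null(names(weights))) weights <- weights[snps]
  stopifnot(length(weights) == length(snps), !anyNA(weights))
  D <- mean_impute_dosages(G$dosages[, snps, drop = FALSE])
  as.numeric(D %*% weights)
}

#' Rank-based inverse normal transform
#'
#' Maps a variable to standard-normal quantiles via its (average,
#' tie-sharing) ranks: `qnorm((r - offset) / (n - 2*offset + 1))` over
#' the non-missing values.  The default `offset = 0.5` is the rankit
#' form; `offset = 0.375` gives Blom scores.  Missing values stay
#' missing; the map is invariant to monotone rescaling of the input.
#'
#' @param x numeric vector, possibly with `NA`s; needs at least two
#'   distinct observed values.
#' @param offset rank offset constant in `[0, 0.5]`.
#' @return Numeric vector of the same length.
#' @export
inverse_normal_transform <- function(x, offset = 0.5) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(unique(v)) < 2)
    stop("inverse normal transform needs >= 2 distinct observed values")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  out <- x
  out[obs] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}
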