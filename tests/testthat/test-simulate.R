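test_that("simulated models respect structural constraints", {
  m0 <- simulate_model(c(metabolite = 6), edge_density = 0,
                       n_discrete = 0, seed = 1)
  expect_equal(n_edges(m0$dag), 0)
  mAS <- simulate_model(c(metabolite = 4, allele_score = 3),
                        edge_density = 0, n_discrete = 0, seed = 2)
  as.nodes <- mAS$meta$name[mAS$meta$vclass == "allele_score"]
  expect_length(as.nodes, 3)
  for (a in as.nodes) {
    expect_length(parents(mAS$dag, a), 0)   # roots
    expect_length(children(mAS$dag, a), 1)  # exactly one child
  }
  m1 <- simulate_model(seed = 7)
  m2 <- simulate_model(seed = 7)
  expect_identical(edges(m1$dag), edges(m2$dag))
  expect_identical(m1$parameters, m2$parameters)
  # typing and degree constraints hold on denser draws
  m3 <- simulate_model(c(clinical = 8, metabolite = 8), edge_density = 0.3,
                       max_in_degree = 3, n_discrete = 3, seed = 3)
  expect_true(is_acyclic(m3$dag))
  viol <- check_constraints(m3$dag, constraint_set(), m3$meta)
  expect_equal(nrow(viol), 0)
  indeg <- colSums(m3$dag$A)
  expect_lte(max(indeg), 3)
})

test_that("sampled datasets satisfy the container invariants across seeds", {
  m <- simulate_model(c(clinical = 4, metabolite = 3, allele_score = 2),
                      edge_density = 0.25, n_discrete = 2, seed = 10)
  for (s in 1:50) {
    d <- simulate_dataset(m, 40, seed = s)$data
    expect_s3_class(d, "mixbn_data")
    expect_true(is_complete(d))
    disc <- which(is_discrete(d$meta))
    for (j in disc)
      expect_true(all(d$x[, j] %in%
                        seq_along(d$meta$levels[[j]])))
  }
})

test_that("zero residual noise gives exact linear relations", {
  m <- simulate_model(c(metabolite = 3), edge_density = 1, n_discrete = 0,
                      residual_sd = 0, seed = 20)
  d <- simulate_dataset(m, 50, seed = 21)$data
  child <- names(which(colSums(m$dag$A) > 0))[1]
  par <- m$parameters[[child]]
  pred <- rep(par$intercepts[1], 50)
  for (cp in names(par$coef)) pred <- pred + par$coef[[cp]] * d$x[, cp]
  expect_equal(unname(d$x[, child]), unname(pred), tolerance = 1e-12)
})

test_that("large-sample moments match the generating parameters", {
  m <- simulate_model(c(metabolite = 2), edge_density = 0, n_discrete = 0,
                      seed = 30)
  d <- simulate_dataset(m, 50000, seed = 31)$data
  # root Gaussian: mean within 3 standard errors of its intercept
  expect_lt(abs(mean(d$x[, 1]) - m$parameters[[1]]$intercepts[1]),
            3 / sqrt(50000))
  # dosage frequencies for MAF 0.3 near the binomial probabilities
  G <- simulate_genotypes(50000, maf = 0.3, seed = 32)
  freq <- tabulate(G$dosages[, 1] + 1, 3) / 50000
  expect_equal(freq, c(0.49, 0.42, 0.09), tolerance = 0.02)
})

test_that("children regressed on their true parents recover the coefficients", {
  m <- simulate_model(c(metabolite = 5), edge_density = 0.4, n_discrete = 0,
                      seed = 40)
  d <- simulate_dataset(m, 20000, seed = 41)$data
  for (v in m$dag$nodes) {
    cp <- m$parameters[[v]]$parents_continuous
    if (!length(cp)) next
    fit <- stats::lm(d$x[, v] ~ d$x[, cp, drop = FALSE])
    est <- stats::coef(fit)[-1]
    se <- sqrt(diag(stats::vcov(fit)))[-1]
    expect_true(all(abs(est - m$parameters[[v]]$coef) < 3.5 * se))
  }
})

test_that("missingness injection masks exactly the requested blocks", {
  m <- simulate_model(c(clinical = 4, metabolite = 2), edge_density = 0.2,
                      n_discrete = 0, seed = 50)
  d <- simulate_dataset(m, 200, seed = 51)$data
  untouched <- inject_missingness(d, missingness_spec(list(
    list(rows = "all", vars = "clin01", fraction = 0))))
  expect_identical(untouched$x, d$x)
  cases <- 1:80
  spec <- missingness_spec(list(
    list(rows = cases, vars = "clin01", fraction = 1),
    list(rows = "all", vars = "clin02", fraction = 0.3)), seed = 52)
  dm <- inject_missingness(d, spec)
  expect_true(all(dm$missing[cases, "clin01"]))
  expect_false(any(dm$missing[-cases, "clin01"]))
  # observed cells keep their exact values
  expect_identical(dm$x[!dm$missing], d$x[!dm$missing])
  # a spec wiping out a variable entirely is rejected
  expect_error(inject_missingness(d, missingness_spec(list(
    list(rows = "all", vars = "met01", fraction = 1)))),
    "no observed values")
})

test_that("ensure_no_complete_row leaves nobody complete", {
  m <- simulate_model(c(clinical = 5), edge_density = 0.2, n_discrete = 0,
                      seed = 55)
  d <- simulate_dataset(m, 120, seed = 56)$data
  spec <- missingness_spec(list(
    list(rows = 1:10, vars = c("clin01", "clin02"), fraction = 0.5)),
    ensure_no_complete_row = TRUE, seed = 57)
  dm <- inject_missingness(d, spec)
  expect_equal(sum(rowSums(dm$missing) == 0), 0)
})

test_that("the cohort preset reproduces the study's shape at scale one", {
  dl <- direct_like(seed = 3, n = 400, n_cases = 105, scale = 0.1,
                    n_protein_missing = 5)
  tab <- table(dl$model$meta$vclass)
  expect_equal(as.vector(tab[c("clinical", "metabolite", "protein",
                               "expression")]),
               c(7, 4, 3, 4))
  expect_equal(n_samples(dl$data), 400)
  expect_length(dl$case_rows, 105)
  # the disease indicator is binary but declared continuous
  t2d.meta <- dl$model$meta[dl$model$meta$name == dl$t2d_var, ]
  expect_equal(t2d.meta$dtype, "continuous")
  expect_setequal(unique(dl$complete_data$x[, dl$t2d_var]), c(0, 1))
  # nobody complete; five individuals missing every protein
  expect_equal(sum(rowSums(dl$data$missing) == 0), 0)
  prot <- dl$model$meta$name[dl$model$meta$vclass == "protein"]
  all.prot.missing <- rowSums(dl$data$missing[, prot, drop = FALSE]) ==
    length(prot)
  expect_gte(sum(all.prot.missing), 5)
  # omics variables complete apart from those individuals
  expr <- dl$model$meta$name[dl$model$meta$vclass == "expression"]
  expect_equal(sum(dl$data$missing[, expr]), 0)
  # constraints anchor every allele score
  expect_equal(length(dl$constraints$parent_only),
               sum(dl$model$meta$vclass == "allele_score"))
})

test_that("full-scale preset counts match the cohort dimensions", {
  # model construction only (no learning): 260 variables, 3029 rows
  dl <- direct_like(seed = 8)
  expect_equal(nrow(dl$model$meta), 260)
  expect_equal(as.vector(table(dl$model$meta$vclass)[
    c("clinical", "metabolite", "protein", "expression", "allele_score")]),
    c(65, 34, 27, 33, 101))
  expect_equal(n_samples(dl$data), 3029)
  expect_length(dl$case_rows, 795)
  expect_equal(sum(rowSums(dl$data$missing) == 0), 0)
  prot <- dl$model$meta$name[dl$model$meta$vclass == "protein"]
  expect_equal(sum(rowSums(dl$data$missing[, prot]) == length(prot)), 14)
})
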