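test_that("association scans recover exact and null effects", {
  set.seed(101)
  G <- simulate_genotypes(300, maf = rep(0.3, 3))
  y <- 2 * G$dosages[, 1]
  res <- association_scan(y, G)
  expect_equal(res$beta[1], 2, tolerance = 1e-10)
  expect_lt(res$pvalue[1], 1e-200)
  # monomorphic SNP: undefined effect, p = 1
  G2 <- genotype_matrix(cbind(rep(0, 50), rbinom(50, 2, 0.4)),
                        c("s1", "s2"), c(1, 1), c(100, 200))
  res2 <- association_scan(stats::rnorm(50), G2)
  expect_true(is.na(res2$beta[res2$snp_id == "s1"]))
  expect_equal(res2$pvalue[res2$snp_id == "s1"], 1)
})

test_that("null p-values are uniform across many SNPs", {
  set.seed(202)
  G <- simulate_genotypes(400, maf = stats::runif(500, 0.1, 0.5))
  y <- stats::rnorm(400)
  res <- association_scan(y, G)
  ks <- stats::ks.test(res$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("regression coefficients match the normal-equations oracle", {
  set.seed(33)
  n <- 10
  g <- stats::rbinom(n, 2, 0.5)
  cov1 <- stats::rnorm(n)
  y <- 0.5 * g - 0.3 * cov1 + stats::rnorm(n)
  G <- genotype_matrix(matrix(g), "s1", 1, 500)
  res <- association_scan(y, G, covariates = cbind(cov1))
  X <- cbind(g, 1, cov1)
  b <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$beta, b[1], tolerance = 1e-10)
  s2 <- sum((y - X %*% b)^2) / (n - 3)
  expect_equal(res$se, sqrt(s2 * solve(t(X) %*% X)[1, 1]), tolerance = 1e-10)
})

test_that("Bonferroni retention honours the per-rule SNP counts", {
  m <- 100                                  # total tests = 3 * 100
  p <- matrix(1, 3, m, dimnames = list(c("v1", "v2", "v3"),
                                       sprintf("s%03d", 1:m)))
  thr <- 0.01 / length(p)
  p["v1", 1:25] <- thr / 2                  # 25 significant
  p["v2", 1:19] <- thr / 2                  # 19: below the default 20
  p["v3", 1:2] <- thr / 2                   # 2: passes the expression rule
  res <- bonferroni_retain(p, filter_params())
  expect_identical(res$retained, "v1")
  expect_length(res$significant_snps$v1, 25)
  rese <- bonferroni_retain(p, filter_params(), rule = "expression")
  expect_setequal(rese$retained, c("v1", "v2", "v3"))
  p["v3", 2] <- 1                           # one significant SNP: dropped
  rese2 <- bonferroni_retain(p, filter_params(), rule = "expression")
  expect_false("v3" %in% rese2$retained)
})

test_that("clumping keeps the lowest-p SNP of each correlated group", {
  # two identical dosage columns: only the lower-p one survives
  set.seed(51)
  g <- stats::rbinom(80, 2, 0.4)
  G <- genotype_matrix(cbind(g, g, stats::rbinom(80, 2, 0.4)),
                       c("s1", "s2", "s3"), c(1, 1, 1),
                       c(1000, 2000, 3000))
  assoc <- data.frame(snp_id = c("s1", "s2", "s3"),
                      pvalue = c(1e-8, 1e-6, 1e-4))
  kept <- clump(assoc, G, r2_max = 0.1, window_bp = 10000)
  expect_identical(kept, c("s1", "s3"))
  # uncorrelated SNPs all survive
  G2 <- simulate_genotypes(500, maf = rep(0.4, 4), seed = 52)
  assoc2 <- data.frame(snp_id = G2$snp_ids, pvalue = c(0.2, 0.1, 0.4, 0.3))
  expect_setequal(clump(assoc2, G2, r2_max = 0.5, window_bp = 1e6),
                  G2$snp_ids)
})

test_that("clumping matches a brute-force greedy oracle on LD blocks", {
  set.seed(53)
  G <- simulate_genotypes(400, maf = rep(0.3, 20), ld_r2 = 0.8)
  assoc <- data.frame(snp_id = G$snp_ids, pvalue = stats::runif(20))
  r2_max <- 0.1; window <- 50000
  kept <- clump(assoc, G, r2_max, window)
  # oracle: plain greedy scan over the p-sorted list
  D <- G$dosages
  ord <- order(assoc$pvalue, assoc$snp_id)
  claimed <- rep(FALSE, 20); exp_keep <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    exp_keep <- c(exp_keep, assoc$snp_id[i])
    for (j in which(!claimed)) {
      if (abs(G$position[j] - G$position[i]) <= window &&
          G$chromosome[j] == G$chromosome[i] &&
          stats::cor(D[, i], D[, j])^2 > r2_max)
        claimed[j] <- TRUE
    }
  }
  expect_identical(kept, exp_keep)
  # antichain: no kept pair is both nearby and correlated
  for (a in kept) for (b in setdiff(kept, a)) {
    ia <- match(a, G$snp_ids); ib <- match(b, G$snp_ids)
    if (abs(G$position[ia] - G$position[ib]) <= window)
      expect_lte(stats::cor(D[, ia], D[, ib])^2, r2_max)
  }
})

test_that("allele scores are weighted dosage sums with mean-filled gaps", {
  D <- matrix(c(0, 1, 2), 1, dimnames = list(NULL, NULL))
  G <- genotype_matrix(D, c("s1", "s2", "s3"), c(1, 1, 1), c(1, 2, 3))
  sc <- allele_score(G, c("s1", "s2", "s3"), c(0.5, 1.0, -0.2))
  expect_equal(sc, 0.6)
  expect_equal(allele_score(G, c("s1", "s2", "s3"), c(0, 0, 0)), 0)
  # missing dosage contributes the SNP mean
  D2 <- rbind(c(0, 2), c(2, NA))
  G2 <- genotype_matrix(D2, c("a", "b"), c(1, 1), c(1, 2))
  sc2 <- allele_score(G2, c("a", "b"), c(1, 1))
  expect_equal(sc2[2], 2 + 2)               # mean of observed b is 2
  # linearity in weights
  set.seed(61)
  G3 <- simulate_genotypes(40, maf = rep(0.3, 5))
  w1 <- stats::runif(5); w2 <- stats::runif(5)
  expect_equal(allele_score(G3, G3$snp_ids, w1 + 2 * w2),
               allele_score(G3, G3$snp_ids, w1) +
                 2 * allele_score(G3, G3$snp_ids, w2),
               tolerance = 1e-10)
  expect_error(allele_score(G3, "nope", 1), "absent")
})

test_that("the inverse normal transform has the rankit closed form", {
  out <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(out, stats::qnorm(c(1, 3, 5) / 6), tolerance = 1e-10)
  expect_equal(out[2], 0)
  # monotone rescaling leaves the output unchanged
  expect_equal(inverse_normal_transform(c(10, 20, 30)^3), out)
  # ties share the averaged rank value; missing stays missing
  tied <- inverse_normal_transform(c(1, 1, 5, NA))
  expect_equal(tied[1], tied[2])
  expect_true(is.na(tied[4]))
  expect_error(inverse_normal_transform(rep(3, 10)), "distinct")
  # Blom variant shifts the extremes slightly inward
  blom <- inverse_normal_transform(c(10, 20, 30), offset = 0.375)
  expect_lt(abs(blom[3]), abs(stats::qnorm(5 / 6)) + 1e-9)
  # near-standardisation at large n
  set.seed(91)
  z <- inverse_normal_transform(stats::rexp(5000))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::var(z) - 1), 0.05)
})
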