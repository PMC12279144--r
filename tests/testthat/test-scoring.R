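test_that("multinomial family matches the closed form", {
  meta <- variable_meta("g", "discrete", "clinical", list(c("a", "b")))
  d <- mixbn_data(data.frame(g = c("a", "a", "b", "b")), meta)
  fs <- family_score("g", character(0), d)
  expect_equal(fs$loglik, 4 * log(0.5), tolerance = 1e-10)
  expect_equal(fs$n_params, 1L)
  expect_equal(fs$bic, -2 * 4 * log(0.5) + log(4), tolerance = 1e-10)
})

test_that("perfect linear fit is floored to a finite score", {
  d <- cont_data(data.frame(x = 1:5, y = 1:5))
  fs <- family_score("y", "x", d)
  expect_true(is.finite(fs$bic))
  expect_equal(fs$n_params, 3L)            # intercept + slope + variance
  orc <- oracle_gauss_family(1:5, matrix(1:5))
  expect_equal(fs$loglik, orc$loglik, tolerance = 1e-6)
})

test_that("a discrete parent decomposes the Gaussian family by configuration", {
  set.seed(31)
  meta <- variable_meta(c("grp", "y"), c("discrete", "continuous"),
                        c("clinical", "clinical"), list(c("u", "v"), NULL))
  grp <- rep(c("u", "v"), each = 30)
  y <- stats::rnorm(60, mean = ifelse(grp == "u", 0, 2))
  d <- mixbn_data(data.frame(grp = grp, y = y), meta)
  fs <- family_score("y", "grp", d)
  # score the two subsets separately with the no-parent family
  lls <- vapply(c("u", "v"), function(g) {
    sub <- mixbn_data(data.frame(y = y[grp == g]),
                      variable_meta("y", "continuous", "clinical"))
    family_score("y", character(0), sub)$loglik
  }, numeric(1))
  expect_equal(fs$loglik, sum(lls), tolerance = 1e-8)
  expect_equal(fs$n_params, 4L)            # (intercept + variance) x 2
  expect_equal(fs$bic, -2 * sum(lls) + 4 * log(60), tolerance = 1e-8)
})

test_that("family BIC equals the independent regression oracle on random mixed families", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    grp <- sample(c("p", "q"), n, replace = TRUE)
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    y <- 0.8 * x1 - 0.5 * x2 + (grp == "q") + stats::rnorm(n)
    meta <- variable_meta(c("grp", "x1", "x2", "y"),
                          c("discrete", rep("continuous", 3)),
                          rep("clinical", 4),
                          list(c("p", "q"), NULL, NULL, NULL))
    d <- mixbn_data(data.frame(grp = grp, x1 = x1, x2 = x2, y = y), meta)
    # mixed family: discrete + continuous parents
    fs <- family_score("y", c("grp", "x1", "x2"), d)
    ll <- 0; k <- 0
    for (g in unique(grp)) {
      rows <- grp == g
      orc <- oracle_gauss_family(y[rows], cbind(x1[rows], x2[rows]))
      # the scorer floors against the child's overall variance
      rssfit <- stats::lm(y[rows] ~ x1[rows] + x2[rows])
      rss <- sum(stats::residuals(rssfit)^2)
      m <- sum(rows)
      s2 <- max(rss / m, 1e-12 * stats::var(y), 1e-300)
      ll <- ll + (-m / 2 * log(2 * pi * s2) - rss / (2 * s2))
      k <- k + 4
    }
    expect_equal(fs$bic, -2 * ll + k * log(n), tolerance = 1e-8)
  }
})

test_that("the network score is decomposable and additive", {
  d <- chain_data(300, c(1, 1), seed = 5)
  empty <- dag(c("V1", "V2", "V3"))
  s_empty <- network_score(empty, d)
  fam0 <- vapply(c("V1", "V2", "V3"), function(v)
    family_score(v, character(0), d)$bic, numeric(1))
  expect_equal(s_empty, sum(fam0), tolerance = 1e-10)
  with_edge <- dag(c("V1", "V2", "V3"), rbind(c("V1", "V2")))
  delta <- network_score(with_edge, d) - s_empty
  expect_equal(delta,
               family_score("V2", "V1", d)$bic -
                 family_score("V2", character(0), d)$bic,
               tolerance = 1e-10)
})

test_that("a real dependence lowers the score when its edge is added", {
  d <- chain_data(1000, 1, seed = 11)
  s0 <- network_score(dag(c("V1", "V2")), d)
  s1 <- network_score(dag(c("V1", "V2"), rbind(c("V1", "V2"))), d)
  expect_lt(s1, s0)
})

test_that("adding a parent never decreases loglik and always adds parameters", {
  set.seed(13)
  for (i in 1:10) {
    n <- 150
    df <- as.data.frame(matrix(stats::rnorm(n * 4), n))
    names(df) <- c("a", "b", "c", "y")
    d <- cont_data(df)
    pa <- sample(c("a", "b", "c"), sample(0:2, 1))
    extra <- sample(setdiff(c("a", "b", "c"), pa), 1)
    f0 <- family_score("y", pa, d)
    f1 <- family_score("y", c(pa, extra), d)
    expect_gte(f1$loglik, f0$loglik - 1e-8)
    expect_gt(f1$n_params, f0$n_params)
  }
})

test_that("cached family scores equal fresh evaluations", {
  d <- chain_data(200, c(0.7, 0.7), seed = 21)
  sc <- make_scorer(d)
  b1 <- sc$bic("V3", c("V2", "V1"))
  b2 <- sc$bic("V3", c("V1", "V2"))       # hits the cache, different order
  expect_identical(b1, b2)
  expect_equal(b1, family_score("V3", c("V1", "V2"), d)$bic)
})

test_that("undefined MLEs flag the family invalid with an infinite score", {
  meta <- variable_meta(c("grp", "x", "y"),
                        c("discrete", "continuous", "continuous"),
                        rep("clinical", 3), list(c("a", "b"), NULL, NULL))
  # configuration "b" has a single observation: fewer rows than the
  # two regression coefficients
  d <- mixbn_data(data.frame(grp = c("a", "a", "a", "b"),
                             x = c(1, 2, 3, 4), y = c(1, 1.5, 2, 9)), meta)
  fs <- family_score("y", c("grp", "x"), d)
  expect_false(fs$valid)
  expect_identical(fs$bic, Inf)
  # a discrete child may not take a continuous parent
  expect_identical(family_score("grp", "x", d)$bic, Inf)
})

test_that("scoring rejects incomplete data", {
  meta <- cont_meta(c("a", "b"))
  d <- mixbn_data(data.frame(a = c(1, NA, 3), b = c(1, 2, 3)), meta)
  expect_error(network_score(dag(c("a", "b")), d), "complete")
})
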