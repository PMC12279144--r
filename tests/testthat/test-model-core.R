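test_that("variable metadata enforces its invariants", {
  expect_error(variable_meta(c("a", "a"), rep("continuous", 2),
                             rep("clinical", 2)), "unique")
  expect_error(variable_meta("a", "discrete", "clinical", list("only")),
               "2 levels")
  expect_error(variable_meta("a", "discrete", "allele_score",
                             list(c("x", "y"))), "continuous")
  meta <- variable_meta(c("sex", "bmi"), c("discrete", "continuous"),
                        c("clinical", "clinical"), list(c("F", "M"), NULL))
  expect_s3_class(meta, "mixbn_meta")
  expect_identical(meta_levels(meta, "sex"), c("F", "M"))
})

test_that("data matrices validate types, levels and missingness", {
  meta <- variable_meta(c("sex", "bmi"), c("discrete", "continuous"),
                        c("clinical", "clinical"), list(c("F", "M"), NULL))
  d <- mixbn_data(data.frame(sex = c("F", "M", NA), bmi = c(21, NA, 30)),
                  meta)
  expect_equal(dim(d$x), c(3L, 2L))
  expect_equal(sum(d$missing), 2)
  expect_equal(unname(d$x[1, "sex"]), 1)   # level code, not label
  expect_equal(as.data.frame(d)$sex, c("F", "M", NA))
  expect_error(mixbn_data(data.frame(sex = "X", bmi = 1), meta),
               "undeclared level")
  expect_error(mixbn_data(data.frame(sex = c("F", "M"),
                                     bmi = c(NA_real_, NA_real_)), meta),
               "non-missing")
  expect_error(mixbn_data(data.frame(bmi = "tall", sex = "F"), meta),
               "non-numeric")
})

test_that("acyclicity matches the trivial cases", {
  expect_true(is_acyclic(dag(LETTERS[1:3], rbind(c("A", "B"), c("B", "C")))))
  expect_false(is_acyclic(dag(LETTERS[1:2], rbind(c("A", "B"), c("B", "A")))))
  expect_true(is_acyclic(dag(LETTERS[1:5])))
  expect_error(dag(LETTERS[1:2], rbind(c("A", "Z"))), "not declared")
  expect_error(dag(LETTERS[1:2], rbind(c("A", "A"))), "self-edges")
})

test_that("acyclicity agrees with brute-force cycle search on random graphs", {
  set.seed(421)
  for (i in 1:500) {
    p <- sample(2:8, 1)
    es <- random_edge_set(p, sample(0:12, 1))
    g <- dag(es$nodes, es$edges)
    expect_identical(is_acyclic(g),
                     !oracle_has_cycle(es$nodes, edges(g)),
                     info = paste("case", i))
  }
})

test_that("topological order puts every parent before its children", {
  g <- dag(LETTERS[1:3], rbind(c("A", "B"), c("A", "C")))
  expect_identical(topological_order(g)[1], "A")
  chain <- dag(LETTERS[1:3], rbind(c("A", "B"), c("B", "C")))
  expect_identical(topological_order(chain), c("A", "B", "C"))
  iso <- dag(c("c", "a", "b"))
  expect_identical(topological_order(iso), c("a", "b", "c"))  # lexicographic
  expect_error(topological_order(dag(LETTERS[1:2],
                                     rbind(c("A", "B"), c("B", "A")))),
               "cyclic")
  set.seed(99)
  for (i in 1:50) {
    g <- random_dag(sample(2:9, 1), 0.4)
    ord <- topological_order(g)
    pos <- match(g$nodes, ord)
    e <- edges(g)
    if (nrow(e))
      expect_true(all(pos[match(e[, 1], g$nodes)] <
                        pos[match(e[, 2], g$nodes)]))
  }
})

test_that("constraint checking flags each rule by name", {
  meta <- variable_meta(c("X", "AS_X", "Centre"),
                        c("continuous", "continuous", "discrete"),
                        c("metabolite", "allele_score", "clinical"),
                        list(NULL, NULL, c("a", "b")))
  cs <- constraint_set(parent_only = "AS_X")
  g <- dag(meta$name, rbind(c("X", "AS_X")))
  v <- check_constraints(g, cs, meta)
  expect_equal(nrow(v), 1)
  expect_equal(v$rule, "edge_into_parent_only")
  g2 <- dag(meta$name, rbind(c("X", "Centre")))
  v2 <- check_constraints(g2, constraint_set(), meta)
  expect_equal(v2$rule, "continuous_parent_of_discrete")
  expect_equal(nrow(check_constraints(dag(meta$name), constraint_set(),
                                      meta)), 0)
  # required / forbidden
  cs3 <- constraint_set(required = rbind(c("AS_X", "X")),
                        forbidden = rbind(c("Centre", "X")))
  g3 <- dag(meta$name, rbind(c("Centre", "X")))
  v3 <- check_constraints(g3, cs3, meta)
  expect_setequal(v3$rule, c("required_missing", "forbidden_edge"))
})

test_that("empty constraints never flag an all-continuous graph", {
  set.seed(7)
  for (i in 1:25) {
    g <- random_dag(sample(2:8, 1), 0.4)
    meta <- cont_meta(g$nodes)
    expect_equal(nrow(check_constraints(g, constraint_set(), meta)), 0)
  }
})

test_that("constraint sets reject contradictions at construction", {
  expect_error(constraint_set(required = rbind(c("a", "b")),
                              forbidden = rbind(c("a", "b"))),
               "both required and forbidden")
  expect_error(constraint_set(required = rbind(c("a", "b")),
                              parent_only = "b"), "parent_only")
  meta <- variable_meta(c("a", "b"), c("continuous", "discrete"),
                        c("clinical", "clinical"),
                        list(NULL, c("x", "y")))
  expect_error(constraint_set(required = rbind(c("a", "b")), meta = meta),
               "continuous parent")
})

test_that("allele-score constraints permit only the anchor edge", {
  meta <- variable_meta(c("X", "Y", "AS_X"), rep("continuous", 3),
                        c("metabolite", "metabolite", "allele_score"))
  cs <- allele_score_constraints(meta, c(AS_X = "X"))
  expect_true("AS_X" %in% cs$parent_only)
  expect_true(any(cs$forbidden[, 1] == "AS_X" & cs$forbidden[, 2] == "Y"))
  expect_false(any(cs$forbidden[, 1] == "AS_X" & cs$forbidden[, 2] == "X"))
})
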