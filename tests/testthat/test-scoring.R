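test_that("family score reproduces the Beta-Binomial closed form", {
  d <- binary_dataset(cbind(A = c(0L, 1L), Treatment = c(0L, 1L)))
  # parentless node, one 0 and one 1, ess = 1: marginal likelihood 1/8
  expect_equal(family_score(d, "A", character(0), ess = 1), log(1 / 8),
               tolerance = 1e-12)
  # zero samples: empty product, log-score 0
  empty <- binary_dataset(matrix(integer(0), 0, 2,
                                 dimnames = list(NULL,
                                                 c("A", "Treatment"))))
  expect_equal(family_score(empty, "A", "Treatment", ess = 1), 0)
  expect_error(family_score(d, "A", ess = 0), "ess")
  expect_error(family_score(d, "A", "A", ess = 1), "parents")
})

test_that("cached scores agree with the naive loop oracle", {
  w <- make_small_world(5, 40, seed = 51)
  cache <- score_cache()
  for (ess in c(1, 4)) {
    for (child in variables(w$d)) {
      others <- setdiff(variables(w$d), child)
      for (k in 0:3) {
        parents <- others[seq_len(k)]
        expect_equal(
          family_score(w$d, child, parents, ess = ess, cache = cache),
          naive_family_score(w$d$values, child, parents, ess),
          tolerance = 1e-10)
      }
    }
  }
})

test_that("bde_score decomposes over families and is score-equivalent", {
  w <- make_small_world(3, 30, seed = 61)
  vars <- variables(w$d)
  g0 <- new_dag(vars)
  expect_equal(bde_score(w$d, g0, ess = 1),
               sum(vapply(vars, function(nd)
                 family_score(w$d, nd, character(0), 1), numeric(1L))))
  # likelihood equivalence of A->B and B->A
  gab <- new_dag(vars, rbind(vars[1:2]))
  gba <- new_dag(vars, rbind(rev(vars[1:2])))
  expect_equal(bde_score(w$d, gab, 1), bde_score(w$d, gba, 1),
               tolerance = 1e-10)
  expect_error(bde_score(w$d, new_dag(c("X", "Y")), 1), "variables")
  # changing one node's parents changes only that family
  g1 <- new_dag(vars, rbind(vars[1:2]))
  f_before <- family_score(w$d, vars[3], character(0), 1)
  expect_equal(bde_score(w$d, g1, 1) - bde_score(w$d, g0, 1),
               family_score(w$d, vars[2], vars[1], 1) -
                 family_score(w$d, vars[2], character(0), 1),
               tolerance = 1e-10)
  expect_equal(f_before, family_score(w$d, vars[3], character(0), 1))
})

test_that("strong dependence is preferred over independence", {
  g <- new_dag(c("F1", "Treatment"), rbind(c("Treatment", "F1")))
  bn <- ground_truth_bn(g, list(Treatment = 0.5, F1 = c(0.05, 0.95)))
  m <- sample_counts(bn, n_samples = 1000, seed = 71)
  d <- binarize_counts(m)
  expect_gt(bde_score(d, g, 1), bde_score(d, new_dag(g$nodes), 1))
})

test_that("delta_score matches full rescoring and composes", {
  w <- make_small_world(4, 50, seed = 81)
  vars <- variables(w$d)
  g <- random_dag(vars, arc_prob = 0.4, seed = 5)
  cache <- score_cache()
  s0 <- bde_score(w$d, g, 1, cache)
  for (u in vars) for (v in vars) {
    if (u == v) next
    dlt <- delta_score(w$d, g, "add", u, v, 1, cache)
    if (!is.na(dlt)) {
      g2 <- add_arc(g, u, v)
      expect_equal(dlt, bde_score(w$d, g2, 1, cache) - s0,
                   tolerance = 1e-10)
      # add then delete the same arc: deltas cancel
      expect_equal(dlt + delta_score(w$d, g2, "delete", u, v, 1, cache),
                   0, tolerance = 1e-10)
    }
    drev <- delta_score(w$d, g, "reverse", u, v, 1, cache)
    if (!is.na(drev)) {
      # reverse decomposes into delete + add applied sequentially
      gdel <- drop_arc(g, u, v)
      expect_equal(drev,
                   delta_score(w$d, g, "delete", u, v, 1, cache) +
                     delta_score(w$d, gdel, "add", v, u, 1, cache),
                   tolerance = 1e-10)
      expect_equal(drev,
                   bde_score(w$d, reverse_arc(g, u, v), 1, cache) - s0,
                   tolerance = 1e-10)
    }
  }
  # illegal moves signal NA, not an error
  arcs <- dag_arcs(g)
  expect_true(is.na(delta_score(w$d, g, "add", arcs[1, 1], arcs[1, 2], 1)))
  expect_true(is.na(delta_score(w$d, g, "delete", arcs[1, 2],
                                arcs[1, 1], 1)))
})
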