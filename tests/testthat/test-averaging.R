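snet <- function(arcs, score, nodes = c("A", "B", "C", "D")) {
  methbn:::scored_network(new_dag(nodes, arcs), score)
}

test_that("softmax weighting reproduces hand-computed probabilities", {
  # single network: every arc has probability 1
  tab1 <- arc_probabilities(list(snet(rbind(c("A", "B")), -5)))
  expect_equal(tab1$probability, 1)
  # two equal-score networks, arc in exactly one: 0.5
  tab2 <- arc_probabilities(list(snet(rbind(c("A", "B")), -2),
                                 snet(NULL, -2)))
  expect_equal(tab2$probability, 0.5)
  # log-scores 0 and log 3, arc only in the second: weight 3/4
  tab3 <- arc_probabilities(list(snet(NULL, 0),
                                 snet(rbind(c("C", "D")), log(3))))
  expect_equal(tab3$probability, 0.75, tolerance = 1e-12)
  expect_equal(sum(attr(tab3, "weights")), 1, tolerance = 1e-12)
  # invariance under a constant shift of all log-scores
  tab3s <- arc_probabilities(list(snet(NULL, -1000),
                                  snet(rbind(c("C", "D")),
                                       log(3) - 1000)))
  expect_equal(tab3s$probability, tab3$probability, tolerance = 1e-12)
  expect_error(arc_probabilities(list()), "non-empty")
})

test_that("duplicate networks keep their weight mass", {
  nets <- c(replicate(3, snet(rbind(c("A", "B")), -2), simplify = FALSE),
            list(snet(NULL, -2)))
  expect_equal(arc_probabilities(nets)$probability, 0.75,
               tolerance = 1e-12)
})

test_that("directional exclusivity holds on searched batches", {
  w <- make_small_world(5, 80, seed = 111)
  batch <- run_search_batch(w$d, NULL,
                            search_params(n_starts = 15, seed = 7))
  tab <- arc_probabilities(batch)
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
  key <- paste(tab$from, tab$to)
  rev_p <- tab$probability[match(paste(tab$to, tab$from), key)]
  rev_p[is.na(rev_p)] <- 0
  expect_true(all(tab$probability + rev_p <= 1 + 1e-12))
  expect_equal(sum(attr(tab, "weights")), 1, tolerance = 1e-12)
})

test_that("well-separated probabilities classify crisply", {
  set.seed(42)
  lo <- 0.02 + runif(10, -0.005, 0.005)
  hi <- 0.95 + runif(10, -0.005, 0.005)
  tab <- data.frame(from = paste0("a", 1:20), to = paste0("b", 1:20),
                    probability = c(lo, hi))
  cls <- classify_arcs(structure(tab,
                                 class = c("methbn_arc_probs",
                                           "data.frame")))
  expect_false(attr(cls, "fallback"))
  expect_setequal(cls$cluster[cls$probability > 0.5], "high")
  expect_setequal(cls$cluster[cls$probability < 0.5], "low")
  expect_true(all(cls$uncertainty < 0.01))

  # grid-search ML oracle over two-Gaussian mixtures agrees on the
  # posterior assignment of every arc
  x <- cls$probability
  grid <- expand.grid(mu1 = seq(0, 0.2, 0.01), mu2 = seq(0.8, 1, 0.01),
                      sd = c(0.003, 0.01, 0.03), pi1 = c(0.3, 0.5, 0.7))
  ll <- apply(grid, 1L, function(g) {
    sum(log(g[["pi1"]] * dnorm(x, g[["mu1"]], g[["sd"]]) +
              (1 - g[["pi1"]]) * dnorm(x, g[["mu2"]], g[["sd"]])))
  })
  b <- grid[which.max(ll), ]
  post1 <- b$pi1 * dnorm(x, b$mu1, b$sd) /
    (b$pi1 * dnorm(x, b$mu1, b$sd) +
       (1 - b$pi1) * dnorm(x, b$mu2, b$sd))
  expect_identical(cls$cluster, ifelse(post1 < 0.5, "high", "low"))
  expect_true(all(abs((1 - pmax(post1, 1 - post1)) -
                        cls$uncertainty) < 0.01))
})

test_that("degenerate inputs fall back to a flagged hard threshold", {
  same <- data.frame(from = c("A", "B"), to = c("B", "C"),
                     probability = c(0.7, 0.7))
  cls <- classify_arcs(structure(same, class = c("methbn_arc_probs",
                                                 "data.frame")))
  expect_true(attr(cls, "fallback"))
  expect_setequal(cls$cluster, "high")
  expect_equal(cls$uncertainty, c(0, 0))

  one <- data.frame(from = "A", to = "B", probability = 0.4)
  cls1 <- classify_arcs(structure(one, class = c("methbn_arc_probs",
                                                 "data.frame")))
  expect_true(attr(cls1, "fallback"))
  expect_equal(cls1$cluster, "low")
})

test_that("mixture recovery separates two well-separated Betas", {
  set.seed(99)
  x <- c(rbeta(100, 1, 25), rbeta(100, 25, 1))
  lab_true <- rep(c("low", "high"), each = 100)
  tab <- data.frame(from = paste0("a", 1:200), to = paste0("b", 1:200),
                    probability = x)
  cls <- classify_arcs(structure(tab, class = c("methbn_arc_probs",
                                                "data.frame")))
  expect_gte(mean(cls$cluster == lab_true), 0.99)
})

test_that("selection gates on label then inclusive thresholds", {
  cls <- structure(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
               probability = c(0.50, 0.49, 0.95),
               cluster = c("high", "high", "low"),
               uncertainty = c(0.01, 0.001, 0.0)),
    class = c("methbn_arc_classes", "data.frame"), fallback = FALSE)
  sel <- select_high_arcs(cls)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$from, "A")  # p = 0.50, unc = 0.01: both bounds inclusive
})
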