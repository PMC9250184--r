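rep_df <- function(...) {
  arcs <- list(...)
  data.frame(from = vapply(arcs, `[[`, "", 1L),
             to = vapply(arcs, `[[`, "", 2L),
             probability = vapply(arcs, function(a)
               as.numeric(a[[3L]]), numeric(1L)))
}

test_that("consensus is the intersection with averaged probabilities", {
  r1 <- rep_df(c("a", "b", 0.9), c("c", "d", 0.8))
  r2 <- rep_df(c("c", "d", 0.6), c("e", "f", 0.7))
  expect_warning(cons0 <- build_consensus(list(rep_df(c("a", "b", 1)),
                                               rep_df(c("x", "y", 1)))),
                 "empty")
  expect_equal(nrow(cons0$arcs), 0L)
  cons <- build_consensus(list(r1, r2))
  expect_equal(cons$arcs$from, "c")
  expect_equal(cons$arcs$to, "d")
  expect_equal(cons$arcs$probability, 0.7)
  expect_equal(cons$nodes, c("c", "d"))  # incident variables only
  # idempotence on identical repetitions
  same <- build_consensus(list(r1, r1, r1))
  expect_equal(same$arcs[order(same$arcs$from), c("from", "to")],
               r1[order(r1$from), c("from", "to")],
               ignore_attr = TRUE)
  expect_equal(sort(same$arcs$probability), sort(r1$probability))
  expect_error(build_consensus(list()), "non-empty")
})

test_that("consensus shrinks monotonically and stays within bounds", {
  w <- make_small_world(6, 150, seed = 121)
  bl <- build_blocklist(suppressWarnings(pairwise_chisq(w$d)), 0.25)
  reps <- run_repetitions(w$d, bl, search_params(n_starts = 8, seed = 5),
                          n_reps = 4)
  prev <- NULL
  for (k in seq_along(reps)) {
    cons <- suppressWarnings(build_consensus(reps[seq_len(k)]))
    keys <- paste(cons$arcs$from, cons$arcs$to)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
    # each consensus probability within [min, max] of its repetitions
    for (i in seq_len(nrow(cons$arcs))) {
      per_rep <- vapply(reps[seq_len(k)], function(r) {
        r$probability[r$from == cons$arcs$from[i] &
                        r$to == cons$arcs$to[i]]
      }, numeric(1L))
      expect_gte(cons$arcs$probability[i], min(per_rep) - 1e-12)
      expect_lte(cons$arcs$probability[i], max(per_rep) + 1e-12)
    }
  }
  # n_reps = 1: consensus equals that repetition's selection
  c1 <- suppressWarnings(build_consensus(reps[1L]))
  expect_setequal(paste(c1$arcs$from, c1$arcs$to),
                  paste(reps[[1L]]$from, reps[[1L]]$to))
  # same master seed reproduces the repetition results exactly
  reps2 <- run_repetitions(w$d, bl, search_params(n_starts = 8, seed = 5),
                           n_reps = 4)
  expect_identical(lapply(reps, as.data.frame),
                   lapply(reps2, as.data.frame))
})

test_that("skeleton-level intersection tolerates direction flips", {
  r1 <- rep_df(c("a", "b", 0.9), c("c", "d", 0.8))
  r2 <- rep_df(c("b", "a", 0.7), c("c", "d", 0.6))
  # directed intersection loses the flipped a-b arc
  cons_dir <- build_consensus(list(r1, r2))
  expect_equal(nrow(cons_dir$arcs), 1L)
  # skeleton intersection keeps it, orienting by majority then
  # lexicographic tie-break, with the mean pair probability
  cons_sk <- build_consensus(list(r1, r2), directed = FALSE)
  expect_equal(nrow(cons_sk$arcs), 2L)
  ab <- cons_sk$arcs[cons_sk$arcs$probability == 0.8, ]
  expect_equal(ab$from, "a")
  expect_equal(ab$to, "b")
  # a repetition selecting both directions contributes their total mass
  r3 <- rep_df(c("a", "b", 0.5), c("b", "a", 0.4))
  both <- build_consensus(list(r3, rep_df(c("b", "a", 0.6))),
                          directed = FALSE)
  expect_equal(both$arcs$probability, mean(c(0.9, 0.6)))
  expect_equal(both$arcs$from, "b")  # majority orientation 2:1
})

test_that("markov blanket covers parents, children and spouses", {
  chain <- rep_df(c("A", "B", 1), c("B", "C", 1))
  expect_setequal(markov_blanket(chain, "B")$members, c("A", "C"))
  vstruct <- rep_df(c("A", "C", 1), c("B", "C", 1))
  expect_setequal(markov_blanket(vstruct, "A")$members, c("B", "C"))
  expect_error(markov_blanket(chain, "Z"), "unknown target")
  # a universe variable with no arcs has an empty blanket
  cons <- build_consensus(list(chain), universe = c("A", "B", "C", "D"))
  expect_equal(markov_blanket(cons, "D")$members, character(0))
})

test_that("structural blanket equals the d-separation oracle", {
  for (seed in 1:40) {
    v <- 4L + (seed %% 5L)
    g <- random_dag(paste0("N", seq_len(v)), arc_prob = 0.35,
                    seed = seed)
    arcs <- dag_arcs(g)
    df <- data.frame(from = arcs[, 1L], to = arcs[, 2L],
                     probability = rep(1, nrow(arcs)))
    target <- paste0("N", 1L + (seed %% v))
    got <- markov_blanket(
      suppressWarnings(build_consensus(list(df), universe = g$nodes)),
      target)$members
    want <- g$nodes[mb_oracle(g$amat, match(target, g$nodes))]
    expect_setequal(got, sort(want))
  }
})
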