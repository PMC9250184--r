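#' Repeated batch -> average -> select cycles
#'
#' Runs the whole per-repetition protocol (`run_search_batch()` then
#' [arc_probabilities()], [classify_arcs()], [select_high_arcs()])
#' `n_reps` times, each repetition with an independent seed derived from
#' the master seed. One family-score cache is shared across all
#' repetitions (same dataset, same prior).
#'
#' @param d A [binary_dataset()].
#' @param blocklist A [build_blocklist()] result or `NULL`.
#' @param params A [search_params()]; `params$seed` is the master seed.
#' @param n_reps Number of repetitions (study protocol: 50).
#' @param prob_min,unc_max Selection thresholds passed to
#'   [select_high_arcs()].
#' @return List of length `n_reps`; each element the repetition's
#'   selected-arc data frame, with the repetition seed as attribute
#'   `"seed"`.
#' @export
run_repetitions <- function(d, blocklist = NULL,
                            params = search_params(), n_reps = 50L,
                            prob_min = 0.5, unc_max = 0.01) {
  n_reps <- check_count_arg(n_reps, "n_reps")
  cache <- score_cache()
  lapply(seq_len(n_reps), function(r) {
    rp <- params
    rp$seed <- derive_seed(params$seed, 100000 + r)
    batch <- run_search_batch(d, blocklist, params = rp, cache = cache)
    classes <- classify_arcs(arc_probabilities(batch),
                             prob_min = prob_min)
    sel <- select_high_arcs(classes, prob_min = prob_min,
                            unc_max = unc_max)
    attr(sel, "seed") <- rp$seed
    sel
  })
}

#' Consensus network from repetition results
#'
#' The consensus keeps the directed arcs present in the selected set of
#' every repetition; each surviving arc is weighted by the arithmetic
#' mean of its per-repetition probabilities. Nodes are the variables
#' incident to at least one consensus arc. The consensus is an arc
#' summary, not a single DAG, so it is not forced acyclic.
#'
#' @param reps Non-empty list of selected-arc data frames
#'   (`from`, `to`, `probability`), e.g. from [run_repetitions()].
#' @param universe Optional character vector of all variable names (used
#'   by [markov_blanket()] to validate targets that have no consensus
#'   arcs); defaults to the nodes seen in `reps`.
#' @param directed If `TRUE` (default) arcs must match in direction
#'   across repetitions. If `FALSE` the intersection is skeleton-level:
#'   an arc survives if the unordered pair is selected in every
#'   repetition, its per-repetition probability is the total selected
#'   mass of the pair, and the reported orientation is the one selected
#'   most often (ties break lexicographically). Offered because BDe
#'   score equivalence can flip directions between searches.
#' @return An object of class `methbn_consensus`: list with `arcs` (data
#'   frame `from`, `to`, `probability`, sorted by decreasing probability
#'   then from/to), `nodes`, `universe`, `n_repetitions` and `directed`.
#' @export
build_consensus <- function(reps, universe = NULL, directed = TRUE) {
  if (!length(reps)) stop("reps must be non-empty")
  keysets <- if (directed) {
    lapply(reps, function(r) arc_key(r$from, r$to))
  } else {
    lapply(reps, function(r) arc_key(pmin(r$from, r$to),
                                     pmax(r$from, r$to)))
  }
  common <- Reduce(intersect, lapply(keysets, unique))
  if (!length(common)) {
    warning("no arc is common to all repetitions; consensus is empty")
    arcs <- data.frame(from = character(0), to = character(0),
                       probability = numeric(0))
  } else {
    probs <- vapply(common, function(k) {
      mean(vapply(seq_along(reps), function(i) {
        sum(reps[[i]]$probability[keysets[[i]] == k])
      }, numeric(1L)))
    }, numeric(1L))
    ft <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
    arcs <- data.frame(from = ft[, 1L], to = ft[, 2L],
                       probability = unname(probs),
                       stringsAsFactors = FALSE)
    if (!directed) {
      for (i in seq_len(nrow(arcs))) {
        k <- common[[i]]
        votes_fwd <- sum(vapply(seq_along(reps), function(j) {
          sum(reps[[j]]$from == arcs$from[i] &
                reps[[j]]$to == arcs$to[i])
        }, numeric(1L)))
        votes_rev <- sum(vapply(seq_along(reps), function(j) {
          sum(reps[[j]]$from == arcs$to[i] &
                reps[[j]]$to == arcs$from[i])
        }, numeric(1L)))
        if (votes_rev > votes_fwd) {
          arcs[i, c("from", "to")] <- arcs[i, c("to", "from")]
        }
      }
    }
    arcs <- arcs[order(-arcs$probability, arcs$from, arcs$to), ,
                 drop = FALSE]
    rownames(arcs) <- NULL
  }
  nodes <- sort(unique(c(arcs$from, arcs$to)))
  if (is.null(universe)) {
    universe <- sort(unique(c(nodes,
                              unlist(lapply(reps, function(r)
                                c(r$from, r$to))))))
  }
  structure(list(arcs = arcs, nodes = nodes, universe = universe,
                 n_repetitions = length(reps), directed = directed),
            class = "methbn_consensus")
}

#' @export
print.methbn_consensus <- function(x, ...) {
  cat(sprintf("<methbn_consensus> %d arcs over %d nodes (%d repetitions)\n",
              nrow(x$arcs), length(x$nodes), x$n_repetitions))
  invisible(x)
}

#' Markov blanket of a variable in the consensus graph
#'
#' The Markov blanket of a target node is its parents, children and
#' spouses (co-parents of its children); conditioning on the blanket
#' renders the target independent of every other variable. The consensus
#' graph is treated as a directed graph as-is.
#'
#' @param x A [build_consensus()] object, or any data frame with `from`
#'   and `to` columns.
#' @param target Variable name (it may have no incident arcs).
#' @return An object of class `methbn_markov_blanket`: list with
#'   `target` and the sorted `members` character vector.
#' @examples
#' arcs <- data.frame(from = c("A", "B"), to = c("C", "C"),
#'                    probability = 1)
#' markov_blanket(arcs, "A")$members  # child C, spouse B
#' @export
markov_blanket <- function(x, target) {
  if (inherits(x, "methbn_consensus")) {
    arcs <- x$arcs
    universe <- x$universe
  } else {
    arcs <- as.data.frame(x)
    universe <- unique(c(arcs$from, arcs$to))
  }
  if (!target %in% unique(c(universe, arcs$from, arcs$to))) {
    stop("unknown target variable: ", target)
  }
  parents <- arcs$from[arcs$to == target]
  children <- arcs$to[arcs$from == target]
  spouses <- arcs$from[arcs$to %in% children]
  members <- setdiff(sort(unique(c(parents, children, spouses))), target)
  structure(list(target = target, members = members),
            class = "methbn_markov_blanket")
}

#' @export
print.methbn_markov_blanket <- function(x, ...) {
  cat(sprintf("Markov blanket of '%s': %s\n", x$target,
              if (length(x$members)) paste(x$members, collapse = ", ")
              else "(empty)"))
  invisible(x)
}
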