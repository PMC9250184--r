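#' Ground-truth Bayesian networks for simulation
#'
#' A `methbn_gtbn` couples a DAG over binary feature nodes plus one binary
#' condition node with a full set of conditional probability tables
#' (CPTs). Each CPT row gives P(state = 1) for one configuration of the
#' node's parents; feature state 0 later maps to a zero read count, so the
#' CPTs control the zero inflation of the sampled count matrix.
#'
#' `ground_truth_bn()` is the low-level constructor for hand-built
#' networks (used heavily in tests); `generate_ground_truth()` draws a
#' random network of a given size.
#'
#' @param dag A [new_dag()] object whose nodes are the features plus the
#'   condition node.
#' @param cpts Named list, one element per node: a numeric vector of
#'   P(state = 1) of length `2^k` for a node with `k` parents. Rows are
#'   ordered by the binary parent configuration with the
#'   alphabetically-first parent as the least significant bit (all parents
#'   sorted by name).
#' @param condition Name of the condition node (default `"Treatment"`).
#' @return An object of class `methbn_gtbn` with fields `dag`, `cpts`,
#'   `condition` and `zero_inflation` (per-feature marginal P(state 0),
#'   estimated by fixed-seed forward sampling).
#' @export
ground_truth_bn <- function(dag, cpts, condition = "Treatment") {
  stopifnot(is_dag(dag))
  if (!condition %in% dag$nodes) stop("condition node not in dag")
  if (!setequal(names(cpts), dag$nodes)) {
    stop("cpts must be named by exactly the dag's nodes")
  }
  for (nd in dag$nodes) {
    k <- length(dag_parents(dag, nd))
    p <- cpts[[nd]]
    if (!is.numeric(p) || length(p) != 2^k) {
      stop("CPT for ", nd, " must have length 2^", k)
    }
    if (any(p < 0 | p > 1)) stop("CPT probabilities for ", nd,
                                 " must lie in [0, 1]")
  }
  bn <- structure(list(dag = dag, cpts = cpts, condition = condition,
                       zero_inflation = NULL),
                  class = "methbn_gtbn")
  feats <- setdiff(dag$nodes, condition)
  states <- .ancestral_sample(bn, 10000L, seed = 987654321L)
  bn$zero_inflation <- colMeans(states[, feats, drop = FALSE] == 0L)
  bn
}

#' @export
print.methbn_gtbn <- function(x, ...) {
  cat(sprintf("<methbn_gtbn> %d features + condition '%s', %d arcs\n",
              length(x$dag$nodes) - 1L, x$condition, n_arcs(x$dag)))
  invisible(x)
}

#' Draw a random ground-truth network
#'
#' Nodes (features `F1..Fn` plus the condition) are placed in a random
#' topological order; each order-respecting arc is included independently
#' with probability `arc_density`, subject to `max_parents`. CPT entries
#' are drawn uniformly on `[cpt_floor, 1 - cpt_floor]`, keeping every
#' conditional distribution away from 0/1 degeneracy. The condition node
#' is an ordinary node: it may have parents and children.
#'
#' @param n_features Number of feature nodes (>= 1).
#' @param max_parents Maximum number of parents per node.
#' @param arc_density Probability of including each eligible arc.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param cpt_floor Distance of CPT entries from 0 and 1 (default 0.05).
#' @param condition Name of the condition node.
#' @return A `methbn_gtbn`.
#' @examples
#' bn <- generate_ground_truth(10, max_parents = 3, seed = 42)
#' topo_sort(bn$dag)
#' @export
generate_ground_truth <- function(n_features, max_parents = 3L,
                                  arc_density = 0.15, seed = 1L,
                                  cpt_floor = 0.05,
                                  condition = "Treatment") {
  n_features <- check_count_arg(n_features, "n_features")
  max_parents <- check_count_arg(max_parents, "max_parents")
  stopifnot(arc_density >= 0, arc_density < 1,
            cpt_floor >= 0, cpt_floor < 0.5)
  nodes <- c(paste0("F", seq_len(n_features)), condition)
  with_seed(seed, {
    ord <- sample(nodes)
    g <- new_dag(nodes)
    v <- length(nodes)
    for (j in seq_len(v)[-1L]) {
      cand <- ord[seq_len(j - 1L)]
      take <- cand[stats::runif(length(cand)) < arc_density]
      if (length(take) > max_parents) {
        take <- sample(take, max_parents)
      }
      for (p in take) g <- add_arc(g, p, ord[[j]])
    }
    cpts <- lapply(nodes, function(nd) {
      k <- length(dag_parents(g, nd))
      stats::runif(2^k, cpt_floor, 1 - cpt_floor)
    })
    names(cpts) <- nodes
    ground_truth_bn(g, cpts, condition = condition)
  })
}

# Ancestral sampling of binary node states; returns an n x v 0/1 integer
# matrix with node-name columns.
.ancestral_sample <- function(bn, n, seed = NULL) {
  with_seed(seed, {
    ord <- topo_sort(bn$dag)
    states <- matrix(0L, n, length(bn$dag$nodes),
                     dimnames = list(NULL, bn$dag$nodes))
    for (nd in ord) {
      pa <- sort(dag_parents(bn$dag, nd))
      cpt <- bn$cpts[[nd]]
      if (length(pa) == 0L) {
        p1 <- rep(cpt[[1L]], n)
      } else {
        cfg <- rep(1L, n)
        mult <- 1L
        for (p in pa) {
          cfg <- cfg + mult * states[, p]
          mult <- mult * 2L
        }
        p1 <- cpt[cfg]
      }
      states[, nd] <- as.integer(stats::runif(n) < p1)
    }
    states
  })
}

#' Count matrices of methylation reads
#'
#' A `methbn_count_matrix` holds a sample-by-feature table of non-negative
#' integer read counts over differentially methylated regions (DMRs)
#' together with a binary condition value per sample (0 = control,
#' 1 = stress). This mirrors a 46-individual x 60-DMR study table with
#' counts in 0..39 and a `Treatment` column.
#'
#' @param counts Integer matrix, samples x features, with column names.
#' @param condition Integer vector of 0/1 condition values, one per sample.
#' @param condition_name Name of the condition variable.
#' @return An object of class `methbn_count_matrix`.
#' @export
count_matrix <- function(counts, condition, condition_name = "Treatment") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have feature names")
  if (anyDuplicated(colnames(counts))) stop("duplicate feature names")
  if (condition_name %in% colnames(counts)) {
    stop("feature names must not include the condition name")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    i <- arrayInd(bad[[1L]], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell: sample %d, feature '%s'",
      i[1L], colnames(counts)[i[2L]]))
  }
  if (length(condition) != nrow(counts)) {
    stop("condition must have one value per sample")
  }
  if (!all(condition %in% c(0L, 1L))) {
    stop("condition values must be 0 (control) or 1 (stress)")
  }
  if (is.null(rownames(counts)) && nrow(counts) > 0L) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  structure(list(counts = matrix(as.integer(counts), nrow(counts),
                                 ncol(counts), dimnames = dimnames(counts)),
                 condition = as.integer(condition),
                 condition_name = condition_name),
            class = "methbn_count_matrix")
}

#' @export
print.methbn_count_matrix <- function(x, ...) {
  cat(sprintf(
    "<methbn_count_matrix> %d samples x %d features (+ '%s': %d/%d split), counts %d..%d\n",
    nrow(x$counts), ncol(x$counts), x$condition_name,
    sum(x$condition == 0L), sum(x$condition == 1L),
    min(x$counts), max(x$counts)))
  invisible(x)
}

#' Sample a zero-inflated count matrix from a ground-truth network
#'
#' Binary states are drawn by ancestral sampling from the network. A
#' feature in state 0 emits count 0 (no methylation); a feature in state 1
#' emits a positive count `1 + Poisson(lambda)` truncated at `max_count`,
#' emulating the observed 0..39 count range with zero as the most frequent
#' value. The condition node's state becomes the condition column. Because
#' downstream analysis binarizes at zero, the positive-count law only
#' affects cosmetics, never inference.
#'
#' @param bn A `methbn_gtbn`.
#' @param n_samples Number of samples to draw (default 46, study scale).
#' @param max_count Largest emitted count (default 39).
#' @param lambda Poisson rate of positive counts minus one (default 4).
#' @param seed Integer seed.
#' @return A `methbn_count_matrix`. The latent binary states are attached
#'   as attribute `"states"` for recovery testing.
#' @export
sample_counts <- function(bn, n_samples = 46L, max_count = 39L,
                          lambda = 4, seed = 1L) {
  if (!inherits(bn, "methbn_gtbn")) stop("bn must be a methbn_gtbn")
  n_samples <- check_count_arg(n_samples, "n_samples")
  max_count <- check_count_arg(max_count, "max_count")
  if (!is_acyclic(bn$dag)) stop("bn dag must be acyclic")
  feats <- setdiff(bn$dag$nodes, bn$condition)
  with_seed(seed, {
    states <- .ancestral_sample(bn, n_samples)
    counts <- matrix(0L, n_samples, length(feats),
                     dimnames = list(paste0("S", seq_len(n_samples)), feats))
    on_idx <- which(states[, feats, drop = FALSE] == 1L)
    if (length(on_idx)) {
      pos <- 1L + stats::rpois(length(on_idx), lambda)
      pos <- pmin(pos, max_count)
      counts[on_idx] <- pos
    }
    m <- count_matrix(counts, states[, bn$condition],
                      condition_name = bn$condition)
    attr(m, "states") <- states
    m
  })
}
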