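# Independent oracles used across the suite. These deliberately avoid the
# package's incremental/caching code paths: scores are recomputed from the
# closed form with explicit per-configuration loops, DAG sets come from
# exhaustive enumeration, and conditional independence comes from the
# moralized-ancestral-graph criterion.

# Direct, loop-based BDe family score (no caching, no vectorized
# configuration encoding).
naive_family_score <- function(x, child, parents, ess) {
  q <- 2^length(parents)
  a <- ess / (2 * q)
  total <- 0
  for (j in seq_len(q)) {
    if (length(parents)) {
      bits <- as.integer(intToBits(j - 1L))[seq_along(parents)]
      in_cfg <- rep(TRUE, nrow(x))
      for (t in seq_along(parents)) {
        in_cfg <- in_cfg & (x[, parents[t]] == bits[t])
      }
    } else {
      in_cfg <- rep(TRUE, nrow(x))
    }
    n1 <- sum(x[in_cfg, child] == 1)
    n0 <- sum(in_cfg) - n1
    total <- total + lgamma(2 * a) - lgamma(2 * a + n0 + n1) +
      lgamma(a + n0) - lgamma(a) + lgamma(a + n1) - lgamma(a)
  }
  total
}

# Full-graph score as a plain sum of naive family scores over an
# adjacency matrix (rows = parents of columns).
naive_bde_score <- function(x, amat, ess) {
  s <- 0
  for (j in seq_len(ncol(amat))) {
    s <- s + naive_family_score(x, j, which(amat[, j] == 1L), ess)
  }
  s
}

# All DAGs on n labelled nodes: each unordered pair is absent, forward
# or backward (3 states), cyclic results filtered out.
enumerate_dags <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  for (code in 0:(3^np - 1)) {
    amat <- matrix(0L, n, n)
    c0 <- code
    for (p in seq_len(np)) {
      s <- c0 %% 3
      c0 <- c0 %/% 3
      if (s == 1) amat[pairs[p, 1L], pairs[p, 2L]] <- 1L
      if (s == 2) amat[pairs[p, 2L], pairs[p, 1L]] <- 1L
    }
    if (is_acyclic(amat)) out[[length(out) + 1L]] <- amat
  }
  out
}

# Second, cruder enumeration (all 2^(n(n-1)) arc subsets, including
# 2-cycles, filtered) to cross-check enumerate_dags counts.
count_dags_bruteforce <- function(n) {
  cells <- which(diag(n) == 0)
  cnt <- 0L
  for (code in 0:(2^length(cells) - 1)) {
    amat <- matrix(0L, n, n)
    amat[cells] <- as.integer(intToBits(code))[seq_along(cells)]
    if (all(amat * t(amat) == 0L) && is_acyclic(amat)) cnt <- cnt + 1L
  }
  cnt
}

# d-separation of x and y given set z in the DAG amat, via the
# moralized ancestral graph: keep ancestors of {x, y} U z, marry
# co-parents, drop directions, delete z, test connectivity.
dsep_oracle <- function(amat, x, y, z = integer(0)) {
  anc <- unique(c(x, y, z))
  repeat {
    pa <- which(rowSums(amat[, anc, drop = FALSE]) > 0)
    grown <- union(anc, pa)
    if (length(grown) == length(anc)) break
    anc <- grown
  }
  sub <- amat[anc, anc, drop = FALSE]
  m <- (sub + t(sub)) > 0
  for (j in seq_along(anc)) {
    pars <- which(sub[, j] == 1L)
    if (length(pars) > 1L) {
      m[pars, pars] <- TRUE
    }
  }
  diag(m) <- FALSE
  drop <- which(anc %in% z)
  if (length(drop)) {
    m[drop, ] <- FALSE
    m[, drop] <- FALSE
  }
  xi <- match(x, anc)
  yi <- match(y, anc)
  seen <- logical(length(anc))
  frontier <- xi
  seen[xi] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(m[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (yi %in% nxt) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

# Markov blanket by brute force: v belongs to the blanket of t iff t and
# v are NOT d-separated given all remaining variables.
mb_oracle <- function(amat, target) {
  v <- ncol(amat)
  others <- setdiff(seq_len(v), target)
  others[vapply(others, function(o) {
    !dsep_oracle(amat, target, o, setdiff(others, o))
  }, logical(1L))]
}

# Signature of all conditional-independence statements a DAG encodes;
# two DAGs are Markov equivalent iff their signatures agree.
ci_signature <- function(amat) {
  v <- ncol(amat)
  out <- logical(0)
  for (x in seq_len(v - 1L)) {
    for (y in seq.int(x + 1L, v)) {
      rest <- setdiff(seq_len(v), c(x, y))
      subsets <- if (length(rest)) {
        unlist(lapply(0:length(rest), function(k) {
          utils::combn(rest, k, simplify = FALSE)
        }), recursive = FALSE)
      } else {
        list(integer(0))
      }
      for (z in subsets) {
        out <- c(out, dsep_oracle(amat, x, y, z))
      }
    }
  }
  paste(as.integer(out), collapse = "")
}

# Shared small-world builder: random ground truth + sampled counts +
# binary dataset for a given seed.
make_small_world <- function(n_features, n_samples, seed,
                             arc_density = 0.3, max_parents = 2) {
  bn <- generate_ground_truth(n_features, max_parents = max_parents,
                              arc_density = arc_density, seed = seed)
  m <- sample_counts(bn, n_samples = n_samples,
                     seed = derive_seed(seed, 1L))
  list(bn = bn, m = m, d = binarize_counts(m))
}

# Ground truth with strong additive parent effects: with k parents the
# activation probability interpolates evenly from `lo` (no parent
# active) to `hi` (all active), so every single parent has a strong,
# chi-square-detectable marginal effect and collider configurations
# remain identifiable (an OR gate would saturate and hide individual
# parents).
make_strong_truth <- function(dag, condition = "Treatment",
                              lo = 0.1, hi = 0.9, root_p = 0.5) {
  cpts <- lapply(dag$nodes, function(nd) {
    k <- length(dag_parents(dag, nd))
    if (k == 0L) return(root_p)
    cfg <- expand.grid(rep(list(0:1), k))
    lo + (hi - lo) * rowSums(cfg) / k
  })
  names(cpts) <- dag$nodes
  ground_truth_bn(dag, cpts, condition = condition)
}
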