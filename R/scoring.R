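#' Bayesian Dirichlet equivalent (BDe) scoring of discrete DAGs
#'
#' The BDe score is the log marginal likelihood of the data under a
#' Dirichlet prior spread uniformly over parent configurations and child
#' states: with `q` parent configurations, `r` child states and
#' equivalent sample size `ess`, every Dirichlet pseudo-count is
#' `alpha = ess / (q * r)`. The score decomposes over node families
#'
#'   sum_j \[ lgamma(a_j) - lgamma(a_j + N_j)
#'            + sum_k ( lgamma(alpha + N_jk) - lgamma(alpha) ) \]
#'
#' with `a_j = r * alpha` and `N_jk` the number of samples with child
#' state `k` under parent configuration `j`. BDe is score-equivalent:
#' Markov-equivalent DAGs receive identical scores.
#'
#' `family_score()` scores one node given a parent set; `bde_score()`
#' sums families over a whole DAG. Both work in the log domain via
#' `lgamma`, and all data here are binary (two child states).
#'
#' @param d A [binary_dataset()].
#' @param child A variable name.
#' @param parents Character vector of parent variable names (may be
#'   empty).
#' @param ess Equivalent (imaginary) sample size, a positive real;
#'   default 1.
#' @param cache Optional cache environment from [score_cache()].
#' @return Log-score (a single real).
#' @examples
#' d <- binary_dataset(cbind(A = c(0L, 1L), Treatment = c(0L, 1L)))
#' family_score(d, "A", character(0), ess = 1)  # log(1/8)
#' @export
family_score <- function(d, child, parents = character(0), ess = 1,
                         cache = NULL) {
  if (!inherits(d, "methbn_binary_dataset")) {
    stop("d must be a methbn_binary_dataset")
  }
  if (!is.numeric(ess) || length(ess) != 1L || !is.finite(ess) ||
      ess <= 0) {
    stop("ess must be a positive real")
  }
  vars <- variables(d)
  if (!child %in% vars) stop("unknown child variable: ", child)
  if (length(parents)) {
    if (child %in% parents) stop("child must not be among its parents")
    unknown <- setdiff(parents, vars)
    if (length(unknown)) stop("unknown parent variable(s): ",
                              paste(unknown, collapse = ", "))
  }
  if (!is.null(cache)) {
    key <- paste(child, paste(sort(parents), collapse = ","), ess,
                 sep = "|")
    hit <- cache$scores[[key]]
    if (!is.null(hit)) return(hit)
    val <- .family_logscore(d$values, child, parents, ess)
    cache$scores[[key]] <- val
    return(val)
  }
  .family_logscore(d$values, child, parents, ess)
}

# Vectorized family log-score on a 0/1 matrix.
.family_logscore <- function(x, child, parents, ess) {
  n <- nrow(x)
  q <- 2^length(parents)
  if (length(parents)) {
    cfg <- rep(1L, n)
    mult <- 1L
    for (p in parents) {
      cfg <- cfg + mult * x[, p]
      mult <- mult * 2L
    }
  } else {
    cfg <- rep(1L, n)
  }
  njk <- tabulate(cfg + q * x[, child], nbins = 2L * q)
  n0 <- njk[seq_len(q)]
  n1 <- njk[q + seq_len(q)]
  a <- ess / (2 * q)
  sum(lgamma(2 * a) - lgamma(2 * a + n0 + n1) +
        lgamma(a + n0) - lgamma(a) +
        lgamma(a + n1) - lgamma(a))
}

#' A family-score cache
#'
#' Memoizes family scores by `(child, sorted parent set)`. The repeated
#' random-restart protocol revisits the same families constantly, so one
#' cache is shared across all searches and repetitions that use the same
#' dataset and `ess`.
#'
#' @return An environment with a `scores` environment inside.
#' @export
score_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$scores <- new.env(parent = emptyenv())
  e
}

#' @rdname family_score
#' @param g A [new_dag()] whose nodes equal the dataset's variables.
#' @export
bde_score <- function(d, g, ess = 1, cache = NULL) {
  if (!is_dag(g)) stop("g must be a methbn_dag")
  if (!setequal(g$nodes, variables(d))) {
    stop("graph nodes must equal dataset variables")
  }
  s <- 0
  for (nd in g$nodes) {
    s <- s + family_score(d, nd, dag_parents(g, nd), ess = ess,
                          cache = cache)
  }
  s
}

#' Score change of a single-arc move
#'
#' Computes `bde_score(after) - bde_score(before)` for an add, delete or
#' reverse of one arc, recomputing only the affected families (the child
#' for add/delete; both endpoints for a reverse). Illegal moves (cycle
#' creation, missing/duplicate arc) return the sentinel `NA` rather than
#' raising, so search loops can enumerate candidates freely.
#'
#' @param d A [binary_dataset()].
#' @param g Current DAG.
#' @param move One of `"add"`, `"delete"`, `"reverse"`.
#' @param from,to Arc endpoints.
#' @param ess Equivalent sample size.
#' @param cache Optional [score_cache()].
#' @return The score delta, or `NA_real_` if the move is illegal.
#' @export
delta_score <- function(d, g, move = c("add", "delete", "reverse"),
                        from, to, ess = 1, cache = NULL) {
  move <- match.arg(move)
  i <- match(from, g$nodes); j <- match(to, g$nodes)
  if (is.na(i) || is.na(j) || i == j) return(NA_real_)
  fam <- function(child, parents) {
    family_score(d, child, parents, ess = ess, cache = cache)
  }
  pa_to <- dag_parents(g, to)
  if (move == "add") {
    if (g$amat[i, j] == 1L || g$amat[j, i] == 1L) return(NA_real_)
    if (.has_path(g$amat, j, i)) return(NA_real_)
    return(fam(to, c(pa_to, from)) - fam(to, pa_to))
  }
  if (g$amat[i, j] != 1L) return(NA_real_)
  if (move == "delete") {
    return(fam(to, setdiff(pa_to, from)) - fam(to, pa_to))
  }
  # reverse: drop from->to, add to->from
  amat2 <- g$amat
  amat2[i, j] <- 0L
  if (.has_path(amat2, i, j)) return(NA_real_)
  pa_from <- dag_parents(g, from)
  (fam(to, setdiff(pa_to, from)) - fam(to, pa_to)) +
    (fam(from, c(pa_from, to)) - fam(from, pa_from))
}
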