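#' Score-weighted arc probabilities
#'
#' Model averaging over a batch of scored networks: network `i` gets
#' weight `w_i = exp(s_i - s_max) / sum_j exp(s_j - s_max)` (softmax over
#' BDe log-scores, i.e. posterior-proportional weighting under a uniform
#' structure prior), and an arc's probability of belonging to a
#' high-scoring network is the total weight of the networks containing
#' it. Duplicate networks keep their weight mass. Arcs absent from every
#' network are omitted (probability 0 implicitly).
#'
#' @param batch Non-empty list of networks from [run_search_batch()].
#' @return An object of class `methbn_arc_probs`: data frame with
#'   columns `from`, `to`, `probability` (sorted by decreasing
#'   probability, then from/to), with the normalized `weights` vector as
#'   an attribute.
#' @examples
#' # two networks with log-scores 0 and log(3): weights 1/4 and 3/4
#' @export
arc_probabilities <- function(batch) {
  if (!length(batch)) stop("batch must be non-empty")
  scores <- vapply(batch, function(x) x$score, numeric(1L))
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(batch)) {
    arcs <- dag_arcs(batch[[i]]$dag)
    for (k in seq_len(nrow(arcs))) {
      key <- arc_key(arcs[k, 1L], arcs[k, 2L])
      prev <- acc[[key]]
      acc[[key]] <- if (is.null(prev)) w[[i]] else prev + w[[i]]
    }
  }
  keys <- ls(acc, sorted = TRUE)
  if (length(keys)) {
    ft <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    tab <- data.frame(from = ft[, 1L], to = ft[, 2L],
                      probability = pmin(
                        vapply(keys, function(k) acc[[k]], numeric(1L)), 1),
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$probability, tab$from, tab$to), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(from = character(0), to = character(0),
                      probability = numeric(0))
  }
  structure(tab, class = c("methbn_arc_probs", "data.frame"),
            weights = w)
}

# Two-component 1-D Gaussian mixture fitted by EM with quantile
# initialization (means at the 25th/75th percentiles) and a common
# variance: with a few dozen points the free-variance likelihood is
# unbounded (a component can collapse onto near-coincident values),
# which mislabels genuine high-probability arcs as uncertain. Returns
# NULL on collapse so the caller can fall back to a hard threshold.
.em_gmm2 <- function(x, max_iter = 500L, tol = 1e-8,
                     var_floor = 1e-6) {
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (mu[[1L]] == mu[[2L]]) return(NULL)
  s2 <- rep(max(stats::var(x), var_floor), 2L)
  pi_k <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lg <- cbind(log(pi_k[[1L]]) + stats::dnorm(x, mu[[1L]],
                                               sqrt(s2[[1L]]), log = TRUE),
                log(pi_k[[2L]]) + stats::dnorm(x, mu[[2L]],
                                               sqrt(s2[[2L]]), log = TRUE))
    m <- pmax(lg[, 1L], lg[, 2L])
    lse <- m + log(exp(lg[, 1L] - m) + exp(lg[, 2L] - m))
    resp <- exp(lg - lse)
    ll <- sum(lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)
    pi_k <- nk / length(x)
    mu <- colSums(resp * x) / nk
    pooled <- sum(resp * (outer(x, mu, "-"))^2) / length(x)
    s2 <- rep(max(pooled, var_floor), 2L)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (!all(is.finite(c(mu, s2, pi_k)))) return(NULL)
  list(mu = mu, s2 = s2, pi = pi_k, resp = resp)
}

#' Classify arc probabilities into high/low clusters
#'
#' Fits a two-component one-dimensional Gaussian mixture to the arc
#' probabilities by EM (quantile initialization, so the fit is
#' deterministic). The component with the larger mean is labelled
#' `"high"`; each arc's uncertainty is one minus its maximum posterior
#' responsibility. Degenerate inputs (fewer than 4 distinct probability
#' values, or EM collapse) fall back to a hard threshold at `prob_min`
#' with uncertainty 0, flagged via the `fallback` attribute.
#'
#' @param table A [arc_probabilities()] result.
#' @param prob_min Threshold used by the degenerate-input fallback.
#' @param max_iter,tol,var_floor EM controls.
#' @return An object of class `methbn_arc_classes`: the table with added
#'   columns `cluster` (`"high"`/`"low"`) and `uncertainty`, plus a
#'   logical attribute `fallback`.
#' @export
classify_arcs <- function(table, prob_min = 0.5, max_iter = 500L,
                          tol = 1e-8, var_floor = 1e-6) {
  if (!nrow(table)) stop("table must be non-empty")
  x <- table$probability
  fallback <- length(unique(x)) < 4L
  fit <- if (!fallback) {
    .em_gmm2(x, max_iter = max_iter, tol = tol, var_floor = var_floor)
  }
  if (is.null(fit)) fallback <- TRUE
  if (fallback) {
    cluster <- ifelse(x >= prob_min, "high", "low")
    uncertainty <- rep(0, length(x))
  } else {
    hi <- which.max(fit$mu)
    cluster <- ifelse(max.col(fit$resp, ties.method = "first") == hi,
                      "high", "low")
    uncertainty <- 1 - pmax(fit$resp[, 1L], fit$resp[, 2L])
  }
  out <- table
  out$cluster <- cluster
  out$uncertainty <- uncertainty
  structure(out, class = c("methbn_arc_classes", "data.frame"),
            fallback = fallback)
}

#' Select highly probable arcs
#'
#' Keeps arcs in the high-probability cluster with probability at least
#' `prob_min` and classification uncertainty at most `unc_max` (both
#' bounds inclusive; the cluster label gates before the thresholds).
#'
#' @param c A [classify_arcs()] result.
#' @param prob_min Minimum probability (default 0.5).
#' @param unc_max Maximum uncertainty (default 0.01).
#' @return Data frame of selected arcs (`from`, `to`, `probability`,
#'   `uncertainty`); zero rows is a valid result.
#' @export
select_high_arcs <- function(c, prob_min = 0.5, unc_max = 0.01) {
  stopifnot(inherits(c, "methbn_arc_classes"))
  keep <- c$cluster == "high" & c$probability >= prob_min &
    c$uncertainty <= unc_max
  out <- as.data.frame(c)[keep, c("from", "to", "probability",
                                  "uncertainty"), drop = FALSE]
  rownames(out) <- NULL
  out
}
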