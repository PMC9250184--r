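#' Search parameters
#'
#' Bundles the knobs of the random-restart tabu search protocol. Defaults
#' mirror the study protocol (100 searches per batch) and common tabu
#' defaults where the protocol is silent: tabu tenure 10 and up to 10
#' consecutive non-improving accepted moves.
#'
#' @param n_starts Number of random-restart searches per batch.
#' @param tabu_length Tabu tenure (iterations a reversed move stays
#'   forbidden); 0 disables the tabu list.
#' @param max_iter Hard cap on search iterations.
#' @param max_noimprove Consecutive non-improving accepted moves allowed
#'   before the search stops.
#' @param ess Equivalent sample size of the BDe prior.
#' @param seed Master seed; per-search seeds are derived by
#'   [derive_seed()].
#' @param max_parents Optional cap on parents per node (`Inf` = none).
#'   With ~46 samples the BDe score supports recovery of up to three
#'   parents per node, but no hard cap is imposed by default.
#' @param arc_prob Arc-inclusion probability of random starting DAGs;
#'   `NULL` means `2 / (v - 1)` (about one arc per node on average).
#' @return An object of class `methbn_search_params`.
#' @export
search_params <- function(n_starts = 100L, tabu_length = 10L,
                          max_iter = 500L, max_noimprove = 10L,
                          ess = 1, seed = 1L, max_parents = Inf,
                          arc_prob = NULL) {
  n_starts <- check_count_arg(n_starts, "n_starts")
  stopifnot(tabu_length >= 0, max_iter >= 1, max_noimprove >= 0,
            is.numeric(ess), ess > 0, max_parents >= 1)
  if (!is.null(arc_prob)) stopifnot(arc_prob >= 0, arc_prob <= 1)
  structure(list(n_starts = n_starts,
                 tabu_length = as.integer(tabu_length),
                 max_iter = as.integer(max_iter),
                 max_noimprove = as.integer(max_noimprove),
                 ess = ess, seed = as.integer(seed),
                 max_parents = max_parents, arc_prob = arc_prob),
            class = "methbn_search_params")
}

#' Random starting DAG
#'
#' Draws a uniformly random topological order of the nodes, then includes
#' each order-respecting, non-blocked arc independently with probability
#' `arc_prob`. The result is acyclic by construction and never contains a
#' blocked arc, so the blocklist is an invariant of the whole search
#' trajectory, not just the final network.
#'
#' @param nodes Variable names.
#' @param blocklist A [build_blocklist()] result, or `NULL` for none.
#' @param arc_prob Inclusion probability per eligible arc.
#' @param seed Integer seed.
#' @return A [new_dag()].
#' @export
random_dag <- function(nodes, blocklist = NULL, arc_prob = 0.1,
                       seed = 1L) {
  stopifnot(length(nodes) >= 1L, arc_prob >= 0, arc_prob <= 1)
  v <- length(nodes)
  blocked <- if (is.null(blocklist)) {
    matrix(FALSE, v, v, dimnames = list(nodes, nodes))
  } else {
    .blocked_matrix(blocklist, nodes)
  }
  with_seed(seed, {
    ord <- if (v == 1L) nodes else sample(nodes)
    amat <- matrix(0L, v, v, dimnames = list(nodes, nodes))
    if (v >= 2L) {
      take <- matrix(FALSE, v, v)
      ut <- upper.tri(take)
      take[ut] <- stats::runif(sum(ut)) < arc_prob
      idx <- which(take, arr.ind = TRUE)
      if (nrow(idx)) {
        from <- ord[idx[, 1L]]
        to <- ord[idx[, 2L]]
        ok <- !blocked[cbind(from, to)]
        amat[cbind(from[ok], to[ok])] <- 1L
      }
    }
    g <- new_dag(nodes)
    g$amat <- amat
    g
  })
}

scored_network <- function(dag, score, search_id = NA_integer_,
                           seed = NA_integer_, iterations = NA_integer_) {
  structure(list(dag = dag, score = score, search_id = search_id,
                 seed = seed, iterations = iterations),
            class = "methbn_scored_network")
}

#' @export
print.methbn_scored_network <- function(x, ...) {
  cat(sprintf("<methbn_scored_network> score %.4f, %d arcs (search %s)\n",
              x$score, n_arcs(x$dag), x$search_id))
  invisible(x)
}

#' Tabu search over DAG structures
#'
#' Best-improvement local search over single-arc moves (add, delete,
#' reverse), excluding blocked arcs and cycle-creating moves. The move
#' applied at each iteration puts its inverse on a tabu list for
#' `tabu_length` iterations (aspiration: a tabu move is allowed if it
#' beats the best score seen). When no improving move exists, up to
#' `max_noimprove` consecutive non-improving best moves are accepted
#' before the search stops; the best DAG visited is returned. Ties among
#' equal-delta moves break to the lexicographically smallest
#' (from, to, move type), so the search is fully deterministic given its
#' starting DAG.
#'
#' @param d A [binary_dataset()].
#' @param blocklist A [build_blocklist()] result or `NULL`.
#' @param start Starting DAG (acyclic, blocklist-clean).
#' @param params A [search_params()].
#' @param cache Optional shared [score_cache()].
#' @return A `methbn_scored_network`.
#' @export
tabu_search <- function(d, blocklist = NULL, start = NULL,
                        params = search_params(), cache = NULL) {
  nodes <- variables(d)
  v <- length(nodes)
  if (is.null(start)) start <- new_dag(nodes)
  if (!setequal(start$nodes, nodes)) {
    stop("start DAG nodes must equal dataset variables")
  }
  blocked <- if (is.null(blocklist)) {
    matrix(FALSE, v, v, dimnames = list(nodes, nodes))
  } else {
    .blocked_matrix(blocklist, nodes)
  }
  if (any(start$amat == 1L & blocked)) {
    stop("starting DAG contains blocked arcs")
  }
  if (!is_acyclic(start)) stop("starting DAG is cyclic")
  if (is.null(cache)) cache <- score_cache()
  ess <- params$ess
  eps <- 1e-12
  x <- d$values

  # index-based internals; cache keys encode the parent set as two
  # order-free powers-of-two sums (exact for up to 90 variables)
  pw1 <- ifelse(seq_len(v) <= 45L, 2^(seq_len(v) - 1L), 0)
  pw2 <- ifelse(seq_len(v) > 45L, 2^(seq_len(v) - 46L), 0)
  store <- cache$scores
  fam_i <- function(child, pidx) {
    key <- paste0("#", child, "|", sum(pw1[pidx]), "|", sum(pw2[pidx]),
                  "|", ess)
    hit <- store[[key]]
    if (!is.null(hit)) return(hit)
    val <- .family_logscore(x, child, pidx, ess)
    store[[key]] <- val
    val
  }
  # alphabetical node ranks for the (from, to, move-type) tie-break
  nrank <- match(seq_len(v), order(nodes))

  amat <- start$amat[nodes, nodes]
  pa <- lapply(seq_len(v), function(j) which(amat[, j] == 1L))
  fam <- vapply(seq_len(v), function(j) fam_i(j, pa[[j]]), numeric(1L))
  cur <- sum(fam)
  best <- cur
  best_amat <- amat
  # tabu expiries indexed by move code: type (1 add, 2 delete,
  # 3 reverse) x from x to
  tabu <- rep(0L, 3L * v * v)
  mcode <- function(ty, u, w) ((ty - 1L) * v + (u - 1L)) * v + w
  noimp <- 0L
  iter <- 0L

  while (iter < params$max_iter) {
    iter <- iter + 1L
    reach <- .reach_closure(amat)
    # additions (no existing arc either way, unblocked, acyclic)
    elig <- amat == 0L & t(amat) == 0L & !blocked & t(reach) == 0
    add_idx <- which(elig, arr.ind = TRUE)
    arc_idx <- which(amat == 1L, arr.ind = TRUE)
    nmax <- nrow(add_idx) + 2L * nrow(arc_idx)
    mv_ty <- integer(nmax); mv_u <- integer(nmax); mv_w <- integer(nmax)
    mv_d <- numeric(nmax)
    nmv <- 0L
    for (k in seq_len(nrow(add_idx))) {
      u <- add_idx[k, 1L]; w <- add_idx[k, 2L]
      if (length(pa[[w]]) >= params$max_parents) next
      nmv <- nmv + 1L
      mv_ty[nmv] <- 1L; mv_u[nmv] <- u; mv_w[nmv] <- w
      mv_d[nmv] <- fam_i(w, c(pa[[w]], u)) - fam[[w]]
    }
    # deletions and reversals of existing arcs
    for (k in seq_len(nrow(arc_idx))) {
      u <- arc_idx[k, 1L]; w <- arc_idx[k, 2L]
      f_del <- fam_i(w, pa[[w]][pa[[w]] != u]) - fam[[w]]
      nmv <- nmv + 1L
      mv_ty[nmv] <- 2L; mv_u[nmv] <- u; mv_w[nmv] <- w
      mv_d[nmv] <- f_del
      if (!blocked[w, u] && length(pa[[u]]) < params$max_parents) {
        amat[u, w] <- 0L
        rev_ok <- !.has_path(amat, u, w)
        amat[u, w] <- 1L
        if (rev_ok) {
          nmv <- nmv + 1L
          mv_ty[nmv] <- 3L; mv_u[nmv] <- u; mv_w[nmv] <- w
          mv_d[nmv] <- f_del + fam_i(u, c(pa[[u]], w)) - fam[[u]]
        }
      }
    }
    if (nmv == 0L) break
    keep <- seq_len(nmv)
    is_tabu <- tabu[mcode(mv_ty[keep], mv_u[keep], mv_w[keep])] >= iter
    allowed <- keep[!is_tabu | cur + mv_d[keep] > best + eps]
    if (!length(allowed)) break
    top <- allowed[mv_d[allowed] >= max(mv_d[allowed]) - 1e-14]
    k <- top[order(nrank[mv_u[top]], nrank[mv_w[top]], mv_ty[top])][[1L]]
    dlt <- mv_d[[k]]
    if (dlt <= eps) {
      noimp <- noimp + 1L
      if (noimp > params$max_noimprove) break
    } else {
      noimp <- 0L
    }
    u <- mv_u[[k]]; w <- mv_w[[k]]; ty <- mv_ty[[k]]
    if (ty == 1L) {
      amat[u, w] <- 1L
      pa[[w]] <- c(pa[[w]], u)
      inv <- mcode(2L, u, w)
    } else if (ty == 2L) {
      amat[u, w] <- 0L
      pa[[w]] <- pa[[w]][pa[[w]] != u]
      inv <- mcode(1L, u, w)
    } else {
      amat[u, w] <- 0L
      amat[w, u] <- 1L
      pa[[w]] <- pa[[w]][pa[[w]] != u]
      pa[[u]] <- c(pa[[u]], w)
      fam[[u]] <- fam_i(u, pa[[u]])
      inv <- mcode(3L, w, u)
    }
    fam[[w]] <- fam_i(w, pa[[w]])
    cur <- sum(fam)
    if (params$tabu_length > 0L) tabu[[inv]] <- iter + params$tabu_length
    if (cur > best + eps) {
      best <- cur
      best_amat <- amat
    }
  }
  out <- new_dag(nodes)
  out$amat <- best_amat
  scored_network(out, best, iterations = iter)
}

#' Batch of random-restart tabu searches
#'
#' Runs `params$n_starts` independent tabu searches, each from a fresh
#' [random_dag()] whose seed is derived deterministically from
#' `params$seed` by a counter-based scheme, and returns each search's
#' single best network (duplicates retained). Identical master seed
#' implies an identical batch regardless of execution order.
#'
#' @inheritParams tabu_search
#' @return List of `methbn_scored_network`, length `params$n_starts`.
#' @export
run_search_batch <- function(d, blocklist = NULL,
                             params = search_params(), cache = NULL) {
  nodes <- variables(d)
  arc_prob <- params$arc_prob
  if (is.null(arc_prob)) {
    arc_prob <- if (length(nodes) > 1L) 2 / (length(nodes) - 1L) else 0
    arc_prob <- min(arc_prob, 1)
  }
  if (is.null(cache)) cache <- score_cache()
  lapply(seq_len(params$n_starts), function(i) {
    s_i <- derive_seed(params$seed, i)
    start <- random_dag(nodes, blocklist, arc_prob = arc_prob, seed = s_i)
    net <- tabu_search(d, blocklist, start, params = params,
                       cache = cache)
    net$search_id <- i
    net$seed <- s_i
    net
  })
}
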