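#' Directed acyclic graphs over named variables
#'
#' A `methbn_dag` is the structural half of a discrete Bayesian network: a
#' set of named nodes and a set of directed arcs stored as a binary
#' adjacency matrix (`amat[i, j] == 1L` means an arc `i -> j`). Acyclicity
#' is checked on construction and after every mutation, so downstream code
#' can assume any `methbn_dag` it receives is a DAG.
#'
#' @param nodes Character vector of unique node names.
#' @param arcs Optional two-column matrix or data frame of arcs
#'   (`from`, `to`); may be `NULL` or zero-row for an empty graph.
#' @return An object of class `methbn_dag`.
#' @examples
#' g <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_parents(g, "B")
#' @export
new_dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1L)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  v <- length(nodes)
  amat <- matrix(0L, v, v, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "methbn_dag")
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2L) stop("arcs must have two columns (from, to)")
    unknown <- setdiff(c(arcs), nodes)
    if (length(unknown)) {
      stop("arcs reference unknown nodes: ", paste(unknown, collapse = ", "))
    }
    if (any(arcs[, 1L] == arcs[, 2L])) stop("self-loops are not allowed")
    g$amat[arcs] <- 1L
    if (!is_acyclic(g)) stop("arc set contains a directed cycle")
  }
  g
}

#' @rdname new_dag
#' @param x Object to test.
#' @export
is_dag <- function(x) inherits(x, "methbn_dag")

#' @export
print.methbn_dag <- function(x, ...) {
  cat(sprintf("<methbn_dag> %d nodes, %d arcs\n",
              length(x$nodes), sum(x$amat)))
  invisible(x)
}

#' Arcs of a DAG as a from/to matrix
#'
#' @param g A `methbn_dag`.
#' @return Character matrix with columns `from`, `to`, one row per arc,
#'   ordered row-major by the adjacency matrix (stable).
#' @export
dag_arcs <- function(g) {
  idx <- which(g$amat == 1L, arr.ind = TRUE)
  out <- cbind(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' @rdname dag_arcs
#' @export
n_arcs <- function(g) sum(g$amat)

#' Parents and children of a node
#'
#' @param g A `methbn_dag`.
#' @param node A node name.
#' @return Character vector of node names.
#' @export
dag_parents <- function(g, node) g$nodes[g$amat[, node] == 1L]

#' @rdname dag_parents
#' @export
dag_children <- function(g, node) g$nodes[g$amat[node, ] == 1L]

#' Acyclicity test and topological order
#'
#' `is_acyclic()` runs Kahn's algorithm; `topo_sort()` returns a topological
#' order of the nodes or errors on a cyclic graph.
#'
#' @param g A `methbn_dag` (or a bare adjacency matrix for internal use).
#' @return `is_acyclic()`: logical; `topo_sort()`: character vector.
#' @export
is_acyclic <- function(g) {
  amat <- if (is_dag(g)) g$amat else g
  !is.null(.kahn_order(amat))
}

#' @rdname is_acyclic
#' @export
topo_sort <- function(g) {
  ord <- .kahn_order(g$amat)
  if (is.null(ord)) stop("graph contains a directed cycle")
  g$nodes[ord]
}

# Kahn's algorithm; returns integer order or NULL if cyclic.
.kahn_order <- function(amat) {
  v <- nrow(amat)
  indeg <- colSums(amat)
  queue <- which(indeg == 0L)
  ord <- integer(0L)
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    ord <- c(ord, i)
    ch <- which(amat[i, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0L])
  }
  if (length(ord) < v) NULL else ord
}

# Reachability closure: m[i, j] == 1 iff a directed path i ~> j exists
# (including i == j). Boolean matrix squaring, O(log v) multiplications.
.reach_closure <- function(amat) {
  m <- (amat > 0) + diag(nrow(amat))
  repeat {
    m2 <- (m %*% m > 0) * 1
    if (identical(m2, m)) return(m)
    m <- m2
  }
}

# TRUE iff a directed path from `from` to `to` exists in amat (BFS).
.has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Single-arc mutations
#'
#' Add, drop or reverse one arc, preserving acyclicity (an error is raised
#' if the mutation would create a cycle or duplicate/missing arcs make the
#' request meaningless).
#'
#' @param g A `methbn_dag`.
#' @param from,to Node names.
#' @return The mutated `methbn_dag`.
#' @export
add_arc <- function(g, from, to) {
  i <- match(from, g$nodes); j <- match(to, g$nodes)
  if (is.na(i) || is.na(j)) stop("unknown node")
  if (i == j) stop("self-loops are not allowed")
  if (g$amat[i, j] == 1L) stop("arc already present")
  if (g$amat[j, i] == 1L || .has_path(g$amat, j, i)) {
    stop("adding ", from, " -> ", to, " would create a cycle")
  }
  g$amat[i, j] <- 1L
  g
}

#' @rdname add_arc
#' @export
drop_arc <- function(g, from, to) {
  if (g$amat[from, to] != 1L) stop("arc not present")
  g$amat[from, to] <- 0L
  g
}

#' @rdname add_arc
#' @export
reverse_arc <- function(g, from, to) {
  if (g$amat[from, to] != 1L) stop("arc not present")
  g$amat[from, to] <- 0L
  i <- match(from, g$nodes); j <- match(to, g$nodes)
  if (.has_path(g$amat, i, j)) {
    stop("reversing ", from, " -> ", to, " would create a cycle")
  }
  g$amat[j, i] <- 1L
  g
}
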