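#' Binary methylation datasets
#'
#' A `methbn_binary_dataset` is the unit every scoring and search function
#' consumes: a samples x variables 0/1 integer matrix whose variables are
#' the DMR features plus the condition, with the condition variable name
#' recorded.
#'
#' @param values 0/1 integer matrix, samples x variables, column names
#'   required and unique.
#' @param condition_name Name of the condition variable; must be a column.
#' @return An object of class `methbn_binary_dataset`.
#' @export
binary_dataset <- function(values, condition_name = "Treatment") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have variable names")
  if (anyDuplicated(colnames(values))) stop("duplicate variable names")
  if (!condition_name %in% colnames(values)) {
    stop("condition variable '", condition_name, "' not present")
  }
  if (!all(values %in% c(0L, 1L))) stop("values must be 0/1")
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  structure(list(values = matrix(as.integer(values), nrow(values),
                                 ncol(values), dimnames = dimnames(values)),
                 condition_name = condition_name),
            class = "methbn_binary_dataset")
}

#' @export
print.methbn_binary_dataset <- function(x, ...) {
  cat(sprintf("<methbn_binary_dataset> %d samples x %d variables (condition '%s')\n",
              nrow(x$values), ncol(x$values), x$condition_name))
  invisible(x)
}

variables <- function(d) colnames(d$values)

#' Discretize methylation counts into binary states
#'
#' Threshold-at-zero rule: a read count of zero becomes state 0 (no
#' methylation) and any positive count becomes state 1 (methylation),
#' regardless of magnitude. The condition column is appended unchanged
#' (0 = control, 1 = stress). With zero the most frequent count, this
#' two-state split is the closest achievable to balanced discrete states.
#'
#' @param m A [count_matrix()].
#' @return A [binary_dataset()] whose variables are the features followed
#'   by the condition.
#' @examples
#' cm <- count_matrix(cbind(A = c(0L, 3L), B = c(17L, 0L)), c(0L, 1L))
#' binarize_counts(cm)$values
#' @export
binarize_counts <- function(m) {
  if (!inherits(m, "methbn_count_matrix")) {
    stop("m must be a methbn_count_matrix")
  }
  vals <- cbind((m$counts > 0L) * 1L, m$condition)
  colnames(vals) <- c(colnames(m$counts), m$condition_name)
  rownames(vals) <- rownames(m$counts)
  binary_dataset(vals, condition_name = m$condition_name)
}

#' Pairwise chi-square contingency tests
#'
#' Tests every unordered pair of variables for independence with a
#' Pearson chi-square test on the 2x2 table of joint binary state counts.
#' Yates continuity correction is applied by default (R's own 2x2
#' default). A variable constant across all samples yields a zero-margin
#' table; its p-values are defined as 1 (no evidence of dependence) and a
#' warning is emitted.
#'
#' @param d A [binary_dataset()].
#' @param yates Apply Yates continuity correction (default `TRUE`).
#' @return Symmetric numeric matrix of p-values (diagonal `NA`).
#' @export
pairwise_chisq <- function(d, yates = TRUE) {
  if (!inherits(d, "methbn_binary_dataset")) {
    stop("d must be a methbn_binary_dataset")
  }
  x <- d$values
  v <- ncol(x)
  if (v < 2L) stop("need at least two variables")
  vars <- colnames(x)
  const <- vars[apply(x, 2L, function(col) length(unique(col)) == 1L)]
  if (length(const)) {
    warning("constant variable(s), p-value defined as 1: ",
            paste(const, collapse = ", "))
  }
  p <- matrix(NA_real_, v, v, dimnames = list(vars, vars))
  for (i in seq_len(v - 1L)) {
    for (j in seq.int(i + 1L, v)) {
      tab <- table(factor(x[, i], levels = 0:1),
                   factor(x[, j], levels = 0:1))
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
        pv <- 1
      } else {
        pv <- suppressWarnings(
          stats::chisq.test(tab, correct = yates)$p.value)
        if (!is.finite(pv)) pv <- 1
      }
      p[i, j] <- pv
      p[j, i] <- pv
    }
  }
  p
}

#' Build the arc blocklist from pairwise p-values
#'
#' Every unordered pair whose chi-square p-value is greater than or equal
#' to `cutoff` (default 0.25) shows no evidence of contingency; both
#' directed arcs of the pair are blocked, i.e. excluded a priori from
#' structure search. The cut is a per-pair screening rule: it removes
#' candidate dependence, it does not declare dependence, so no
#' multiple-testing adjustment applies.
#'
#' @param pvals Symmetric p-value matrix from [pairwise_chisq()].
#' @param cutoff Blocking threshold in (0, 1]; pairs with `p >= cutoff`
#'   are blocked.
#' @return An object of class `methbn_blocklist`: list with `blocked`
#'   (data frame of directed `from`/`to` pairs, direction-symmetric),
#'   `pvalues` (the input matrix) and `cutoff`.
#' @export
build_blocklist <- function(pvals, cutoff = 0.25) {
  stopifnot(is.matrix(pvals), nrow(pvals) == ncol(pvals))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1) {
    stop("cutoff must lie in (0, 1]")
  }
  vars <- colnames(pvals)
  idx <- which(upper.tri(pvals) & pvals >= cutoff, arr.ind = TRUE)
  blocked <- data.frame(
    from = c(vars[idx[, 1L]], vars[idx[, 2L]]),
    to = c(vars[idx[, 2L]], vars[idx[, 1L]]),
    stringsAsFactors = FALSE)
  blocked <- blocked[order(blocked$from, blocked$to), , drop = FALSE]
  rownames(blocked) <- NULL
  structure(list(blocked = blocked, pvalues = pvals, cutoff = cutoff,
                 variables = vars),
            class = "methbn_blocklist")
}

#' @export
print.methbn_blocklist <- function(x, ...) {
  cat(sprintf("<methbn_blocklist> %d directed arcs blocked (p >= %g) over %d variables\n",
              nrow(x$blocked), x$cutoff, length(x$variables)))
  invisible(x)
}

#' An empty blocklist over a variable set
#'
#' @param vars Variable names.
#' @return A `methbn_blocklist` blocking nothing.
#' @export
empty_blocklist <- function(vars) {
  p <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  diag(p) <- NA_real_
  build_blocklist(p, cutoff = 1)
}

# Logical v x v matrix: TRUE where the directed arc is blocked.
.blocked_matrix <- function(blocklist, nodes) {
  b <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  bl <- blocklist$blocked
  keep <- bl$from %in% nodes & bl$to %in% nodes
  if (any(keep)) b[as.matrix(bl[keep, c("from", "to")])] <- TRUE
  b
}

#' Number of possible directed arcs over v variables
#'
#' Every ordered pair of distinct variables is a candidate arc, so the
#' count is `v * (v - 1)`; 61 variables give 3,660.
#'
#' @param v Number of variables.
#' @return Integer arc count.
#' @export
n_possible_arcs <- function(v) {
  v <- check_count_arg(v, "v")
  v * (v - 1L)
}
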