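#' Full consensus-network pipeline
#'
#' Runs the whole analysis on a count matrix: binarize counts at zero,
#' screen all variable pairs with chi-square contingency tests, block
#' arcs between pairs with `p >= chisq_cutoff`, run `n_reps` repetitions
#' of `n_starts` BDe tabu searches with score-weighted arc averaging and
#' high/low classification, intersect the per-repetition selections into
#' a weighted consensus network, and extract the Markov blanket of the
#' condition node.
#'
#' @param m A [count_matrix()] (or a path readable by
#'   [read_count_matrix()]).
#' @param chisq_cutoff Blocklist p-value cut-off (default 0.25).
#' @param yates Yates continuity correction for the chi-square tests.
#' @param params A [search_params()]; its `seed` is the master seed that
#'   determines every random draw in the run.
#' @param n_reps Number of repetitions (default 50).
#' @param prob_min,unc_max Arc selection thresholds (defaults 0.5 and
#'   0.01).
#' @param condition_name Condition column name when `m` is a path.
#' @return An object of class `methbn_result`: list with `binary`,
#'   `pvalues`, `blocklist`, `repetitions`, `consensus`,
#'   `markov_blanket` and `provenance`.
#' @export
run_pipeline <- function(m, chisq_cutoff = 0.25, yates = TRUE,
                         params = search_params(), n_reps = 50L,
                         prob_min = 0.5, unc_max = 0.01,
                         condition_name = "Treatment") {
  if (is.character(m)) m <- read_count_matrix(m, condition_name)
  d <- binarize_counts(m)
  pvals <- pairwise_chisq(d, yates = yates)
  blocklist <- build_blocklist(pvals, cutoff = chisq_cutoff)
  reps <- run_repetitions(d, blocklist, params = params,
                          n_reps = n_reps, prob_min = prob_min,
                          unc_max = unc_max)
  consensus <- build_consensus(reps, universe = variables(d))
  mb <- markov_blanket(consensus, m$condition_name)
  provenance <- list(
    package = "methbn",
    version = as.character(utils::packageVersion("methbn")),
    condition = m$condition_name,
    n_samples = nrow(d$values),
    n_variables = ncol(d$values),
    chisq_cutoff = chisq_cutoff,
    yates = yates,
    n_blocked_arcs = nrow(blocklist$blocked),
    n_possible_arcs = n_possible_arcs(ncol(d$values)),
    search = unclass(params),
    n_reps = n_reps,
    prob_min = prob_min,
    unc_max = unc_max,
    weighting = "softmax over BDe log-scores",
    repetition_seeds = vapply(reps, attr, integer(1L), "seed"))
  structure(list(binary = d, pvalues = pvals, blocklist = blocklist,
                 repetitions = reps, consensus = consensus,
                 markov_blanket = mb, provenance = provenance),
            class = "methbn_result")
}

#' @export
print.methbn_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("methbn pipeline result (%d samples x %d variables)\n",
              p$n_samples, p$n_variables))
  cat(sprintf("  blocked arcs : %d of %d possible (chi-square p >= %g)\n",
              p$n_blocked_arcs, p$n_possible_arcs, p$chisq_cutoff))
  cat(sprintf("  repetitions  : %d x %d tabu searches (master seed %d)\n",
              p$n_reps, p$search$n_starts, p$search$seed))
  cat(sprintf("  consensus    : %d arcs over %d of %d variables\n",
              nrow(x$consensus$arcs), length(x$consensus$nodes),
              p$n_variables))
  print(x$markov_blanket)
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the blocklist, the p-value matrix, the consensus arc table,
#' GraphML and DOT renderings, the Markov-blanket member list and a JSON
#' provenance record (full configuration, all derived seeds, package
#' version).
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_blocklist(result$blocklist, file.path(dir, "blocklist.tsv"))
  write_pvalue_matrix(result$pvalues, file.path(dir, "pvalues.tsv"))
  write_arc_table(result$consensus, file.path(dir, "consensus.tsv"))
  write_graph_file(result$consensus, file.path(dir, "consensus.graphml"),
                   "graphml")
  write_graph_file(result$consensus, file.path(dir, "consensus.dot"),
                   "dot")
  writeLines(result$markov_blanket$members,
             file.path(dir, "markov_blanket.txt"))
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
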