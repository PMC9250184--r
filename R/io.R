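#' Read a tab-delimited count matrix
#'
#' Parses the study's table dialect: a header row of DMR names plus the
#' condition column (default `"Treatment"`), then one row of integer
#' counts per individual. Column order is preserved; the condition
#' column may appear anywhere.
#'
#' @param path Path to a tab-delimited file with header.
#' @param condition_name Name of the condition column.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, condition_name = "Treatment") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!condition_name %in% colnames(df)) {
    stop("missing condition column '", condition_name, "'")
  }
  if (anyDuplicated(colnames(df))) {
    stop("duplicate feature name(s): ",
         paste(unique(colnames(df)[duplicated(colnames(df))]),
               collapse = ", "))
  }
  cond <- df[[condition_name]]
  if (!all(cond %in% c(0, 1))) {
    stop("condition column must contain only 0 and 1")
  }
  feats <- setdiff(colnames(df), condition_name)
  for (f in feats) {
    col <- df[[f]]
    if (!is.numeric(col) || any(is.na(col)) || any(col < 0) ||
        any(col != floor(col))) {
      stop("non-integer or negative count in column '", f, "'")
    }
  }
  counts <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(counts) <- "integer"
  count_matrix(counts, as.integer(cond), condition_name = condition_name)
}

#' @rdname read_count_matrix
#' @param m A [count_matrix()].
#' @export
write_count_matrix <- function(m, path) {
  df <- as.data.frame(m$counts)
  df[[m$condition_name]] <- m$condition
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read weighted arc tables
#'
#' The arc-table dialect has columns `arc` (1-based index), `from`, `to`
#' and `Average.Probability`, ordered by descending probability then
#' lexicographic (from, to) — the layout of the study's consensus-arc
#' supplement.
#'
#' @param arcs Data frame with `from`, `to`, `probability` columns (a
#'   consensus object's `arcs` or a selection result).
#' @param path Output path.
#' @return `write_arc_table()`: the path, invisibly; `read_arc_table()`:
#'   a data frame with `from`, `to`, `probability`.
#' @export
write_arc_table <- function(arcs, path) {
  if (inherits(arcs, "methbn_consensus")) arcs <- arcs$arcs
  arcs <- as.data.frame(arcs)
  arcs <- arcs[order(-arcs$probability, arcs$from, arcs$to), ,
               drop = FALSE]
  out <- data.frame(arc = seq_len(nrow(arcs)), from = arcs$from,
                    to = arcs$to,
                    Average.Probability = arcs$probability)
  utils::write.table(format(out, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arc_table
#' @export
read_arc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(from = as.character(df$from), to = as.character(df$to),
             probability = as.numeric(df$Average.Probability),
             stringsAsFactors = FALSE)
}

#' Write / read an arc blocklist
#'
#' Blocklists are persisted as a two-column `from`/`to` tab-delimited
#' table of directed blocked arcs; the p-value matrix is written as a
#' square tab-delimited file with variable names on both axes.
#'
#' @param blocklist A [build_blocklist()] result.
#' @param path Output path.
#' @export
write_blocklist <- function(blocklist, path) {
  utils::write.table(blocklist$blocked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocklist
#' @export
read_blocklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  vars <- sort(unique(c(df$from, df$to)))
  bl <- structure(list(blocked = df, pvalues = NULL, cutoff = NA_real_,
                       variables = vars),
                  class = "methbn_blocklist")
  bl
}

#' @rdname write_blocklist
#' @param pvals Symmetric p-value matrix.
#' @export
write_pvalue_matrix <- function(pvals, path) {
  utils::write.table(format(pvals, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Export a weighted arc set as GraphML or DOT
#'
#' Edge weight is the arc probability; a `band` edge attribute carries
#' the probability bands used for display (0.90-1.00, 0.80-0.89,
#' 0.70-0.79, 0.60-0.69, below).
#'
#' @param arcs A consensus object or data frame (`from`, `to`,
#'   `probability`).
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_graph_file <- function(arcs, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  nodes <- NULL
  if (inherits(arcs, "methbn_consensus")) {
    nodes <- arcs$nodes
    arcs <- arcs$arcs
  }
  arcs <- as.data.frame(arcs)
  if (is.null(nodes)) nodes <- sort(unique(c(arcs$from, arcs$to)))
  g <- igraph::graph_from_data_frame(
    arcs[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- arcs$probability
  igraph::E(g)$band <- probability_band(arcs$probability)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname write_graph_file
#' @param p Numeric probabilities.
#' @export
probability_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.60, 0.70, 0.80, 0.90, Inf),
      labels = c("<0.60", "0.60-0.69", "0.70-0.79", "0.80-0.89",
                 "0.90-1.00"),
      right = FALSE) |> as.character()
}

#' Persist / restore a batch of scored networks
#'
#' The archive is a tab-delimited edge list with one row per arc
#' (`search_id`, `from`, `to`) plus a scores sidecar
#' (`search_id`, `seed`, `iterations`, `score`), enough to restore the
#' batch exactly (arc-less networks included).
#'
#' @param batch List of scored networks from [run_search_batch()].
#' @param prefix Path prefix; writes `<prefix>_arcs.tsv` and
#'   `<prefix>_scores.tsv`.
#' @export
write_network_batch <- function(batch, prefix) {
  arcs <- do.call(rbind, lapply(batch, function(net) {
    a <- dag_arcs(net$dag)
    if (!nrow(a)) return(NULL)
    data.frame(search_id = net$search_id, from = a[, 1L], to = a[, 2L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(arcs)) {
    arcs <- data.frame(search_id = integer(0), from = character(0),
                       to = character(0))
  }
  scores <- data.frame(
    search_id = vapply(batch, `[[`, integer(1L), "search_id"),
    seed = vapply(batch, `[[`, integer(1L), "seed"),
    iterations = vapply(batch, `[[`, integer(1L), "iterations"),
    score = vapply(batch, `[[`, numeric(1L), "score"))
  utils::write.table(arcs, paste0(prefix, "_arcs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format(scores, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     paste0(prefix, "_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_network_batch
#' @param nodes Variable names of the underlying dataset.
#' @export
read_network_batch <- function(prefix, nodes) {
  arcs <- utils::read.delim(paste0(prefix, "_arcs.tsv"),
                            stringsAsFactors = FALSE)
  scores <- utils::read.delim(paste0(prefix, "_scores.tsv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(scores)), function(i) {
    id <- scores$search_id[[i]]
    sub <- arcs[arcs$search_id == id, c("from", "to"), drop = FALSE]
    scored_network(new_dag(nodes, as.matrix(sub)), scores$score[[i]],
                   search_id = id, seed = scores$seed[[i]],
                   iterations = scores$iterations[[i]])
  })
}
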