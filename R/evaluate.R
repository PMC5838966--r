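#  Evaluation of a predicted gene set: exact hypergeometric upper-tail
#  overlap against gold-standard lists, and the shortest-path proximity
#  baseline with tie expansion at the cutoff.

#' Exact upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` gold-standard genes when `n` genes are drawn without
#' replacement from a population of `N` genes containing `K` gold-standard
#' ones.  Computed by exact summation of the probability mass over the upper
#' tail (no normal approximation; the populations involved are small).
#'
#' @param N population size.
#' @param K gold-standard genes in the population.
#' @param n genes drawn (predicted set size).
#' @param k observed overlap.
#' @return the p-value in `[0, 1]`.
#' @examples
#' hypergeometric_upper_tail(331, 3, 37, 2)  # ~0.034
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop_ppn("N, K, n, k must be non-negative integers",
             class = "ppn_validation_error")
  }
  if (K > N || n > N || k > min(K, n)) {
    stop_ppn("require K <= N, n <= N and k <= min(K, n)",
             class = "ppn_validation_error")
  }
  k_lo <- max(0, n - (N - K))  # smallest achievable overlap
  if (k <= k_lo) return(1)
  sum(stats::dhyper(seq(k, min(K, n)), K, N - K, n))
}

#' Hypergeometric overlap test between gene sets
#'
#' @param population character vector: the candidate population (e.g. all
#'   screened enzymes).
#' @param gold character vector: gold-standard genes, a subset of
#'   `population`.
#' @param predicted character vector: predicted genes, a subset of
#'   `population`.
#' @return list of class `gene_set_overlap` with `N`, `K`, `n`, `k` and
#'   `p_value` (upper-tail).
#' @export
overlap_test <- function(population, gold, predicted) {
  population <- unique(as.character(population))
  gold <- unique(as.character(gold))
  predicted <- unique(as.character(predicted))
  out_g <- setdiff(gold, population)
  out_p <- setdiff(predicted, population)
  if (length(out_g) || length(out_p)) {
    stop_ppn("gold and predicted sets must be subsets of the population (offenders: %s)",
             paste(c(out_g, out_p), collapse = ", "),
             class = "ppn_validation_error")
  }
  N <- length(population)
  K <- length(gold)
  n <- length(predicted)
  k <- length(intersect(gold, predicted))
  structure(list(N = N, K = K, n = n, k = k,
                 p_value = hypergeometric_upper_tail(N, K, n, k)),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf(
    "Gene-set overlap: %d of %d predicted genes hit %d gold-standard genes (population %d)\n  upper-tail hypergeometric p-value: %.4g\n",
    x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Average shortest path length from a gene to the marker panel
#'
#' Unweighted breadth-first shortest path length from `gene` to each panel
#' marker, averaged.  Markers unreachable from the gene are excluded from
#' the average (keeping the statistic finite); if every marker is
#' unreachable the result is `NA` (flagged undefined).
#'
#' @param network a [phospho_network()].
#' @param gene the query gene id.
#' @param panel a [marker_panel()] or character vector of marker ids.
#' @param mode `"undirected"` (default, the usual proximity baseline) or
#'   `"directed"` (following enzyme-to-substrate edges).
#' @return mean path length (edges), or `NA` if no marker is reachable.
#' @export
avg_path_to_panel <- function(network, gene, panel,
                              mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  ids <- panel_ids(panel)
  absent <- setdiff(c(gene, ids), network$nodes$id)
  if (length(absent)) {
    stop_ppn("id(s) not in the network: %s", paste(absent, collapse = ", "),
             class = "ppn_validation_error")
  }
  g <- network_graph(network)
  d <- igraph::distances(g, v = gene, to = ids,
                         mode = if (mode == "directed") "out" else "all")
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Shortest-path proximity of many genes to the marker panel
#'
#' @param genes character vector of query gene ids.
#' @inheritParams avg_path_to_panel
#' @return data.frame with `gene_id`, `avg_path_length` (`NA` when no marker
#'   is reachable) and `rank` (ascending length, min rank for ties).
#' @export
proximity_table <- function(network, genes, panel,
                            mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  lens <- vapply(genes, function(g) avg_path_to_panel(network, g, panel, mode),
                 numeric(1))
  data.frame(gene_id = as.character(genes),
             avg_path_length = unname(lens),
             rank = rank(lens, ties.method = "min", na.last = "keep"),
             stringsAsFactors = FALSE)
}

#' Top-k genes by proximity, with tie expansion
#'
#' Genes are sorted by ascending average path length and the `k` nearest are
#' selected — together with *every* gene tied at the k-th length, so the
#' returned set may exceed `k` (selecting a fixed-size nearest set is not
#' well defined across a tie class).  Genes with undefined (`NA`) length are
#' never selected.
#'
#' @param results data.frame from [proximity_table()] (columns `gene_id`,
#'   `avg_path_length`).
#' @param k nominal set size, `>= 1`.
#' @return character vector of selected gene ids.
#' @export
top_k_by_proximity <- function(results, k) {
  stopifnot(k >= 1L, all(c("gene_id", "avg_path_length") %in% names(results)))
  defined <- results[!is.na(results$avg_path_length), , drop = FALSE]
  if (!nrow(defined)) return(character(0))
  if (k >= nrow(defined)) return(as.character(defined$gene_id))
  lens <- sort(defined$avg_path_length)
  cutoff <- lens[k]
  as.character(defined$gene_id[defined$avg_path_length <= cutoff])
}
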