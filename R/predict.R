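#  Therapeutic-target calling: compare marker phosphorylation directions
#  across the reference, atrophic (stimulated) and gene-inhibited states.
#  A marker is "recovered" by an inhibition when the inhibition reverses the
#  marker's reference -> atrophic direction of change; a candidate is selected
#  when enough markers are recovered in every replicate screen.

#' Direction of change between two phosphorylation statuses
#'
#' The screen compares directions, not magnitudes.  An exact tie (or a
#' difference within `epsilon`) yields `"none"`, which can never count as a
#' reversal: ties are evidence of nothing.
#'
#' @param status_a,status_b phosphorylation status values (before / after).
#' @param epsilon half-width of the tie band around zero (default 0: statuses
#'   are means of integers, so exact ties are meaningful).
#' @return `"up"`, `"down"` or `"none"` (vectorized).
#' @export
direction_of_change <- function(status_a, status_b, epsilon = 0) {
  d <- status_b - status_a
  ifelse(d > epsilon, "up", ifelse(d < -epsilon, "down", "none"))
}

#' Read a marker panel TSV
#'
#' @param path tab-separated file with header columns `protein_id` and
#'   `expected_atrophic_direction` (`up`/`down`).
#' @return data.frame with columns `protein_id`, `direction`.
#' @export
read_panel <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "expected_atrophic_direction"))
  marker_panel(df$protein_id, df$expected_atrophic_direction)
}

#' Construct a marker panel
#'
#' @param protein_id marker protein ids (unique).
#' @param direction expected direction of the phosphorylation change from the
#'   reference to the diseased (atrophic) state, `"up"` or `"down"`.
#' @return data.frame of class `marker_panel`.
#' @export
marker_panel <- function(protein_id, direction) {
  protein_id <- as.character(protein_id)
  direction <- as.character(direction)
  stopifnot(length(protein_id) == length(direction),
            !anyDuplicated(protein_id),
            all(direction %in% c("up", "down")))
  structure(data.frame(protein_id = protein_id, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

#' @rdname marker_panel
#' @param panel a `marker_panel`.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(
    data.frame(protein_id = panel$protein_id,
               expected_atrophic_direction = panel$direction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

panel_ids <- function(panel) {
  if (is.data.frame(panel)) as.character(panel$protein_id)
  else as.character(panel)
}

#' Count markers recovered by an inhibition
#'
#' A marker counts as recovered iff its reference-to-atrophic and
#' atrophic-to-inhibited directions of change are both non-`"none"` and
#' opposite — the inhibition reverses the disease-induced change.
#'
#' @param reference,atrophic,inhibited phosphorylation statuses (named
#'   numeric vectors from [simulate_state()]) covering every panel marker.
#' @param panel a [marker_panel()] (or a character vector of marker ids).
#' @param epsilon tie band passed to [direction_of_change()].
#' @return integer count in `[0, nrow(panel)]`; invariant under panel
#'   reordering.
#' @export
count_recovered <- function(reference, atrophic, inhibited, panel,
                            epsilon = 0) {
  ids <- panel_ids(panel)
  for (nm in list(reference = reference, atrophic = atrophic,
                  inhibited = inhibited)) {
    missing <- setdiff(ids, names(nm))
    if (length(missing)) {
      stop_ppn("marker(s) missing from a status vector: %s",
               paste(missing, collapse = ", "), class = "ppn_validation_error")
    }
  }
  d1 <- direction_of_change(reference[ids], atrophic[ids], epsilon)
  d2 <- direction_of_change(atrophic[ids], inhibited[ids], epsilon)
  sum(d1 != "none" & d2 != "none" & d1 != d2)
}

#' Enzymes linked to the marker panel
#'
#' The screenable candidate population: kinases and phosphatases from which
#' at least one panel marker is reachable along enzyme-to-substrate edges
#' (directed reachability; an undirected reading is available via `mode`).
#'
#' @param network a [phospho_network()].
#' @param panel a [marker_panel()] or character vector of marker ids.
#' @param mode `"directed"` (default) follows edge direction;
#'   `"undirected"` ignores it.
#' @return sorted character vector of enzyme ids.
#' @export
candidate_enzymes <- function(network, panel, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  ids <- panel_ids(panel)
  missing <- setdiff(ids, network$nodes$id)
  if (length(missing)) {
    stop_ppn("marker(s) not in the network: %s",
             paste(missing, collapse = ", "), class = "ppn_validation_error")
  }
  g <- network_graph(network)
  igraph_mode <- if (mode == "directed") "in" else "all"
  linked <- unique(unlist(lapply(ids, function(m) {
    names(igraph::subcomponent(g, m, mode = igraph_mode))
  })))
  enzymes <- network$nodes$id[network$nodes$role %in% c("kinase", "phosphatase")]
  sort(intersect(enzymes, linked))
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$interactions[, c("enzyme_id", "substrate_id")],
    directed = TRUE, vertices = network$nodes$id)
}

#' Target-selection rule on replicate recovery counts
#'
#' @param counts integer vector of markers recovered, one per replicate
#'   inhibited-state screen.
#' @param min_recovered minimum count required in *every* replicate
#'   (default 4 of a 5-marker panel).
#' @return logical: selected or not.  For example the replicate triples
#'   `(5, 5, 3)` and `(4, 5, 3)` are rejected, `(4, 4, 5)` is accepted.
#' @export
select_by_recovery <- function(counts, min_recovered = 4L) {
  stopifnot(length(counts) >= 1L, all(counts >= 0))
  all(counts >= min_recovered)
}

#' Screen candidate genes for marker recovery
#'
#' Fixes one reference and one atrophic phosphorylation status (computed once
#' and reused for all candidates), then, for every candidate gene, simulates
#' `replicates` independently seeded inhibited states (the atrophic stimulus
#' plus zero activity on the candidate) and counts recovered markers per
#' replicate.  A candidate is selected when every replicate recovers at least
#' `min_recovered` markers.
#'
#' Replicate seeds derive from `config$seed` and the candidate id, so
#' candidate order cannot change any result.  A candidate that is itself a
#' stimulus direct target is dropped from the clamp set for its own
#' inhibited-state runs: the knock-down overrides the stimulus.
#'
#' @param network a [phospho_network()].
#' @param config a [sim_config()].
#' @param panel a [marker_panel()].
#' @param candidates character vector of candidate gene ids (see
#'   [candidate_enzymes()]).
#' @param stimulus_targets place ids clamped to high activity in the atrophic
#'   state (the stimulus's direct targets).
#' @param replicates inhibited-state replicates per candidate (default 3).
#' @param min_recovered selection cutoff per replicate (default 4).
#' @param epsilon tie band for [direction_of_change()].
#' @param reference,atrophic optional precomputed statuses (recomputed from
#'   `config` when `NULL`).
#' @return data.frame with one row per candidate: `gene_id`, one `rep<i>`
#'   column per replicate, and `selected`; the reference and atrophic
#'   statuses are attached as attributes.
#' @export
predict_targets <- function(network, config, panel, candidates,
                            stimulus_targets, replicates = 3L,
                            min_recovered = 4L, epsilon = 0,
                            reference = NULL, atrophic = NULL) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1L,
            min_recovered <= length(panel_ids(panel)))
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, network$nodes$id)
  if (length(missing)) {
    stop_ppn("candidate(s) not in the network: %s",
             paste(missing, collapse = ", "), class = "ppn_validation_error")
  }
  high <- 2L * config$threshold
  atr_pert <- perturbation(clamp_high = stimulus_targets, high_value = high)
  if (is.null(reference)) {
    reference <- simulate_state(network, config, NULL,
                                seed = mix_seed(config$seed, "reference"))
  }
  if (is.null(atrophic)) {
    atrophic <- simulate_state(network, config, atr_pert,
                               seed = mix_seed(config$seed, "atrophic"))
  }

  counts <- matrix(NA_integer_, nrow = length(candidates), ncol = replicates)
  for (ci in seq_along(candidates)) {
    cand <- candidates[ci]
    pert <- perturbation(clamp_high = setdiff(stimulus_targets, cand),
                         inhibit = cand, high_value = high)
    for (r in seq_len(replicates)) {
      inh <- simulate_state(network, config, pert,
                            seed = mix_seed(config$seed, "inhibit", cand, r))
      counts[ci, r] <- count_recovered(reference, atrophic, inh, panel,
                                       epsilon)
    }
  }
  out <- data.frame(gene_id = candidates, stringsAsFactors = FALSE)
  for (r in seq_len(replicates)) out[[paste0("rep", r)]] <- counts[, r]
  out$selected <- apply(counts, 1L, select_by_recovery,
                        min_recovered = min_recovered)
  attr(out, "reference") <- reference
  attr(out, "atrophic") <- atrophic
  out
}
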