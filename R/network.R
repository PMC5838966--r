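#  Phosphorylation network model: places (proteins) and typed interactions
#  (phosphorylation / de-phosphorylation), with the construction steps used
#  to clean an integrated kinase-phosphatase network: deduplication, conflict
#  resolution, activation-condition inference and tissue filtering.

NODE_ROLES   <- c("kinase", "phosphatase", "substrate_only")
ACTIVATIONS  <- c("with_phosphorylation", "without_phosphorylation")
ITYPES       <- c("phosphorylation", "de_phosphorylation")
ITYPE_CODES  <- c(P = "phosphorylation", D = "de_phosphorylation")

#' Construct a validated phosphorylation network
#'
#' A `phospho_network` holds protein nodes (each with a role and an activation
#' condition) and directed enzyme-to-substrate interactions typed as
#' phosphorylation or de-phosphorylation.  The constructor enforces the model
#' invariants: unique node ids, enzyme endpoints with an enzymatic role,
#' no dangling interaction endpoints, unique `(enzyme, substrate, type)`
#' triples, and the convention that substrate-only proteins carry the
#' `with_phosphorylation` activation value (they never gate a transition,
#' but the field is always defined).
#'
#' @param nodes data.frame with columns `id`, `role`
#'   (`kinase`/`phosphatase`/`substrate_only`) and `activation`
#'   (`with_phosphorylation`/`without_phosphorylation`).
#' @param interactions data.frame with columns `enzyme_id`, `substrate_id`,
#'   `itype` (`phosphorylation`/`de_phosphorylation`) and optionally `source`
#'   (free-text provenance).
#' @return an object of class `phospho_network`.
#' @seealso [load_network()], [network_stats()], [generate_network()]
#' @export
phospho_network <- function(nodes, interactions) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  need_n <- c("id", "role", "activation")
  if (!all(need_n %in% names(nodes))) {
    stop_ppn("node table must have columns %s", paste(need_n, collapse = ", "),
             class = "ppn_validation_error")
  }
  if (!nrow(interactions)) {
    interactions <- data.frame(enzyme_id = character(0),
                               substrate_id = character(0),
                               itype = character(0),
                               source = character(0),
                               stringsAsFactors = FALSE)
  }
  need_i <- c("enzyme_id", "substrate_id", "itype")
  if (!all(need_i %in% names(interactions))) {
    stop_ppn("interaction table must have columns %s",
             paste(need_i, collapse = ", "), class = "ppn_validation_error")
  }
  if (is.null(interactions$source)) interactions$source <- NA_character_
  interactions <- interactions[, c(need_i, "source")]
  nodes <- nodes[, need_n]

  if (anyDuplicated(nodes$id)) {
    stop_ppn("duplicated node id(s): %s",
             paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
             class = "ppn_validation_error")
  }
  if (!all(nodes$role %in% NODE_ROLES)) {
    stop_ppn("invalid role value(s): %s",
             paste(setdiff(unique(nodes$role), NODE_ROLES), collapse = ", "),
             class = "ppn_validation_error")
  }
  if (!all(nodes$activation %in% ACTIVATIONS)) {
    stop_ppn("invalid activation value(s): %s",
             paste(setdiff(unique(nodes$activation), ACTIVATIONS), collapse = ", "),
             class = "ppn_validation_error")
  }
  bad_sub <- nodes$role == "substrate_only" &
    nodes$activation != "with_phosphorylation"
  if (any(bad_sub)) {
    stop_ppn("substrate-only node(s) must use activation 'with_phosphorylation': %s",
             paste(nodes$id[bad_sub], collapse = ", "),
             class = "ppn_validation_error")
  }
  if (!all(interactions$itype %in% ITYPES)) {
    stop_ppn("invalid interaction type(s): %s",
             paste(setdiff(unique(interactions$itype), ITYPES), collapse = ", "),
             class = "ppn_validation_error")
  }
  dangling <- setdiff(c(interactions$enzyme_id, interactions$substrate_id),
                      nodes$id)
  if (length(dangling)) {
    stop_ppn("interaction endpoint(s) missing from the node table: %s",
             paste(dangling, collapse = ", "), class = "ppn_validation_error")
  }
  role_of <- stats::setNames(nodes$role, nodes$id)
  non_enz <- unique(interactions$enzyme_id[
    role_of[interactions$enzyme_id] == "substrate_only"])
  if (length(non_enz)) {
    stop_ppn("interaction enzyme(s) are not kinases or phosphatases: %s",
             paste(non_enz, collapse = ", "), class = "ppn_validation_error")
  }
  key <- interaction_key(interactions)
  if (anyDuplicated(key)) {
    stop_ppn("duplicated (enzyme, substrate, type) triple(s); run deduplicate_interactions() first",
             class = "ppn_validation_error")
  }
  rownames(nodes) <- NULL
  rownames(interactions) <- NULL
  structure(list(nodes = nodes, interactions = interactions),
            class = "phospho_network")
}

interaction_key <- function(interactions, with_type = TRUE) {
  if (with_type) {
    paste(interactions$enzyme_id, interactions$substrate_id,
          interactions$itype, sep = "\r")
  } else {
    paste(interactions$enzyme_id, interactions$substrate_id, sep = "\r")
  }
}

#' @export
print.phospho_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(paste0(
    "phospho_network: %d proteins (%d kinases, %d phosphatases, %d substrate-only)\n",
    "  %d interactions (%d phosphorylation, %d de-phosphorylation)\n",
    "  enzymes activated without phosphorylation: %d\n"),
    s$n_nodes, s$n_kinases, s$n_phosphatases, s$n_substrate_only,
    s$n_interactions, s$n_phosphorylation, s$n_de_phosphorylation,
    s$n_without_phosphorylation))
  invisible(x)
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_ppn("%s: missing required column(s): %s", path,
             paste(missing, collapse = ", "), class = "ppn_parse_error")
  }
  df
}

decode_column <- function(values, map, column, path) {
  out <- unname(map[values])
  out[values %in% map] <- values[values %in% map]   # accept full names too
  bad <- which(is.na(out))
  if (length(bad)) {
    # +1 for the header line
    stop_ppn("%s line %d: invalid %s value '%s'", path, bad[1L] + 1L,
             column, values[bad[1L]], class = "ppn_parse_error")
  }
  out
}

#' Load a phosphorylation network from TSV tables
#'
#' @param interaction_path tab-separated file with header columns
#'   `enzyme_id`, `substrate_id`, `itype` (`P` or `D`, full names also
#'   accepted) and optionally `source`.
#' @param annotation_path tab-separated file with header columns
#'   `protein_id`, `role` (`kinase`/`phosphatase`/`substrate`) and
#'   `activation` (`with`/`without`).
#' @return a validated [phospho_network()].  Interactions referencing
#'   proteins absent from the annotation table raise a validation error.
#' @export
load_network <- function(interaction_path, annotation_path) {
  ann <- read_tsv_checked(annotation_path,
                          c("protein_id", "role", "activation"))
  role_map <- c(kinase = "kinase", phosphatase = "phosphatase",
                substrate = "substrate_only", substrate_only = "substrate_only")
  act_map <- c(with = "with_phosphorylation",
               without = "without_phosphorylation")
  nodes <- data.frame(
    id = ann$protein_id,
    role = decode_column(ann$role, role_map, "role", annotation_path),
    activation = decode_column(ann$activation, act_map, "activation",
                               annotation_path),
    stringsAsFactors = FALSE)

  inter <- read_tsv_checked(interaction_path,
                            c("enzyme_id", "substrate_id", "itype"))
  interactions <- data.frame(
    enzyme_id = inter$enzyme_id,
    substrate_id = inter$substrate_id,
    itype = if (nrow(inter)) {
      decode_column(inter$itype, ITYPE_CODES, "itype", interaction_path)
    } else character(0),
    source = inter$source %||% rep(NA_character_, nrow(inter)),
    stringsAsFactors = FALSE)
  phospho_network(nodes, interactions)
}

#' Write a phosphorylation network to TSV tables
#'
#' Inverse of [load_network()]; a load/write/load round trip reproduces the
#' network exactly.
#'
#' @param network a [phospho_network()].
#' @param interaction_path,annotation_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(network, interaction_path, annotation_path) {
  stopifnot(inherits(network, "phospho_network"))
  inter <- network$interactions
  out_i <- data.frame(enzyme_id = inter$enzyme_id,
                      substrate_id = inter$substrate_id,
                      itype = c(phosphorylation = "P",
                                de_phosphorylation = "D")[inter$itype],
                      source = ifelse(is.na(inter$source), "", inter$source),
                      stringsAsFactors = FALSE)
  utils::write.table(out_i, interaction_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- network$nodes
  out_a <- data.frame(
    protein_id = nodes$id,
    role = c(kinase = "kinase", phosphatase = "phosphatase",
             substrate_only = "substrate")[nodes$role],
    activation = c(with_phosphorylation = "with",
                   without_phosphorylation = "without")[nodes$activation],
    stringsAsFactors = FALSE)
  utils::write.table(out_a, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(interaction_path, annotation_path))
}

#' Collapse exact duplicate interactions
#'
#' Exact `(enzyme, substrate, type)` duplicates are collapsed to their first
#' occurrence (keeping that row's provenance).  A pair recorded with *both*
#' interaction types is not a duplicate but a conflict; see
#' [resolve_conflicts()].
#'
#' @param interactions interaction data.frame (as in [phospho_network()]).
#' @return the deduplicated data.frame.  Idempotent.
#' @export
deduplicate_interactions <- function(interactions) {
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!nrow(interactions)) return(interactions)
  out <- interactions[!duplicated(interaction_key(interactions)), ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve pairs annotated with both interaction types
#'
#' An ordered `(enzyme, substrate)` pair carrying both a phosphorylation and a
#' de-phosphorylation row is contradictory.  When a resolution table provides
#' curated evidence for the pair, the designated type is kept; pairs without
#' evidence are removed wholesale (both rows), with a warning reporting the
#' count — absent evidence, conservative removal.
#'
#' @param interactions interaction data.frame.
#' @param resolution optional data.frame with columns `enzyme_id`,
#'   `substrate_id`, `keep` (`P`/`D` or full type names): the type to retain
#'   for that pair.  Entries for pairs that are not conflicted are ignored
#'   with a warning.
#' @return the interaction data.frame with all conflicts resolved.
#' @export
resolve_conflicts <- function(interactions, resolution = NULL) {
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!nrow(interactions)) return(interactions)
  pair <- interaction_key(interactions, with_type = FALSE)
  n_types <- tapply(interactions$itype, pair, function(x) length(unique(x)))
  conflicted <- names(n_types)[n_types == 2L]

  keep_map <- character(0)
  if (!is.null(resolution) && nrow(resolution)) {
    resolution <- as.data.frame(resolution, stringsAsFactors = FALSE)
    stopifnot(all(c("enzyme_id", "substrate_id", "keep") %in% names(resolution)))
    rpair <- paste(resolution$enzyme_id, resolution$substrate_id, sep = "\r")
    rkeep <- decode_column(resolution$keep, ITYPE_CODES, "keep",
                           "resolution table")
    extraneous <- !(rpair %in% conflicted)
    if (any(extraneous)) {
      warning(sprintf("resolution entries for %d non-conflicted pair(s) ignored",
                      sum(extraneous)))
    }
    keep_map <- stats::setNames(rkeep[!extraneous], rpair[!extraneous])
  }

  drop <- logical(nrow(interactions))
  n_dropped_pairs <- 0L
  for (p in conflicted) {
    rows <- pair == p
    if (p %in% names(keep_map)) {
      drop <- drop | (rows & interactions$itype != keep_map[[p]])
    } else {
      drop <- drop | rows
      n_dropped_pairs <- n_dropped_pairs + 1L
    }
  }
  if (n_dropped_pairs > 0L) {
    warning(sprintf("%d conflicted pair(s) without resolution evidence removed (both directions)",
                    n_dropped_pairs))
  }
  out <- interactions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer an enzyme's activation condition from regulatory annotations
#'
#' Most kinases and phosphatases are assumed to be activated by
#' phosphorylation (the phosphorylation-cascade default).  An enzyme is
#' instead classified as activated *without* phosphorylation (i.e. inhibited
#' by phosphorylation) when at least one incoming regulatory annotation pairs
#' *activation* with *de-phosphorylation*, or *inhibition* with
#' *phosphorylation*: the special evidence overrides the default.
#'
#' @param pairs data.frame of regulatory annotations with columns
#'   `enzyme_id` (the regulator), `target_id` (the regulated enzyme),
#'   `effect` (`activation`/`inhibition`) and `mechanism`
#'   (`phosphorylation`/`de_phosphorylation`, codes `P`/`D` accepted).
#' @param enzyme_id the enzyme whose activation condition is wanted.
#' @return `"without_phosphorylation"` or `"with_phosphorylation"`.
#'   Order-independent in `pairs`.
#' @export
infer_activation <- function(pairs, enzyme_id) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("enzyme_id", "target_id", "effect", "mechanism") %in%
                  names(pairs)))
  inc <- pairs[pairs$target_id == enzyme_id, , drop = FALSE]
  if (!nrow(inc)) return("with_phosphorylation")
  bad_eff <- setdiff(unique(inc$effect), c("activation", "inhibition"))
  if (length(bad_eff)) {
    stop_ppn("invalid effect value(s): %s", paste(bad_eff, collapse = ", "),
             class = "ppn_validation_error")
  }
  mech <- decode_column(inc$mechanism, ITYPE_CODES, "mechanism",
                        "annotation pairs")
  flips <- (inc$effect == "activation" & mech == "de_phosphorylation") |
           (inc$effect == "inhibition" & mech == "phosphorylation")
  if (any(flips)) "without_phosphorylation" else "with_phosphorylation"
}

#' Restrict a network to proteins detected in a tissue
#'
#' Every interaction with an endpoint outside the detected set is removed;
#' proteins left with no interaction are then dropped (so the result contains
#' only proteins that still participate in the network).  Idempotent.
#'
#' @param network a [phospho_network()].
#' @param detected_ids character vector of detected protein ids.
#' @return the filtered [phospho_network()].
#' @export
filter_by_tissue <- function(network, detected_ids) {
  stopifnot(inherits(network, "phospho_network"))
  inter <- network$interactions
  keep <- inter$enzyme_id %in% detected_ids &
          inter$substrate_id %in% detected_ids
  inter <- inter[keep, , drop = FALSE]
  active <- unique(c(inter$enzyme_id, inter$substrate_id))
  nodes <- network$nodes[network$nodes$id %in% active, , drop = FALSE]
  phospho_network(nodes, inter)
}

#' Summary statistics of a phosphorylation network
#'
#' @param network a [phospho_network()].
#' @return a list with node counts by role, interaction counts by type, and
#'   enzyme counts by activation condition.
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "phospho_network"))
  nodes <- network$nodes
  inter <- network$interactions
  enz <- nodes$role %in% c("kinase", "phosphatase")
  list(
    n_nodes = nrow(nodes),
    n_kinases = sum(nodes$role == "kinase"),
    n_phosphatases = sum(nodes$role == "phosphatase"),
    n_substrate_only = sum(nodes$role == "substrate_only"),
    n_interactions = nrow(inter),
    n_phosphorylation = sum(inter$itype == "phosphorylation"),
    n_de_phosphorylation = sum(inter$itype == "de_phosphorylation"),
    n_with_phosphorylation = sum(enz & nodes$activation == "with_phosphorylation"),
    n_without_phosphorylation = sum(enz & nodes$activation == "without_phosphorylation")
  )
}
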