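#  Seeded synthetic phosphorylation networks and complete simulation
#  scenarios (stimulus targets, marker panel, optional planted relay), so
#  the whole pipeline is testable without any external data.
#
#  Planted-relay arithmetic: with unit-gain edges and degradation rate g,
#  the per-block map of a place fed by d constantly firing enzymes,
#  n -> floor((1-g)(n+d)), has a whole interval of fixed points,
#  [9d - 10, 9d] at g = 0.1; trajectories enter it at its lower end from
#  below and at its upper end from above, then stop.  Two consequences
#  shape the motif.  (i) A place crosses the default threshold 35 upward
#  from *any* start only if its whole band lies above it: fan-in >= 6.
#  (ii) Adding or removing one edge shifts the band by 9 but moves a place
#  already inside its band not at all, so an enzyme fed by at most one
#  state-dependent edge can never be switched between states; since
#  everything strictly downstream of a single relay receives exactly one
#  relay-dependent edge, a single cut-vertex relay can only move its
#  *direct* substrates — and therefore only in one direction, its own
#  catalytic sign.  The planted motif embraces this: 6 stimulus-target
#  kinases (clamped high only in the atrophic state) feed a relay
#  phosphatase, which then sits in the 44-54 band (ON) in the atrophic
#  state and decays to 0 (OFF) in the reference state; every marker is held
#  in the 26-36 band by a pool of 4 constitutively active kinases
#  (activation without phosphorylation, zero in-degree, so they idle near
#  zero tokens and are permanently enabled) and is de-phosphorylated
#  directly by the relay, which pulls it down to <= 27 in the atrophic
#  state.  Every stimulus-to-marker path runs through the relay, so
#  inhibiting it restores every marker; the panel's expected atrophic
#  direction, derived from this wiring, is "down" for every marker.

#' Specification of a synthetic phosphorylation network scenario
#'
#' @param n_kinases,n_phosphatases,n_substrates node counts by role.
#' @param n_phospho_edges,n_dephospho_edges interaction counts by type
#'   (phosphorylation edges originate only from kinases, de-phosphorylation
#'   edges only from phosphatases).
#' @param frac_without_phosph fraction of (non-motif) enzymes activated
#'   without phosphorylation; default 0.05, mirroring the roughly 25-in-526
#'   share seen in curated kinase/phosphatase annotation.
#' @param n_markers marker panel size (default 5, the size of a validated
#'   atrophy marker panel).
#' @param n_stimulus_targets direct targets of the stimulus (default 6: with
#'   10% degradation a planted relay needs fan-in of at least 6 clamped
#'   targets to cross the default threshold from any initial marking — see
#'   the file header and the package vignette).
#' @param plant_relay wire the network so the stimulus influences every
#'   marker exclusively through one relay enzyme (the recoverable ground
#'   truth for screening tests).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_kinases = 12L, n_phosphatases = 3L,
                       n_substrates = 20L, n_phospho_edges = 40L,
                       n_dephospho_edges = 10L, frac_without_phosph = 0.05,
                       n_markers = 5L, n_stimulus_targets = 6L,
                       plant_relay = FALSE, seed = 1L) {
  spec <- list(n_kinases = as.integer(n_kinases),
               n_phosphatases = as.integer(n_phosphatases),
               n_substrates = as.integer(n_substrates),
               n_phospho_edges = as.integer(n_phospho_edges),
               n_dephospho_edges = as.integer(n_dephospho_edges),
               frac_without_phosph = as.numeric(frac_without_phosph),
               n_markers = as.integer(n_markers),
               n_stimulus_targets = as.integer(n_stimulus_targets),
               plant_relay = isTRUE(plant_relay),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_kinases >= 1L, n_phosphatases >= 0L, n_substrates >= 1L,
              n_phospho_edges >= 0L, n_dephospho_edges >= 0L,
              frac_without_phosph >= 0, frac_without_phosph < 1,
              n_markers >= 1L, n_markers <= n_substrates,
              n_stimulus_targets >= 1L, n_stimulus_targets <= n_kinases)
    if (n_dephospho_edges > 0L && n_phosphatases == 0L) {
      stop_ppn("de-phosphorylation edges require at least one phosphatase",
               class = "ppn_validation_error")
    }
  })
  if (spec$plant_relay) {
    if (spec$n_stimulus_targets < 6L) {
      stop_ppn("plant_relay needs n_stimulus_targets >= 6 (relay fan-in must clear the threshold from any start)",
               class = "ppn_validation_error")
    }
    if (spec$n_kinases < spec$n_stimulus_targets + 4L) {
      stop_ppn("plant_relay needs n_kinases >= n_stimulus_targets + 4 (a pool of 4 constitutive kinases)",
               class = "ppn_validation_error")
    }
    if (spec$n_phosphatases < 1L) {
      stop_ppn("plant_relay needs at least one phosphatase (the relay)",
               class = "ppn_validation_error")
    }
  }
  structure(spec, class = "synth_spec")
}

safe_sample <- function(x, n) x[sample.int(length(x), n)]

# Sample `n` ordered (from, to) pairs uniformly without replacement from
# origins x targets, excluding self-loops and `exclude` pairs.
sample_edges <- function(origins, targets, n, exclude = character(0)) {
  if (n == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(from = origins, to = targets,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$from != grid$to, , drop = FALSE]
  key <- paste(grid$from, grid$to, sep = "\r")
  grid <- grid[!(key %in% exclude), , drop = FALSE]
  if (nrow(grid) < n) {
    stop_ppn("infeasible synthetic spec: need %d edges but only %d candidate pairs",
             n, nrow(grid), class = "ppn_validation_error")
  }
  out <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_df <- function(from, to, itype) {
  n <- length(from)
  data.frame(enzyme_id = from, substrate_id = to,
             itype = rep(itype, n),
             source = rep("synthetic", n), stringsAsFactors = FALSE)
}

#' Generate a synthetic phosphorylation network and scenario
#'
#' Builds a random kinase/phosphatase/substrate network obeying all
#' [phospho_network()] invariants, together with a runnable scenario: the
#' stimulus's direct targets, a marker panel whose expected atrophic
#' directions are derived from the planted wiring, and (with
#' `plant_relay = TRUE`) a relay enzyme that is the unique cut vertex between
#' stimulus and markers.  Marker reachability from the stimulus — and, for a
#' planted relay, the fact that removing the relay disconnects every marker
#' from every stimulus target — is asserted at generation time.
#'
#' @param spec a [synth_spec()].
#' @return list with elements `network` (a [phospho_network()]) and
#'   `scenario` (list with `stimulus_targets`, `panel` (a [marker_panel()])
#'   and `relay`, `NA` when none is planted).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  kin <- sprintf("K%02d", seq_len(spec$n_kinases))
  phos <- if (spec$n_phosphatases) {
    sprintf("P%02d", seq_len(spec$n_phosphatases))
  } else character(0)
  sub <- sprintf("S%02d", seq_len(spec$n_substrates))
  all_ids <- c(kin, phos, sub)
  enzymes <- c(kin, phos)

  stim <- safe_sample(kin, spec$n_stimulus_targets)
  markers <- safe_sample(sub, spec$n_markers)
  activation <- stats::setNames(rep("with_phosphorylation", length(all_ids)),
                                all_ids)
  planted <- edge_df(character(0), character(0), character(0))
  relay <- NA_character_

  if (spec$plant_relay) {
    cpool <- safe_sample(setdiff(kin, stim), 4L)
    relay <- safe_sample(phos, 1L)
    activation[cpool] <- "without_phosphorylation"

    planted <- rbind(
      # stimulus targets fan into the relay phosphatase (ON only when clamped)
      edge_df(stim, rep(relay, length(stim)), "phosphorylation"),
      # the constitutive pool holds every marker in the 26-36 band
      edge_df(rep(cpool, each = length(markers)),
              rep(markers, times = length(cpool)), "phosphorylation"),
      # the relay pulls every marker down when active
      edge_df(rep(relay, length(markers)), markers, "de_phosphorylation"))
    if (sum(planted$itype == "phosphorylation") > spec$n_phospho_edges ||
        sum(planted$itype == "de_phosphorylation") > spec$n_dephospho_edges) {
      stop_ppn("infeasible synthetic spec: planted relay motif needs more edges than requested",
               class = "ppn_validation_error")
    }
    motif <- c(stim, relay, cpool, markers)
    p_origins <- setdiff(kin, stim)
    d_origins <- setdiff(phos, relay)
    filler_targets <- setdiff(all_ids, motif)
    directions <- rep("down", length(markers))
  } else {
    if (spec$n_phospho_edges < spec$n_markers) {
      stop_ppn("infeasible synthetic spec: need at least one phosphorylation edge per marker",
               class = "ppn_validation_error")
    }
    from <- stim[sample.int(length(stim), spec$n_markers, replace = TRUE)]
    planted <- edge_df(from, markers, "phosphorylation")
    n_wo <- min(round(spec$frac_without_phosph * length(enzymes)),
                length(enzymes))
    if (n_wo > 0L) {
      activation[safe_sample(enzymes, n_wo)] <- "without_phosphorylation"
    }
    p_origins <- kin
    d_origins <- phos
    filler_targets <- all_ids
  }

  if (spec$plant_relay) {
    filler_enz <- setdiff(enzymes, c(stim, cpool, relay))
    n_wo <- min(round(spec$frac_without_phosph * length(filler_enz)),
                length(filler_enz))
    if (n_wo > 0L) {
      activation[safe_sample(filler_enz, n_wo)] <- "without_phosphorylation"
    }
  }

  planted_key <- paste(planted$enzyme_id, planted$substrate_id, sep = "\r")
  n_fill_p <- spec$n_phospho_edges -
    sum(planted$itype == "phosphorylation")
  n_fill_d <- spec$n_dephospho_edges -
    sum(planted$itype == "de_phosphorylation")
  fill_p <- sample_edges(p_origins, filler_targets, n_fill_p, planted_key)
  fill_d <- sample_edges(d_origins, filler_targets, n_fill_d, planted_key)

  interactions <- rbind(planted,
                        edge_df(fill_p$from, fill_p$to, "phosphorylation"),
                        edge_df(fill_d$from, fill_d$to, "de_phosphorylation"))
  roles <- c(rep("kinase", length(kin)), rep("phosphatase", length(phos)),
             rep("substrate_only", length(sub)))
  act <- unname(activation[all_ids])
  act[roles == "substrate_only"] <- "with_phosphorylation"
  nodes <- data.frame(id = all_ids, role = roles, activation = act,
                      stringsAsFactors = FALSE)
  network <- phospho_network(nodes, interactions)

  g <- network_graph(network)
  d <- igraph::distances(g, v = stim, to = markers, mode = "out")
  if (!all(apply(is.finite(d), 2L, any))) {
    stop_ppn("internal error: generated marker unreachable from the stimulus",
             class = "ppn_internal_error")
  }
  if (spec$plant_relay) {
    g2 <- igraph::delete_vertices(g, relay)
    d2 <- igraph::distances(g2, v = stim, to = markers, mode = "out")
    if (any(is.finite(d2))) {
      stop_ppn("internal error: planted relay is not a stimulus-marker cut vertex",
               class = "ppn_internal_error")
    }
  }

  scenario <- list(
    stimulus_targets = stim,
    panel = if (spec$plant_relay) {
      marker_panel(markers, directions)
    } else {
      marker_panel(markers, rep("up", length(markers)))
    },
    relay = relay)
  list(network = network, scenario = scenario)
}

#' Write a complete runnable scenario to disk
#'
#' Emits the network TSVs (readable by [load_network()]), the marker panel
#' TSV (readable by [read_panel()]), a simulation configuration
#' (readable by [read_sim_config()]) and a scenario key-value file naming
#' the stimulus targets and any planted relay.
#'
#' @param generated the list returned by [generate_network()].
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()] to write alongside the scenario.
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(generated, out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(interactions = file.path(out_dir, "interactions.tsv"),
             annotations = file.path(out_dir, "annotations.tsv"),
             panel = file.path(out_dir, "panel.tsv"),
             config = file.path(out_dir, "config.cfg"),
             scenario = file.path(out_dir, "scenario.cfg"))
  write_network(generated$network, paths[["interactions"]],
                paths[["annotations"]])
  write_panel(generated$scenario$panel, paths[["panel"]])
  write_sim_config(config, paths[["config"]])
  write_keyvals(list(
    stimulus_targets = paste(generated$scenario$stimulus_targets,
                             collapse = ","),
    relay = if (is.na(generated$scenario$relay)) "" else
      generated$scenario$relay), paths[["scenario"]])
  invisible(paths)
}

#' Read a scenario key-value file written by [write_fixture()]
#'
#' @param path the `scenario.cfg` path.
#' @return list with `stimulus_targets` (character vector) and `relay`
#'   (id or `NA`).
#' @export
read_scenario <- function(path) {
  kv <- read_keyvals(path)
  st <- kv[["stimulus_targets"]] %||% ""
  relay <- kv[["relay"]] %||% ""
  list(stimulus_targets = if (nzchar(st)) strsplit(st, ",")[[1]] else character(0),
       relay = if (nzchar(relay)) relay else NA_character_)
}
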