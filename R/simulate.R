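#  Phosphorylation-specific Petri net execution.
#
#  Places are proteins, tokens count phosphates.  A transition (enzyme ->
#  substrate) is gated only by its input place: an enzyme activated *with*
#  phosphorylation enables its transitions when its tokens exceed the
#  enabling threshold, one activated *without* phosphorylation when its
#  tokens are below it.  Firing adds (phosphorylation) or removes
#  (de-phosphorylation, clamped at zero) one token on the substrate and
#  never touches the enzyme.  One block = one pass over a freshly shuffled
#  transition list followed by a degradation step removing 10% of the tokens
#  in every place.

#' Simulation configuration
#'
#' @param threshold enabling threshold \eqn{\tau} (tokens); default 35, the
#'   most robust value under the pairwise rank-correlation scan (see
#'   [scan_thresholds()]).
#' @param blocks number of blocks per simulation (default 100; token counts
#'   saturate well before the final block at the default degradation rate).
#' @param degradation_rate fraction of tokens removed from every place after
#'   each block (default 0.10); counts update as
#'   \eqn{n \leftarrow \lfloor(1-\gamma)n\rfloor}.
#' @param iterations number of independently seeded simulations averaged into
#'   a phosphorylation status (default 10).
#' @param init_max upper bound of the uniform integer initial marking,
#'   default twice the enabling threshold.
#' @param seed master seed; every random stream is derived from it via
#'   [mix_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(threshold = 35L, blocks = 100L, degradation_rate = 0.1,
                       iterations = 10L, init_max = 2L * threshold,
                       seed = 1L) {
  threshold <- as.integer(threshold)
  blocks <- as.integer(blocks)
  iterations <- as.integer(iterations)
  init_max <- as.integer(init_max)
  seed <- as.integer(seed)
  stopifnot(length(threshold) == 1L, threshold > 0L,
            length(blocks) == 1L, blocks > 0L,
            length(iterations) == 1L, iterations > 0L,
            length(init_max) == 1L, init_max >= 0L,
            length(degradation_rate) == 1L,
            degradation_rate > 0, degradation_rate < 1,
            length(seed) == 1L, !is.na(seed))
  structure(list(threshold = threshold, blocks = blocks,
                 degradation_rate = degradation_rate,
                 iterations = iterations, init_max = init_max, seed = seed),
            class = "sim_config")
}

#' Read / write a simulation configuration as a flat key-value file
#'
#' @param path file path.
#' @return [read_sim_config()] returns a [sim_config()];
#'   `write_sim_config()` returns the path invisibly.
#' @export
read_sim_config <- function(path) {
  kv <- read_keyvals(path)
  known <- c("threshold", "blocks", "degradation_rate", "iterations",
             "init_max", "seed")
  kv <- kv[names(kv) %in% known]
  args <- lapply(kv, as.numeric)
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  write_keyvals(unclass(config), path)
}

#' State-specific perturbation
#'
#' Perturbations are applied before every transition check.  `clamp_high`
#' places model a persistent stimulus (the atrophic state clamps the
#' stimulus's direct targets to high activity, standing in for myostatin,
#' which carries no place of its own); `inhibit` places model a gene
#' knock-down: their tokens are forced to zero *and* every transition whose
#' input place is inhibited is suppressed, so that enzymes activated without
#' phosphorylation (for which zero tokens would otherwise mean *active*) are
#' silenced too.
#'
#' @param clamp_high character vector of place ids held at `high_value`.
#' @param inhibit character vector of place ids forced to zero activity.
#' @param high_value token count assigned to clamped places (default 70,
#'   twice the default enabling threshold).
#' @return an object of class `perturbation`.
#' @export
perturbation <- function(clamp_high = character(0), inhibit = character(0),
                         high_value = 70L) {
  clamp_high <- as.character(clamp_high)
  inhibit <- as.character(inhibit)
  high_value <- as.integer(high_value)
  stopifnot(length(high_value) == 1L, high_value >= 0L)
  both <- intersect(clamp_high, inhibit)
  if (length(both)) {
    stop_ppn("place(s) cannot be both clamped high and inhibited: %s",
             paste(both, collapse = ", "), class = "ppn_config_error")
  }
  structure(list(clamp_high = unique(clamp_high), inhibit = unique(inhibit),
                 high_value = high_value),
            class = "perturbation")
}

#' Transition enabling rule
#'
#' A transition is enabled by its input place alone: strictly more than
#' `threshold` tokens for an enzyme activated with phosphorylation, strictly
#' fewer for one activated without.  A count exactly equal to the threshold
#' enables nothing under either regime.
#'
#' @param input_tokens token count(s) of the input place.
#' @param activation `"with_phosphorylation"` or `"without_phosphorylation"`
#'   (recycled against `input_tokens`).
#' @param threshold enabling threshold.
#' @return logical vector.
#' @export
is_enabled <- function(input_tokens, activation, threshold) {
  stopifnot(all(input_tokens >= 0), all(activation %in% ACTIVATIONS))
  ifelse(activation == "without_phosphorylation",
         input_tokens < threshold,
         input_tokens > threshold)
}

#' Fire a single transition
#'
#' Phosphorylation adds one token to the substrate place; de-phosphorylation
#' removes one, clamped at zero (the net carries no output-side enabling
#' condition, so a de-phosphorylation may fire on an empty substrate without
#' effect).  The enzyme's own tokens are never changed by firing.
#'
#' @param interaction a list or one-row data.frame with `enzyme_id`,
#'   `substrate_id`, `itype`.
#' @param marking named integer vector of token counts.
#' @return the updated marking.
#' @export
fire <- function(interaction, marking) {
  s <- as.character(interaction$substrate_id)
  stopifnot(s %in% names(marking))
  d <- if (interaction$itype == "phosphorylation") 1L else -1L
  marking[s] <- max(0L, marking[s] + d)
  marking
}

#' Token degradation
#'
#' Models bulk protein/phosphate turnover: every place loses `rate` of its
#' tokens after each block, with the count floored to keep it integral, so
#' every positive count strictly decays in the absence of firing.
#'
#' @param marking named integer vector of token counts.
#' @param rate degradation fraction in (0, 1).
#' @return the degraded marking (integer, non-negative).
#' @export
degrade <- function(marking, rate) {
  stopifnot(rate > 0, rate < 1)
  out <- as.integer(floor((1 - rate) * marking))
  names(out) <- names(marking)
  out
}

#' Apply a perturbation to a marking
#'
#' @param marking named integer vector of token counts.
#' @param perturbation a [perturbation()] (or `NULL` for the unperturbed
#'   reference state, in which case the marking is returned untouched).
#' @return the perturbed marking.
#' @export
apply_perturbation <- function(marking, perturbation = NULL) {
  if (is.null(perturbation)) return(marking)
  stopifnot(inherits(perturbation, "perturbation"))
  unknown <- setdiff(c(perturbation$clamp_high, perturbation$inhibit),
                     names(marking))
  if (length(unknown)) {
    stop_ppn("perturbed place(s) not in the marking: %s",
             paste(unknown, collapse = ", "), class = "ppn_config_error")
  }
  marking[perturbation$clamp_high] <- perturbation$high_value
  marking[perturbation$inhibit] <- 0L
  marking
}

# Index-based view of a network for the inner simulation loop.
compile_network <- function(network) {
  stopifnot(inherits(network, "phospho_network"))
  ids <- network$nodes$id
  inter <- network$interactions
  list(
    ids = ids,
    enz = match(inter$enzyme_id, ids),
    sub = match(inter$substrate_id, ids),
    delta = ifelse(inter$itype == "phosphorylation", 1L, -1L),
    with_phos = network$nodes$activation == "with_phosphorylation"
  )
}

compile_perturbation <- function(perturbation, ids) {
  if (is.null(perturbation)) {
    return(list(clamp = integer(0), high = 0L, inhibit = integer(0),
                blocked = rep(FALSE, length(ids))))
  }
  stopifnot(inherits(perturbation, "perturbation"))
  unknown <- setdiff(c(perturbation$clamp_high, perturbation$inhibit), ids)
  if (length(unknown)) {
    stop_ppn("perturbed place(s) not in the network: %s",
             paste(unknown, collapse = ", "), class = "ppn_config_error")
  }
  inhibit <- match(perturbation$inhibit, ids)
  blocked <- rep(FALSE, length(ids))
  blocked[inhibit] <- TRUE
  list(clamp = match(perturbation$clamp_high, ids),
       high = perturbation$high_value, inhibit = inhibit, blocked = blocked)
}

# One pass over the transitions in the order `ord`.  The perturbation is
# re-applied before every transition check and once after the last one (so a
# firing onto a clamped or inhibited place never leaks into the recorded
# marking), inhibited enzymes never fire, and de-phosphorylation clamps the
# substrate at zero.
sweep_transitions <- function(tokens, ord, cn, tau, pt) {
  clamp <- pt$clamp; inhibit <- pt$inhibit
  has_pert <- length(clamp) > 0L || length(inhibit) > 0L
  enz <- cn$enz; sub <- cn$sub; delta <- cn$delta
  with_phos <- cn$with_phos; blocked <- pt$blocked; high <- pt$high
  for (t in ord) {
    if (has_pert) {
      tokens[clamp] <- high
      tokens[inhibit] <- 0L
    }
    e <- enz[t]
    if (blocked[e]) next
    m <- tokens[e]
    if (if (with_phos[e]) m > tau else m < tau) {
      s <- sub[t]
      v <- tokens[s] + delta[t]
      tokens[s] <- if (v < 0L) 0L else v
    }
  }
  if (has_pert) {
    tokens[clamp] <- high
    tokens[inhibit] <- 0L
  }
  tokens
}

#' Execute one simulation block
#'
#' One block shuffles the transition list (using the current R random number
#' state), traverses it once — re-applying the perturbation before each
#' transition check, testing [is_enabled()] on the input place, suppressing
#' transitions of inhibited enzymes, and firing when enabled — and finally
#' applies one [degrade()] step to every place.
#'
#' @param network a [phospho_network()].
#' @param marking named integer vector covering every place.
#' @param perturbation a [perturbation()] or `NULL`.
#' @param threshold enabling threshold.
#' @param degradation_rate degradation fraction.
#' @return the marking after the block.
#' @export
run_block <- function(network, marking, perturbation = NULL, threshold = 35L,
                      degradation_rate = 0.1) {
  cn <- compile_network(network)
  if (!setequal(names(marking), cn$ids) ||
      length(marking) != length(cn$ids)) {
    stop_ppn("marking must cover every place exactly once",
             class = "ppn_config_error")
  }
  tokens <- as.integer(marking[cn$ids])
  pt <- compile_perturbation(perturbation, cn$ids)
  ord <- sample.int(length(cn$enz))
  tokens <- sweep_transitions(tokens, ord, cn, as.integer(threshold), pt)
  tokens <- as.integer(floor((1 - degradation_rate) * tokens))
  stats::setNames(tokens, cn$ids)
}

#' Run one Petri net simulation and record its trajectory
#'
#' The initial marking assigns every place an independent uniform integer in
#' `[0, init_max]` (by default `[0, 2 * threshold]`); the network then runs
#' for `config$blocks` blocks, reshuffling the transition list at each block.
#'
#' @param network a [phospho_network()].
#' @param config a [sim_config()].
#' @param perturbation a [perturbation()] or `NULL`.
#' @param seed seed for this simulation (defaults to `config$seed`).
#' @return integer matrix, one row per block and one column per place, with
#'   the initial marking in attribute `"initial_marking"`.
#' @export
simulate_trajectory <- function(network, config, perturbation = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cn <- compile_network(network)
  pt <- compile_perturbation(perturbation, cn$ids)
  n_place <- length(cn$ids)
  n_trans <- length(cn$enz)
  tau <- config$threshold
  gamma <- config$degradation_rate

  set.seed(seed)
  tokens <- sample.int(config$init_max + 1L, n_place, replace = TRUE) - 1L
  init <- stats::setNames(tokens, cn$ids)
  traj <- matrix(0L, nrow = config$blocks, ncol = n_place,
                 dimnames = list(NULL, cn$ids))
  for (b in seq_len(config$blocks)) {
    ord <- if (n_trans) sample.int(n_trans) else integer(0)
    tokens <- sweep_transitions(tokens, ord, cn, tau, pt)
    tokens <- as.integer(floor((1 - gamma) * tokens))
    traj[b, ] <- tokens
  }
  attr(traj, "initial_marking") <- init
  traj
}

#' Phosphorylation status of a state
#'
#' Runs `config$iterations` simulations with sub-seeds derived from `seed`
#' via [mix_seed()] and returns, for every place, the arithmetic mean of the
#' final-block (saturated) token counts — the phosphorylation status of the
#' state defined by `perturbation`.
#'
#' @inheritParams simulate_trajectory
#' @return named numeric vector (one value per place), with the matrix of
#'   final markings in attribute `"finals"`.
#' @export
simulate_state <- function(network, config, perturbation = NULL,
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n_place <- nrow(network$nodes)
  finals <- matrix(0L, nrow = config$iterations, ncol = n_place,
                   dimnames = list(NULL, network$nodes$id))
  for (i in seq_len(config$iterations)) {
    traj <- simulate_trajectory(network, config, perturbation,
                                seed = mix_seed(seed, "iteration", i))
    finals[i, ] <- traj[config$blocks, ]
  }
  status <- colMeans(finals)
  attr(status, "finals") <- finals
  status
}
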