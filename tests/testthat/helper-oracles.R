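# Fixtures built in code and independent oracles used across the suite.

# A 4-protein toy network: kinase K1 phosphorylates S1 and S2, phosphatase
# P1 de-phosphorylates S1.
toy_network <- function() {
  phospho_network(
    nodes = data.frame(
      id = c("K1", "P1", "S1", "S2"),
      role = c("kinase", "phosphatase", "substrate_only", "substrate_only"),
      activation = c("with_phosphorylation", "with_phosphorylation",
                     "with_phosphorylation", "with_phosphorylation")),
    interactions = data.frame(
      enzyme_id = c("K1", "K1", "P1"),
      substrate_id = c("S1", "S2", "S1"),
      itype = c("phosphorylation", "phosphorylation", "de_phosphorylation")))
}

write_toy_tsvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ip <- file.path(dir, "interactions.tsv")
  ap <- file.path(dir, "annotations.tsv")
  writeLines(c("enzyme_id\tsubstrate_id\titype\tsource",
               "K1\tS1\tP\tdb1",
               "K1\tS2\tP\tdb1",
               "P1\tS1\tD\tdb2"), ip)
  writeLines(c("protein_id\trole\tactivation",
               "K1\tkinase\twith",
               "P1\tphosphatase\twith",
               "S1\tsubstrate\twith",
               "S2\tsubstrate\twith"), ap)
  c(interactions = ip, annotations = ap)
}

# O(n^2) Spearman oracle: tied ranks computed by pairwise comparison counts,
# then Pearson's r evaluated from explicit sums.
oracle_spearman <- function(x, y) {
  tied_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  rx <- tied_rank(x)
  ry <- tied_rank(y)
  mx <- sum(rx) / length(rx)
  my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Hypergeometric upper tail by explicit enumeration of all C(N, n) draws
# (feasible for N <= 12).
oracle_hyper_enum <- function(N, K, n, k) {
  population <- seq_len(N)
  gold <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% gold))
  mean(hits >= k)
}

# Hypergeometric upper tail by log-gamma pmf summation (independent of
# stats::dhyper).
oracle_hyper_lgamma <- function(N, K, n, k) {
  i <- seq(max(k, max(0, n - (N - K))), min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Reference one-block sweep composed from the exported elementary operations
# (apply_perturbation / is_enabled / fire / degrade), traversing transitions
# in the given order.
oracle_run_block <- function(network, marking, pert, ord, tau, rate) {
  nodes <- network$nodes
  act <- stats::setNames(nodes$activation, nodes$id)
  inhibited <- if (is.null(pert)) character(0) else pert$inhibit
  for (t in ord) {
    row <- network$interactions[t, ]
    marking <- apply_perturbation(marking, pert)
    if (row$enzyme_id %in% inhibited) next
    if (is_enabled(marking[[row$enzyme_id]], act[[row$enzyme_id]], tau)) {
      marking <- fire(row, marking)
    }
  }
  marking <- apply_perturbation(marking, pert)
  degrade(marking, rate)
}

in_degree <- function(network) {
  tab <- table(factor(network$interactions$substrate_id,
                      levels = network$nodes$id))
  stats::setNames(as.integer(tab), network$nodes$id)
}

# Trajectory bound asserted by the suite: a place with in-degree d gains at
# most d tokens per block against a 10% decay, so it can never exceed
# max(init_max, 10 d + 10).
trajectory_bound <- function(network, init_max) {
  d <- in_degree(network)
  stats::setNames(pmax(init_max, 10L * d + 10L), names(d))
}
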