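test_that("load_network reads TSV tables and validates endpoints", {
  paths <- write_toy_tsvs()
  net <- load_network(paths[["interactions"]], paths[["annotations"]])
  expect_s3_class(net, "phospho_network")
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$interactions), 3L)
  expect_setequal(net$interactions$itype,
                  c("phosphorylation", "de_phosphorylation"))
  expect_equal(net$interactions$source[1], "db1")

  # empty interaction table keeps the annotated nodes
  empty <- file.path(dirname(paths[["interactions"]]), "empty.tsv")
  writeLines("enzyme_id\tsubstrate_id\titype\tsource", empty)
  net0 <- load_network(empty, paths[["annotations"]])
  expect_equal(nrow(net0$nodes), 4L)
  expect_equal(nrow(net0$interactions), 0L)

  # an interaction naming an unannotated protein is a validation error
  dangling <- file.path(dirname(paths[["interactions"]]), "dangling.tsv")
  writeLines(c("enzyme_id\tsubstrate_id\titype\tsource",
               "K1\tS9\tP\t"), dangling)
  expect_error(load_network(dangling, paths[["annotations"]]),
               "S9", class = "ppn_validation_error")

  # a malformed type code is reported with its line number
  bad <- file.path(dirname(paths[["interactions"]]), "bad.tsv")
  writeLines(c("enzyme_id\tsubstrate_id\titype\tsource",
               "K1\tS1\tP\t",
               "K1\tS2\tX\t"), bad)
  expect_error(load_network(bad, paths[["annotations"]]),
               "line 3", class = "ppn_parse_error")
})

test_that("network construction enforces the model invariants", {
  nodes <- toy_network()$nodes
  inter <- toy_network()$interactions
  expect_error(phospho_network(rbind(nodes, nodes[1, ]), inter),
               "duplicated", class = "ppn_validation_error")
  bad_act <- nodes
  bad_act$activation[3] <- "without_phosphorylation"  # a substrate-only node
  expect_error(phospho_network(bad_act, inter), "substrate-only",
               class = "ppn_validation_error")
  bad_enz <- inter
  bad_enz$enzyme_id[1] <- "S2"
  expect_error(phospho_network(nodes, bad_enz), "not kinases",
               class = "ppn_validation_error")
  expect_error(phospho_network(nodes, rbind(inter, inter[1, ])),
               "deduplicate", class = "ppn_validation_error")
})

test_that("write/load round trip preserves the network exactly", {
  gen <- generate_network(synth_spec(seed = 42L))
  dir <- withr::local_tempdir()
  write_network(gen$network, file.path(dir, "i.tsv"), file.path(dir, "a.tsv"))
  back <- load_network(file.path(dir, "i.tsv"), file.path(dir, "a.tsv"))
  expect_equal(back$nodes, gen$network$nodes)
  expect_equal(back$interactions, gen$network$interactions)
})

test_that("deduplication collapses exact triples, keeps first provenance, and is idempotent", {
  mk <- function(e, s, t, src = NA_character_) {
    data.frame(enzyme_id = e, substrate_id = s, itype = t, source = src)
  }
  dup <- rbind(mk("K1", "S1", "phosphorylation", "first"),
               mk("K1", "S1", "phosphorylation", "second"))
  out <- deduplicate_interactions(dup)
  expect_equal(nrow(out), 1L)
  expect_equal(out$source, "first")

  # opposite types on the same pair are a conflict, not a duplicate
  conf <- rbind(mk("K1", "S1", "phosphorylation"),
                mk("K1", "S1", "de_phosphorylation"))
  expect_equal(deduplicate_interactions(conf), conf)

  five <- rbind(mk("K1", "S1", "phosphorylation"),
                mk("K1", "S1", "phosphorylation"),
                mk("K1", "S2", "phosphorylation"),
                mk("P1", "S1", "de_phosphorylation"),
                mk("P1", "S1", "de_phosphorylation"))
  expect_equal(nrow(deduplicate_interactions(five)), 3L)

  for (seed in 1:5) {
    set.seed(seed)
    n <- 30L
    tab <- mk(sample(c("K1", "K2"), n, TRUE), sample(c("S1", "S2"), n, TRUE),
              sample(c("phosphorylation", "de_phosphorylation"), n, TRUE))
    once <- deduplicate_interactions(tab)
    expect_lte(nrow(once), nrow(tab))
    expect_equal(deduplicate_interactions(once), once)
  }
})

test_that("conflict resolution honors curated evidence and drops unresolved pairs", {
  inter <- data.frame(
    enzyme_id = c("K1", "K1", "K2", "K2", "K3"),
    substrate_id = c("S1", "S1", "S2", "S2", "S3"),
    itype = c("phosphorylation", "de_phosphorylation",
              "phosphorylation", "de_phosphorylation", "phosphorylation"),
    source = NA_character_)
  res <- data.frame(enzyme_id = "K1", substrate_id = "S1", keep = "P")
  expect_warning(resolve_conflicts(inter, res), "without resolution")
  out <- suppressWarnings(resolve_conflicts(inter, res))
  expect_equal(out$itype[out$enzyme_id == "K1"], "phosphorylation")
  expect_false("K2" %in% out$enzyme_id)   # unresolved conflict dropped wholesale
  expect_true("K3" %in% out$enzyme_id)

  # no conflicts: identity
  clean <- inter[c(1, 3, 5), ]
  expect_equal(resolve_conflicts(clean), clean, ignore_attr = "row.names")

  # a resolution entry for a non-conflicted pair is ignored with a warning
  extraneous <- data.frame(enzyme_id = "K3", substrate_id = "S3", keep = "P")
  expect_warning(resolve_conflicts(clean, extraneous), "non-conflicted")
})

test_that("activation inference applies the override rule order-independently", {
  pairs <- data.frame(
    enzyme_id = c("Q1", "Q2", "Q3"),
    target_id = c("K1", "K1", "K2"),
    effect = c("activation", "activation", "inhibition"),
    mechanism = c("phosphorylation", "de_phosphorylation", "phosphorylation"))
  # activation + de-phosphorylation flips the default
  expect_equal(infer_activation(pairs, "K1"), "without_phosphorylation")
  # inhibition + phosphorylation flips it too
  expect_equal(infer_activation(pairs, "K2"), "without_phosphorylation")
  # activation + phosphorylation (or no evidence) keeps the cascade default
  expect_equal(infer_activation(pairs[1, ], "K1"), "with_phosphorylation")
  expect_equal(infer_activation(pairs, "K9"), "with_phosphorylation")
  for (i in 1:5) {
    set.seed(i)
    shuffled <- pairs[sample.int(nrow(pairs)), ]
    expect_equal(infer_activation(shuffled, "K1"), "without_phosphorylation")
  }
})

test_that("tissue filtering removes undetected endpoints plus orphans and is idempotent", {
  net <- toy_network()
  # S2 undetected: the K1->S2 interaction disappears and S2 with it
  f <- filter_by_tissue(net, c("K1", "P1", "S1"))
  expect_setequal(f$nodes$id, c("K1", "P1", "S1"))
  expect_equal(nrow(f$interactions), 2L)
  expect_equal(filter_by_tissue(f, c("K1", "P1", "S1")), f)
  # all detected: identity
  expect_equal(filter_by_tissue(net, net$nodes$id), net)
  # nothing detected: empty network
  e <- filter_by_tissue(net, character(0))
  expect_equal(nrow(e$nodes), 0L)
  expect_equal(nrow(e$interactions), 0L)
})

test_that("network statistics count roles, edge types and activation regimes", {
  s <- network_stats(toy_network())
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_kinases, 1L)
  expect_equal(s$n_phosphatases, 1L)
  expect_equal(s$n_substrate_only, 2L)
  expect_equal(s$n_phosphorylation, 2L)
  expect_equal(s$n_de_phosphorylation, 1L)
  expect_equal(s$n_without_phosphorylation, 0L)

  empty <- filter_by_tissue(toy_network(), character(0))
  expect_true(all(unlist(network_stats(empty)) == 0L))

  gen <- generate_network(synth_spec(n_kinases = 10L, n_phosphatases = 3L,
                                     n_substrates = 20L, seed = 7L))
  expect_equal(network_stats(gen$network)$n_kinases, 10L)
})
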