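test_that("the enabling rule is strict in both activation regimes", {
  expect_true(is_enabled(36, "with_phosphorylation", 35))
  expect_false(is_enabled(34, "with_phosphorylation", 35))
  expect_true(is_enabled(34, "without_phosphorylation", 35))
  expect_false(is_enabled(36, "without_phosphorylation", 35))
  # a count exactly at the threshold enables nothing under either regime
  expect_false(is_enabled(35, "with_phosphorylation", 35))
  expect_false(is_enabled(35, "without_phosphorylation", 35))
  expect_equal(is_enabled(c(0, 35, 70),
                          rep("with_phosphorylation", 3), 35),
               c(FALSE, FALSE, TRUE))
  expect_error(is_enabled(10, "sometimes", 35))
})

test_that("firing changes only the substrate, by one token, clamped at zero", {
  m <- c(K1 = 40L, S1 = 10L)
  p <- list(enzyme_id = "K1", substrate_id = "S1", itype = "phosphorylation")
  d <- list(enzyme_id = "K1", substrate_id = "S1", itype = "de_phosphorylation")
  expect_equal(fire(p, m), c(K1 = 40L, S1 = 11L))
  expect_equal(fire(d, m), c(K1 = 40L, S1 = 9L))
  # de-phosphorylation on an empty substrate fires without effect
  expect_equal(fire(d, c(K1 = 40L, S1 = 0L)), c(K1 = 40L, S1 = 0L))
  # total-token deltas: +1 for phosphorylation, -1 (or 0 at the clamp) for
  # de-phosphorylation; the enzyme place is never altered
  for (tok in c(0L, 1L, 7L)) {
    m2 <- c(K1 = 40L, S1 = tok)
    expect_equal(sum(fire(p, m2)) - sum(m2), 1L)
    expect_equal(sum(fire(d, m2)) - sum(m2), if (tok == 0L) 0L else -1L)
    expect_equal(fire(p, m2)[["K1"]], 40L)
    expect_equal(fire(d, m2)[["K1"]], 40L)
  }
})

test_that("degradation floors to an integer and strictly decays positive counts", {
  expect_equal(degrade(c(A = 10L), 0.1), c(A = 9L))
  expect_equal(degrade(c(A = 35L), 0.1), c(A = 31L))  # floor(31.5)
  expect_equal(degrade(c(A = 0L), 0.1), c(A = 0L))
  n <- 1:100
  out <- degrade(stats::setNames(n, paste0("p", n)), 0.1)
  expect_true(all(out < n))
  expect_true(all(out >= 0L))
  expect_type(out, "integer")
  expect_error(degrade(c(A = 1L), 1.5))
})

test_that("perturbations clamp, inhibit, reject overlap and unknown places", {
  m <- c(A = 12L, G = 55L, X = 3L)
  expect_equal(apply_perturbation(m, perturbation(clamp_high = "A",
                                                  high_value = 70L)),
               c(A = 70L, G = 55L, X = 3L))
  expect_equal(apply_perturbation(m, perturbation(inhibit = "G")),
               c(A = 12L, G = 0L, X = 3L))
  expect_equal(apply_perturbation(m, NULL), m)
  expect_equal(apply_perturbation(m, perturbation()), m)
  expect_error(perturbation(clamp_high = "A", inhibit = "A"),
               class = "ppn_config_error")
  expect_error(apply_perturbation(m, perturbation(inhibit = "ZZ")),
               class = "ppn_config_error")
})

test_that("a block is the composition of the elementary operations", {
  net <- generate_network(synth_spec(seed = 9L))$network
  n_trans <- nrow(net$interactions)
  marking <- stats::setNames(rep(20L, nrow(net$nodes)), net$nodes$id)
  perts <- list(NULL,
                perturbation(clamp_high = net$nodes$id[1],
                             inhibit = net$nodes$id[2], high_value = 70L))
  for (pert in perts) {
    for (seed in 1:3) {
      set.seed(seed)
      got <- run_block(net, marking, pert, threshold = 12L,
                       degradation_rate = 0.1)
      set.seed(seed)
      ord <- sample.int(n_trans)
      want <- oracle_run_block(net, marking, pert, ord, 12L, 0.1)
      expect_identical(got, want)
    }
  }
})

test_that("a network with no transitions changes only by degradation", {
  net <- phospho_network(toy_network()$nodes,
                         toy_network()$interactions[0, ])
  m <- c(K1 = 10L, P1 = 10L, S1 = 10L, S2 = 0L)
  expect_equal(run_block(net, m, NULL, 35L, 0.1),
               c(K1 = 9L, P1 = 9L, S1 = 9L, S2 = 0L))
})

test_that("trajectories are integral, non-negative, bounded and reproducible", {
  for (seed in 1:3) {
    gen <- generate_network(synth_spec(plant_relay = seed == 2L, seed = seed))
    cfg <- sim_config(blocks = 40L, iterations = 2L, seed = seed)
    pert <- perturbation(clamp_high = gen$scenario$stimulus_targets,
                         high_value = 70L)
    for (p in list(NULL, pert)) {
      traj <- simulate_trajectory(gen$network, cfg, p)
      expect_type(traj, "integer")
      expect_true(all(traj >= 0L))
      bound <- trajectory_bound(gen$network, cfg$init_max)
      expect_true(all(t(traj) <= bound[colnames(traj)]))
      expect_identical(traj, simulate_trajectory(gen$network, cfg, p))
    }
    s1 <- simulate_state(gen$network, cfg, pert)
    s2 <- simulate_state(gen$network, cfg, pert)
    expect_identical(s1, s2)
  }
})

test_that("the all-zero marking is absorbing when every enzyme needs phosphorylation", {
  gen <- generate_network(synth_spec(frac_without_phosph = 0, seed = 4L))
  expect_true(all(gen$network$nodes$activation == "with_phosphorylation"))
  # forcing init_max = 0 starts every simulation from the absorbing state
  cfg <- sim_config(blocks = 20L, iterations = 2L, init_max = 0L, seed = 4L)
  traj <- simulate_trajectory(gen$network, cfg, NULL)
  expect_true(all(traj == 0L))
  m0 <- stats::setNames(rep(0L, nrow(gen$network$nodes)), gen$network$nodes$id)
  expect_equal(unname(run_block(gen$network, m0, NULL, 35L, 0.1)),
               rep(0L, length(m0)))
})

test_that("an inhibited place is zero throughout its trajectory and status", {
  gen <- generate_network(synth_spec(seed = 5L))
  victim <- gen$scenario$stimulus_targets[1]
  cfg <- sim_config(blocks = 30L, iterations = 3L, seed = 5L)
  pert <- perturbation(inhibit = victim)
  traj <- simulate_trajectory(gen$network, cfg, pert)
  expect_true(all(traj[, victim] == 0L))
  status <- simulate_state(gen$network, cfg, pert)
  expect_equal(unname(status[victim]), 0)
})

test_that("clamping an upstream activator raises the downstream status", {
  chain <- phospho_network(
    nodes = data.frame(
      id = c("A", "K1", "M"),
      role = c("kinase", "kinase", "substrate_only"),
      activation = rep("with_phosphorylation", 3)),
    interactions = data.frame(
      enzyme_id = c("A", "K1"), substrate_id = c("K1", "M"),
      itype = rep("phosphorylation", 2)))
  cfg <- sim_config(threshold = 5L, blocks = 60L, iterations = 10L,
                    init_max = 10L, seed = 3L)
  on <- simulate_state(chain, cfg, perturbation(clamp_high = "A",
                                                high_value = 10L))
  off <- simulate_state(chain, cfg, NULL)
  expect_gt(on[["M"]], off[["M"]])
})

test_that("a state's status is the mean of independently seeded final markings", {
  gen <- generate_network(synth_spec(seed = 6L))
  cfg <- sim_config(blocks = 25L, iterations = 4L, seed = 6L)
  status <- simulate_state(gen$network, cfg, NULL, seed = 123L)
  finals <- t(vapply(seq_len(cfg$iterations), function(i) {
    traj <- simulate_trajectory(gen$network, cfg, NULL,
                                seed = mix_seed(123L, "iteration", i))
    traj[cfg$blocks, ]
  }, numeric(nrow(gen$network$nodes))))
  expect_equal(unclass(status)[names(status)], colMeans(finals),
               ignore_attr = TRUE)
  expect_equal(colnames(attr(status, "finals")), gen$network$nodes$id)
})
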