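test_that("probabilistic connectivity has Bernoulli edge statistics", {
  expect_equal(nrow(sample_connectivity(30, 0, seed = 1)), 0)
  expect_equal(nrow(sample_connectivity(30, 1, directed = TRUE, seed = 1)),
               870)  # complete digraph minus self-loops
  counts <- vapply(1:200, function(s)
    nrow(sample_connectivity(30, 0.2, directed = TRUE, seed = s)), 0)
  expect_equal(mean(counts), 174, tolerance = 4 / 174) # 0.2 * 30 * 29
  expect_identical(sample_connectivity(30, 0.2, seed = 5),
                   sample_connectivity(30, 0.2, seed = 5))
  edges <- sample_connectivity(30, 0.5, directed = TRUE, seed = 2)
  expect_true(all(edges$pre != edges$post))
})

test_that("gap-junction current is ohmic and conserved", {
  expect_equal(gap_junction_current(-60, -60, 600),
               c(i_into_a = 0, i_into_b = 0))
  i <- gap_junction_current(-60, 0, 600)
  expect_equal(unname(i[1]), 0.1)      # 60 mV / 600 MOhm
  expect_equal(unname(sum(i)), 0)      # conservation
  i2 <- gap_junction_current(-70, -60, 100)
  expect_equal(unname(abs(i2[1])), 0.1)
  expect_error(gap_junction_current(0, 0, -5))
})

test_that("the dIN population has the stated column structure", {
  net <- build_din_population(n = 30, seed = 3)
  expect_equal(length(net$neurons), 30)
  pos <- vapply(net$neurons, `[[`, 0, "position")
  expect_equal(pos, -10 * (0:29))
  # all chemical synapses target the soma/dendrite compartment
  expect_true(all(net$synapses$comp == 1))
  expect_true(all(net$synapses$pre != net$synapses$post))
  # each connected pair carries an AMPA and an NMDA component
  expect_equal(sum(net$synapses$nmda), nrow(net$synapses) / 2)
  # gap junctions are dense among axon-overlapping pairs and all 600 MOhm
  expect_true(all(net$gap_junctions$resistance == 600))
  expect_gt(nrow(net$gap_junctions), 100)
  # rostral-to-caudal ordering of junction endpoints
  expect_true(all(net$gap_junctions$neuron_a < net$gap_junctions$neuron_b))
  # removing electrical coupling leaves a valid network
  net0 <- remove_gap_junctions(net)
  expect_equal(nrow(net0$gap_junctions), 0)
  # determinism
  expect_identical(build_din_population(seed = 7),
                   build_din_population(seed = 7))
})

test_that("the generic population has soma-to-soma coupling and conductance
           noise with the stated statistics", {
  counts <- vapply(1:200, function(s) {
    net <- build_generic_population(n = 30, seed = s)
    nrow(net$gap_junctions)
  }, 0)
  expect_equal(mean(counts), 87, tolerance = 3 / 87) # 0.2 * 30 * 29 / 2

  net <- build_generic_population(n = 30, seed = 5)
  expect_true(all(net$gap_junctions$comp_a == 1 &
                    net$gap_junctions$comp_b == 1))
  expect_true(all(net$gap_junctions$resistance == 100))
  # sigma2 = 0.1 -> relative sd of the NMDA peak conductances ~ sqrt(0.1)
  gn <- net$synapses$g_peak[net$synapses$nmda]
  expect_gt(sd(gn) / mean(gn), 0.15)

  net0 <- build_generic_population(n = 10, sigma2 = 0, density_sigma = 0,
                                   seed = 5)
  expect_equal(length(unique(net0$synapses$g_peak[net0$synapses$nmda])), 1)
  expect_identical(build_generic_population(seed = 9),
                   build_generic_population(seed = 9))
})

test_that("identical symmetrically coupled neurons stay uniform under a
           uniform stimulus", {
  nets <- build_generic_population(n = 4, p_gj = 1, p_syn = 0, sigma2 = 0,
                                   density_sigma = 0, seed = 1)
  inj <- data.frame(neuron = 1:4, amp = 0.25, t0 = 20, t1 = 300)
  rec <- simulate(nets, list(injections = inj), sim_config(300, dt = 0.025))
  spread <- apply(rec$v, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-6)
})
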