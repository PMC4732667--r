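test_that("dIN construction follows the column geometry and channel
           complement", {
  m <- build_din()
  expect_s3_class(m, "neuron_model")
  expect_equal(sum(m$comps$is_soma), 1)
  expect_setequal(vapply(m$channels[[1]], `[[`, "", "name"),
                  c("leak", "na", "kf", "ks", "ca"))  # 5 channel types
  for (ci in 2:nrow(m$comps))
    expect_true(all(c("na", "kf") %in%
                      vapply(m$channels[[ci]], `[[`, "", "name")))

  # explicit discretisation: 1000 um span, 20 um compartments -> 50 axon
  # compartments descending caudally (decreasing coordinate)
  p <- din_params(axon_span = 1000, axon_comp_len = 20)
  m2 <- build_din(p, position = 0)
  expect_equal(nrow(m2$comps), 51)
  expect_true(all(diff(m2$comps$position_um) < 0))
  expect_gte(min(m2$comps$position_um), -1000)

  # determinism: identical params -> identical models
  expect_identical(build_din(), build_din())
  expect_error(build_din(din_params(axon_span = 5, axon_comp_len = 20)))
})

test_that("generic neuron is a single compartment with leak, Na and K and a
           stable resting state", {
  m <- build_generic_hh()
  expect_equal(nrow(m$comps), 1)
  expect_setequal(vapply(m$channels[[1]], `[[`, "", "name"),
                  c("leak", "na", "k"))
  rec <- simulate(single_neuron_net(m), list(), sim_config(500, dt = 0.025))
  v <- rec$v[rec$time > 100, 1]
  expect_lt(diff(range(v)), 1)           # within 1 mV after settling
  expect_equal(length(rec$spikes[[1]]), 0)
})

test_that("generic neuron frequency under a step current matches a fine-step
           reference", {
  net <- single_neuron_net(build_generic_hh())
  inj <- data.frame(neuron = 1, amp = 0.3, t0 = 100, t1 = 1000)
  rec <- simulate(net, list(injections = inj), sim_config(1000, dt = 0.025))
  f <- firing_frequency(rec$spikes[[1]], c(200, 1000))
  # frozen from a dt = 0.001 ms reference integration of the same model
  expect_equal(f, 70, tolerance = 0.03)
  recf <- simulate(net, list(injections = inj),
                   sim_config(1000, dt = 0.005))
  expect_equal(firing_frequency(recf$spikes[[1]], c(200, 1000)), f,
               tolerance = 0.02)
})

test_that("density noise is multiplicative, truncated, seeded and has the
           stated spread", {
  m <- build_generic_hh()
  expect_identical(apply_density_noise(m, 0), m)
  expect_identical(apply_density_noise(m, 0.1, seed = 3),
                   apply_density_noise(m, 0.1, seed = 3))

  base <- vapply(m$channels[[1]], `[[`, 0, "density")
  mults <- replicate(800, {
    nm <- apply_density_noise(m, 0.1)
    vapply(nm$channels[[1]], `[[`, 0, "density") / base
  })
  expect_equal(mean(mults), 1, tolerance = 0.01)
  expect_equal(sd(as.vector(mults)), 0.1, tolerance = 0.01 / 0.1)
  expect_true(all(mults >= 0))
})

test_that("with all channel densities zero a uniformly polarised cable stays
           constant", {
  p <- din_params(
    soma_channels = list(leak = channel_spec("leak", 0, -60)),
    axon_channels = list(leak = channel_spec("leak", 0, -60)))
  net <- single_neuron_net(build_din(p))
  rec <- simulate(net, list(), sim_config(100, dt = 0.025))
  expect_true(all(abs(rec$v - rec$v[1, 1]) < 1e-9))
})

test_that("a somatic current step elicits a spike that propagates to the last
           axon compartment", {
  m <- build_din()
  net <- single_neuron_net(m)
  inj <- data.frame(neuron = 1, amp = 0.05, t0 = 100, t1 = 300)
  rec <- simulate(net, list(injections = inj), sim_config(400, dt = 0.025),
                  record_comps = data.frame(neuron = 1,
                                            comp = nrow(m$comps)))
  expect_gt(max(rec$v), 0)        # soma spike
  expect_gt(max(rec$v_extra), 0)  # distal axon spike
})
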