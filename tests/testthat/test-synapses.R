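test_that("dual-exponential peak time and normalisation match hand values", {
  pk <- synapse_peak(5, 80)
  expect_equal(pk$t_peak, 14.7871399, tolerance = 1e-6)
  expect_equal(pk$norm, 0.7792855, tolerance = 1e-6)
  pk2 <- synapse_peak(1.5, 20)
  expect_equal(pk2$t_peak, 4.2004332, tolerance = 1e-6)
  expect_equal(pk2$norm, 0.7497742, tolerance = 1e-6)
  # slow-closing limit: norm -> 1
  expect_gt(synapse_peak(5, 1e6)$norm, 0.999)
  expect_error(synapse_peak(5, 5))
  expect_error(synapse_kinetics(5, 5, 1))
})

test_that("single-event conductance peaks at exactly g_peak for all shipped
           kinetics", {
  kins <- list(feedback_nmda(2), feedback_ampa(0.5), gaba_kinetics(2),
               perfusion_nmda(1), synapse_kinetics(0.5, 12, 3.3))
  for (kin in kins) {
    tt <- c(seq(0, 12 * kin$tau_c, by = kin$tau_o / 50), kin$t_peak)
    g <- synapse_conductance(kin, events = 0, t = tt)
    expect_equal(max(g), kin$g_peak, tolerance = 1e-6)
    expect_true(all(g >= 0))
  }
  kin <- feedback_nmda(2)
  expect_equal(synapse_conductance(kin, events = 5, t = 5), 0) # B - A = 0 at onset
  expect_equal(synapse_conductance(kin, numeric(0), t = c(0, 50)), c(0, 0))
})

test_that("magnesium-block voltage dependence matches Eq hand values and is
           monotone", {
  expect_equal(mg_vdep(-80), 1 / (1 + 0.05 * exp(6.4)), tolerance = 1e-9)
  expect_equal(mg_vdep(-80), 0.03216, tolerance = 1e-4)
  expect_equal(mg_vdep(0), 1 / 1.05, tolerance = 1e-9)
  v <- seq(-100, 60, by = 0.5)
  vd <- mg_vdep(v)
  expect_true(all(diff(vd) > 0))
  expect_true(all(vd > 0 & vd <= 1))
  expect_equal(mg_vdep(v, mg_block_params(mg_out = 0)), rep(1, length(v)))
})

test_that("synaptic current follows g*(V - E)*vdep with outward-positive
           sign", {
  kin <- synapse_kinetics(5, 80, 1, e_rev = 0)
  expect_equal(synaptic_current(1, 0, kin), 0)
  expect_equal(synaptic_current(1, -70, kin), -0.07)
  kin_mg <- feedback_nmda(1)
  expect_equal(synaptic_current(1, -70, kin_mg), -0.07 * mg_vdep(-70),
               tolerance = 1e-9)
  expect_equal(synaptic_current(1, -70, kin_mg), -0.0048205,
               tolerance = 1e-4)
})

test_that("summation ratio matches the closed-form values, the fine-step ODE
           oracle, and the monotonicity claims", {
  kin <- feedback_nmda(1)
  expect_equal(summation_ratio(kin, 25, 1), 1.0)
  expect_equal(summation_ratio(kin, 25, 40), 2.70, tolerance = 2e-3)
  expect_equal(summation_ratio(kin, 10, 40), 1.43, tolerance = 3e-3)

  # event-driven result vs brute-force integration of the state ODEs
  for (f in c(10, 25)) {
    ev <- (0:19) * 1000 / f
    oracle <- ode_synapse_max(5, 80, ev, max(ev) + 400, dt = 5e-4)
    expect_equal(summation_ratio(kin, f, 20), oracle, tolerance = 1e-4)
  }

  # non-decreasing in frequency, -> 1 as frequency -> 0
  fr <- c(1, 5, 10, 15, 20, 25, 40, 100)
  ratios <- vapply(fr, function(f) summation_ratio(kin, f, 40), 0)
  expect_true(all(diff(ratios) >= 0))
  expect_equal(summation_ratio(kin, 0.05, 40), 1, tolerance = 1e-3)
  # swimming-frequency bound for the 80 ms closing time
  expect_lt(max(ratios[fr >= 10 & fr <= 25]), 3)
})

test_that("presynaptic events are delivered after the synaptic delay with the
           stated transmission statistics", {
  # two generic neurons; neuron 1 driven to spike, synapse 1 -> 2
  net <- swimnet:::new_network(
    list(build_generic_hh(), build_generic_hh()),
    rbind(swimnet:::.syn_row(1L, 2L, 1L, feedback_ampa(g_peak = 1))),
    empty_gj(), seed = 1)
  inj <- data.frame(neuron = 1, amp = 0.3, t0 = 50, t1 = 60)
  rec <- simulate(net, list(injections = inj), sim_config(120, dt = 0.025))
  expect_equal(length(rec$spikes[[1]]), 1)
  expect_equal(nrow(rec$deliveries), 1)
  expect_equal(rec$deliveries$time, rec$spikes[[1]] + 1, tolerance = 0.025)

  # transmission_p = 0: nothing delivered
  net0 <- net
  net0$synapses$p <- 0
  rec0 <- simulate(net0, list(injections = inj), sim_config(120, dt = 0.025))
  expect_equal(nrow(rec0$deliveries), 0)

  # p = 0.5 over many scheduled events: binomial 3-sigma band
  ev <- schedule_events(1, seq_len(10000), delay = 1, p = 0.5, seed = 7)
  expect_equal(nrow(ev) / 10000, 0.5, tolerance = 0.015)
})
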