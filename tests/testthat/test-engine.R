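test_that("spike detection uses an upward crossing with hysteresis and
           interpolation", {
  tt <- seq(0, 1000, by = 0.1)
  expect_equal(length(detect_spikes(rep(-60, length(tt)), tt)), 0)
  v1 <- synthetic_trace(tt, 500)
  expect_equal(length(detect_spikes(v1, tt)), 1)
  # 20 Hz synthetic train over 1 s: 20 events at 50 +- 0.1 ms intervals
  at <- seq(25, 975, by = 50)
  v20 <- synthetic_trace(tt, at)
  spk <- detect_spikes(v20, tt)
  expect_equal(length(spk), 20)
  expect_true(all(abs(diff(spk) - 50) < 0.1))
  # a wobble above the reset level must not retrigger
  vw <- rep(-60, length(tt))
  vw[tt >= 100 & tt < 120] <- 20
  vw[tt >= 120 & tt < 140] <- -5  # stays above the reset level
  vw[tt >= 140 & tt < 160] <- 20
  expect_equal(length(detect_spikes(vw, tt)), 1)
})

test_that("simulation is deterministic and a settled dIN network stays at
           rest without stimuli", {
  net <- build_din_population(n = 5, seed = 2)
  cfg <- sim_config(400, dt = 0.025, seed = 9)
  r1 <- simulate(net, list(), cfg)
  r2 <- simulate(net, list(), cfg)
  expect_identical(r1$spikes, r2$spikes)   # bit-identical spike tables
  expect_identical(r1$v, r2$v)
  expect_equal(sum(lengths(r1$spikes)), 0)
  late <- r1$v[r1$time > 200, ]
  expect_lt(max(abs(sweep(late, 2, late[nrow(late), ]))), 1)
})

test_that("numerical blow-up aborts with a diagnostic", {
  # a huge sustained current drives V beyond the +-200 mV guard
  net <- single_neuron_net(build_generic_hh())
  inj <- data.frame(neuron = 1, amp = 500, t0 = 0, t1 = 100)
  expect_error(simulate(net, list(injections = inj),
                        sim_config(100, dt = 0.025)),
               "blow-up")
})

test_that("with sodium conductance zero no trace crosses 0 mV under strong
           perfusion", {
  p <- din_params(soma_channels = din_soma_channels(na_density = 0),
                  axon_channels = din_axon_channels(na_density = 0))
  net <- build_din_population(n = 5, din = p, seed = 1)
  pf <- perfusion_table(perfusion_protocol(20, onset = 50, mg = FALSE), 1:5)
  rec <- simulate(net, list(perfusion = pf), sim_config(600, dt = 0.025))
  expect_lt(max(rec$v), 0)
  expect_equal(sum(lengths(rec$spikes)), 0)
})

test_that("halving the step preserves spike times in a small coupled
           network", {
  net <- build_din_population(n = 5, seed = 4,
                              nmda = feedback_nmda(0.3),
                              ampa = feedback_ampa(0.3))
  pf <- perfusion_table(perfusion_protocol(1.5, onset = 50), 1:5)
  r1 <- simulate(net, list(perfusion = pf), sim_config(600, dt = 0.025))
  r2 <- simulate(net, list(perfusion = pf), sim_config(600, dt = 0.0125))
  expect_gt(sum(lengths(r1$spikes)), 5)
  for (n in 1:5) {
    a <- r1$spikes[[n]]; b <- r2$spikes[[n]]
    k <- min(length(a), length(b))
    expect_gt(k, 0)
    expect_lt(max(abs(a[1:k] - b[1:k])), 0.5)
  }
})

test_that("recordings export to CSV and JSON with a config echo", {
  net <- single_neuron_net(build_generic_hh())
  rec <- simulate(net, list(), sim_config(50, dt = 0.025, seed = 3))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_recording_csv(rec, csv)
  long <- read.csv(csv)
  expect_named(long, c("neuron", "t", "v"))
  expect_equal(nrow(long), length(rec$time))
  write_spikes_json(rec, js)
  obj <- jsonlite::read_json(js)
  expect_equal(obj$config$seed, 3)
  unlink(c(csv, js))
})
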