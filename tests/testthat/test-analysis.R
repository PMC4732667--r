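test_that("firing frequency is spike count over window length", {
  expect_equal(firing_frequency(numeric(0), c(0, 1000)), 0)
  expect_equal(firing_frequency(seq(25, 975, by = 50), c(0, 1000)), 20)
  spk <- seq(100, 900, by = 40)
  expect_equal(firing_frequency(spk, c(100, 900)), 25, tolerance = 0.05)
  expect_error(firing_frequency(1, c(10, 10)))
})

test_that("sustained means at least one spike in the final quiet tail", {
  expect_false(sustained_flag(numeric(0), 1500))
  expect_true(sustained_flag(c(100, 800, 1450), 1500))
  expect_false(sustained_flag(seq(100, 400, by = 40), 1500))
  expect_true(sustained_flag(1250, 1500, quiet_tail = 300))
  expect_false(sustained_flag(1150, 1500, quiet_tail = 300))
})

test_that("the synchrony index separates coincident, jittered and
           independent spike trains", {
  set.seed(42)
  template <- seq(410, 1490, by = 50)            # 20 Hz
  identical_trains <- replicate(30, template, simplify = FALSE)
  s_id <- synchrony_index(identical_trains, c(400, 1500), seed = 1)
  expect_gt(s_id, 0.8)

  poisson <- lapply(1:30, function(i) sort(runif(22, 400, 1500)))
  s_po <- mean(vapply(1:10, function(s) {
    set.seed(s + 100)
    p <- lapply(1:30, function(i) sort(runif(22, 400, 1500)))
    synchrony_index(p, c(400, 1500), seed = s)
  }, 0))
  expect_lt(s_po, 0.2)

  jittered <- lapply(1:30, function(i) sort(template + rnorm(22, 0, 2)))
  s_ji <- synchrony_index(jittered, c(400, 1500), seed = 1)
  expect_gt(s_ji, s_po)
  expect_lt(s_ji, s_id)
})

test_that("stop probability aggregates seeded trials against inhibition
           duration", {
  # synthetic runner: firing always stops iff duration >= 40 ms
  fake_run <- function(n_spikes, isi, seed) {
    dur <- (n_spikes - 1) * isi
    spikes <- if (dur >= 40) list(seq(100, 700, by = 40))
              else list(seq(100, 1400, by = 40))
    structure(list(spikes = spikes,
                   config = sim_config(1500)), class = "swim_recording")
  }
  tab <- stop_probability(fake_run, n_spikes_grid = c(1, 3, 5),
                          isi_grid = c(10, 20), n_trials = 2,
                          onset = 700, master_seed = 1)
  expect_equal(tab$stop_fraction[tab$duration == 0], c(0, 0))
  expect_true(all(tab$stop_fraction[tab$duration >= 40] == 1))
  agg <- tapply(tab$stop_fraction, tab$duration, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) >= 0))
})

test_that("frequency sweep summarises runs and flags reliability", {
  fake_run <- function(g, seed) {
    spikes <- if (g >= 1) replicate(5, seq(400, 1450, by = 1000 / (20 * g)),
                                    simplify = FALSE)
              else replicate(5, c(410, 450), simplify = FALSE)
    structure(list(spikes = spikes, config = sim_config(1500)),
              class = "swim_recording")
  }
  sw <- frequency_sweep(fake_run, g_values = c(0.5, 1, 2), seeds = 1:3,
                        window = c(400, 1500))
  expect_s3_class(sw, "sweep_result")
  expect_false(sw$reliable[1])
  expect_true(all(sw$reliable[2:3]))
  expect_true(all(diff(sw$mean_freq) > 0))
})
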