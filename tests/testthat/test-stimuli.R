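test_that("the tIN spike-count distribution satisfies the printed anchor
           constraints and normalises everywhere", {
  for (s in seq(0, 200, by = 2.5))
    expect_equal(sum(tin_count_distribution(s)), 1, tolerance = 1e-12)
  expect_equal(unname(tin_count_distribution(95)["1"]), 0.5)
  expect_equal(unname(tin_count_distribution(100)["1"]), 1)
  for (s in c(121, 130, 150, 500))
    expect_equal(unname(tin_count_distribution(s)["1"]), 0.3)
  expect_equal(unname(tin_count_distribution(0)["0"]), 1)
  # monotone recruitment below threshold
  p1 <- vapply(seq(85, 100, by = 1),
               function(s) unname(tin_count_distribution(s)["1"]), 0)
  expect_true(all(diff(p1) >= 0))
})

test_that("tIN spike-count draws match the distribution", {
  expect_true(all(sample_tin_spike_count(100, n = 1e4, seed = 1) == 1))
  expect_true(all(sample_tin_spike_count(0, n = 1e3, seed = 1) == 0))
  f95 <- mean(sample_tin_spike_count(95, n = 1e4, seed = 2) == 1)
  expect_equal(f95, 0.5, tolerance = 0.015 / 0.5)
  f130 <- mean(sample_tin_spike_count(130, n = 1e4, seed = 3) == 1)
  expect_equal(f130, 0.3, tolerance = 0.014 / 0.3)
  # above 120% some tINs fire multiply: mean count > 1
  expect_gt(mean(sample_tin_spike_count(130, n = 1e4, seed = 4)), 1)
})

test_that("tIN spike times are per-slot normal, sorted and seeded", {
  expect_equal(sample_tin_spike_times(0), numeric(0))
  expect_error(sample_tin_spike_times(6))
  m <- tin_spike_model()
  t1 <- replicate(1e4, 0)
  set.seed(11)
  t1 <- vapply(1:1e4, function(i) sample_tin_spike_times(1, m), 0)
  expect_equal(mean(t1), m$mu[1], tolerance = 3 * m$sigma[1] / 100 / m$mu[1])
  set.seed(12)
  many <- replicate(200, sample_tin_spike_times(5, m), simplify = FALSE)
  expect_true(all(vapply(many, function(x) all(diff(x) >= 0), TRUE)))
  expect_identical(sample_tin_spike_times(3, seed = 5),
                   sample_tin_spike_times(3, seed = 5))
})

test_that("the sensory volley recruits one spike per tIN at threshold
           strength", {
  v <- generate_sensory_volley(100, seed = 1)
  expect_equal(length(v), 20)
  expect_equal(sum(lengths(v)), 20)  # exactly one spike per tIN
  expect_equal(sum(lengths(generate_sensory_volley(0, seed = 2))), 0)
  n130 <- mean(vapply(1:200, function(s)
    sum(lengths(generate_sensory_volley(130, seed = s))) / 20, 0))
  expect_gt(n130, 1)
  vo <- generate_sensory_volley(100, onset = 250, seed = 3)
  expect_true(all(unlist(vo) > 250))
})

test_that("MHR bursts are arithmetic with duration (n-1)*ISI", {
  b <- mhr_burst(5, 15, onset = 700)
  expect_equal(mhr_burst_times(b), c(700, 715, 730, 745, 760))
  expect_equal(b$duration, 60)
  expect_equal(mhr_burst(1, 15)$duration, 0)
  expect_equal(mhr_burst(3, 20)$duration, 40)
  expect_error(mhr_burst(0, 15))
})

test_that("the perfusion drive ramps to the target conductance", {
  p <- perfusion_protocol(1, onset = 100)
  tt <- seq(0, 2000, by = 0.5)
  g <- perfusion_drive(p, tt)
  expect_true(all(g[tt <= 100] == 0))
  expect_equal(max(g), 1, tolerance = 0.01)  # steady ~ target within 1%
  expect_true(all(perfusion_drive(perfusion_protocol(0), tt) == 0))
  p75 <- perfusion_protocol(7.5, onset = 0)
  expect_equal(max(perfusion_drive(p75, tt)), 7.5, tolerance = 0.01)
})

test_that("scheduled events honour delay and transmission probability", {
  ev <- schedule_events(c(4, 9), c(10, 20), delay = 1)
  expect_equal(nrow(ev), 4)
  expect_setequal(ev$time, c(11, 21))
  expect_equal(nrow(schedule_events(integer(0), 1:3)), 0)
  frac <- nrow(schedule_events(1, 1:1e4, p = 0.5, seed = 1)) / 1e4
  expect_equal(frac, 0.5, tolerance = 0.03)
})
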