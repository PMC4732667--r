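test_that("gate rates reproduce the classic squid values and handle the
           removable singularity", {
  ch <- squid_channels()
  n <- ch$k$gates[[1]]
  r <- gate_rates(n, -65)
  expect_equal(r$alpha / (r$alpha + r$beta), 0.3177, tolerance = 1e-3)

  # alpha_n has a removable singularity at V = -55; the limit is 0.1 ms^-1
  r55 <- gate_rates(n, -55)
  expect_true(is.finite(r55$alpha))
  expect_equal(r55$alpha, 0.1, tolerance = 1e-4)

  # continuity: rates 0.001 mV apart differ by < 1%
  for (v in c(-80, -55.0005, -40, 0)) {
    ra <- gate_rates(n, v)$alpha
    rb <- gate_rates(n, v + 0.001)$alpha
    expect_lt(abs(ra - rb) / max(ra, 1e-12), 0.01)
  }

  expect_error(gate_rates(n, Inf))
})

test_that("every shipped gate has x_inf in [0,1] and positive tau over the
           physiological range", {
  sets <- c(squid_channels(), din_soma_channels(), din_axon_channels())
  v <- seq(-100, 60, by = 1)
  for (ch in sets) {
    for (g in ch$gates) {
      xinf <- gate_steady_state(g, v)
      tau <- gate_time_constant(g, v)
      expect_true(all(xinf >= 0 & xinf <= 1))
      expect_true(all(is.finite(tau) & tau > 0))
    }
  }
})

test_that("hh_current follows g * prod(gates^exp) * (V - E)", {
  n <- gate_kinetics(c(-0.55, -0.01, -1, 55, -10), c(0.125, 0, 0, 65, 80),
                     exponent = 4)
  k <- channel_spec("k", 36, -77, list(n))
  expect_equal(hh_current(k, 1, -77), 0)          # at reversal
  expect_equal(hh_current(k, 0.5, -30), 36 * 0.0625 * 47) # 105.75
  # linear in density
  k2 <- channel_spec("k", 72, -77, list(n))
  expect_equal(hh_current(k2, 0.5, -30), 2 * hh_current(k, 0.5, -30))
  # sign change exactly at E_rev
  expect_lt(hh_current(k, 0.5, -77.1), 0)
  expect_gt(hh_current(k, 0.5, -76.9), 0)
  expect_error(hh_current(k, 1.2, 0))
})

test_that("GHK calcium current matches a high-precision reference and is
           continuous at V = 0", {
  p <- ghk_params(1e-6, ca_in = 1e-4, ca_out = 10, temperature = 293)
  # frozen from an extended-precision evaluation of the constant-field flux
  expect_equal(ghk_calcium_current(p, -60), -9.2515761261262,
               tolerance = 1e-10)
  # no gradient and no field -> no current
  p0 <- ghk_params(1e-6, ca_in = 10, ca_out = 10, temperature = 293)
  expect_equal(ghk_calcium_current(p0, 0), 0, tolerance = 1e-12)
  # removable singularity at V = 0: inward limit value
  i0 <- ghk_calcium_current(p, 0)
  expect_equal(i0, -1.9296807029999, tolerance = 1e-8)
  expect_lt(i0, 0)
  # the series expansion agrees with direct evaluation of the flux
  # expression at |V| = 1e-3 mV to 1e-6 relative
  direct <- function(Vmv) {
    z <- 2; Tk <- 293; ci <- 1e-4 * 1e-6; co <- 10 * 1e-6
    u <- z * 96485 * (Vmv * 1e-3) / (8.314 * Tk)
    1e-6 * z * 96485 * u * (ci - co * exp(-u)) / (1 - exp(-u)) * 1e6
  }
  for (dv in c(1e-3, -1e-3))
    expect_equal(ghk_calcium_current(p, dv), direct(dv),
                 tolerance = 1e-6)
  expect_error(ghk_params(1e-6, ca_in = -1))
  expect_error(ghk_params(1e-6, temperature = 0))
})
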