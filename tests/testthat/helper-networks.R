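# Small builders used across the test files.

empty_gj <- function() {
  data.frame(neuron_a = integer(0), comp_a = integer(0),
             neuron_b = integer(0), comp_b = integer(0),
             resistance = numeric(0))
}

# a network holding a single isolated neuron (no synapses, no coupling)
single_neuron_net <- function(model) {
  swimnet:::new_network(list(model), swimnet:::.empty_syn_table(),
                        empty_gj(), seed = 1,
                        kind = "single")
}

# brute-force integration of the A/B synapse states (dA/dt = -A/tau_o,
# dB/dt = -B/tau_c, unit step at each event) -- the independent oracle for
# the event-driven synapse path
ode_synapse_max <- function(tau_o, tau_c, events, t_end, dt = 1e-3) {
  tt <- seq(0, t_end, by = dt)
  A <- 0; B <- 0
  gmax <- 0
  ev <- sort(events); k <- 1
  for (t in tt) {
    while (k <= length(ev) && ev[k] <= t + 1e-12) {
      A <- A + 1; B <- B + 1; k <- k + 1
    }
    gmax <- max(gmax, B - A)
    A <- A - dt * A / tau_o
    B <- B - dt * B / tau_c
  }
  gmax / synapse_peak(tau_o, tau_c)$norm
}

# synthetic spike waveform: one smooth spike centred at each time in `at`
synthetic_trace <- function(times, at, width = 1, amp = 80, base = -60) {
  v <- rep(base, length(times))
  for (t0 in at) v <- v + amp * exp(-((times - t0) / width)^2)
  v
}
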