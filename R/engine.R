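#' Simulation configuration
#'
#' @param duration total simulated time, ms.
#' @param dt integration step, ms (default 0.025).
#' @param seed integer seed for the synaptic-transmission stream.
#' @param record_every store voltages every this many steps.
#' @param record_g also record the per-neuron summed (pre-Mg-block) NMDAR
#'   synaptic conductance.
#' @param spike_threshold,spike_reset detection threshold and hysteresis
#'   reset level, mV.
#' @param theta implicitness of the voltage update: 0.5 (default) is the
#'   second-order trapezoidal scheme, 1 fully implicit Euler.
#' @export
sim_config <- function(duration, dt = 0.025, seed = 1, record_every = 8L,
                       record_g = FALSE, spike_threshold = 0,
                       spike_reset = -10, theta = 0.5) {
  stopifnot(dt > 0, duration >= dt, record_every >= 1,
            theta >= 0.5, theta <= 1)
  structure(list(duration = duration, dt = dt, seed = seed,
                 record_every = as.integer(record_every),
                 record_g = record_g, spike_threshold = spike_threshold,
                 spike_reset = spike_reset, theta = theta),
            class = "sim_config")
}

# flatten a swim_network into the arrays the C++ core expects (0-based)
.flatten_network <- function(net) {
  neurons <- net$neurons
  ncomps <- vapply(neurons, function(nm) nrow(nm$comps), 0L)
  noff <- c(0L, cumsum(ncomps))
  cap <- unlist(lapply(neurons, `[[`, "cap_nF"))
  ax_g <- unlist(lapply(neurons, `[[`, "ax_g"))
  if (is.null(ax_g)) ax_g <- numeric(0)

  ch_comp <- integer(0); ch_kind <- integer(0)
  ch_g <- numeric(0); ch_E <- numeric(0)
  ch_parea <- numeric(0); ch_ci <- numeric(0); ch_co <- numeric(0)
  ch_T <- numeric(0)
  gate_exp <- integer(0); gate_rows <- list()
  ch_goff <- 0L
  for (ni in seq_along(neurons)) {
    nm <- neurons[[ni]]
    for (ci in seq_len(nrow(nm$comps))) {
      comp0 <- noff[ni] + ci - 1L
      for (ch in nm$channels[[ci]]) {
        ch_comp <- c(ch_comp, comp0)
        if (ch$kind == "ohmic") {
          ch_kind <- c(ch_kind, 0L)
          ch_g <- c(ch_g, ch$density * nm$area_cm2[ci] * 1e3) # mS -> uS
          ch_E <- c(ch_E, ch$reversal)
          ch_parea <- c(ch_parea, 0); ch_ci <- c(ch_ci, 0)
          ch_co <- c(ch_co, 0); ch_T <- c(ch_T, 1)
        } else {
          ch_kind <- c(ch_kind, 1L)
          ch_g <- c(ch_g, 0); ch_E <- c(ch_E, 0)
          ch_parea <- c(ch_parea, ch$permeability * nm$area_cm2[ci])
          ch_ci <- c(ch_ci, ch$ghk$ca_in * 1e-6)   # mM -> mol/cm^3
          ch_co <- c(ch_co, ch$ghk$ca_out * 1e-6)
          ch_T <- c(ch_T, ch$ghk$temperature)
        }
        for (g in ch$gates) {
          gate_exp <- c(gate_exp, g$exponent)
          gate_rows[[length(gate_rows) + 1]] <- c(g$alpha, g$beta)
        }
        ch_goff <- c(ch_goff, length(gate_exp))
      }
    }
  }
  gate_rate <- if (length(gate_rows))
    matrix(unlist(gate_rows), nrow = 10) else matrix(0, 10, 0)

  syn <- net$synapses
  gj <- net$gap_junctions
  # resting potential estimate: leak reversal of the soma channel set
  v0 <- numeric(sum(ncomps))
  for (ni in seq_along(neurons)) {
    nm <- neurons[[ni]]
    leaks <- Filter(function(ch) length(ch$gates) == 0 && ch$kind == "ohmic",
                    nm$channels[[1]])
    vr <- if (length(leaks)) leaks[[1]]$reversal else -65
    v0[(noff[ni] + 1):noff[ni + 1]] <- vr
  }

  list(cap = cap, neuron_offset = noff, ax_g = ax_g, v0 = v0,
       ch_comp = ch_comp, ch_kind = ch_kind, ch_g = ch_g, ch_E = ch_E,
       ch_parea = ch_parea, ch_ci = ch_ci, ch_co = ch_co, ch_T = ch_T,
       ch_gate_offset = as.integer(ch_goff), gate_exp = gate_exp,
       gate_rate = gate_rate,
       gj_a = as.integer(noff[gj$neuron_a] + gj$comp_a - 1L),
       gj_b = as.integer(noff[gj$neuron_b] + gj$comp_b - 1L),
       gj_g = 1 / gj$resistance, # MOhm -> uS
       syn_post = as.integer(noff[syn$post] + syn$comp - 1L),
       syn_pre = as.integer(ifelse(is.na(syn$pre), -1L, syn$pre - 1L)),
       syn_tauo = syn$tau_o, syn_tauc = syn$tau_c,
       syn_g = syn$g_peak * 1e-3, # nS -> uS
       syn_E = syn$e_rev, syn_mgc = syn$mgc, syn_gamma = syn$gamma,
       syn_norm = vapply(seq_len(nrow(syn)), function(i)
         synapse_peak(syn$tau_o[i], syn$tau_c[i])$norm, 0),
       syn_delay = syn$delay, syn_p = syn$p,
       syn_nmda = as.integer(syn$nmda))
}

#' Simulate a network
#'
#' Integrates the coupled compartment/synapse system with the fixed-step
#' implicit scheme: gate variables by analytic exponential update, membrane
#' voltages implicitly in the ohmic and synaptic terms with axial coupling
#' solved per neuron, gap junctions and the GHK calcium current explicit.
#' Presynaptic somatic 0 mV upward crossings (with hysteresis below
#' -10 mV) trigger synaptic events delivered after the synaptic delay,
#' snapped to the nearest step. The run is deterministic given the network,
#' stimuli and config seed. Numerical blow-up (|V| > 200 mV) aborts with a
#' diagnostic.
#'
#' @param net a `swim_network`.
#' @param stimuli optional list with any of:
#'   `events` (data.frame `syn`, `time`: external deliveries, see
#'   [schedule_events()]), `perfusion` (data.frame `neuron`, `target`,
#'   `onset`, `tau_o`, `tau_c`, `mgc`, `gamma`, `e_rev`, see
#'   [perfusion_table()]), and `injections` (data.frame `neuron`, `comp`,
#'   `amp` (nA), `t0`, `t1`).
#' @param config a [sim_config()].
#' @param record_comps optional data.frame with columns `neuron`, `comp`:
#'   additional (non-soma) compartments whose voltages are recorded in the
#'   `v_extra` matrix.
#' @return an object of class `swim_recording`: list with `time` (ms),
#'   `v` (samples x neurons soma voltages, mV), `g_nmda` (same shape, nS,
#'   if recorded), `spikes` (per-neuron spike-time vectors), `deliveries`
#'   (data.frame of delivered synaptic events) and the config echo.
#' @export
simulate <- function(net, stimuli = list(), config, record_comps = NULL) {
  stopifnot(inherits(net, "swim_network"), inherits(config, "sim_config"))
  flat <- .flatten_network(net)

  ev <- stimuli$events
  if (is.null(ev)) ev <- data.frame(syn = integer(0), time = numeric(0))
  drive <- list(ev_syn = as.integer(ev$syn - 1L), ev_time = ev$time)

  pf <- stimuli$perfusion
  noff <- flat$neuron_offset
  if (is.null(pf)) {
    flat$perf_comp <- integer(0); flat$perf_g <- numeric(0)
    flat$perf_onset <- numeric(0); flat$perf_tauo <- numeric(0)
    flat$perf_tauc <- numeric(0); flat$perf_norm <- numeric(0)
    flat$perf_mgc <- numeric(0); flat$perf_gamma <- numeric(0)
    flat$perf_E <- numeric(0)
  } else {
    flat$perf_comp <- as.integer(noff[pf$neuron]) # soma (comp 1) 0-based
    flat$perf_g <- pf$target * 1e-3               # nS -> uS
    flat$perf_onset <- pf$onset
    flat$perf_tauo <- pf$tau_o; flat$perf_tauc <- pf$tau_c
    flat$perf_norm <- vapply(seq_len(nrow(pf)), function(i)
      synapse_peak(pf$tau_o[i], pf$tau_c[i])$norm, 0)
    flat$perf_mgc <- pf$mgc; flat$perf_gamma <- pf$gamma
    flat$perf_E <- pf$e_rev
  }

  inj <- stimuli$injections
  if (is.null(inj)) {
    flat$inj_comp <- integer(0); flat$inj_amp <- numeric(0)
    flat$inj_t0 <- numeric(0); flat$inj_t1 <- numeric(0)
  } else {
    comp <- if (is.null(inj$comp)) rep(1L, nrow(inj)) else inj$comp
    flat$inj_comp <- as.integer(noff[inj$neuron] + comp - 1L)
    flat$inj_amp <- inj$amp; flat$inj_t0 <- inj$t0; flat$inj_t1 <- inj$t1
  }

  rc <- integer(0)
  if (!is.null(record_comps))
    rc <- as.integer(noff[record_comps$neuron] + record_comps$comp - 1L)
  res <- .sim_core(flat, drive,
                   list(dt = config$dt, duration = config$duration,
                        seed = config$seed,
                        record_every = config$record_every,
                        record_g = config$record_g,
                        spike_threshold = config$spike_threshold,
                        spike_reset = config$spike_reset,
                        theta = config$theta,
                        record_comps = rc))
  structure(list(time = res$time, v = res$v,
                 v_extra = res$v_extra,
                 g_nmda = if (!is.null(res$g_nmda)) res$g_nmda * 1e3, # uS->nS
                 spikes = lapply(res$spikes, as.numeric),
                 deliveries = data.frame(syn = res$delivery_syn + 1L,
                                         time = res$delivery_time),
                 config = config, network_seed = net$seed),
            class = "swim_recording")
}

#' @export
print.swim_recording <- function(x, ...) {
  nsp <- vapply(x$spikes, length, 0L)
  cat(sprintf("<swim_recording> %d neurons, %.0f ms (dt %.4g ms), %d spikes total\n",
              ncol(x$v), max(x$time), x$config$dt, sum(nsp)))
  invisible(x)
}

#' Perfusion stimulus table
#'
#' Expands a [perfusion_protocol()] into one drive row per target neuron.
#'
#' @param p a [perfusion_protocol()].
#' @param neurons target neuron indices.
#' @return data.frame consumed by [simulate()]'s `stimuli$perfusion`.
#' @export
perfusion_table <- function(p, neurons) {
  stopifnot(inherits(p, "perfusion_protocol"))
  mgc <- 0; gamma <- 0
  if (!is.null(p$mg)) { mgc <- p$mg$eta * p$mg$mg_out; gamma <- p$mg$gamma }
  data.frame(neuron = neurons, target = p$target, onset = p$onset,
             tau_o = p$tau_o, tau_c = p$tau_c, mgc = mgc, gamma = gamma,
             e_rev = p$e_rev)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold` with hysteresis: after a detection no
#' new spike is registered until the trace falls below `reset`. Crossing
#' times are linearly interpolated between samples.
#'
#' @param v voltage samples, mV.
#' @param time sample times, ms (uniform).
#' @param threshold detection threshold, mV.
#' @param reset hysteresis reset level, mV.
#' @return numeric vector of spike times, ms.
#' @export
detect_spikes <- function(v, time, threshold = 0, reset = -10) {
  stopifnot(length(v) == length(time), length(v) >= 2)
  out <- numeric(0)
  armed <- v[1] < threshold
  for (i in 2:length(v)) {
    if (armed && v[i - 1] < threshold && v[i] >= threshold) {
      out <- c(out, time[i - 1] + (time[i] - time[i - 1]) *
                 (threshold - v[i - 1]) / (v[i] - v[i - 1]))
      armed <- FALSE
    } else if (!armed && v[i] < reset) armed <- TRUE
  }
  out
}

#' Export a recording
#'
#' `write_recording_csv()` writes the soma voltage traces in long format
#' (`neuron`, `t`, `v`); `write_spikes_json()` writes the per-neuron spike
#' tables with the config echo for provenance.
#'
#' @param rec a `swim_recording`.
#' @param path output file.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "swim_recording"))
  nn <- ncol(rec$v)
  long <- data.frame(neuron = rep(seq_len(nn), each = length(rec$time)),
                     t = rep(rec$time, nn), v = as.vector(rec$v))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
write_spikes_json <- function(rec, path) {
  stopifnot(inherits(rec, "swim_recording"))
  jsonlite::write_json(list(config = unclass(rec$config),
                            spikes = rec$spikes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
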