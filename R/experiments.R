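#' Default dIN network used by the experiment drivers
#'
#' Thirty dINs in a column (10 um soma spacing), axo-axonal 600 MOhm gap
#' junctions, AMPA + NMDA feedback synapses sampled at probability 0.2.
#'
#' @param nmda_g,ampa_g feedback peak conductances per synapse, nS.
#' @param mg logical: magnesium block on the feedback NMDAR.
#' @param gap_junctions logical: keep electrical coupling.
#' @param n population size.
#' @param seed integer seed for connectivity/conductance noise.
#' @param ... passed to [build_din_population()].
#' @return a `swim_network`.
#' @export
din_experiment_network <- function(nmda_g = 0.11, ampa_g = nmda_g,
                                   mg = TRUE, gap_junctions = TRUE,
                                   n = 30, seed = 1, ...) {
  net <- build_din_population(
    n = n, nmda = feedback_nmda(g_peak = nmda_g, mg = mg),
    ampa = feedback_ampa(g_peak = ampa_g), seed = seed, ...)
  if (!gap_junctions) net <- remove_gap_junctions(net)
  net
}

# attach per-dIN sensory (tIN) synapses and schedule a volley with shared
# per-(spike, target) transmission failures across the AMPA/NMDA components
.sensory_events <- function(net, volley, ampa_kin, nmda_kin, p = 0.5,
                            seed = NULL) {
  n <- length(net$neurons)
  net <- attach_external_synapse(net, ampa_kin)
  ampa_ids <- attr(net$synapses, "last_added")
  net <- attach_external_synapse(net, nmda_kin)
  nmda_ids <- attr(net$synapses, "last_added")
  times <- sort(unlist(volley))
  ev <- with_seed(seed, {
    rows <- list()
    for (tt in times) {
      hit <- runif(n) < p
      if (any(hit)) {
        tg <- which(hit)
        rows[[length(rows) + 1]] <- data.frame(
          syn = c(ampa_ids[tg], nmda_ids[tg]),
          time = tt + ampa_kin$delay)
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(syn = integer(0), time = numeric(0))
  })
  list(net = net, events = ev)
}

#' NMDA perfusion experiment
#'
#' Bath NMDA application onto the dIN population, with and without NMDAR
#' voltage dependence (extracellular magnesium). Two sub-experiments:
#' steady-state somatic depolarisation versus NMDAR conductance with the
#' sodium conductance set to zero to prevent firing, and firing frequency
#' versus NMDAR conductance with sodium intact. The physiological band of
#' synaptic conductance measured during swimming (0.6-1.5 nS) is annotated
#' in the returned tables.
#'
#' @param g_values perfusion conductances to sweep, nS.
#' @param n population size.
#' @param duration run length, ms.
#' @param dt integration step, ms.
#' @param seed integer seed.
#' @param steady_state also run the sodium-free steady-state
#'   sub-experiment.
#' @param outdir optional output directory for CSV tables.
#' @return list with data.frames `steady_state` (columns g, mg, v_ss) and
#'   `frequency` (columns g, mg, mean_freq, sustained), plus the
#'   physiological band annotation.
#' @export
run_perfusion <- function(g_values = c(0.25, 0.5, 1, 2, 4, 7.5, 15, 30),
                          n = 30, duration = 1500, dt = 0.025, seed = 1,
                          steady_state = TRUE, outdir = NULL) {
  sweep_one <- function(g, mg, na_zero) {
    soma <- if (na_zero) din_soma_channels(na_density = 0)
            else din_soma_channels()
    axon <- if (na_zero) din_axon_channels(na_density = 0)
            else din_axon_channels()
    net <- build_din_population(n = n,
                                nmda = feedback_nmda(g_peak = 0),
                                ampa = feedback_ampa(g_peak = 0),
                                din = din_params(soma_channels = soma,
                                                 axon_channels = axon),
                                seed = seed)
    pf <- perfusion_table(perfusion_protocol(g, onset = 100, mg = mg),
                          seq_len(n))
    simulate(net, list(perfusion = pf),
             sim_config(duration, dt = dt, seed = seed))
  }
  ss <- NULL
  if (steady_state)
    ss <- do.call(rbind, lapply(c(TRUE, FALSE), function(mg)
      do.call(rbind, lapply(g_values, function(g) {
        rec <- sweep_one(g, mg, na_zero = TRUE)
        data.frame(g = g, mg = mg,
                   v_ss = mean(rec$v[nrow(rec$v), ]))
      }))))
  fr <- do.call(rbind, lapply(c(TRUE, FALSE), function(mg)
    do.call(rbind, lapply(g_values, function(g) {
      rec <- sweep_one(g, mg, na_zero = FALSE)
      f <- vapply(rec$spikes, firing_frequency, 0,
                  window = c(400, duration))
      data.frame(g = g, mg = mg, mean_freq = mean(f),
                 sustained = sustained_flag(unlist(rec$spikes), duration))
    }))))
  out <- list(steady_state = ss, frequency = fr,
              physiological_band_nS = c(0.6, 1.5))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(ss))
      write.csv(ss, file.path(outdir, "perfusion_steady_state.csv"),
                row.names = FALSE)
    write.csv(fr, file.path(outdir, "perfusion_frequency.csv"),
              row.names = FALSE)
  }
  out
}

#' NMDAR summation experiment
#'
#' Regular spike trains of different frequencies delivered to a single
#' NMDAR synapse with an 80 ms closing time constant; reports the maximum
#' summed conductance relative to the single-event peak.
#'
#' @param freqs train frequencies, Hz.
#' @param n_spikes spikes per train.
#' @param tau_o,tau_c synapse time constants, ms.
#' @param outdir optional output directory.
#' @return data.frame with columns `freq`, `ratio` (monotone increasing).
#' @export
run_summation <- function(freqs = c(5, 10, 15, 20, 25, 40, 60, 100),
                          n_spikes = 40, tau_o = 5, tau_c = 80,
                          outdir = NULL) {
  kin <- synapse_kinetics(tau_o, tau_c, g_peak = 1, label = "nmda")
  tab <- data.frame(freq = freqs,
                    ratio = vapply(freqs, function(f)
                      summation_ratio(kin, f, n_spikes), 0))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(outdir, "summation.csv"), row.names = FALSE)
  }
  tab
}

#' Sensory start experiment
#'
#' A brief head-skin stimulus drives the tIN population, which excites
#' every dIN through unreliable (50%) glutamatergic synapses; mutual
#' AMPA/NMDA feedback then determines whether rhythmic firing
#' self-sustains. Runs a single seeded protocol at one feedback strength.
#'
#' @param nmda_g feedback NMDAR peak conductance per synapse, nS.
#' @param s stimulus strength, % of swim threshold.
#' @param onset volley onset, ms.
#' @param duration run length, ms.
#' @param dt integration step, ms.
#' @param seed integer master seed (connectivity, volley, transmission).
#' @param mg,gap_junctions passed to [din_experiment_network()].
#' @param sensory_g peak conductance of each tIN-dIN component, nS.
#' @param record_g record the summed feedback NMDAR conductance.
#' @param n population size.
#' @return a `swim_recording`.
#' @export
run_start <- function(nmda_g = 0.11, s = 100, onset = 100, duration = 1500,
                      dt = 0.025, seed = 1, mg = TRUE, gap_junctions = TRUE,
                      sensory_g = 0.4, record_g = FALSE, n = 30) {
  net <- din_experiment_network(nmda_g = nmda_g, mg = mg,
                                gap_junctions = gap_junctions, n = n,
                                seed = derive_seed(seed, 1))
  volley <- generate_sensory_volley(s, onset = onset,
                                    seed = derive_seed(seed, 2))
  sens <- .sensory_events(net, volley,
                          ampa_kin = feedback_ampa(g_peak = sensory_g),
                          nmda_kin = feedback_nmda(g_peak = sensory_g,
                                                   mg = mg),
                          p = 0.5, seed = derive_seed(seed, 3))
  simulate(sens$net, list(events = sens$events),
           sim_config(duration, dt = dt, seed = derive_seed(seed, 4),
                      record_g = record_g))
}

#' Feedback-strength sweep of the start protocol
#'
#' Classifies each feedback conductance as `"dies_out"`, `"sustained"`
#' (mean sustained-phase frequency within the half-CNS swimming band) or
#' `"sustained_fast"` (above it).
#'
#' @param g_values feedback NMDAR conductances, nS.
#' @param seeds integer seeds.
#' @param swim_band frequency band counted as swimming, Hz.
#' @param duration,dt,... passed to [run_start()].
#' @return a `sweep_result` data.frame with an added `class` column.
#' @export
run_start_sweep <- function(g_values = c(0.07, 0.11, 0.15),
                            seeds = 1:3, swim_band = c(10, 30),
                            duration = 1500, dt = 0.025, ...) {
  sw <- frequency_sweep(function(g, seed)
    run_start(nmda_g = g, seed = seed, duration = duration, dt = dt, ...),
    g_values, seeds, window = c(400, duration))
  sw$class <- ifelse(!sw$reliable, "dies_out",
                     ifelse(sw$mean_freq <= swim_band[2], "sustained",
                            "sustained_fast"))
  sw
}

#' Inhibitory stop experiment
#'
#' Starts the dIN network with the sensory protocol, then delivers a
#' synchronous MHR GABA-A burst (tau_o 1.5 ms, tau_c 20 ms, E -70 mV,
#' g_peak 2 nS) to every dIN.
#'
#' @param n_spikes,isi MHR burst size and inter-spike interval, ms.
#' @param inh_onset burst onset, ms.
#' @param gaba_g GABA-A peak conductance, nS.
#' @param nmda_g feedback NMDAR conductance, nS (default chosen so the
#'   rhythm stabilises within the swimming range).
#' @param duration run length, ms.
#' @param dt integration step, ms.
#' @param seed integer master seed.
#' @param ... passed to [run_start()] internals via
#'   [din_experiment_network()].
#' @return a `swim_recording`.
#' @export
run_stop <- function(n_spikes = 5, isi = 15, inh_onset = 700, gaba_g = 2,
                     nmda_g = 0.11, duration = 1500, dt = 0.025, seed = 1,
                     ...) {
  net <- din_experiment_network(nmda_g = nmda_g,
                                seed = derive_seed(seed, 1), ...)
  volley <- generate_sensory_volley(100, onset = 100,
                                    seed = derive_seed(seed, 2))
  sens <- .sensory_events(net, volley,
                          ampa_kin = feedback_ampa(g_peak = 0.4),
                          nmda_kin = feedback_nmda(g_peak = 0.4),
                          p = 0.5, seed = derive_seed(seed, 3))
  net <- sens$net
  net <- attach_external_synapse(net, gaba_kinetics(g_peak = gaba_g))
  gaba_ids <- attr(net$synapses, "last_added")
  burst <- mhr_burst(n_spikes, isi, onset = inh_onset)
  ev_gaba <- schedule_events(gaba_ids, mhr_burst_times(burst), delay = 1)
  simulate(net, list(events = rbind(sens$events, ev_gaba)),
           sim_config(duration, dt = dt, seed = derive_seed(seed, 4)))
}

#' Stop-probability grid of the stop experiment
#'
#' @param n_spikes_grid,isi_grid MHR protocol grids.
#' @param n_trials seeded trials per grid point.
#' @param master_seed base seed.
#' @param inh_onset inhibition onset, ms.
#' @param duration,dt,... passed to [run_stop()].
#' @return data.frame from [stop_probability()].
#' @export
run_stop_grid <- function(n_spikes_grid = 1:5, isi_grid = c(10, 15, 20),
                          n_trials = 5, master_seed = 1, inh_onset = 700,
                          duration = 1500, dt = 0.025, ...) {
  stop_probability(function(ns, isi, seed)
    run_stop(n_spikes = ns, isi = isi, inh_onset = inh_onset,
             duration = duration, dt = dt, seed = seed, ...),
    n_spikes_grid = n_spikes_grid, isi_grid = isi_grid,
    onset = inh_onset, n_trials = n_trials, master_seed = master_seed)
}

#' Generic-population experiment
#'
#' Thirty single-compartment Hodgkin-Huxley neurons with NMDA/AMPA
#' feedback, somatic gap junctions (100 MOhm, p = 0.2) and conductance
#' noise. A brief excitatory volley switches the network on; an optional
#' inhibitory burst (10 events at 7 ms intervals, 3 nS, E -70 mV) switches
#' it off.
#'
#' @param nmda_g feedback NMDAR peak conductance, nS.
#' @param exc_onsets excitatory volley onsets, ms.
#' @param inh_onsets inhibitory burst onsets, ms (empty for none).
#' @param duration run length, ms.
#' @param dt integration step, ms.
#' @param seed integer master seed.
#' @param gap_junctions logical.
#' @param exc_g peak conductance of the start-volley components, nS.
#' @param exc_dur duration of each excitatory volley (events every 10 ms
#'   from onset), ms.
#' @param n population size.
#' @return a `swim_recording`.
#' @export
run_generic <- function(nmda_g = 0.5, exc_onsets = 100,
                        inh_onsets = numeric(0),
                        duration = 1100, dt = 0.025, seed = 1,
                        gap_junctions = TRUE, exc_g = 3, exc_dur = 150,
                        n = 30) {
  net <- build_generic_population(
    n = n, nmda = feedback_nmda(g_peak = nmda_g),
    ampa = feedback_ampa(g_peak = 0.2 * nmda_g),
    seed = derive_seed(seed, 1))
  if (!gap_junctions) net <- remove_gap_junctions(net)
  # start volley: a short burst of suprathreshold mixed AMPA/NMDA events
  net <- attach_external_synapse(net, feedback_ampa(g_peak = exc_g))
  ampa_ids <- attr(net$synapses, "last_added")
  net <- attach_external_synapse(net, feedback_nmda(g_peak = exc_g))
  nmda_ids <- attr(net$synapses, "last_added")
  ev <- data.frame(syn = integer(0), time = numeric(0))
  for (on in exc_onsets) {
    times <- seq(on, on + exc_dur, by = 10)
    ev <- rbind(ev,
                schedule_events(c(ampa_ids, nmda_ids), times, delay = 1,
                                p = 1))
  }
  if (length(inh_onsets)) {
    net <- attach_external_synapse(
      net, synapse_kinetics(1.5, 20, g_peak = 3, e_rev = -70,
                            label = "gaba"))
    gaba_ids <- attr(net$synapses, "last_added")
    for (on in inh_onsets) {
      burst <- mhr_burst(10, 7, onset = on)
      ev <- rbind(ev, schedule_events(gaba_ids, mhr_burst_times(burst),
                                      delay = 1))
    }
  }
  simulate(net, list(events = ev),
           sim_config(duration, dt = dt, seed = derive_seed(seed, 4)))
}

#' Feedback-strength sweep of the generic population
#'
#' @param g_values feedback NMDAR conductances, nS.
#' @param seeds integer seeds per value.
#' @param duration,dt,... passed to [run_generic()].
#' @return a `sweep_result` data.frame (columns g, mean_freq, sd_freq,
#'   sustained_fraction, reliable).
#' @export
run_generic_sweep <- function(g_values = c(0.15, 0.3, 0.5, 0.7, 0.9, 1.1,
                                           1.3, 1.5, 1.75, 2, 2.5, 3),
                              seeds = 1:3, duration = 1100, dt = 0.025,
                              ...) {
  frequency_sweep(function(g, seed)
    run_generic(nmda_g = g, seed = seed, duration = duration, dt = dt, ...),
    g_values, seeds, window = c(400, duration))
}
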