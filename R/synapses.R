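#' Dual-exponential synapse kinetics
#'
#' Chemical synaptic conductance is the difference of two decaying
#' exponentials, an opening state A (time constant `tau_o`) and a closing
#' state B (time constant `tau_c`):
#' \deqn{dA/dt = -A/\tau_o, \quad dB/dt = -B/\tau_c}
#' One millisecond (the synaptic delay) after the presynaptic action
#' potential crosses 0 mV in the soma, A and B each step up by 1. The
#' conductance \eqn{g_{syn} = g_{peak}(B - A)/norm} is normalised so that a
#' single event peaks at exactly `g_peak` (see [synapse_peak()]). The NMDAR
#' variant additionally multiplies the current by the voltage-dependent
#' magnesium-block factor [mg_vdep()].
#'
#' @param tau_o,tau_c opening and closing time constants, ms (> 0, unequal).
#' @param g_peak peak conductance, nS (>= 0).
#' @param e_rev reversal potential, mV.
#' @param mg optional [mg_block_params()]; `NULL` for a voltage-independent
#'   synapse.
#' @param delay synaptic delay from threshold crossing to delivery, ms.
#' @param presyn_threshold presynaptic detection threshold, mV.
#' @param transmission_p per-event transmission probability in `[0, 1]`.
#' @param label optional receptor label ("ampa", "nmda", "gaba", ...).
#' @return an object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_o, tau_c, g_peak, e_rev = 0, mg = NULL,
                             delay = 1, presyn_threshold = 0,
                             transmission_p = 1, label = NULL) {
  stopifnot(tau_o > 0, tau_c > 0, g_peak >= 0, delay >= 0,
            transmission_p >= 0, transmission_p <= 1)
  if (tau_o == tau_c)
    stop("tau_o must differ from tau_c (degenerate alpha function)")
  if (!is.null(mg)) stopifnot(inherits(mg, "mg_block_params"))
  pk <- synapse_peak(tau_o, tau_c)
  structure(list(tau_o = tau_o, tau_c = tau_c, g_peak = g_peak,
                 e_rev = e_rev, mg = mg, delay = delay,
                 presyn_threshold = presyn_threshold,
                 transmission_p = transmission_p,
                 t_peak = pk$t_peak, norm = pk$norm, label = label),
            class = "synapse_kinetics")
}

#' Magnesium-block parameters for the NMDAR
#'
#' The voltage dependence of the NMDAR conductance:
#' \deqn{vdep(V) = 1 / (1 + \eta [Mg^{2+}]_o e^{-\gamma V})}
#' Defaults: eta 0.1 mM^-1, gamma 0.08 mV^-1, 0.5 mM external magnesium.
#'
#' @param eta Mg binding coefficient, mM^-1 (>= 0).
#' @param gamma voltage sensitivity, mV^-1 (>= 0).
#' @param mg_out external magnesium concentration, mM (>= 0).
#' @export
mg_block_params <- function(eta = 0.1, gamma = 0.08, mg_out = 0.5) {
  stopifnot(eta >= 0, gamma >= 0, mg_out >= 0)
  structure(list(eta = eta, gamma = gamma, mg_out = mg_out),
            class = "mg_block_params")
}

#' Peak time and normalisation of the dual-exponential waveform
#'
#' For a unit event, \eqn{B(t) - A(t) = e^{-t/\tau_c} - e^{-t/\tau_o}}
#' attains its maximum at
#' \deqn{t_{peak} = \frac{\tau_o \tau_c}{\tau_c - \tau_o}
#'       \log(\tau_c/\tau_o)}
#' and the normalisation factor is the value of the difference there, so the
#' normalised waveform peaks at exactly 1.
#'
#' @param tau_o,tau_c opening and closing time constants, ms.
#' @return list with `t_peak` (ms, > 0) and `norm` (dimensionless, in (0,1)).
#' @examples
#' synapse_peak(5, 80)   # NMDAR: t_peak ~ 14.79 ms, norm ~ 0.779
#' synapse_peak(1.5, 20) # GABA-A: t_peak ~ 4.20 ms, norm ~ 0.750
#' @export
synapse_peak <- function(tau_o, tau_c) {
  stopifnot(tau_o > 0, tau_c > 0)
  if (tau_o == tau_c) stop("tau_o must differ from tau_c")
  t_peak <- tau_o * tau_c / (tau_c - tau_o) * log(tau_c / tau_o)
  norm <- exp(-t_peak / tau_c) - exp(-t_peak / tau_o)
  list(t_peak = t_peak, norm = norm)
}

#' Synaptic conductance waveform after a train of delivered events
#'
#' Evaluates \eqn{g_{syn}(t) = g_{peak} (B - A)/norm} exactly (the A/B
#' states decay analytically between the step increases of 1 at each
#' delivery time).
#'
#' @param kin a [synapse_kinetics()] object.
#' @param events delivery times, ms (sorted or not).
#' @param t evaluation times, ms.
#' @return conductance, nS (same length as `t`).
#' @export
synapse_conductance <- function(kin, events, t) {
  stopifnot(inherits(kin, "synapse_kinetics"))
  events <- sort(as.numeric(events))
  g <- numeric(length(t))
  for (ev in events) {
    dtt <- t - ev
    on <- dtt >= 0
    g[on] <- g[on] + exp(-dtt[on] / kin$tau_c) - exp(-dtt[on] / kin$tau_o)
  }
  kin$g_peak * g / kin$norm
}

#' NMDAR magnesium-block voltage dependence
#'
#' \eqn{vdep(V) = 1/(1 + \eta [Mg]_o e^{-\gamma V})}: strictly increasing
#' in V, approaching 1 at depolarised potentials, and identically 1 when
#' external magnesium is zero.
#'
#' @param V membrane potential(s), mV.
#' @param p a [mg_block_params()] object.
#' @return dimensionless factor in (0, 1].
#' @export
mg_vdep <- function(V, p = mg_block_params()) {
  stopifnot(inherits(p, "mg_block_params"))
  1 / (1 + p$eta * p$mg_out * exp(-p$gamma * V))
}

#' Synaptic current
#'
#' \eqn{i_{syn} = g_{syn}(V - E_{syn})}, multiplied by [mg_vdep()] when the
#' kinetics carry magnesium-block parameters. Outward positive, so an
#' excitatory synapse at rest yields a negative (inward) current.
#'
#' @param g_syn synaptic conductance, nS.
#' @param V postsynaptic membrane potential, mV.
#' @param kin a [synapse_kinetics()] object.
#' @return current, nA (g in nS, V in mV: nS * mV = 1e-3 nA... returned in
#'   nA, i.e. `g_syn * 1e-3 * (V - e_rev) * vdep`).
#' @export
synaptic_current <- function(g_syn, V, kin) {
  stopifnot(inherits(kin, "synapse_kinetics"))
  vd <- if (is.null(kin$mg)) 1 else mg_vdep(V, kin$mg)
  g_syn * 1e-3 * (V - kin$e_rev) * vd
}

#' Steady-state summation ratio of a synapse driven by a regular train
#'
#' Delivers `n_spikes` events at frequency `freq` and returns the maximum
#' conductance over the whole train divided by the single-event peak
#' (`g_peak`). The maximum is located analytically within each
#' inter-event interval from the A/B state recursion, so the result is
#' exact for the stated kinetics.
#'
#' @param kin a [synapse_kinetics()] object.
#' @param freq presynaptic train frequency, Hz (> 0).
#' @param n_spikes number of events (>= 1).
#' @return dimensionless ratio >= 1 (equal to 1 for a single event).
#' @export
summation_ratio <- function(kin, freq, n_spikes) {
  stopifnot(inherits(kin, "synapse_kinetics"), freq > 0, n_spikes >= 1)
  period <- 1000 / freq
  to <- kin$tau_o; tc <- kin$tau_c
  A <- 0; B <- 0
  gmax <- 0
  for (k in seq_len(n_spikes)) {
    A <- A + 1; B <- B + 1
    horizon <- if (k < n_spikes) period else 10 * tc
    # maximum of B e^(-t/tc) - A e^(-t/to) on (0, horizon]
    cand <- horizon
    tstar <- log(A * tc / (B * to)) / (1 / to - 1 / tc)
    if (is.finite(tstar) && tstar > 0 && tstar < horizon) cand <- c(tstar, cand)
    val <- vapply(cand, function(tt)
      B * exp(-tt / tc) - A * exp(-tt / to), 0)
    gmax <- max(gmax, val)
    A <- A * exp(-period / to)
    B <- B * exp(-period / tc)
  }
  gmax / kin$norm
}

#' Shipped synapse kinetics
#'
#' Receptor parameter sets used throughout the experiments:
#' * `feedback_nmda`: tau_o 5 ms, tau_c 80 ms, Mg block by default;
#' * `feedback_ampa`: tau_o 0.1 ms, tau_c 3 ms;
#' * `gaba`: tau_o 1.5 ms, tau_c 20 ms, E -70 mV (the MHR stop synapse);
#' * `perfusion_nmda`: tau_o 5 ms, tau_c 10 s (bath NMDA activation).
#' Excitatory reversal potentials default to 0 mV.
#'
#' @param g_peak peak conductance, nS.
#' @param mg `TRUE` for the default magnesium block, `FALSE` for none, or a
#'   [mg_block_params()] object.
#' @param ... passed on to [synapse_kinetics()].
#' @name shipped_kinetics
NULL

.mg_arg <- function(mg) {
  if (isTRUE(mg)) mg_block_params()
  else if (isFALSE(mg) || is.null(mg)) NULL
  else mg
}

#' @rdname shipped_kinetics
#' @export
feedback_nmda <- function(g_peak = 0.11, mg = TRUE, ...) {
  synapse_kinetics(5, 80, g_peak, e_rev = 0, mg = .mg_arg(mg),
                   label = "nmda", ...)
}

#' @rdname shipped_kinetics
#' @export
feedback_ampa <- function(g_peak = 0.11, ...) {
  synapse_kinetics(0.1, 3, g_peak, e_rev = 0, label = "ampa", ...)
}

#' @rdname shipped_kinetics
#' @export
gaba_kinetics <- function(g_peak = 2, ...) {
  synapse_kinetics(1.5, 20, g_peak, e_rev = -70, label = "gaba", ...)
}

#' @rdname shipped_kinetics
#' @export
perfusion_nmda <- function(g_peak = 1, mg = TRUE, ...) {
  synapse_kinetics(5, 10000, g_peak, e_rev = 0, mg = .mg_arg(mg),
                   label = "nmda_perfusion", ...)
}
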