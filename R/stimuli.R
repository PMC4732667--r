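#' Generative spike model of a trigeminal interneuron (tIN)
#'
#' In response to a head-skin stimulus of strength `s` (% of the swimming
#' threshold), a tIN fires between 0 and 5 spikes. The spike count is drawn
#' from a stimulus-dependent distribution p(N = n | s) constrained by the
#' experimental observations: P(1 spike | s = 95) = 0.5, P(1 | s = 100) = 1,
#' and P(1 | s > 120) = 0.3 with the remaining mass on multiple firing.
#' Between those anchors the default distribution interpolates linearly and
#' monotonically in `s`; the multiple-spike residual mass is spread
#' geometrically over counts 2-5. Spike times are drawn independently per
#' slot from normal distributions with increasing means.
#'
#' The anchor constraints are experimental; the interpolation, the
#' geometric residual and the default timing parameters
#' (`mu_k = 10 + 8 (k-1)` ms, `sigma_k = 2 + 1.5 (k-1)` ms) are package
#' defaults, all overridable.
#'
#' @param mu,sigma numeric(5): per-slot spike-time means and sds, ms.
#' @param multi_ratio geometric ratio of the residual mass over counts 2-5.
#' @return an object of class `tin_spike_model`.
#' @export
tin_spike_model <- function(mu = 10 + 8 * (0:4), sigma = 2 + 1.5 * (0:4),
                            multi_ratio = 0.5) {
  stopifnot(length(mu) == 5, length(sigma) == 5, all(sigma > 0),
            all(diff(mu) > 0), multi_ratio > 0)
  structure(list(mu = mu, sigma = sigma, multi_ratio = multi_ratio),
            class = "tin_spike_model")
}

#' Spike-count distribution of the tIN model
#'
#' @param s stimulus strength, % of swim threshold (scalar, >= 0).
#' @param model a [tin_spike_model()].
#' @return numeric(6): probabilities of firing 0..5 spikes (sums to 1).
#' @export
tin_count_distribution <- function(s, model = tin_spike_model()) {
  stopifnot(s >= 0, inherits(model, "tin_spike_model"))
  p1 <- if (s < 90) 0
  else if (s <= 95) 0.5 * (s - 90) / 5
  else if (s <= 100) 0.5 + 0.5 * (s - 95) / 5
  else if (s <= 120) 1 - 0.7 * (s - 100) / 20
  else 0.3
  multi <- if (s <= 100) 0 else 1 - p1
  w <- model$multi_ratio^(0:3)
  w <- w / sum(w)
  p <- c(1 - p1 - multi, p1, multi * w)
  names(p) <- as.character(0:5)
  p
}

#' Draw tIN spike counts
#'
#' @param s stimulus strength (% of swim threshold).
#' @param model a [tin_spike_model()].
#' @param n number of draws.
#' @param seed optional integer seed applied locally.
#' @return integer vector of spike counts in 0..5.
#' @export
sample_tin_spike_count <- function(s, model = tin_spike_model(), n = 1,
                                   seed = NULL) {
  p <- tin_count_distribution(s, model)
  with_seed(seed, sample(0:5, n, replace = TRUE, prob = p))
}

#' Draw tIN spike times for a given count
#'
#' The k-th spike time is normal with mean `mu[k]` and sd `sigma[k]`;
#' the returned vector is sorted ascending.
#'
#' @param n spike count (0 to 5).
#' @param model a [tin_spike_model()].
#' @param seed optional integer seed applied locally.
#' @return numeric vector of `n` times, ms.
#' @export
sample_tin_spike_times <- function(n, model = tin_spike_model(),
                                   seed = NULL) {
  stopifnot(n >= 0)
  if (n > 5) stop("a tIN fires between 0 and 5 spikes")
  if (n == 0) return(numeric(0))
  with_seed(seed,
            sort(rnorm(n, mean = model$mu[seq_len(n)],
                       sd = model$sigma[seq_len(n)])))
}

#' Generate the sensory volley of a tIN population
#'
#' Draws independent spike trains for `n_tins` tINs at stimulus strength
#' `s`. Each tIN contacts every dIN (100% connectivity); per-spike,
#' per-target transmission failures (50% by default) are applied by the
#' synapse layer when the volley is scheduled.
#'
#' @param s stimulus strength (% of swim threshold).
#' @param n_tins population size (default 20).
#' @param model a [tin_spike_model()].
#' @param onset volley onset added to all times, ms.
#' @param seed optional integer seed applied locally.
#' @return list of per-tIN spike-time vectors (class `sensory_volley`).
#' @export
generate_sensory_volley <- function(s, n_tins = 20,
                                    model = tin_spike_model(), onset = 0,
                                    seed = NULL) {
  with_seed(seed, {
    counts <- sample_tin_spike_count(s, model, n = n_tins)
    trains <- lapply(counts, function(k)
      onset + sample_tin_spike_times(k, model))
    structure(trains, class = "sensory_volley", s = s, onset = onset)
  })
}

#' MHR inhibitory burst
#'
#' A burst of `n_spikes` spikes at a regular inter-spike interval starting
#' at `onset`; the duration of inhibition is `(n_spikes - 1) * isi`.
#'
#' @param n_spikes number of spikes (>= 1).
#' @param isi inter-spike interval, ms (> 0).
#' @param onset burst onset, ms.
#' @return object of class `mhr_burst` with fields `times` and `duration`.
#' @export
mhr_burst <- function(n_spikes, isi, onset = 0) {
  stopifnot(n_spikes >= 1, isi > 0)
  times <- onset + (seq_len(n_spikes) - 1) * isi
  structure(list(n_spikes = n_spikes, isi = isi, onset = onset,
                 times = times, duration = (n_spikes - 1) * isi),
            class = "mhr_burst")
}

#' @rdname mhr_burst
#' @param b an `mhr_burst`.
#' @export
mhr_burst_times <- function(b) {
  stopifnot(inherits(b, "mhr_burst"))
  b$times
}

#' NMDA perfusion protocol
#'
#' Bath application of NMDA is modelled as a conductance drive identical in
#' every neuron: a dual-exponential waveform with slow opening (default
#' 5 ms) and very slow closing (default 10 s), normalised so its peak
#' equals the `target` conductance. With `mg = FALSE` the magnesium-block
#' factor is held at 1 (zero extracellular Mg).
#'
#' @param target peak NMDAR conductance, nS (>= 0).
#' @param onset ramp onset, ms.
#' @param tau_o,tau_c opening/closing time constants, ms.
#' @param mg logical or [mg_block_params()].
#' @param e_rev reversal potential, mV.
#' @return object of class `perfusion_protocol`.
#' @export
perfusion_protocol <- function(target, onset = 0, tau_o = 5, tau_c = 10000,
                               mg = TRUE, e_rev = 0) {
  stopifnot(target >= 0, onset >= 0, tau_o > 0, tau_c > tau_o)
  structure(list(target = target, onset = onset, tau_o = tau_o,
                 tau_c = tau_c, mg = .mg_arg(mg), e_rev = e_rev),
            class = "perfusion_protocol")
}

#' Conductance of a perfusion drive at given times
#'
#' @param p a [perfusion_protocol()].
#' @param t times, ms.
#' @return conductance, nS.
#' @export
perfusion_drive <- function(p, t) {
  stopifnot(inherits(p, "perfusion_protocol"))
  pk <- synapse_peak(p$tau_o, p$tau_c)
  ts <- t - p$onset
  g <- ifelse(ts > 0,
              (exp(-ts / p$tau_c) - exp(-ts / p$tau_o)) / pk$norm, 0)
  p$target * pmax(g, 0)
}

#' Schedule external synaptic events
#'
#' Builds an event table delivering presynaptic spike times to external
#' synapse rows (added with [attach_external_synapse()]), applying the
#' synaptic delay and independent per-(spike, synapse) transmission
#' failures at probability `p` (the unreliable tIN-to-dIN transmission
#' rule).
#'
#' @param syn_ids synapse row indices in the network's synapse table.
#' @param times presynaptic spike times, ms (delivered to every synapse in
#'   `syn_ids`).
#' @param delay synaptic delay, ms.
#' @param p per-event transmission probability.
#' @param seed optional integer seed applied locally.
#' @return data.frame with columns `syn`, `time`.
#' @export
schedule_events <- function(syn_ids, times, delay = 1, p = 1, seed = NULL) {
  if (length(times) == 0 || length(syn_ids) == 0)
    return(data.frame(syn = integer(0), time = numeric(0)))
  grid <- expand.grid(syn = syn_ids, time = times + delay)
  with_seed(seed, {
    if (p < 1) grid <- grid[runif(nrow(grid)) < p, , drop = FALSE]
    rownames(grid) <- NULL
    grid
  })
}
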