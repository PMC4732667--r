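#' Firing frequency within a window
#'
#' Number of spikes falling in `[t0, t1)` divided by the window length.
#'
#' @param spikes spike times, ms.
#' @param window numeric(2): `c(t0, t1)`, ms, `t1 > t0`.
#' @return frequency, Hz.
#' @export
firing_frequency <- function(spikes, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sum(spikes >= window[1] & spikes < window[2]) /
    (window[2] - window[1]) * 1000
}

#' Is activity sustained to the end of the run?
#'
#' Activity counts as sustained iff at least one spike occurs within the
#' final `quiet_tail` of the run.
#'
#' @param spikes spike times (one neuron or pooled), ms.
#' @param duration run duration, ms.
#' @param quiet_tail tail window, ms.
#' @export
sustained_flag <- function(spikes, duration, quiet_tail = 300) {
  any(spikes >= duration - quiet_tail)
}

#' Population synchrony index
#'
#' Pools all spikes in the analysis window into bins of width `bin` and
#' compares the variance of the binned population count with its
#' expectation under a surrogate ensemble of independent homogeneous
#' Poisson trains of the same per-neuron rates. The variance ratio R is
#' mapped to `[0, 1]` as `(R - 1)/(n_neurons - 1)`, clipped: near 0 for
#' independent trains, near 1 for perfectly coincident trains.
#'
#' @param spike_list list of per-neuron spike-time vectors (>= 2 neurons).
#' @param window analysis window `c(t0, t1)`, ms.
#' @param bin bin width, ms.
#' @param n_surrogate surrogate ensemble size.
#' @param seed optional integer seed for the surrogates.
#' @return synchrony index in `[0, 1]`.
#' @export
synchrony_index <- function(spike_list, window, bin = 5, n_surrogate = 20,
                            seed = NULL) {
  stopifnot(length(spike_list) >= 2, length(window) == 2,
            window[2] > window[1])
  t0 <- window[1]; t1 <- window[2]
  breaks <- seq(t0, t1, by = bin)
  if (length(breaks) < 3) stop("window too short for the chosen bin")
  counts_of <- function(times) {
    times <- times[times >= t0 & times < breaks[length(breaks)]]
    tabulate(findInterval(times, breaks), nbins = length(breaks) - 1)
  }
  pooled <- counts_of(sort(unlist(spike_list)))
  v_emp <- var(pooled)
  nspk <- vapply(spike_list, function(s)
    sum(s >= t0 & s < breaks[length(breaks)]), 0)
  span <- breaks[length(breaks)] - t0
  v_sur <- with_seed(seed, {
    mean(vapply(seq_len(n_surrogate), function(i) {
      pooled_s <- sort(runif(sum(nspk), t0, t0 + span))
      var(counts_of(pooled_s))
    }, 0))
  })
  if (v_sur <= 0) return(0)
  r <- v_emp / v_sur
  min(1, max(0, (r - 1) / (length(spike_list) - 1)))
}

#' Stop probability over an inhibition-protocol grid
#'
#' For each combination of MHR burst length (`n_spikes`) and inter-spike
#' interval (`isi`), runs `n_trials` seeded simulations of the given
#' start+stop protocol and reports the fraction of trials in which the
#' network emits no spikes from 200 ms after the end of inhibition to the
#' end of the run. Results are reported against the inhibition duration
#' `(n_spikes - 1) * isi`.
#'
#' @param run_fn function(n_spikes, isi, seed) returning a
#'   `swim_recording` of the start+stop protocol.
#' @param n_spikes_grid,isi_grid protocol grids.
#' @param onset inhibition onset used by `run_fn`, ms (for the
#'   post-inhibition window).
#' @param n_trials seeded trials per grid point.
#' @param master_seed base seed; trial seeds are derived from it.
#' @return data.frame with columns `n_spikes`, `isi`, `duration`,
#'   `stop_fraction`.
#' @export
stop_probability <- function(run_fn, n_spikes_grid = 1:5,
                             isi_grid = c(10, 15, 20), onset = 700,
                             n_trials = 5, master_seed = 1) {
  stopifnot(n_trials >= 1)
  grid <- expand.grid(n_spikes = n_spikes_grid, isi = isi_grid)
  grid$duration <- (grid$n_spikes - 1) * grid$isi
  grid$stop_fraction <- NA_real_
  for (i in seq_len(nrow(grid))) {
    stopped <- logical(n_trials)
    for (tr in seq_len(n_trials)) {
      seed <- derive_seed(master_seed, i * 1000 + tr)
      rec <- run_fn(grid$n_spikes[i], grid$isi[i], seed)
      t_end_inh <- onset + grid$duration[i]
      all_spk <- unlist(rec$spikes)
      stopped[tr] <- !any(all_spk >= t_end_inh + 200)
    }
    grid$stop_fraction[i] <- mean(stopped)
  }
  grid
}

#' Firing frequency versus feedback conductance sweep
#'
#' For each feedback peak conductance in `g_values`, runs the supplied
#' protocol for each seed, computes the mean sustained-phase firing
#' frequency over neurons and whether activity is sustained, and reports
#' per-conductance summaries. "Reliably sustained" means sustained in at
#' least 90% of seeds.
#'
#' @param run_fn function(g, seed) returning a `swim_recording`.
#' @param g_values feedback peak conductances to sweep, nS.
#' @param seeds integer seeds.
#' @param window sustained-phase analysis window `c(t0, t1)`, ms.
#' @param quiet_tail tail used by [sustained_flag()], ms.
#' @return object of class `sweep_result`: data.frame with columns `g`,
#'   `mean_freq`, `sd_freq`, `sustained_fraction`, `reliable`.
#' @export
frequency_sweep <- function(run_fn, g_values, seeds, window,
                            quiet_tail = 300) {
  rows <- lapply(g_values, function(g) {
    freqs <- numeric(0); sus <- logical(0)
    for (s in seeds) {
      rec <- run_fn(g, s)
      dur <- rec$config$duration
      f <- vapply(rec$spikes, firing_frequency, 0, window = window)
      freqs <- c(freqs, mean(f))
      sus <- c(sus, sustained_flag(unlist(rec$spikes), dur, quiet_tail))
    }
    data.frame(g = g, mean_freq = mean(freqs), sd_freq = sd_or_zero(freqs),
               sustained_fraction = mean(sus), reliable = mean(sus) >= 0.9)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

sd_or_zero <- function(x) if (length(x) > 1) stats::sd(x) else 0
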