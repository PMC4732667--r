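#' Sample probabilistic connectivity
#'
#' Each non-self pair — ordered when `directed`, unordered otherwise — is
#' included independently with probability `p`.
#'
#' @param n number of neurons (>= 2).
#' @param p connection probability in `[0, 1]`.
#' @param directed logical.
#' @param seed optional integer seed applied locally.
#' @return data.frame with columns `pre`, `post` (directed) or `a`, `b`
#'   (undirected, a < b).
#' @export
sample_connectivity <- function(n, p, directed = TRUE, seed = NULL) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  with_seed(seed, {
    if (directed) {
      pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
      pairs <- pairs[pairs$pre != pairs$post, ]
    } else {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pairs <- data.frame(a = idx[, 1], b = idx[, 2])
    }
    keep <- runif(nrow(pairs)) < p
    out <- pairs[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Ohmic gap-junction current
#'
#' Current flowing into each coupled compartment through a resistive gap
#' junction: `i_into_a = (V_b - V_a)/R`, and by conservation
#' `i_into_b = -i_into_a`.
#'
#' @param v_a,v_b membrane potentials of the two compartments, mV.
#' @param resistance junction resistance, MOhm (> 0).
#' @return named numeric vector `c(i_into_a, i_into_b)`, nA.
#' @export
gap_junction_current <- function(v_a, v_b, resistance) {
  if (!(resistance > 0)) stop("gap-junction resistance must be positive")
  i_a <- (v_b - v_a) / resistance
  c(i_into_a = i_a, i_into_b = -i_a)
}

.empty_syn_table <- function() {
  data.frame(pre = integer(0), post = integer(0), comp = integer(0),
             tau_o = numeric(0), tau_c = numeric(0), g_peak = numeric(0),
             e_rev = numeric(0), mgc = numeric(0), gamma = numeric(0),
             delay = numeric(0), p = numeric(0), nmda = logical(0),
             label = character(0))
}

.syn_row <- function(pre, post, comp, kin, g_mult = 1) {
  mgc <- 0; gamma <- 0
  if (!is.null(kin$mg)) {
    mgc <- kin$mg$eta * kin$mg$mg_out
    gamma <- kin$mg$gamma
  }
  k <- max(length(pre), length(post))
  data.frame(pre = rep_len(pre, k), post = rep_len(post, k),
             comp = rep_len(comp, k), tau_o = kin$tau_o,
             tau_c = kin$tau_c, g_peak = kin$g_peak * rep_len(g_mult, k),
             e_rev = kin$e_rev, mgc = mgc, gamma = gamma, delay = kin$delay,
             p = kin$transmission_p,
             nmda = !is.null(kin$label) && grepl("nmda", kin$label),
             label = if (is.null(kin$label)) "syn" else kin$label)
}

# sample directed feedback edges and build the AMPA+NMDA synapse rows with
# truncated-normal peak-conductance multipliers (relative variance sigma2);
# uses the current RNG state
.feedback_edges <- function(n, p_syn, sigma2, nmda, ampa) {
  edges <- sample_connectivity(n, p_syn, directed = TRUE)
  if (nrow(edges) == 0) return(.empty_syn_table())
  mult_n <- pmax(0, rnorm(nrow(edges), 1, sqrt(sigma2)))
  mult_a <- pmax(0, rnorm(nrow(edges), 1, sqrt(sigma2)))
  if (sigma2 == 0) mult_n <- mult_a <- rep(1, nrow(edges))
  rows_n <- .syn_row(edges$pre, edges$post, 1L, nmda, g_mult = mult_n)
  rows_a <- .syn_row(edges$pre, edges$post, 1L, ampa, g_mult = mult_a)
  # interleave so each connection's two components are adjacent
  out <- rbind(rows_n, rows_a)
  out <- out[order(rep(seq_len(nrow(edges)), 2)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_network <- function(neurons, synapses, gap_junctions, seed = NULL,
                        kind = "custom") {
  stopifnot(all(vapply(neurons, inherits, TRUE, "neuron_model")))
  if (nrow(synapses) > 0 &&
      any(!is.na(synapses$pre) & synapses$pre == synapses$post))
    stop("self chemical synapses are not allowed")
  if (nrow(gap_junctions) > 0) {
    stopifnot(all(gap_junctions$resistance > 0))
    key <- paste(pmin(gap_junctions$neuron_a, gap_junctions$neuron_b),
                 pmax(gap_junctions$neuron_a, gap_junctions$neuron_b),
                 gap_junctions$comp_a, gap_junctions$comp_b)
    if (anyDuplicated(key)) stop("duplicate gap junctions")
  }
  structure(list(neurons = neurons, synapses = synapses,
                 gap_junctions = gap_junctions, seed = seed, kind = kind),
            class = "swim_network")
}

#' @export
print.swim_network <- function(x, ...) {
  cat(sprintf("<swim_network:%s> %d neurons, %d chemical synapses, %d gap junctions\n",
              x$kind, length(x$neurons), nrow(x$synapses),
              nrow(x$gap_junctions)))
  if (!is.null(x$seed)) cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Build the electrically coupled dIN population
#'
#' `n` dINs arranged in a rostro-caudal column with `spacing` um between
#' adjacent somata (soma positions 0, -spacing, -2 spacing, ...). For every
#' ordered rostral-to-caudal pair whose descending axon overlaps the caudal
#' soma, one gap junction (default 600 MOhm) is placed between the rostral
#' neuron's axon compartment nearest the caudal soma and the caudal
#' neuron's proximal axon compartment. Chemical feedback synapses (an AMPA
#' and an NMDA component per connection) are sampled independently at
#' probability `p_syn` between ordered pairs and target the soma/dendrite
#' compartment; peak conductances are jittered by a truncated-normal
#' multiplier with relative variance `g_sigma2`.
#'
#' @param n population size.
#' @param spacing inter-soma spacing, um.
#' @param gj_resistance gap-junction resistance, MOhm. Use `Inf` to remove
#'   electrical coupling.
#' @param p_syn feedback connection probability.
#' @param nmda,ampa [synapse_kinetics()] for the two feedback components
#'   (set `g_peak` here to sweep feedback strength).
#' @param g_sigma2 relative variance of synaptic peak-conductance noise
#'   (0 disables).
#' @param din a [din_params()] list.
#' @param seed integer seed for connectivity and conductance noise.
#' @return a `swim_network`.
#' @export
build_din_population <- function(n = 30, spacing = 10, gj_resistance = 600,
                                 p_syn = 0.2,
                                 nmda = feedback_nmda(),
                                 ampa = feedback_ampa(),
                                 g_sigma2 = 0.1,
                                 din = din_params(), seed = NULL) {
  positions <- -spacing * (seq_len(n) - 1)
  neurons <- lapply(positions, function(p) build_din(din, position = p))

  # gap junctions: rostral axon over the caudal proximal axon (the
  # initial-segment compartments close to the caudal soma); caudal
  # endpoints rotate over the initial segment so junctions are spread
  # along it rather than stacked on a single compartment
  gj <- list()
  if (is.finite(gj_resistance)) {
    n_axon <- nrow(neurons[[1]]$comps) - 1L
    n_prox <- max(1L, min(n_axon, as.integer(
      round(din$hillock_len / din$axon_comp_len))))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        dist <- positions[i] - positions[j]  # > 0, rostral i to caudal j
        if (dist > din$axon_span) next
        k <- max(1L, min(n_axon, as.integer(round(dist / din$axon_comp_len))))
        gj[[length(gj) + 1]] <- data.frame(
          neuron_a = i, comp_a = 1L + k,          # rostral axon near caudal soma
          neuron_b = j, comp_b = 2L + (i %% n_prox), # caudal proximal axon
          resistance = gj_resistance)
      }
    }
  }
  gj <- if (length(gj)) do.call(rbind, gj) else
    data.frame(neuron_a = integer(0), comp_a = integer(0),
               neuron_b = integer(0), comp_b = integer(0),
               resistance = numeric(0))

  syn <- with_seed(seed, .feedback_edges(n, p_syn, g_sigma2, nmda, ampa))
  new_network(neurons, syn, gj, seed = seed, kind = "din")
}

#' Build the generic Hodgkin-Huxley population
#'
#' `n` single-compartment neurons with classic squid channel parameters,
#' soma-to-soma gap junctions (default 100 MOhm) sampled per unordered pair
#' at probability `p_gj`, NMDA + AMPA feedback synapses sampled per ordered
#' pair at `p_syn`, synaptic peak conductances jittered with relative
#' variance `sigma2`, and channel-density noise of relative standard
#' deviation `density_sigma` per neuron.
#'
#' @param n population size.
#' @param gj_resistance somatic gap-junction resistance, MOhm (`Inf`
#'   removes coupling).
#' @param p_gj,p_syn electrical / chemical connection probabilities.
#' @param sigma2 relative variance of the synaptic peak-conductance
#'   multiplier (truncated normal, mean 1).
#' @param density_sigma relative sd of channel-density noise.
#' @param nmda,ampa feedback [synapse_kinetics()].
#' @param generic a [generic_params()] list.
#' @param seed integer seed.
#' @return a `swim_network`.
#' @export
build_generic_population <- function(n = 30, gj_resistance = 100, p_gj = 0.2,
                                     p_syn = 0.2, sigma2 = 0.1,
                                     density_sigma = 0.1,
                                     nmda = feedback_nmda(g_peak = 1),
                                     ampa = feedback_ampa(g_peak = 0.2),
                                     generic = generic_params(),
                                     seed = NULL) {
  with_seed(seed, {
    neurons <- lapply(seq_len(n), function(i) {
      m <- build_generic_hh(generic)
      apply_density_noise(m, density_sigma)
    })
    gj <- data.frame(neuron_a = integer(0), comp_a = integer(0),
                     neuron_b = integer(0), comp_b = integer(0),
                     resistance = numeric(0))
    if (is.finite(gj_resistance)) {
      pairs <- sample_connectivity(n, p_gj, directed = FALSE)
      if (nrow(pairs) > 0)
        gj <- data.frame(neuron_a = pairs$a, comp_a = 1L,
                         neuron_b = pairs$b, comp_b = 1L,
                         resistance = gj_resistance)
    }
    rows <- .feedback_edges(n, p_syn, sigma2, nmda, ampa)
    new_network(neurons, rows, gj, seed = seed, kind = "generic")
  })
}

#' Attach an external (stimulus-driven) synapse to neurons
#'
#' Adds one synapse per target neuron with no presynaptic neuron; events
#' are delivered to it by the stimulus layer (see [schedule_events()]).
#' Returns the network with an attribute-free synapse table; the indices of
#' the new rows are in `attr(, "syn_id")`.
#'
#' @param net a `swim_network`.
#' @param kin a [synapse_kinetics()].
#' @param targets neuron indices (default all).
#' @param comp target compartment (default soma, 1).
#' @return the augmented network; `attr(net$synapses, "last_added")` holds
#'   the new row indices.
#' @export
attach_external_synapse <- function(net, kin, targets = NULL, comp = 1L) {
  stopifnot(inherits(net, "swim_network"))
  if (is.null(targets)) targets <- seq_along(net$neurons)
  rows <- do.call(rbind, lapply(targets, function(tg)
    .syn_row(NA_integer_, tg, comp, kin)))
  first <- nrow(net$synapses) + 1L
  net$synapses <- rbind(net$synapses, rows)
  attr(net$synapses, "last_added") <- seq(first, nrow(net$synapses))
  net
}

#' Remove electrical coupling from a network
#'
#' @param net a `swim_network`.
#' @return the network with an empty gap-junction table.
#' @export
remove_gap_junctions <- function(net) {
  stopifnot(inherits(net, "swim_network"))
  net$gap_junctions <- net$gap_junctions[0, , drop = FALSE]
  net
}

#' Serialize a network to JSON
#'
#' Writes neurons (geometry summary), chemical synapse and gap-junction
#' edge tables and the construction seed, sufficient for exact replay of
#' the topology.
#'
#' @param net a `swim_network`.
#' @param path output file.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "swim_network"))
  obj <- list(
    kind = net$kind, seed = net$seed,
    n_neurons = length(net$neurons),
    neurons = lapply(net$neurons, function(nm)
      list(n_comp = nrow(nm$comps), position = nm$position,
           axon_span = nm$axon_span)),
    synapses = net$synapses,
    gap_junctions = net$gap_junctions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
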