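#' dIN model parameters
#'
#' Geometry, passive properties and channel sets of the multicompartment
#' dIN. The soma/dendrite is a single electrotonically compact compartment;
#' the descending axon is a chain of compartments extending caudally.
#' Axon geometry is not constrained by anatomy beyond "fine and long":
#' the defaults (600 um span, 20 um compartments, 0.3 um diameter) are
#' package choices and fully overridable.
#'
#' @param soma_diam,soma_len soma cylinder diameter and length, um.
#' @param axon_diam axon diameter, um.
#' @param axon_span total axon length, um.
#' @param axon_comp_len axon compartment length, um.
#' @param hillock_diam,hillock_len diameter and length of the initial
#'   axon segment (the proximal region carrying the axo-axonal gap
#'   junctions), um.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param ra axial resistivity, Ohm cm.
#' @param soma_channels,axon_channels channel sets (lists of
#'   [channel_spec()]).
#' @export
din_params <- function(soma_diam = 12, soma_len = 12, axon_diam = 0.3,
                       axon_span = 600, axon_comp_len = 20,
                       hillock_diam = 1, hillock_len = 60, cm = 1,
                       ra = 100, soma_channels = din_soma_channels(),
                       axon_channels = din_axon_channels()) {
  stopifnot(soma_diam > 0, soma_len > 0, axon_diam > 0, axon_span > 0,
            axon_comp_len > 0, cm > 0, ra > 0, hillock_diam > 0,
            hillock_len >= 0)
  list(soma_diam = soma_diam, soma_len = soma_len, axon_diam = axon_diam,
       axon_span = axon_span, axon_comp_len = axon_comp_len,
       hillock_diam = hillock_diam, hillock_len = hillock_len, cm = cm,
       ra = ra, soma_channels = soma_channels, axon_channels = axon_channels)
}

#' Generic single-compartment Hodgkin-Huxley neuron parameters
#'
#' @param soma_diam,soma_len soma cylinder dimensions, um.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param channels channel set; defaults to the classic squid parameters
#'   ([squid_channels()]): leak, sodium and potassium currents only.
#' @export
generic_params <- function(soma_diam = 30, soma_len = 30, cm = 1,
                           channels = squid_channels()) {
  stopifnot(soma_diam > 0, soma_len > 0, cm > 0)
  list(soma_diam = soma_diam, soma_len = soma_len, cm = cm, ra = 100,
       channels = channels)
}

# lateral area of a cylinder in cm^2
.cyl_area_cm2 <- function(diam_um, len_um) pi * diam_um * len_um * 1e-8

#' Build a multicompartment dIN
#'
#' One soma/dendrite compartment (all chemical synapses target it) plus a
#' chain of axon compartments descending caudally (decreasing rostro-caudal
#' coordinate) from the soma position. The axon carries sodium and fast
#' potassium channels at higher sodium density than the soma, which
#' supports action-potential propagation despite gap-junction shunting.
#'
#' @param params a [din_params()] list.
#' @param position rostro-caudal soma position, um (rostral = larger).
#' @return an object of class `neuron_model`: a list with a compartment
#'   table (`comps`), per-compartment channel lists (`channels`), soma
#'   index 1, and the chain axial conductances in uS (`ax_g`).
#' @export
build_din <- function(params = din_params(), position = 0) {
  n_axon <- as.integer(round(params$axon_span / params$axon_comp_len))
  if (n_axon < 1) stop("axon must have at least one compartment")
  n_hill <- min(n_axon,
                as.integer(round(params$hillock_len / params$axon_comp_len)))
  len <- c(params$soma_len, rep(params$axon_comp_len, n_axon))
  diam <- c(params$soma_diam, rep(params$hillock_diam, n_hill),
            rep(params$axon_diam, n_axon - n_hill))
  # compartment centre positions, soma at `position`, axon descending
  pos <- c(position,
           position - params$soma_len / 2 -
             (seq_len(n_axon) - 0.5) * params$axon_comp_len)
  comps <- data.frame(length_um = len, diam_um = diam, position_um = pos,
                      is_soma = c(TRUE, rep(FALSE, n_axon)))
  channels <- c(list(params$soma_channels),
                rep(list(params$axon_channels), n_axon))
  new_neuron_model(comps, channels, cm = params$cm, ra = params$ra,
                   position = position, axon_span = params$axon_span)
}

#' Build a generic single-compartment Hodgkin-Huxley neuron
#'
#' @param params a [generic_params()] list.
#' @return a `neuron_model` with exactly one compartment.
#' @export
build_generic_hh <- function(params = generic_params()) {
  comps <- data.frame(length_um = params$soma_len, diam_um = params$soma_diam,
                      position_um = 0, is_soma = TRUE)
  new_neuron_model(comps, list(params$channels), cm = params$cm,
                   ra = params$ra, position = 0, axon_span = 0)
}

new_neuron_model <- function(comps, channels, cm, ra, position, axon_span) {
  stopifnot(nrow(comps) == length(channels), sum(comps$is_soma) == 1,
            all(comps$length_um > 0), all(comps$diam_um > 0))
  # chain axial conductances between consecutive compartments (uS):
  # series of the two half-compartment axial resistances
  n <- nrow(comps)
  ax_g <- numeric(max(n - 1, 0))
  if (n > 1) {
    # axial resistance of each compartment, Ohm
    r_ax <- ra * (comps$length_um * 1e-4) /
      (pi * (comps$diam_um / 2 * 1e-4)^2)
    ax_g <- 1e6 / (0.5 * (r_ax[-n] + r_ax[-1]))  # Ohm -> uS
  }
  area <- .cyl_area_cm2(comps$diam_um, comps$length_um)
  structure(list(comps = comps, channels = channels, cm = cm, ra = ra,
                 area_cm2 = area, cap_nF = cm * area * 1e3,
                 ax_g = ax_g, soma = 1L, position = position,
                 axon_span = axon_span),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> %d compartment(s), soma at %.0f um, axon span %.0f um\n",
              nrow(x$comps), x$position, x$axon_span))
  cat(sprintf("  soma channels: %s\n",
              paste(vapply(x$channels[[1]], `[[`, "", "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Multiplicative noise on channel conductance densities
#'
#' Each channel's conductance density (or GHK permeability) is multiplied
#' by an independent draw from a normal distribution with mean 1 and
#' standard deviation `sigma_rel`, truncated at zero. Uses the R RNG: set
#' the seed (or pass `seed`) for reproducibility.
#'
#' @param model a `neuron_model`.
#' @param sigma_rel relative standard deviation (>= 0).
#' @param seed optional integer seed applied locally.
#' @return the perturbed `neuron_model`.
#' @export
apply_density_noise <- function(model, sigma_rel, seed = NULL) {
  stopifnot(inherits(model, "neuron_model"), sigma_rel >= 0)
  if (sigma_rel == 0) return(model)
  with_seed(seed, {
    # one multiplier per channel type, applied across all compartments so a
    # neuron's axon and soma are perturbed coherently
    names_all <- unique(unlist(lapply(model$channels,
                                      function(cs) vapply(cs, `[[`, "", "name"))))
    mult <- setNames(pmax(0, rnorm(length(names_all), 1, sigma_rel)),
                     names_all)
    for (ci in seq_along(model$channels)) {
      for (k in seq_along(model$channels[[ci]])) {
        ch <- model$channels[[ci]][[k]]
        m <- mult[[ch$name]]
        if (ch$kind == "ohmic") ch$density <- ch$density * m
        else {
          ch$permeability <- ch$permeability * m
          ch$ghk$permeability <- ch$ghk$permeability * m
        }
        model$channels[[ci]][[k]] <- ch
      }
    }
    model
  })
}
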