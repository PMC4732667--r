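#' Voltage-dependent gate kinetics
#'
#' A gate (activation or inactivation variable) of a Hodgkin-Huxley-type
#' channel. Both rate functions use the generalised five-coefficient form
#' \deqn{r(V) = (A + B V) / (C + \exp((D + V)/E))}
#' (units ms\eqn{^{-1}}, V in mV), which covers the classic
#' exponential, sigmoid and exponential-linear rate shapes. Removable
#' singularities (numerator and denominator vanishing together) are replaced
#' by their analytic limit.
#'
#' @param alpha,beta numeric(5): coefficients `c(A, B, C, D, E)` of the
#'   opening and closing rate functions.
#' @param exponent integer power of the gate in the channel open fraction.
#' @param name optional gate label (e.g. `"m"`, `"h"`, `"n"`).
#' @return an object of class `gate_kinetics`.
#' @examples
#' # classic squid delayed-rectifier n gate
#' n <- gate_kinetics(alpha = c(-0.55, -0.01, -1, 55, -10),
#'                    beta  = c(0.125, 0, 0, 65, 80), exponent = 4)
#' r <- gate_rates(n, -65)
#' r$alpha / (r$alpha + r$beta)  # n_inf at rest, ~0.3177
#' @export
gate_kinetics <- function(alpha, beta, exponent = 1L, name = NULL) {
  stopifnot(length(alpha) == 5, length(beta) == 5,
            is.finite(alpha), is.finite(beta),
            exponent >= 1, alpha[5] != 0, beta[5] != 0)
  g <- structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                      exponent = as.integer(exponent), name = name),
                 class = "gate_kinetics")
  # rates must be finite and non-negative across the physiological range
  v <- seq(-100, 60, by = 0.5)
  r <- gate_rates(g, v)
  if (any(!is.finite(r$alpha)) || any(!is.finite(r$beta)) ||
      any(r$alpha < 0) || any(r$beta < 0))
    stop("gate rates must be finite and non-negative on [-100, 60] mV")
  g
}

#' Evaluate gate opening and closing rates
#'
#' @param kinetics a [gate_kinetics()] object.
#' @param V membrane potential(s), mV. Must be finite.
#' @return list with numeric vectors `alpha` and `beta` (ms^-1).
#' @export
gate_rates <- function(kinetics, V) {
  stopifnot(inherits(kinetics, "gate_kinetics"), all(is.finite(V)))
  list(alpha = .gate_rate_cpp(kinetics$alpha, as.numeric(V)),
       beta  = .gate_rate_cpp(kinetics$beta, as.numeric(V)))
}

#' Gate steady state and time constant
#'
#' `gate_steady_state()` returns \eqn{x_\infty = \alpha/(\alpha+\beta)};
#' `gate_time_constant()` returns \eqn{\tau_x = 1/(\alpha+\beta)} (ms).
#'
#' @inheritParams gate_rates
#' @export
gate_steady_state <- function(kinetics, V) {
  r <- gate_rates(kinetics, V)
  r$alpha / (r$alpha + r$beta)
}

#' @rdname gate_steady_state
#' @export
gate_time_constant <- function(kinetics, V) {
  r <- gate_rates(kinetics, V)
  1 / (r$alpha + r$beta)
}

#' Channel specification
#'
#' An ohmic Hodgkin-Huxley-type channel (`channel_spec()`) carries a maximal
#' conductance density and a reversal potential; a Goldman-Hodgkin-Katz
#' calcium channel (`ghk_channel_spec()`) carries a permeability and fixed
#' internal/external Ca concentrations instead. Exactly one of the two
#' current formulations applies to any channel.
#'
#' @param name channel label.
#' @param density maximal conductance density, mS/cm^2 (>= 0).
#' @param reversal reversal potential, mV.
#' @param gates list of [gate_kinetics()] (empty for a passive leak).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, density, reversal, gates = list()) {
  stopifnot(is.character(name), density >= 0, is.finite(reversal))
  stopifnot(all(vapply(gates, inherits, TRUE, "gate_kinetics")))
  structure(list(name = name, kind = "ohmic", density = density,
                 reversal = reversal, gates = gates),
            class = "channel_spec")
}

#' @rdname channel_spec
#' @param permeability membrane permeability to Ca2+, cm/s (>= 0).
#' @param ca_in,ca_out internal / external Ca2+ concentration, mM (> 0).
#' @param temperature absolute temperature, K (> 0).
#' @export
ghk_channel_spec <- function(name, permeability, ca_in = 1e-4, ca_out = 10,
                             temperature = .T_DEFAULT, gates = list()) {
  p <- ghk_params(permeability, ca_in, ca_out, temperature)
  structure(list(name = name, kind = "ghk", permeability = permeability,
                 ghk = p, gates = gates),
            class = "channel_spec")
}

#' Goldman-Hodgkin-Katz parameter set
#'
#' @inheritParams ghk_channel_spec
#' @return an object of class `ghk_params` (ion valence fixed at 2).
#' @export
ghk_params <- function(permeability, ca_in = 1e-4, ca_out = 10,
                       temperature = .T_DEFAULT) {
  if (!(ca_in > 0 && ca_out > 0)) stop("GHK concentrations must be positive")
  if (!(temperature > 0)) stop("GHK temperature must be positive")
  stopifnot(permeability >= 0)
  structure(list(permeability = permeability, ca_in = ca_in, ca_out = ca_out,
                 temperature = temperature, valence = 2L),
            class = "ghk_params")
}

#' Hodgkin-Huxley channel current density
#'
#' \eqn{i = \bar g \prod_k x_k^{e_k} (V - E_{rev})}, outward positive.
#'
#' @param spec an ohmic [channel_spec()].
#' @param gates numeric vector of gate states, one per gate of `spec`, each
#'   in `[0, 1]`.
#' @param V membrane potential, mV.
#' @return current density, uA/cm^2.
#' @export
hh_current <- function(spec, gates, V) {
  stopifnot(inherits(spec, "channel_spec"), spec$kind == "ohmic",
            length(gates) == length(spec$gates))
  if (any(gates < 0 | gates > 1)) stop("gate states must lie in [0, 1]")
  open <- 1
  for (k in seq_along(spec$gates))
    open <- open * gates[k]^spec$gates[[k]]$exponent
  # mS/cm^2 * mV = uA/cm^2
  spec$density * open * (V - spec$reversal)
}

#' Goldman-Hodgkin-Katz calcium current density
#'
#' Constant-field flux equation for a divalent ion, outward positive:
#' \deqn{i = P z^2 F^2 V / (RT) \cdot
#'   \frac{[Ca]_i - [Ca]_o e^{-zFV/RT}}{1 - e^{-zFV/RT}}}
#' The removable singularity at V = 0 is replaced by its series limit.
#' For physiological gradients (external Ca above internal) the current is
#' inward (negative) at negative potentials.
#'
#' @param p a [ghk_params()] object.
#' @param V membrane potential(s), mV.
#' @return current density, uA/cm^2.
#' @export
ghk_calcium_current <- function(p, V) {
  stopifnot(inherits(p, "ghk_params"), all(is.finite(V)))
  # .ghk_current_cpp works in absolute terms (perm * area, nA); with area
  # 1 cm^2 the result in nA equals 1e3 * uA/cm^2
  ci <- p$ca_in * 1e-6   # mM -> mol/cm^3
  co <- p$ca_out * 1e-6
  .ghk_current_cpp(p$permeability, ci, co, p$temperature, as.numeric(V)) / 1e3
}

# ---- shipped channel sets --------------------------------------------------

#' Classic squid-axon Hodgkin-Huxley channel set
#'
#' The canonical squid giant axon parameters (resting potential -65 mV):
#' Na 120 mS/cm^2 (m^3 h, E 50 mV), K 36 mS/cm^2 (n^4, E -77 mV), leak
#' 0.3 mS/cm^2 (E -54.387 mV). Used by the generic single-compartment
#' neuron model.
#'
#' @return named list of [channel_spec()] objects.
#' @export
squid_channels <- function() {
  m <- gate_kinetics(c(-4.0, -0.1, -1, 40, -10), c(4, 0, 0, 65, 18),
                     exponent = 3L, name = "m")
  h <- gate_kinetics(c(0.07, 0, 0, 65, 20), c(1, 0, 1, 35, -10),
                     exponent = 1L, name = "h")
  n <- gate_kinetics(c(-0.55, -0.01, -1, 55, -10), c(0.125, 0, 0, 65, 80),
                     exponent = 4L, name = "n")
  list(leak = channel_spec("leak", 0.3, -54.387),
       na = channel_spec("na", 120, 50, list(m, h)),
       k = channel_spec("k", 36, -77, list(n)))
}

# constant-tau sigmoid gate: x_inf = 1/(1+exp(-(V-theta)/k)), tau = 1/a
.sigmoid_gate <- function(theta, k, tau, exponent = 1L, name = NULL) {
  a <- 1 / tau
  gate_kinetics(alpha = c(a, 0, 1, -theta, -k),
                beta  = c(a, 0, 1, -theta, k),
                exponent = exponent, name = name)
}

#' Default dIN channel sets
#'
#' Channel complement of the model dIN: leak, sodium, fast and slow
#' potassium, and a Goldman-Hodgkin-Katz calcium current on the
#' soma/dendrite compartment (`din_soma_channels()`); leak, sodium and fast
#' potassium at higher sodium density on the axon
#' (`din_axon_channels()`). The rate functions and densities are package
#' defaults tuned to the qualitative behaviour expected of dINs (resting
#' potential near -57 mV, repetitive 5-30 Hz firing under sustained NMDAR
#' conductances of roughly 0.5-2 nS); they are fully config-overridable.
#'
#' @param na_density,kf_density,ks_density,leak_density,ca_permeability
#'   override individual densities (mS/cm^2) / permeability (cm/s).
#' @return named list of [channel_spec()] objects.
#' @export
din_soma_channels <- function(na_density = 40, kf_density = 12,
                              ks_density = 3, leak_density = 0.01,
                              ca_permeability = 1.5e-6) {
  g <- .din_gates()
  list(leak = channel_spec("leak", leak_density, -57),
       na = channel_spec("na", na_density, 50, list(g$m, g$h)),
       kf = channel_spec("kf", kf_density, -80, list(g$n)),
       ks = channel_spec("ks", ks_density, -80, list(g$ks)),
       ca = ghk_channel_spec("ca", ca_permeability, gates = list(g$mca)))
}

#' @rdname din_soma_channels
#' @export
din_axon_channels <- function(na_density = 150, kf_density = 40,
                              leak_density = 0.01) {
  g <- .din_gates()
  list(leak = channel_spec("leak", leak_density, -57),
       na = channel_spec("na", na_density, 50, list(g$m, g$h)),
       kf = channel_spec("kf", kf_density, -80, list(g$n)))
}

# dIN gate set: Boltzmann steady states with fixed time constants. The
# midpoints keep the potassium window currents negligible at the -57 mV
# resting potential, giving the high input resistance of these small
# neurons; the slow potassium gate (tau 60 ms) paces repetitive firing.
.din_gates <- function() {
  list(
    m = .sigmoid_gate(theta = -33, k = 5, tau = 0.5, exponent = 3L,
                      name = "m"),
    h = .sigmoid_gate(theta = -52, k = -7, tau = 4, exponent = 1L,
                      name = "h"),
    n = .sigmoid_gate(theta = -20, k = 6, tau = 2.5, exponent = 2L,
                      name = "n"),
    ks = .sigmoid_gate(theta = -35, k = 6, tau = 30, exponent = 2L,
                       name = "ks"),
    mca = .sigmoid_gate(theta = -25, k = 7, tau = 4, exponent = 2L,
                        name = "mca"))
}
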