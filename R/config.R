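#' Write and read channel sets as YAML
#'
#' Channel definitions (name, kind, density or permeability, reversal, gate
#' rate coefficients and exponents) round-trip through a small YAML dialect
#' so parameter sets can be shipped, inspected and overridden as plain
#' text. The shipped defaults live under `inst/extdata/`.
#'
#' @param channels named list of [channel_spec()] objects.
#' @param path file path.
#' @return `read_channel_set()` returns a named list of [channel_spec()].
#' @export
write_channel_set <- function(channels, path) {
  obj <- lapply(channels, function(ch) {
    gates <- lapply(ch$gates, function(g)
      list(name = g$name, exponent = g$exponent,
           alpha = as.list(g$alpha), beta = as.list(g$beta)))
    if (ch$kind == "ohmic")
      list(kind = "ohmic", density = ch$density, reversal = ch$reversal,
           gates = gates)
    else
      list(kind = "ghk", permeability = ch$permeability,
           ca_in = ch$ghk$ca_in, ca_out = ch$ghk$ca_out,
           temperature = ch$ghk$temperature, gates = gates)
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_channel_set
#' @export
read_channel_set <- function(path) {
  obj <- yaml::read_yaml(path)
  out <- lapply(names(obj), function(nm) {
    ch <- obj[[nm]]
    gates <- lapply(ch$gates, function(g)
      gate_kinetics(unlist(g$alpha), unlist(g$beta),
                    exponent = g$exponent, name = g$name))
    if (identical(ch$kind, "ohmic"))
      channel_spec(nm, ch$density, ch$reversal, gates)
    else
      ghk_channel_spec(nm, ch$permeability, ca_in = ch$ca_in,
                       ca_out = ch$ca_out, temperature = ch$temperature,
                       gates = gates)
  })
  names(out) <- names(obj)
  out
}

#' Write and read synapse kinetics as YAML
#'
#' @param kinetics named list of [synapse_kinetics()] objects.
#' @param path file path.
#' @export
write_kinetics_set <- function(kinetics, path) {
  obj <- lapply(kinetics, function(k) {
    o <- list(tau_o = k$tau_o, tau_c = k$tau_c, g_peak = k$g_peak,
              e_rev = k$e_rev, delay = k$delay,
              transmission_p = k$transmission_p, label = k$label)
    if (!is.null(k$mg))
      o$mg <- list(eta = k$mg$eta, gamma = k$mg$gamma,
                   mg_out = k$mg$mg_out)
    o
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_kinetics_set
#' @export
read_kinetics_set <- function(path) {
  obj <- yaml::read_yaml(path)
  out <- lapply(obj, function(k) {
    mg <- if (!is.null(k$mg))
      mg_block_params(k$mg$eta, k$mg$gamma, k$mg$mg_out)
    synapse_kinetics(k$tau_o, k$tau_c, k$g_peak, e_rev = k$e_rev, mg = mg,
                     delay = k$delay, transmission_p = k$transmission_p,
                     label = k$label)
  })
  names(out) <- names(obj)
  out
}

#' Locate a shipped configuration file
#'
#' @param name file name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @export
swimnet_config <- function(name = NULL) {
  base <- system.file("extdata", package = "swimnet")
  if (is.null(name)) return(list.files(base))
  path <- file.path(base, name)
  if (!file.exists(path)) stop("no shipped config named ", name)
  path
}
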