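#' Membrane parameters of the Hodgkin-Huxley model
#'
#' Container for the passive and maximal-conductance parameters of the
#' squid-axon model in the depolarization convention: the membrane potential
#' `V` is the displacement from rest, so rest is 0 mV and the potassium
#' reversal potential is negative.
#'
#' @param Cm membrane capacitance (uF/cm^2)
#' @param gL,gK,gNa maximal conductance densities (mS/cm^2)
#' @param VL,VK,VNa reversal potentials (mV)
#'
#' @return An object of class `hh_parameters` (a named list).
#' @examples
#' p <- hh_parameters()
#' p$gK
#' @export
hh_parameters <- function(Cm = 1, gL = 0.3, VL = 10.6, gK = 36, VK = -12,
                          gNa = 120, VNa = 120) {
  stopifnot(is.numeric(Cm), Cm > 0,
            gL >= 0, gK >= 0, gNa >= 0,
            is.finite(VL), is.finite(VK), is.finite(VNa))
  structure(list(Cm = Cm, gL = gL, VL = VL, gK = gK, VK = VK,
                 gNa = gNa, VNa = VNa),
            class = "hh_parameters")
}

#' @export
print.hh_parameters <- function(x, ...) {
  cat("Hodgkin-Huxley membrane parameters (depolarization convention)\n")
  cat(sprintf("  Cm = %g uF/cm^2\n", x$Cm))
  cat(sprintf("  gL = %g mS/cm^2, VL = %g mV\n", x$gL, x$VL))
  cat(sprintf("  gK = %g mS/cm^2, VK = %g mV\n", x$gK, x$VK))
  cat(sprintf("  gNa = %g mS/cm^2, VNa = %g mV\n", x$gNa, x$VNa))
  invisible(x)
}

#' Finite potassium-channel population
#'
#' Describes a membrane patch carrying a finite number of stochastically
#' gating potassium channels.  The channel count is density times area and
#' the single-channel conductance is chosen so that the fully open population
#' reproduces the macroscopic conductance density `gK`.
#'
#' @param rho_K channel density (um^-2)
#' @param area_um2 membrane area (um^2)
#' @param params [hh_parameters()] supplying `gK` and `VK`
#'
#' @return An object of class `channel_population` with fields `N_K`
#'   (integer channel count), `gamma_pS` (single-channel conductance, pS),
#'   `V_K` (mV), `rho_K`, `area_um2`.
#' @examples
#' pop <- channel_population()       # 18/um^2 x 500 um^2 -> 9000 channels, 20 pS
#' pop$N_K
#' @export
channel_population <- function(rho_K = 18, area_um2 = 500,
                               params = hh_parameters()) {
  stopifnot(rho_K > 0, area_um2 > 0)
  N_K <- as.integer(round(rho_K * area_um2))
  if (N_K < 1L) stop("channel count rho_K * area_um2 must be >= 1")
  # gK [mS/cm^2] * area [um^2]: 1e-3 S/cm^2 * 1e-8 cm^2/um^2 = 1e-11 S = 10 pS
  gamma_pS <- params$gK * area_um2 * 10 / N_K
  structure(list(rho_K = rho_K, area_um2 = area_um2, N_K = N_K,
                 gamma_pS = gamma_pS, V_K = params$VK, params = params),
            class = "channel_population")
}

#' @export
print.channel_population <- function(x, ...) {
  cat(sprintf("Channel population: %d channels (%g/um^2 x %g um^2), %g pS each\n",
              x$N_K, x$rho_K, x$area_um2, x$gamma_pS))
  invisible(x)
}

#' Single open-channel current
#'
#' Ohmic current through one open channel, `gamma_K * (V - V_K)`, with the
#' pS x mV -> pA conversion.
#'
#' @param population a [channel_population()]
#' @param V membrane potential (mV)
#' @return Current in pA.
#' @export
single_channel_current <- function(population, V) {
  population$gamma_pS * (V - population$V_K) * 1e-3
}

#' Read or write membrane parameters as JSON
#'
#' @param params an [hh_parameters()] object
#' @param path JSON file path
#' @return `write_hh_parameters()` returns `path` invisibly;
#'   `read_hh_parameters()` returns an `hh_parameters` object.
#' @export
write_hh_parameters <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hh_parameters
#' @export
read_hh_parameters <- function(path) {
  do.call(hh_parameters, jsonlite::read_json(path, simplifyVector = TRUE))
}
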