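# Photon spectra.

#' Construct a photon spectrum
#'
#' @param energy_bins bin energies in MeV (strictly increasing)
#' @param weights non-negative fluence fractions; normalized to sum to 1
#' @return an object of class `photon_spectrum` with fields `energy_bins`,
#'   `weights` and `mean_energy` (fluence-weighted mean, MeV)
#' @export
photon_spectrum <- function(energy_bins, weights) {
  if (length(energy_bins) == 0) stop("empty spectrum")
  stopifnot(length(energy_bins) == length(weights))
  if (any(diff(energy_bins) <= 0)) stop("energy bins must be strictly increasing")
  if (any(weights < 0)) stop("weights must be >= 0")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  w <- weights / s
  structure(list(energy_bins = energy_bins, weights = w,
                 mean_energy = sum(w * energy_bins)),
            class = "photon_spectrum")
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat(sprintf("<photon_spectrum> %d bins, %.3g-%.3g MeV, mean %.3f MeV\n",
              length(x$energy_bins), min(x$energy_bins), max(x$energy_bins),
              x$mean_energy))
  invisible(x)
}

# Shape parameters of the parametric bremsstrahlung stand-in, per nominal MV.
# The 15 MV scale parameter is calibrated once so that the homogeneous-water
# depth of maximum dose of the engine lands near 3.0 cm.
.spectrum_params <- list(
  `6` = list(shape = 0.6, scale = 1.05),
  `10` = list(shape = 0.6, scale = 1.75),
  `15` = list(shape = 0.6, scale = 2.60),
  `18` = list(shape = 0.6, scale = 2.95)
)

#' Parametric megavoltage bremsstrahlung spectrum
#'
#' A thin-target-style analytic stand-in for a clinical linac spectrum:
#' fluence weights proportional to `E^shape * exp(-E/scale)` on 0.25 MeV bins
#' up to the nominal accelerating potential (the spectrum endpoint).
#'
#' @param nominal nominal accelerating potential in MV; one of 6, 10, 15, 18
#' @return a [photon_spectrum()]
#' @export
synthesize_spectrum <- function(nominal = 15) {
  key <- as.character(nominal)
  if (!key %in% names(.spectrum_params))
    stop("unsupported nominal MV: ", nominal, " (supported: ",
         paste(names(.spectrum_params), collapse = ", "), ")")
  p <- .spectrum_params[[key]]
  e <- seq(0.25, nominal, by = 0.25)
  w <- (e / p$scale)^p$shape * exp(-e / p$scale)
  photon_spectrum(e, w)
}
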