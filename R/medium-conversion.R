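# Bragg-Gray dose-to-medium conversion.

#' Mass collision stopping-power ratio of two materials
#'
#' Ratio of the interpolated mass collision stopping powers of `a` and `b`
#' at electron energy `E0`, i.e. `(S/rho)_a / (S/rho)_b`.
#'
#' Note on reporting conventions: the factor that converts a measured
#' dose-to-water into dose-to-medium is `(S/rho)_medium / (S/rho)_water`
#' (Bragg-Gray), i.e. `stopping_power_ratio(medium, water, E0)`; for PMMA and
#' lung tissue at megavoltage secondary-electron energies this is ~0.97 and
#' ~0.99 respectively. Quoted "water-medium" conversion ratios in the
#' literature usually refer to this factor.
#'
#' @param a,b [material()] objects
#' @param E0 electron energy in MeV (see [mean_secondary_electron_energy()])
#' @return unitless ratio
#' @export
stopping_power_ratio <- function(a, b, E0) {
  lookup(a, E0, "stopping_power") / lookup(b, E0, "stopping_power")
}

#' Convert dose-to-water to dose-to-medium
#'
#' Bragg-Gray cavity relation: `Dw / Dg = (S/rho)_w / (S/rho)_g`, so
#' `Dg = Dw / stopping_power_ratio(water, medium, E0)`.
#'
#' @param Dw dose to water, cGy (>= 0, vectorized)
#' @param medium target [material()]
#' @param E0 evaluation energy in MeV
#' @param water water material (defaults to the packaged one)
#' @return dose to `medium`, cGy
#' @export
dose_to_medium <- function(Dw, medium, E0, water = get_material("water")) {
  if (any(Dw < 0)) stop("dose must be >= 0")
  Dw / stopping_power_ratio(water, medium, E0)
}
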