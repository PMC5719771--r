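# Material objects and energy-indexed physics tables.

#' Construct a material
#'
#' A material bundles a density, an elemental composition and two
#' energy-indexed tables: mass collision stopping power (MeV cm^2/g) and mass
#' attenuation coefficient (cm^2/g). The four packaged media (`water`,
#' `pmma`, `lung`, `lif`) are available through [get_material()].
#'
#' @param name identifier
#' @param density bulk density in g/cm^3 used for transport (for lung this is
#'   the inflated-lung/cork value, not the density of the stopping-power
#'   tabulation)
#' @param composition named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-6)
#' @param stopping_power data.frame with columns `energy_MeV`, `value`
#' @param attenuation data.frame with columns `energy_MeV`, `value`
#' @return an object of class `material`
#' @export
material <- function(name, density, composition, stopping_power, attenuation) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  for (tab in list(stopping_power, attenuation)) {
    stopifnot(is.data.frame(tab), all(c("energy_MeV", "value") %in% names(tab)))
    if (any(diff(tab$energy_MeV) <= 0))
      stop("table energies must be strictly increasing")
    if (any(tab$value <= 0)) stop("table values must be positive")
  }
  structure(list(name = name, density = density, composition = composition,
                 stopping_power = stopping_power, attenuation = attenuation),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material '%s'>  density %.4g g/cm^3\n", x$name, x$density))
  cat("  composition:",
      paste(sprintf("%s %.4f", names(x$composition), x$composition),
            collapse = ", "), "\n")
  cat(sprintf("  tables: %d stopping-power / %d attenuation points, %.3g-%.3g MeV\n",
              nrow(x$stopping_power), nrow(x$attenuation),
              min(x$stopping_power$energy_MeV), max(x$stopping_power$energy_MeV)))
  invisible(x)
}

.material_cache <- new.env(parent = emptyenv())

# Transport densities (g/cm^3). Lung defaults to the inflated-lung / cork
# value; override via get_material("lung", density = ...).
.default_densities <- c(water = 1.000, pmma = 1.190, lung = 0.260, lif = 2.635)

#' Retrieve a packaged material
#'
#' @param name one of `"water"`, `"pmma"`, `"lung"`, `"lif"`
#' @param density optional override of the transport density (g/cm^3)
#' @return a [material()]
#' @export
get_material <- function(name, density = NULL) {
  name <- match.arg(tolower(name), names(.default_densities))
  key <- name
  if (is.null(.material_cache[[key]])) {
    sp <- read.csv(system.file("extdata",
                               paste0("stopping_power_", name, ".csv"),
                               package = "lungpdd", mustWork = TRUE))
    at <- read.csv(system.file("extdata",
                               paste0("attenuation_", name, ".csv"),
                               package = "lungpdd", mustWork = TRUE))
    .material_cache[[key]] <- material(name, .default_densities[[name]],
                                       .compositions[[name]], sp, at)
  }
  m <- .material_cache[[key]]
  if (!is.null(density)) {
    if (density <= 0) stop("density must be > 0")
    m$density <- density
  }
  m
}

#' Available packaged material names
#' @return character vector
#' @export
list_materials <- function() names(.default_densities)

#' Interpolate a material table
#'
#' Log-log interpolation between bracketing tabulated points; exact at grid
#' points. Energies outside the tabulated range raise an error (no silent
#' extrapolation).
#'
#' @param material a [material()]
#' @param E energy in MeV (vectorized)
#' @param quantity `"stopping_power"` (MeV cm^2/g) or `"attenuation"` (cm^2/g)
#' @return interpolated values
#' @export
lookup <- function(material, E, quantity = c("stopping_power", "attenuation")) {
  stopifnot(inherits(material, "material"))
  quantity <- match.arg(quantity)
  tab <- material[[quantity]]
  rng <- range(tab$energy_MeV)
  if (any(E < rng[1] | E > rng[2]))
    stop(sprintf("energy outside table range [%.4g, %.4g] MeV for %s of '%s'",
                 rng[1], rng[2], quantity, material$name))
  exp(stats::approx(log(tab$energy_MeV), log(tab$value), xout = log(E),
                    ties = "ordered")$y)
}

#' Electron density of a material relative to water
#'
#' Ratio of electrons per cm^3 to that of unit-density water; the exponent
#' basis of the Batho power law and the scaling used for radiological depth.
#'
#' @param material a [material()]
#' @return unitless relative electron density
#' @export
rel_electron_density <- function(material) {
  stopifnot(inherits(material, "material"))
  za_w <- .mean_z_over_a(.compositions$water)
  material$density * .mean_z_over_a(material$composition) / (1.0 * za_w)
}
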