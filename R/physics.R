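# Electron stopping powers, photon cross sections and the Compton mean-energy
# computation. These routines also generate the packaged material tables
# (see data-raw/make_material_tables.R).

# Z and atomic weight for the elements appearing in the package media.
.elements <- data.frame(
  symbol = c("H", "Li", "C", "N", "O", "F", "Na", "Mg", "P", "S", "Cl",
             "K", "Ca", "Fe", "Zn"),
  Z = c(1, 3, 6, 7, 8, 9, 11, 12, 15, 16, 17, 19, 20, 26, 30),
  A = c(1.008, 6.941, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
        30.974, 32.06, 35.45, 39.098, 40.078, 55.845, 65.38),
  stringsAsFactors = FALSE
)

# Elemental compositions (mass fractions). Lung is the ICRU-44 adult lung
# tissue composition; its stopping-power table is evaluated at the tabulated
# tissue density 1.05 g/cm^3 while the phantom transport density (inflated
# lung / cork) defaults to 0.26 g/cm^3.
.compositions <- list(
  water = c(H = 0.111894, O = 0.888106),
  pmma  = c(H = 0.080538, C = 0.599848, O = 0.319614),
  lung  = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
            P = 0.002, S = 0.003, Cl = 0.003, K = 0.002),
  lif   = c(Li = 0.267585, F = 0.732415)
)

# Sternheimer density-effect fit coefficients (I in eV; rho_tab is the
# density at which the fit applies). The fit satisfies delta(x0) ~ 0.
.sternheimer <- list(
  water = list(I = 75.0, Cbar = 3.5017, x0 = 0.2400, x1 = 2.8004,
               a = 0.09116, m = 3.4773, rho_tab = 1.000),
  pmma  = list(I = 74.0, Cbar = 3.3297, x0 = 0.1824, x1 = 2.6681,
               a = 0.11433, m = 3.3836, rho_tab = 1.190),
  lung  = list(I = 75.3, Cbar = 3.4708, x0 = 0.2261, x1 = 2.8001,
               a = 0.08588, m = 3.5353, rho_tab = 1.050),
  lif   = list(I = 94.0, Cbar = 3.1667, x0 = 0.0171, x1 = 2.7049,
               a = 0.07593, m = 3.7478, rho_tab = 2.635)
)

.mean_z_over_a <- function(composition) {
  idx <- match(names(composition), .elements$symbol)
  if (anyNA(idx)) stop("unknown element(s): ",
                       paste(names(composition)[is.na(idx)], collapse = ", "))
  sum(composition * .elements$Z[idx] / .elements$A[idx])
}

.sternheimer_delta <- function(x, p) {
  # x = log10(beta*gamma)
  d <- numeric(length(x))
  mid <- x >= p$x0 & x < p$x1
  hi <- x >= p$x1
  d[mid] <- 4.6052 * x[mid] - p$Cbar + p$a * (p$x1 - x[mid])^p$m
  d[hi] <- 4.6052 * x[hi] - p$Cbar
  d
}

# Mass collision stopping power for electrons (MeV cm^2/g), Berger-Seltzer
# formulation with Moller close collisions and Sternheimer density effect.
.bethe_scol <- function(E, composition, stern) {
  tau <- E / .mc2
  gamma <- tau + 1
  beta2 <- 1 - 1 / gamma^2
  x <- log10(sqrt(gamma^2 - 1))
  za <- .mean_z_over_a(composition)
  I_mc2 <- stern$I * 1e-6 / .mc2
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  L <- log(tau^2 * (tau + 2) / 2 / I_mc2^2) + Fm - .sternheimer_delta(x, stern)
  0.1535336 / beta2 * za * L
}

#' Klein-Nishina cross sections for Compton scattering off a free electron
#'
#' Computes the total Klein-Nishina cross section (closed form) and the
#' energy-transfer cross section (numerical integration of the Klein-Nishina
#' angular distribution weighted by the electron's energy share) per free
#' electron.
#'
#' @param E photon energy in MeV (vectorized, all > 0)
#' @return an object of class `kn_cross_sections`: a list with `energy`
#'   (MeV), `sigma_total` and `sigma_transfer` (cm^2/electron).
#' @examples
#' kn <- kn_cross_sections(c(0.511, 4))
#' kn$sigma_transfer / kn$sigma_total
#' @export
kn_cross_sections <- function(E) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("photon energy must be > 0")
  alpha <- E / .mc2
  st <- 2 * pi * .re^2 * (
    (1 + alpha) / alpha^2 *
      (2 * (1 + alpha) / (1 + 2 * alpha) - log(1 + 2 * alpha) / alpha) +
      log(1 + 2 * alpha) / (2 * alpha) -
      (1 + 3 * alpha) / (1 + 2 * alpha)^2
  )
  # low-energy series (the closed form cancels catastrophically as alpha -> 0)
  small <- alpha < 5e-3
  st[small] <- .sigma_thomson *
    (1 - 2 * alpha[small] + 26 / 5 * alpha[small]^2)
  # numerical integration over scattering angle for the transfer part
  str <- vapply(alpha, function(a) {
    mu <- seq(-1, 1, length.out = 2001)
    eps <- 1 / (1 + a * (1 - mu))
    dsig <- pi * .re^2 * eps^2 * (eps + 1 / eps - (1 - mu^2))
    f <- dsig * (1 - eps)
    h <- mu[2] - mu[1]
    n <- length(mu)
    w <- rep(c(4, 2), length.out = n - 2)
    sum(c(1, w, 1) * f) * h / 3
  }, numeric(1))
  structure(list(energy = E, sigma_total = st, sigma_transfer = str),
            class = "kn_cross_sections")
}

#' @export
print.kn_cross_sections <- function(x, ...) {
  cat("Klein-Nishina cross sections (cm^2/electron)\n")
  print(data.frame(energy_MeV = x$energy, sigma_total = x$sigma_total,
                   sigma_transfer = x$sigma_transfer,
                   transfer_fraction = x$sigma_transfer / x$sigma_total))
  invisible(x)
}

#' Mean initial energy of Compton secondary electrons
#'
#' Evaluates `E0 = hv/2 * sigma_tr(hv)/sigma(hv)` where `hv` is the mean
#' energy of the photon spectrum and the cross sections are the Klein-Nishina
#' total and energy-transfer cross sections per electron, both evaluated at
#' `hv`. This is the energy at which stopping-power ratios for dose-to-medium
#' conversion are taken.
#'
#' @param spectrum a [photon_spectrum()]
#' @return mean secondary-electron energy in MeV
#' @export
mean_secondary_electron_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "photon_spectrum"))
  hv <- spectrum$mean_energy
  kn <- kn_cross_sections(hv)
  0.5 * hv * kn$sigma_transfer / kn$sigma_total
}

# --- photon interaction coefficients (analytic models) ---------------------

# Pair production per atom (cm^2): Bethe-Heitler high-energy form without
# screening, Z(Z+1) to fold in triplet production; zero below ~3.6 MeV where
# pair production is a negligible share of the total at these beam qualities.
.pair_sigma_atom <- function(E, Z) {
  k <- E / .mc2
  base <- 28 / 9 * log(2 * k) - 218 / 27
  base[!is.finite(base) | base < 0 | k < 2] <- 0
  .alpha_fs * .re^2 * Z * (Z + 1) * base
}

# Photoelectric per atom (cm^2): Z^4.5/E^3 scaling normalized to low-Z media;
# only relevant below ~0.1 MeV here.
.pe_sigma_atom <- function(E, Z) {
  9.36e-34 * Z^4.5 / E^3
}

# Mass attenuation coefficient components (cm^2/g) for a composition.
.mu_over_rho <- function(E, composition, part = c("total", "compton",
                                                  "photoelectric", "pair")) {
  part <- match.arg(part)
  idx <- match(names(composition), .elements$symbol)
  Z <- .elements$Z[idx]; A <- .elements$A[idx]
  kn <- kn_cross_sections(E)$sigma_total
  out <- numeric(length(E))
  comp <- pe <- pr <- numeric(length(E))
  for (i in seq_along(Z)) {
    natom <- composition[i] * .NA_AVOG / A[i]
    comp <- comp + natom * Z[i] * kn
    pe <- pe + natom * .pe_sigma_atom(E, Z[i])
    pr <- pr + natom * .pair_sigma_atom(E, Z[i])
  }
  switch(part, total = comp + pe + pr, compton = comp,
         photoelectric = pe, pair = pr)
}
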