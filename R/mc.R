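# Monte Carlo dose engine: configuration, simulation wrapper, detector
# perturbation workflow and homogeneous beam data.

#' Equivalent circular field radius of a square field
#'
#' Equal-area conversion `pi R^2 = L^2`, i.e. `R = L / sqrt(pi)`, preserving
#' the scattering conditions of the square field in cylindrical geometry.
#'
#' @param L square field side in cm (> 0, vectorized)
#' @return radius in cm
#' @export
equivalent_radius <- function(L) {
  if (any(L <= 0)) stop("field side must be > 0")
  L / sqrt(pi)
}

#' Beam configuration
#'
#' @param nominal nominal MV (label; selects the packaged spectrum when
#'   `spectrum` is NULL)
#' @param square_side field side L in cm
#' @param ssd source-to-surface distance in cm (point source)
#' @param spectrum a [photon_spectrum()]; default [synthesize_spectrum()]
#' @return object of class `beam_config` with the equivalent circular field
#'   radius `equivalent_radius = L/sqrt(pi)`
#' @export
beam_config <- function(nominal = 15, square_side = 10, ssd = 100,
                        spectrum = NULL) {
  if (ssd <= 0) stop("ssd must be > 0")
  if (is.null(spectrum)) spectrum <- synthesize_spectrum(nominal)
  stopifnot(inherits(spectrum, "photon_spectrum"))
  structure(list(nominal = nominal, spectrum = spectrum, ssd = ssd,
                 square_side = square_side,
                 equivalent_radius = equivalent_radius(square_side)),
            class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf("<beam_config> %g MV, %gx%g cm^2 (R = %.4f cm), SSD %g cm\n",
              x$nominal, x$square_side, x$square_side, x$equivalent_radius,
              x$ssd))
  invisible(x)
}

#' Transport options for the Monte Carlo engine
#'
#' @param n_histories number of primary histories
#' @param seed integer RNG seed (the engine is bit-reproducible for a fixed
#'   seed)
#' @param photon_cutoff photon cutoff in keV (default 1 keV; photons below it
#'   deposit locally)
#' @param electron_cutoff electron kinetic-energy cutoff in keV (default
#'   70 keV, kinetic-energy convention; electrons below it deposit locally)
#' @param electron_transport `"kernel"` (density-scaled straight-line CSDA
#'   kernel with lateral Gaussian spread) or `"off"` (local deposition)
#' @param scoring `"axis"` (default): azimuthal-reciprocity estimator of the
#'   central-axis dose — a pencil beam is transported on the axis and energy
#'   deposited within the depth-projected field radius is collected, which
#'   for a laterally invariant slab geometry equals the axis dose of the
#'   uniform divergent field (inverse-square fluence factor applied);
#'   `"chip"`: analog disk source with scoring in the fixed chip-area
#'   cylinder (required, and selected automatically, when a detector insert
#'   is present, which breaks lateral invariance)
#' @param n_batches batches for statistical uncertainty (default 20)
#' @param primary_only if TRUE, deposit the photon energy at its first
#'   interaction site and stop (closed-form attenuation test mode)
#' @param forward_fraction effective forward range as a fraction of the CSDA
#'   range (accounts for electron path detours)
#' @param lateral_frac lateral Gaussian sigma per unit path length of the
#'   electron kernel
#' @param n_substeps kernel deposition substeps per electron
#' @param target_rel_se optional target relative standard error at the
#'   maximum-dose bin; the simulation is extended in chunks of `n_histories`
#'   (up to `max_histories`) until reached
#' @param max_histories cap for the `target_rel_se` loop
#' @return object of class `transport_options`
#' @export
transport_options <- function(n_histories = 1e6, seed = 1,
                              photon_cutoff = 1, electron_cutoff = 70,
                              electron_transport = c("kernel", "off"),
                              scoring = c("axis", "chip"),
                              n_batches = 20, primary_only = FALSE,
                              forward_fraction = 0.80, lateral_frac = 0.30,
                              n_substeps = 24, target_rel_se = NULL,
                              max_histories = 6e7) {
  electron_transport <- match.arg(electron_transport)
  scoring <- match.arg(scoring)
  if (photon_cutoff <= 0 || electron_cutoff <= 0) stop("cutoffs must be > 0")
  if (n_histories < 1) stop("n_histories must be >= 1")
  structure(list(n_histories = as.integer(n_histories), seed = as.integer(seed),
                 photon_cutoff = photon_cutoff,
                 electron_cutoff = electron_cutoff,
                 electron_transport = electron_transport,
                 scoring = scoring,
                 n_batches = as.integer(n_batches),
                 primary_only = primary_only,
                 forward_fraction = forward_fraction,
                 lateral_frac = lateral_frac,
                 n_substeps = as.integer(n_substeps),
                 target_rel_se = target_rel_se,
                 max_histories = max_histories),
            class = "transport_options")
}

# area-equivalent radius of the 3.0 x 3.0 mm^2 TLD chip face
.chip_area_cm2 <- 0.09
.chip_radius <- sqrt(.chip_area_cm2 / pi)
.chip_thickness <- 0.09

# per-material cross-section property row for the engine
.mat_props_row <- function(m) {
  idx <- match(names(m$composition), .elements$symbol)
  Z <- .elements$Z[idx]; A <- .elements$A[idx]; w <- m$composition
  c(rho = m$density,
    ne_per_g = .NA_AVOG * sum(w * Z / A),
    spair_per_g = .NA_AVOG * sum(w / A * Z * (Z + 1)),
    spe_per_g = .NA_AVOG * sum(w / A * Z^4.5),
    rel_edens = rel_electron_density(m))
}

#' Simulate a central-axis depth-dose profile
#'
#' Analog photon transport (Klein-Nishina Compton sampling, pair production
#' above 1.022 MeV, photoelectric absorption) from a point source collimated
#' to the beam's equivalent circular field at the surface, with secondary
#' electrons handled by the configured model. Dose is tallied in 60 slabs of
#' 0.5 cm within a central scoring cylinder whose cross-section equals the
#' TLD chip area (0.09 cm^2).
#'
#' @param phantom a [phantom_stack()]
#' @param beam a [beam_config()]
#' @param options a [transport_options()]
#' @param detector_at optional depth (cm) at which a detector chip layer
#'   (0.09 cm thick, chip cross-section) is inserted on the axis
#' @param detector_material material of the inserted chip (default `"lif"`)
#' @return object of class `dose_profile`: depth bin centers, dose per
#'   incident fluence, per-bin relative standard error (batch statistics),
#'   scoring radius and run metadata
#' @export
simulate_depth_dose <- function(phantom, beam, options = transport_options(),
                                detector_at = NULL,
                                detector_material = "lif") {
  stopifnot(inherits(phantom, "phantom_stack"), inherits(beam, "beam_config"),
            inherits(options, "transport_options"))
  nbins <- 60L; bin_w <- 0.5
  scoring <- options$scoring
  if (!is.null(detector_at)) scoring <- "chip" # insert breaks lateral invariance
  # geometry intervals: slab boundaries plus detector faces
  zb <- c(0, cumsum(phantom$slabs$thickness_cm))
  mats <- phantom$materials
  mat_names <- phantom$slabs$material
  ins_mat <- -1L
  if (!is.null(detector_at)) {
    d <- detector_at
    if (d - .chip_thickness / 2 < 0 || d + .chip_thickness / 2 > phantom$total_depth)
      stop("detector position outside phantom")
    zb <- sort(unique(c(zb, d - .chip_thickness / 2, d + .chip_thickness / 2)))
    det <- get_material(detector_material)
    mats <- c(mats, list(det))
    mat_names <- c(mat_names, det$name)
    ins_mat <- length(mats) - 1L # 0-based index for C++
  }
  n_iv <- length(zb) - 1
  iv_mid <- (zb[-1] + zb[-length(zb)]) / 2
  base_idx <- .slab_index(phantom, pmin(iv_mid, phantom$total_depth)) - 1L
  ins_active <- integer(n_iv)
  if (!is.null(detector_at))
    ins_active <- as.integer(iv_mid > detector_at - .chip_thickness / 2 &
                             iv_mid < detector_at + .chip_thickness / 2)
  props <- t(vapply(mats, .mat_props_row, numeric(5)))
  spec <- beam$spectrum
  cumw <- cumsum(spec$weights)
  cumw[length(cumw)] <- 1
  emode <- if (options$electron_transport == "kernel") 1L else 0L

  run_chunk <- function(n, seed) {
    .cpp_run_transport(as.integer(n), as.double(seed), options$n_batches,
                       zb, base_idx, ins_active, props,
                       ins_mat, .chip_radius,
                       spec$energy_bins, cumw,
                       beam$ssd, beam$equivalent_radius,
                       .chip_radius, nbins, bin_w,
                       options$photon_cutoff / 1000,
                       options$electron_cutoff / 1000,
                       emode, options$primary_only,
                       options$forward_fraction, options$lateral_frac,
                       options$n_substeps, if (scoring == "axis") 1L else 0L)
  }

  res <- run_chunk(options$n_histories, options$seed)
  edep <- res$edep
  e_emitted <- res$e_emitted
  e_deposited <- res$e_deposited
  n_run <- options$n_histories
  if (scoring == "axis") {
    # reciprocity normalization: collected energy per unit area over the
    # field, divided by areal bin mass, times the inverse-square factor
    centers <- (seq_len(nbins) - 0.5) * bin_w
    mass <- .bin_masses(phantom, nbins, bin_w, NULL) / (pi * .chip_radius^2)
    invsq <- (beam$ssd / (beam$ssd + centers))^2
  } else {
    # per-bin mass of the scoring cylinder (g), honoring the detector insert
    mass <- .bin_masses(phantom, nbins, bin_w, detector_at, detector_material)
    invsq <- rep(1, nbins)
  }

  prof <- function(edep, n_run) {
    tot <- rowSums(edep)
    dose <- ifelse(mass > 0, tot / mass / n_run, 0) * invsq
    nb <- ncol(edep)
    bm <- sweep(edep * nb, 1, mass, "/") / n_run # per-batch dose estimates
    se <- apply(bm, 1, stats::sd) / sqrt(nb) * invsq
    rel_se <- ifelse(dose > 0, se / dose, 0)
    list(dose = dose, rel_se = rel_se)
  }
  p <- prof(edep, n_run)
  if (!is.null(options$target_rel_se)) {
    k <- 1
    while (TRUE) {
      imax <- .smoothed_argmax(p$dose)
      if (sum(p$dose) > 0 && p$rel_se[imax] <= options$target_rel_se) break
      if (n_run + options$n_histories > options$max_histories) break
      k <- k + 1
      res2 <- run_chunk(options$n_histories, options$seed + 7919 * (k - 1))
      edep <- edep + res2$edep
      e_emitted <- e_emitted + res2$e_emitted
      e_deposited <- e_deposited + res2$e_deposited
      n_run <- n_run + options$n_histories
      p <- prof(edep, n_run)
    }
  }
  if (sum(p$dose) <= 0)
    stop("zero scored energy; increase n_histories")
  structure(list(depth = (seq_len(nbins) - 0.5) * bin_w,
                 dose = p$dose, rel_se = p$rel_se,
                 scoring = scoring, scoring_radius = .chip_radius,
                 n_histories = n_run, seed = options$seed,
                 e_emitted = e_emitted, e_deposited = e_deposited,
                 detector_at = detector_at),
            class = "dose_profile")
}

# scoring-cylinder bin masses in g, with the LiF insert overriding the slab
# material inside its z-extent (insert radius = scoring radius)
.bin_masses <- function(phantom, nbins, bin_w, detector_at = NULL,
                        detector_material = "lif") {
  area <- pi * .chip_radius^2
  tops <- c(0, cumsum(phantom$slabs$thickness_cm))
  rho <- phantom$slabs$density
  lif_rho <- get_material(detector_material)$density
  vapply(seq_len(nbins), function(b) {
    z0 <- (b - 1) * bin_w; z1 <- b * bin_w
    m <- 0
    for (s in seq_along(rho)) {
      ov <- max(0, min(z1, tops[s + 1]) - max(z0, tops[s]))
      if (ov <= 0) next
      if (!is.null(detector_at)) {
        d0 <- detector_at - .chip_thickness / 2
        d1 <- detector_at + .chip_thickness / 2
        ins <- max(0, min(z1, min(tops[s + 1], d1)) - max(z0, max(tops[s], d0)))
        m <- m + (ov - ins) * rho[s] + ins * lif_rho
      } else m <- m + ov * rho[s]
    }
    m * area
  }, numeric(1))
}

# argmax of a 3-bin moving average (noise-robust dmax bin)
.smoothed_argmax <- function(x) {
  n <- length(x)
  sm <- (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
  which.max(sm)
}

#' @export
print.dose_profile <- function(x, ...) {
  imax <- .smoothed_argmax(x$dose)
  cat(sprintf("<dose_profile> 60 x 0.5 cm bins, %s histories, dmax bin %.2f cm, rel SE there %.2f%%\n",
              format(x$n_histories, big.mark = ","), x$depth[imax],
              100 * x$rel_se[imax]))
  invisible(x)
}

#' Detector perturbation factors by paired Monte Carlo runs
#'
#' For each requested depth, the depth-dose profile is simulated with and
#' without a LiF chip at that depth using the same random seed (paired
#' streams), and `Fcor = PDD_with_detector / PDD_without` at the bin
#' containing the depth.
#'
#' @param phantom a [phantom_stack()]
#' @param beam a [beam_config()]
#' @param depths depths (cm) aligned with bin centers
#' @param options a [transport_options()]
#' @param detector_material material of the inserted chip (default `"lif"`)
#' @return data.frame with columns `depth_cm`, `fcor`, `rel_se`
#' @export
perturbation_profile <- function(phantom, beam, depths,
                                 options = transport_options(),
                                 detector_material = "lif") {
  if (any(abs((depths - 0.25) %% 0.5) > 1e-9))
    stop("depths must align with 0.5 cm bin centers")
  out <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    opt <- options
    opt$seed <- options$seed + (i - 1L)
    with_det <- simulate_depth_dose(phantom, beam, opt, detector_at = d,
                                    detector_material = detector_material)
    without <- simulate_depth_dose(phantom, beam, opt)
    b <- which.min(abs(with_det$depth - d))
    p1 <- normalize_pdd(with_det)
    p0 <- normalize_pdd(without)
    f <- p1$pdd[b] / p0$pdd[b]
    rse <- sqrt(with_det$rel_se[b]^2 + without$rel_se[b]^2)
    c(depth_cm = d, fcor = f, rel_se = rse)
  })
  as.data.frame(do.call(rbind, out))
}

#' Apply detector perturbation factors to measured doses
#'
#' `Fcor` converts a detector-present value to a detector-free one, so the
#' unperturbed dose is estimated as `measured / Fcor`.
#'
#' @param measured data.frame with columns `depth_cm`, `dose`
#' @param fcor data.frame with columns `depth_cm`, `fcor`
#' @return `measured` with dose replaced by the corrected dose
#' @export
apply_perturbation <- function(measured, fcor) {
  if (nrow(measured) != nrow(fcor) ||
      any(abs(measured$depth_cm - fcor$depth_cm) > 1e-9))
    stop("depth grids of measured doses and correction factors do not match")
  measured$dose <- measured$dose / fcor$fcor
  measured
}
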