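# Analytic heterogeneity-correction algorithms driven by homogeneous beam
# data: generalized Batho power law, modified Batho (dmax-shifted TMR) and a
# 1-D equivalent-TAR.

#' Construct a beam-data table
#'
#' Tissue-maximum-ratio (TMR) and tissue-air-ratio (TAR) values on a
#' rectangular depth x field-radius grid, as consumed by
#' [correction_factor()].
#'
#' @param radii field radii in cm (ascending)
#' @param depths depths in cm (ascending)
#' @param TMR,TAR matrices `length(depths) x length(radii)`, positive
#' @param dmax reference depth of maximum dose in cm (TMR(dmax) = 1)
#' @return object of class `beam_data_table`
#' @export
beam_data_table <- function(radii, depths, TMR, TAR, dmax) {
  stopifnot(is.matrix(TMR), is.matrix(TAR),
            nrow(TMR) == length(depths), ncol(TMR) == length(radii),
            all(dim(TMR) == dim(TAR)))
  if (any(TMR <= 0) || any(TAR <= 0)) stop("beam data must be positive")
  for (j in seq_along(radii)) {
    v <- .interp_col(depths, TMR[, j], dmax)
    if (abs(v - 1) > 1e-6 + 0.05) # tolerate MC noise, catch gross errors
      stop("TMR at dmax differs grossly from 1 for radius ", radii[j])
  }
  structure(list(radii = radii, depths = depths, TMR = TMR, TAR = TAR,
                 dmax = dmax), class = "beam_data_table")
}

#' @export
print.beam_data_table <- function(x, ...) {
  cat(sprintf("<beam_data_table> %d depths (%.2f-%.1f cm) x %d radii (%s cm), dmax %.2f cm\n",
              length(x$depths), min(x$depths), max(x$depths), length(x$radii),
              paste(round(x$radii, 2), collapse = ", "), x$dmax))
  invisible(x)
}

.interp_col <- function(xs, ys, x) {
  stats::approx(xs, ys, xout = x, rule = 1, ties = "ordered")$y
}

# bilinear lookup in a beam-data matrix; depth below the first grid point is
# clamped to it (the power-law formulas probe arbitrarily small depths near
# layer tops); depth above the grid or radius outside the grid is an error.
.beam_lookup <- function(table, which = c("TMR", "TAR"), depth, radius) {
  which <- match.arg(which)
  M <- table[[which]]
  if (radius < min(table$radii) - 1e-9 || radius > max(table$radii) + 1e-9)
    stop(sprintf("field radius %.3f cm outside beam-data range [%.3f, %.3f]",
                 radius, min(table$radii), max(table$radii)))
  radius <- min(max(radius, min(table$radii)), max(table$radii))
  depth <- pmax(depth, min(table$depths))
  if (any(depth > max(table$depths) + 1e-9))
    stop(sprintf("depth %.2f cm outside beam-data range (max %.2f)",
                 max(depth), max(table$depths)))
  depth <- pmin(depth, max(table$depths))
  if (length(table$radii) == 1) return(.interp_col(table$depths, M[, 1], depth))
  j <- findInterval(radius, table$radii, rightmost.closed = TRUE)
  j <- min(max(j, 1), length(table$radii) - 1)
  w <- (radius - table$radii[j]) / (table$radii[j + 1] - table$radii[j])
  (1 - w) * .interp_col(table$depths, M[, j], depth) +
    w * .interp_col(table$depths, M[, j + 1], depth)
}

#' Homogeneous beam data from the Monte Carlo engine
#'
#' Simulates a 30 cm homogeneous water phantom for each field radius and
#' derives TMR by the inverse-square conversion
#' `TMR(d) = PDD(d) * ((SSD+d)/(SSD+dmax))^2`, renormalized to 1 at dmax.
#' TAR is taken equal to TMR (backscatter-free approximation: peak scatter
#' factor treated as 1, adequate for relative correction factors at
#' megavoltage energies). Tables are extended beyond the simulated 30 cm by
#' an exponential tail fitted to the last bins, so that the dmax-shifted
#' modified-Batho lookups stay in range.
#'
#' @param field_sides square field sides in cm (converted internally with
#'   [equivalent_radius()])
#' @param options a [transport_options()]; one simulation per field size
#' @param nominal,ssd beam parameters (see [beam_config()])
#' @param dmax optional fixed reference dmax (cm); default: smoothed argmax
#'   of the largest-field PDD
#' @return a [beam_data_table()]
#' @export
homogeneous_beam_data <- function(field_sides = c(1, 2, 5, 10),
                                  options = transport_options(),
                                  nominal = 15, ssd = 100, dmax = NULL) {
  field_sides <- sort(field_sides)
  water <- phantom_stack("water", 30)
  pdds <- list()
  for (i in seq_along(field_sides)) {
    opt <- options
    opt$seed <- options$seed + 101L * (i - 1L)
    beam <- beam_config(nominal = nominal, square_side = field_sides[i],
                        ssd = ssd)
    pdds[[i]] <- normalize_pdd(simulate_depth_dose(water, beam, opt))
  }
  if (is.null(dmax)) dmax <- pdds[[length(pdds)]]$dmax
  depths <- pdds[[1]]$depth
  TMR <- sapply(pdds, function(p) {
    tmr <- p$pdd / 100 * ((ssd + p$depth) / (ssd + dmax))^2
    tmr / .interp_col(p$depth, tmr, dmax)
  })
  # exponential tail to 40 cm from the last 8 bins of each column
  ext <- seq(max(depths) + 0.5, 40, by = 0.5)
  tail_fit <- apply(TMR, 2, function(col) {
    n <- length(depths)
    idx <- (n - 7):n
    fit <- stats::lm(log(col[idx]) ~ depths[idx])
    exp(coef(fit)[1] + coef(fit)[2] * ext)
  })
  depths_all <- c(depths, ext)
  TMR <- rbind(TMR, tail_fit)
  beam_data_table(radii = equivalent_radius(field_sides), depths = depths_all,
                  TMR = TMR, TAR = TMR, dmax = dmax)
}

#' Heterogeneity correction factor at a depth
#'
#' Computes the TPS-style correction factor CF (heterogeneous dose relative
#' to the homogeneous unit-density dose at the same point) by one of:
#'
#' * `batho` — generalized Batho power law:
#'   `CF = prod_m TAR(z_m, r)^(rho_m - rho_above_m) / TAR(d, r)` over the
#'   layers at and above the point, `z_m` the distance from the point to the
#'   top of layer `m`, `rho` relative electron densities and the density of
#'   the region above the phantom taken as 0 (the division by `TAR(d, r)`
#'   is the same product evaluated on the homogeneous unit-density phantom);
#' * `mbatho` — modified Batho: the same product with dmax-shifted TMR,
#'   `TMR(z + dmax, r)`, restoring buildup behavior near interfaces;
#' * `etar` — equivalent TAR in 1-D slab form:
#'   `CF = TAR(d', r*) / TAR(d, r)` with `d'` the radiological depth and
#'   `r* = r * rho_tilde`, `rho_tilde` the thickness-weighted mean relative
#'   electron density from the surface to `d`.
#'
#' In the buildup region (`d < dmax`) the Batho variants are undefined and CF
#' is held at its value at dmax.
#'
#' @param method `"batho"`, `"mbatho"` or `"etar"`
#' @param phantom a [phantom_stack()]
#' @param d depth in cm (vectorized)
#' @param field a [beam_config()]
#' @param data a [beam_data_table()]
#' @return numeric vector of correction factors
#' @export
correction_factor <- function(method = c("batho", "mbatho", "etar"),
                              phantom, d, field, data) {
  method <- match.arg(method)
  stopifnot(inherits(phantom, "phantom_stack"), inherits(field, "beam_config"),
            inherits(data, "beam_data_table"))
  if (any(d < 0 | d > phantom$total_depth)) stop("depth outside phantom")
  r <- field$equivalent_radius
  if (method %in% c("batho", "mbatho")) {
    dd <- pmax(d, data$dmax) # hold CF at its dmax value in the buildup region
    vapply(dd, function(di) .batho_cf(method, phantom, di, r, data), numeric(1))
  } else {
    vapply(d, function(di) {
      dprime <- radiological_depth(phantom, di)
      rho_tilde <- if (di > 0) dprime / di else 1
      .beam_lookup(data, "TAR", dprime, r * rho_tilde) /
        .beam_lookup(data, "TAR", di, r)
    }, numeric(1))
  }
}

.batho_cf <- function(method, phantom, d, r, data) {
  red <- vapply(phantom$materials, rel_electron_density, numeric(1))
  tops <- c(0, cumsum(phantom$slabs$thickness_cm))
  k <- .slab_index(phantom, d)
  lookup1 <- function(z) {
    # the TAR power law is defined from dmax onward; clamping the lookup at
    # dmax avoids the unphysical buildup-region blow-up at layer tops (the
    # dmax-shifted TMR of the modified variant handles buildup instead)
    if (method == "batho") .beam_lookup(data, "TAR", max(z, data$dmax), r)
    else .beam_lookup(data, "TMR", z + data$dmax, r)
  }
  logcf <- 0
  for (m in seq_len(k)) {
    rho_above <- if (m == 1) 0 else red[m - 1]
    z <- d - tops[m]
    logcf <- logcf + (red[m] - rho_above) * log(lookup1(z))
  }
  # same product on the homogeneous unit-density phantom collapses to the
  # single surface-layer factor at z = d
  logcf <- logcf - log(lookup1(d))
  exp(logcf)
}

#' Heterogeneity-corrected PDD curve
#'
#' Multiplies a homogeneous PDD curve by the per-depth correction factor of
#' the chosen algorithm and renormalizes with [normalize_pdd()].
#'
#' @param method `"batho"`, `"mbatho"` or `"etar"`
#' @param homogeneous_pdd a `pdd_curve` on the standard depth grid
#' @param phantom a [phantom_stack()]
#' @param field a [beam_config()]
#' @param data a [beam_data_table()]
#' @return a `pdd_curve`; depths beyond the phantom are dropped
#' @export
corrected_pdd <- function(method, homogeneous_pdd, phantom, field, data) {
  stopifnot(inherits(homogeneous_pdd, "pdd_curve"))
  keep <- homogeneous_pdd$depth <= phantom$total_depth
  depth <- homogeneous_pdd$depth[keep]
  cf <- correction_factor(method, phantom, depth, field, data)
  normalize_pdd(data.frame(depth_cm = depth,
                           dose = homogeneous_pdd$pdd[keep] * cf,
                           rel_se = homogeneous_pdd$rel_se[keep]))
}
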