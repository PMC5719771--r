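# PDD normalization, ratio curves and interface metrics.

#' Normalize a depth-dose profile to percentage depth dose
#'
#' Values are scaled to 100 at the maximum-dose bin. On noisy Monte Carlo
#' curves the maximum bin is chosen as the argmax of a 3-bin moving average;
#' the raw (unsmoothed) bin value at that bin defines the 100% level.
#' Normalizing an already-normalized curve returns it unchanged.
#'
#' @param profile a [dose_profile()][simulate_depth_dose], `pdd_curve`, or
#'   data.frame with columns `depth_cm` and `dose`
#' @return object of class `pdd_curve`: `depth`, `pdd` (percent), `rel_se`,
#'   `dmax` (cm, center of the maximum-dose bin)
#' @export
normalize_pdd <- function(profile) {
  if (inherits(profile, "pdd_curve")) {
    depth <- profile$depth; dose <- profile$pdd; rel_se <- profile$rel_se
  } else if (inherits(profile, "dose_profile")) {
    depth <- profile$depth; dose <- profile$dose; rel_se <- profile$rel_se
  } else {
    stopifnot(is.data.frame(profile), all(c("depth_cm", "dose") %in% names(profile)))
    depth <- profile$depth_cm; dose <- profile$dose
    rel_se <- if ("rel_se" %in% names(profile)) profile$rel_se else rep(0, length(dose))
  }
  if (all(dose <= 0)) stop("all-zero profile cannot be normalized")
  imax <- .smoothed_argmax(dose)
  structure(list(depth = depth, pdd = 100 * dose / dose[imax],
                 rel_se = rel_se, dmax = depth[imax]),
            class = "pdd_curve")
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf("<pdd_curve> %d bins, dmax %.2f cm\n", length(x$depth), x$dmax))
  invisible(x)
}

#' Per-depth ratio of two PDD curves
#'
#' Elementwise `a/b` on a common depth grid; relative uncertainties are added
#' in quadrature. Bins where `b` is zero are excluded (NA) .
#'
#' @param a,b `pdd_curve` objects on the same grid
#' @return object of class `ratio_curve`: `depth`, `ratio`, `rel_se`
#' @export
ratio_curve <- function(a, b) {
  stopifnot(inherits(a, "pdd_curve"), inherits(b, "pdd_curve"))
  if (length(a$depth) != length(b$depth) || any(abs(a$depth - b$depth) > 1e-9))
    stop("PDD curves are not on the same depth grid")
  bad <- b$pdd <= 0
  r <- ifelse(bad, NA_real_, a$pdd / b$pdd)
  rse <- ifelse(bad, NA_real_, sqrt(a$rel_se^2 + b$rel_se^2))
  structure(list(depth = a$depth, ratio = r, rel_se = rse,
                 n_excluded = sum(bad)),
            class = "ratio_curve")
}

#' @export
print.ratio_curve <- function(x, ...) {
  ok <- is.finite(x$ratio)
  cat(sprintf("<ratio_curve> %d bins (%d excluded), range %.3f-%.3f\n",
              length(x$depth), x$n_excluded,
              min(x$ratio[ok]), max(x$ratio[ok])))
  invisible(x)
}

#' Interface over/under-dosage metrics of a ratio curve
#'
#' Quantifies how a calculated PDD (numerator of the ratio) deviates from the
#' reference (denominator) around the soft-tissue/lung interfaces of a slab
#' phantom:
#' * `lung_overdose_pct`: 100 x (max ratio − 1) over lung bins within
#'   `window` below the soft->lung interface;
#' * `soft_underdose_pct`: 100 x (1 − min ratio) over soft-tissue bins within
#'   `window` below the lung->soft interface;
#' * `max_lung_discrepancy_pct`: 100 x max |ratio − 1| over all lung bins.
#'
#' @param r a [ratio_curve()]
#' @param phantom the [phantom_stack()] the curves were computed on (must
#'   contain a lung layer)
#' @param window interface window in cm (default 1.0)
#' @return object of class `comparison_result`
#' @export
interface_metrics <- function(r, phantom, window = 1.0) {
  stopifnot(inherits(r, "ratio_curve"), inherits(phantom, "phantom_stack"))
  if (window <= 0) stop("window must be > 0")
  if (!"lung" %in% phantom$slabs$material)
    stop("phantom has no lung layer")
  inside <- r$depth <= phantom$total_depth
  region <- rep(NA_character_, length(r$depth))
  region[inside] <- material_at_depth(phantom, r$depth[inside])
  lung_idx <- which(region == "lung" & is.finite(r$ratio))
  if (!length(lung_idx)) stop("no lung bins with finite ratio")
  tops <- c(0, cumsum(phantom$slabs$thickness_cm))
  s <- which(phantom$slabs$material == "lung")[1]
  lung_top <- tops[s]; lung_bottom <- tops[s + 1]
  in_win_lung <- lung_idx[r$depth[lung_idx] <= lung_top + window]
  soft_idx <- which(region != "lung" & !is.na(region) & is.finite(r$ratio) &
                    r$depth > lung_bottom & r$depth <= lung_bottom + window)
  lung_over <- if (length(in_win_lung))
    100 * (max(r$ratio[in_win_lung]) - 1) else NA_real_
  soft_under <- if (length(soft_idx))
    100 * (1 - min(r$ratio[soft_idx])) else NA_real_
  structure(list(
    ratio = r,
    region = region,
    lung_overdose_pct = lung_over,
    soft_underdose_pct = soft_under,
    max_lung_discrepancy_pct = 100 * max(abs(r$ratio[lung_idx] - 1)),
    window_cm = window
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  cat(sprintf("  lung overdose near soft->lung interface: %.1f%%\n",
              x$lung_overdose_pct))
  cat(sprintf("  soft-tissue underdose near lung->soft interface: %.1f%%\n",
              x$soft_underdose_pct))
  cat(sprintf("  max |ratio-1| in lung: %.1f%%\n", x$max_lung_discrepancy_pct))
  invisible(x)
}
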