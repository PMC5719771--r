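# Shared fixtures. Expensive Monte Carlo artifacts are computed once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# homogeneous beam data over the reference radii plus brackets
ref_beam_data <- function() fixture("beam_data", {
  homogeneous_beam_data(c(0.4, 1, 2, 5, 10, 12.5),
                        transport_options(n_histories = 1e6, seed = 11))
})

# heterogeneous-phantom PDD for a given field side (cached per side)
ref_het_pdd <- function(L, n = 1e6, seed = 21) {
  fixture(sprintf("het_pdd_%s_%g_%d", L, n, seed), {
    normalize_pdd(simulate_depth_dose(
      make_reference_phantom(), beam_config(15, L, 100),
      transport_options(n_histories = n, seed = seed)))
  })
}

# truncate a pdd_curve to the phantom depth range
pdd_within <- function(pdd, phantom) {
  keep <- pdd$depth <= phantom$total_depth
  structure(list(depth = pdd$depth[keep], pdd = pdd$pdd[keep],
                 rel_se = pdd$rel_se[keep], dmax = pdd$dmax),
            class = "pdd_curve")
}

# synthetic exponential-ish truth curve for TLD recovery studies
tld_truth <- function(depths = seq(0.75, 27.75, by = 1)) {
  data.frame(depth_cm = depths, dose_cGy = 100 * exp(-0.04 * depths))
}

# toy beam-data table: TAR(z) = exp(-k z), TMR(y) = exp(-k (y - dmax)) so
# that the dmax-shifted TMR of the modified Batho coincides with the TAR of
# the generalized Batho; radius-independent
toy_beam_data <- function(k = 0.04, dmax = 0.2, radii = c(0.2, 8)) {
  depths <- seq(dmax, 40, by = 0.2)
  TAR <- matrix(rep(exp(-k * depths), length(radii)), ncol = length(radii))
  TMR <- matrix(rep(exp(-k * (depths - dmax)), length(radii)),
                ncol = length(radii))
  beam_data_table(radii, depths, TMR = TMR, TAR = TAR, dmax = dmax)
}
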