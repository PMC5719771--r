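# Heterogeneity-correction algorithms.

test_that("all three methods give CF = 1 on a homogeneous unit-density
           phantom", {
  bd <- toy_beam_data()
  hw <- phantom_stack("water", 30)
  beam <- beam_config(15, 5, 100)
  d <- c(0.5, 3, 10, 25)
  expect_equal(correction_factor("batho", hw, d, beam, bd), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(correction_factor("mbatho", hw, d, beam, bd), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(correction_factor("etar", hw, d, beam, bd), rep(1, 4),
               tolerance = 1e-12)
})

test_that("the generalized Batho product matches a hand evaluation on a
           two-layer toy with TAR(z) = exp(-0.04 z)", {
  k <- 0.04
  bd <- toy_beam_data(k = k)
  toy <- phantom_stack(c("water", "lung"), c(1, 20))
  beam <- beam_config(15, 5, 100)
  red_lung <- rel_electron_density(get_material("lung"))
  # point 2 cm deep (1 cm into lung): product collapses to TAR(1)^(rho_l - 1)
  cf <- correction_factor("batho", toy, 2, beam, bd)
  expect_equal(cf, exp(-k * 1)^(red_lung - 1), tolerance = 1e-6)
  # deeper point, same structure
  cf7 <- correction_factor("batho", toy, 7, beam, bd)
  expect_equal(cf7, exp(-k * 6)^(red_lung - 1), tolerance = 1e-6)
  expect_gt(cf7, cf) # correction grows with depth inside the low-density layer
})

test_that("Batho and modified Batho coincide when the TAR and dmax-shifted
           TMR tables are constructed to coincide", {
  bd <- toy_beam_data()
  ph <- make_reference_phantom()
  beam <- beam_config(15, 2, 100)
  # depths keeping every layer-top distance above dmax, where the TAR
  # lookup of the generalized Batho is clamped by construction
  d <- c(seq(1, 4.5, 0.5), seq(5.5, 17.5, 0.5), seq(18.5, 27, 0.5))
  cb <- correction_factor("batho", ph, d, beam, bd)
  cm <- correction_factor("mbatho", ph, d, beam, bd)
  expect_equal(cb, cm, tolerance = 1e-6)
})

test_that("equivalent-TAR CF is continuous across slab interfaces", {
  bd <- toy_beam_data()
  ph <- make_reference_phantom()
  beam <- beam_config(15, 2, 100)
  for (di in c(5, 18)) {
    eps <- 1e-4
    cf <- correction_factor("etar", ph, c(di - eps, di + eps), beam, bd)
    expect_lt(abs(diff(cf)), 1e-3)
  }
})

test_that("all three methods predict increased dose deep inside low-density
           lung on the reference phantom with Monte Carlo beam data", {
  bd <- ref_beam_data()
  ph <- make_reference_phantom()
  beam <- beam_config(15, 1, 100)
  d <- seq(11, 17, by = 1.5)
  for (m in c("batho", "mbatho", "etar")) {
    cf <- correction_factor(m, ph, d, beam, bd)
    expect_true(all(cf > 1), info = m)
  }
})

test_that("corrected PDD is the identity under CF = 1 and is range-checked", {
  bd <- toy_beam_data()
  hw <- phantom_stack("water", 30)
  beam <- beam_config(15, 5, 100)
  hom <- normalize_pdd(data.frame(depth_cm = seq(0.25, 29.75, 0.5),
                                  dose = exp(-0.03 * seq(0.25, 29.75, 0.5)) *
                                    pmin(1, seq(0.25, 29.75, 0.5) / 3)))
  out <- corrected_pdd("etar", hom, hw, beam, bd)
  expect_equal(out$pdd, hom$pdd, tolerance = 1e-9)
  expect_error(.beam_lookup <- lungpdd:::.beam_lookup(bd, "TAR", 50, 1),
               "outside beam-data range")
  expect_error(lungpdd:::.beam_lookup(bd, "TAR", 10, 20),
               "outside beam-data range")
})
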