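# Monte Carlo engine: geometry, determinism, bookkeeping, perturbation
# workflow and beam-data derivation.

test_that("equivalent circular field preserves the square-field area", {
  expect_equal(equivalent_radius(1), 0.564190, tolerance = 1e-6)
  expect_equal(equivalent_radius(10), 5.641896, tolerance = 1e-6)
  set.seed(1)
  L <- runif(20, 0.3, 25)
  expect_true(all(abs(pi * equivalent_radius(L)^2 - L^2) < 1e-12))
  expect_error(equivalent_radius(0), "> 0")
})

test_that("a fixed seed reproduces the dose profile bit-for-bit and energy
           bookkeeping holds", {
  ph <- make_reference_phantom()
  beam <- beam_config(15, 2, 100)
  opt <- transport_options(n_histories = 5e4, seed = 123)
  p1 <- simulate_depth_dose(ph, beam, opt)
  p2 <- simulate_depth_dose(ph, beam, opt)
  expect_identical(p1$dose, p2$dose)
  expect_identical(p1$rel_se, p2$rel_se)
  p3 <- simulate_depth_dose(ph, beam, transport_options(n_histories = 5e4,
                                                        seed = 124))
  expect_false(identical(p1$dose, p3$dose))
  expect_lte(p1$e_deposited, p1$e_emitted)
  expect_gt(p1$e_deposited, 0)
})

test_that("photon-only transport reproduces closed-form exponential
           attenuation within statistics", {
  # monoenergetic 2 MeV pencil on a water slab, first-interaction scoring
  spec <- photon_spectrum(2, 1)
  beam <- beam_config(15, 2, 100, spectrum = spec)
  phw <- phantom_stack("water", 30)
  p <- simulate_depth_dose(phw, beam,
                           transport_options(n_histories = 2e5, seed = 5,
                                             primary_only = TRUE))
  mu <- lookup(get_material("water"), 2, "attenuation")
  pred <- exp(-mu * p$depth) * (100 / (100 + p$depth))^2
  sc <- sum(p$dose * pred / p$rel_se^2) / sum(pred^2 / p$rel_se^2)
  z <- (p$dose - sc * pred) / (p$dose * p$rel_se)
  expect_lt(stats::quantile(abs(z), 0.95), 3)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("relative standard error scales as one over root n_histories", {
  ph <- phantom_stack("water", 30)
  beam <- beam_config(15, 5, 100)
  p1 <- simulate_depth_dose(ph, beam, transport_options(n_histories = 5e4,
                                                        seed = 31))
  p4 <- simulate_depth_dose(ph, beam, transport_options(n_histories = 2e5,
                                                        seed = 32))
  i <- which.max(p1$dose)
  ratio <- p4$rel_se[i] / p1$rel_se[i]
  expect_gt(ratio, 0.5 * 0.7)  # 1/sqrt(4) within ~30%
  expect_lt(ratio, 0.5 * 1.4)
})

test_that("detector perturbation factors are unity for a same-material chip
           and reproducible for LiF", {
  phw <- phantom_stack("water", 30)
  beam <- beam_config(15, 2, 100)
  fc <- perturbation_profile(phw, beam, 5.25,
                             transport_options(n_histories = 2e5, seed = 9),
                             detector_material = "water")
  expect_lt(abs(fc$fcor - 1), 3 * fc$rel_se)

  ph <- make_reference_phantom()
  f1 <- perturbation_profile(ph, beam, 11.75,
                             transport_options(n_histories = 2e5, seed = 40))
  f2 <- perturbation_profile(ph, beam, 11.75,
                             transport_options(n_histories = 2e5, seed = 41))
  expect_gt(f1$fcor, 0)
  expect_lt(abs(f1$fcor - f2$fcor),
            3 * sqrt(f1$rel_se^2 + f2$rel_se^2) * f1$fcor)
  expect_error(perturbation_profile(ph, beam, 1.1), "bin centers")
})

test_that("perturbation correction divides measured doses by Fcor and
           round-trips a constructed closure", {
  meas <- data.frame(depth_cm = c(1.25, 5.75), dose = c(100, 80))
  fc1 <- data.frame(depth_cm = c(1.25, 5.75), fcor = c(1, 1))
  expect_equal(apply_perturbation(meas, fc1)$dose, meas$dose)
  fc2 <- data.frame(depth_cm = c(1.25, 5.75), fcor = c(1.05, 0.9))
  expect_equal(apply_perturbation(meas, fc2)$dose[1], 100 / 1.05,
               tolerance = 1e-12)
  truth <- c(55, 70)
  observed <- truth * fc2$fcor
  rec <- apply_perturbation(data.frame(depth_cm = fc2$depth_cm,
                                       dose = observed), fc2)
  expect_equal(rec$dose, truth, tolerance = 1e-12)
  expect_error(apply_perturbation(meas, data.frame(depth_cm = c(1, 2),
                                                   fcor = c(1, 1))),
               "do not match")
})

test_that("homogeneous beam data: TMR is 1 at dmax, decreases beyond it, and
           grows with field size at depth", {
  bd <- ref_beam_data()
  for (j in seq_along(bd$radii)) {
    tmr_dmax <- stats::approx(bd$depths, bd$TMR[, j], bd$dmax)$y
    expect_lt(abs(tmr_dmax - 1), 0.03)
    beyond <- bd$depths >= bd$dmax + 1 & bd$depths <= 30
    fit <- stats::lm(bd$TMR[beyond, j] ~ bd$depths[beyond])
    expect_lt(coef(fit)[2], 0) # decreasing trend beyond dmax
  }
  # scatter monotonicity at 20 cm depth across the reference radii
  tmr20 <- vapply(seq_along(bd$radii), function(j)
    stats::approx(bd$depths, bd$TMR[, j], 20)$y, numeric(1))
  expect_gt(tmr20[length(tmr20)], tmr20[2])
  expect_true(all(diff(tmr20) > -0.02))
})
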