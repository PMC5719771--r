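# TLD processing chain.

test_that("batch characterization recovers sensitivities and flags dead
           dosimeters", {
  zero <- data.frame(dosimeter_id = c("a", "b"), raw = c(100, 100))
  ref <- data.frame(dosimeter_id = c("a", "b"), raw = c(1100, 1100))
  ch <- characterize_batch(zero, ref)
  expect_equal(ch$TL0, 100)
  expect_equal(unname(ch$S), c(1, 1))
  # net reference readings 90 and 110 give S = 0.9, 1.1
  ref2 <- data.frame(dosimeter_id = c("a", "b"), raw = c(190, 210))
  ch2 <- characterize_batch(zero, ref2)
  expect_equal(unname(ch2$S), c(0.9, 1.1))
  expect_lt(abs(mean(ch2$S) - 1), 1e-12)
  dead <- data.frame(dosimeter_id = c("a", "b"), raw = c(100, 400))
  expect_error(characterize_batch(zero, dead), "a")
})

test_that("session factors are 1 for the reference session and absorb a
           uniform scaling exactly", {
  ids <- sprintf("c%d", 1:8)
  zero <- data.frame(dosimeter_id = ids, raw = rep(0, 8))
  ref <- data.frame(dosimeter_id = ids, raw = 1000 * seq(0.9, 1.25, 0.05))
  ch <- characterize_batch(zero, ref)
  ctl <- data.frame(dosimeter_id = ids, raw = ref$raw)
  sc <- session_factor(ctl, ch, NULL, "ref")
  expect_equal(unname(sc$FCm["ref"]), 1)
  sc <- session_factor(transform(ctl, raw = raw * 1.05), ch, sc, "m1")
  expect_equal(unname(sc$FCm[["m1"]]), 1.05, tolerance = 1e-12)
  # corrected readings invariant under session-wide rescaling (TL0 = 0)
  raw <- c(5000, 7000)
  for (k in c(0.7, 1.3)) {
    sck <- session_factor(transform(ctl, raw = raw * 0 + ctl$raw * k),
                          ch, sc, "mk")
    expect_equal(correct_reading(raw * k, ch, sck, "mk", c("c1", "c2")),
                 correct_reading(raw, ch, sc, "ref", c("c1", "c2")),
                 tolerance = 1e-12)
  }
  expect_error(session_factor(ctl[1:7, ], ch, sc, "m2"), "missing control")
  expect_warning(session_factor(transform(ctl, raw = raw * 0 + ctl$raw * 3),
                                ch, sc, "m3"), "reader fault")
})

test_that("reading correction implements (raw - TL0)/Si / FCm", {
  ids <- c("a", "b")
  ch <- characterize_batch(
    data.frame(dosimeter_id = ids, raw = c(100, 100)),
    data.frame(dosimeter_id = ids, raw = c(1100, 3100)))
  # S = net/mean(net) = (1000, 3000)/2000 = (0.5, 1.5)
  sc <- session_factor(data.frame(dosimeter_id = ids, raw = c(1100, 3100)),
                       ch, NULL, "ref")
  sc$FCm["m"] <- 0.5
  expect_equal(unname(correct_reading(1100, ch, sc, "m", "a")),
               ((1100 - 100) / 0.5) / 0.5)
  # identity configuration
  ch$TL0 <- 0; ch$S[] <- 1; sc$FCm["id"] <- 1
  expect_equal(unname(correct_reading(42.5, ch, sc, "id", "a")), 42.5)
})

test_that("calibration fit is exact on noiseless collinear groups and the
           reference fixture returns its intercept at zero reading", {
  tl <- c(23000, 23000, 48000, 48000, 98000, 98000)
  d <- 0.001 * tl + 2
  cal <- fit_calibration(data.frame(dose_cGy = d, tlcorr = tl))
  expect_equal(cal$A, 0.001, tolerance = 1e-12)
  expect_equal(cal$B, 2, tolerance = 1e-9)
  expect_error(fit_calibration(data.frame(dose_cGy = rep(50, 4),
                                          tlcorr = c(1, 2, 3, 4))),
               "2 distinct dose levels")
  # the published calibration fixture
  cal9 <- calibration_curve(0.0009, 1.4243)
  expect_identical(reading_to_dose(c(0, 0), cal9)$dose_cGy, 1.4243)
  inv <- (100 - 1.4243) / 0.0009
  expect_equal(reading_to_dose(rep(inv, 2), cal9)$dose_cGy, 100,
               tolerance = 1e-9)
  expect_error(calibration_curve(-1, 0), "A must be > 0")
})

test_that("dose uncertainty combines replicate spread, session factor and
           fit covariance in quadrature", {
  cal <- calibration_curve(0.001, 1, residual_sd = 0.1,
                           cov = matrix(c(0.04, 0, 0, 1e-12), 2))
  r <- reading_to_dose(c(9000, 11000), cal, fcm_rel_u = 0.01)
  m <- 10000
  u_rep <- 0.001 * stats::sd(c(9000, 11000)) / sqrt(2)
  u_fit <- sqrt(0.04 + m^2 * 1e-12)
  u_fc <- 0.001 * m * 0.01
  expect_equal(r$dose_cGy, 11)
  expect_equal(r$u_cGy, sqrt(u_rep^2 + u_fit^2 + u_fc^2), tolerance = 1e-12)
  expect_true(reading_to_dose(c(100, 120), cal, ldl_reading = 50)$reliable)
  expect_false(reading_to_dose(c(10, 20), cal, ldl_reading = 50)$reliable)
})

test_that("the full chain recovers synthetic doses and respects the
           uncertainty budget", {
  truth <- tld_truth()
  st <- generate_tld_study(truth, synthetic_study_params(seed = 12))
  res <- process_tld_study(st$readings)
  err <- res$doses$dose_cGy / truth$dose_cGy - 1
  # a single study shares one calibration, so the in-tolerance fraction
  # fluctuates seed to seed; the strict pooled check is in the acceptance
  # suite
  expect_gt(mean(abs(err) < 0.02), 0.7)
  expect_lt(stats::median(abs(err)), 0.015)
  expect_lt(max(res$doses$rel_u), 0.05)
  expect_gt(res$ldl_cGy, 0)
  # calibration prediction at the calibration doses within residual sd
  cal_rows <- st$readings[st$readings$role == "calibration", ]
  for (dl in unique(cal_rows$dose_level_cGy)) {
    raw <- cal_rows$raw[cal_rows$dose_level_cGy == dl]
    tl <- correct_reading(raw, res$char, res$session, "cal",
                          cal_rows$dosimeter_id[cal_rows$dose_level_cGy == dl])
    pred <- res$cal$A * mean(tl) + res$cal$B
    expect_lt(abs(pred - dl), 3 * max(res$cal$residual_sd, 0.3))
  }
})
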