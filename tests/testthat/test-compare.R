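# Normalization, ratio curves and interface metrics.

test_that("normalize_pdd scales to 100 at the maximum bin and is
           idempotent", {
  d <- seq(0.25, 29.75, 0.5)
  flat <- normalize_pdd(data.frame(depth_cm = d, dose = rep(3, length(d))))
  expect_true(all(flat$pdd == 100))
  dose <- exp(-((d - 7.1)^2) / 20)
  p <- normalize_pdd(data.frame(depth_cm = d, dose = dose))
  expect_equal(max(p$pdd), 100)
  expect_equal(p$dmax, d[which.max(dose)])
  expect_true(all(p$pdd[d != p$dmax] < 100))
  expect_equal(normalize_pdd(p)$pdd, p$pdd)
  expect_error(normalize_pdd(data.frame(depth_cm = d, dose = 0 * d)),
               "all-zero")
})

test_that("smoothed normalization picks the planted maximum under 1% noise", {
  d <- seq(0.25, 29.75, 0.5)
  shape <- pmin(1, d / 3) * exp(-0.035 * pmax(0, d - 3))
  true_bin <- d[which.max(shape)]
  set.seed(9)
  hits <- vapply(1:25, function(i) {
    noisy <- shape * (1 + rnorm(length(d), 0, 0.01))
    normalize_pdd(data.frame(depth_cm = d, dose = noisy))$dmax
  }, numeric(1))
  expect_gte(mean(abs(hits - true_bin) <= 0.5), 0.95)
})

test_that("ratio curves divide elementwise with quadrature uncertainties", {
  d <- seq(0.25, 27.75, 0.5)
  a <- normalize_pdd(data.frame(depth_cm = d, dose = exp(-0.03 * d),
                                rel_se = rep(0.01, length(d))))
  expect_true(all(abs(ratio_curve(a, a)$ratio - 1) < 1e-12))
  b <- a; b$pdd <- a$pdd / 1.2
  r <- ratio_curve(a, b)
  expect_true(all(abs(r$ratio - 1.2) < 1e-9))
  expect_equal(r$rel_se, sqrt(a$rel_se^2 + a$rel_se^2), tolerance = 1e-12)
  bad <- a; bad$depth <- a$depth + 0.5
  expect_error(ratio_curve(a, bad), "same depth grid")
  z <- a; z$pdd[3] <- 0
  rz <- ratio_curve(a, z)
  expect_true(is.na(rz$ratio[3]))
  expect_equal(rz$n_excluded, 1L)
})

test_that("interface metrics reproduce a constructed over/under-dosage
           pattern and are invariant to common rescaling", {
  ph <- make_reference_phantom()
  d <- seq(0.25, 27.75, 0.5)
  base <- rep(1, length(d))
  base[d > 5 & d <= 6] <- 1.4    # first lung centimetre
  base[d > 18 & d <= 19] <- 0.82 # first soft-tissue centimetre after lung
  mk <- function(v) structure(list(depth = d, ratio = v,
                                   rel_se = rep(0, length(d)),
                                   n_excluded = 0L), class = "ratio_curve")
  m <- interface_metrics(mk(base), ph, window = 1.0)
  expect_equal(m$lung_overdose_pct, 40, tolerance = 1e-9)
  expect_equal(m$soft_underdose_pct, 18, tolerance = 1e-9)
  expect_equal(m$max_lung_discrepancy_pct, 40, tolerance = 1e-9)
  m0 <- interface_metrics(mk(rep(1, length(d))), ph)
  expect_equal(m0$lung_overdose_pct, 0)
  expect_equal(m0$soft_underdose_pct, 0)
  expect_equal(m0$max_lung_discrepancy_pct, 0)
  # common rescaling of both curves cancels in the ratio by construction:
  # metrics depend on the ratio only
  a <- normalize_pdd(data.frame(depth_cm = d, dose = exp(-0.02 * d)))
  b <- normalize_pdd(data.frame(depth_cm = d, dose = 2 * exp(-0.02 * d)))
  expect_equal(ratio_curve(a, b)$ratio, rep(1, length(d)), tolerance = 1e-12)
  expect_error(interface_metrics(mk(base), phantom_stack("water", 30)),
               "no lung layer")
})
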