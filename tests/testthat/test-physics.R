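# Klein-Nishina cross sections, mean secondary-electron energy and material
# table lookups.

test_that("Klein-Nishina total cross section has the Thomson limit and the
           closed-form value at alpha = 1", {
  sigma_thomson <- 6.652459e-25
  kn <- kn_cross_sections(c(1e-6, 1e-4, 1e-3))
  expect_lt(abs(kn$sigma_total[1] / sigma_thomson - 1), 1e-3)
  expect_lt(abs(kn$sigma_total[3] / sigma_thomson - 1), 1e-2)
  # transfer fraction vanishes at low energy
  expect_lt(kn$sigma_transfer[1] / kn$sigma_total[1], 1e-4)

  # independent evaluation of the closed form at alpha = 1 (E = mc^2)
  a <- 1
  re <- 2.8179403e-13
  closed <- 2 * pi * re^2 * ((1 + a) / a^2 *
    (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
    log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
  kn1 <- kn_cross_sections(0.51099895)
  expect_equal(kn1$sigma_total, closed, tolerance = 1e-12)
})

test_that("Compton energy-transfer fraction lies in (0,1) and increases with
           energy over 0.01-20 MeV", {
  E <- 10^seq(log10(0.01), log10(20), length.out = 25)
  kn <- kn_cross_sections(E)
  f <- kn$sigma_transfer / kn$sigma_total
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) > 0))
})

test_that("transfer cross section matches an independent quadrature and a
           brute-force sample of the Klein-Nishina electron distribution", {
  for (E in c(1.25, 4)) {
    a <- E / 0.51099895
    # independent quadrature via stats::integrate over scattering angle
    dsig <- function(mu) {
      eps <- 1 / (1 + a * (1 - mu))
      pi * (2.8179403e-13)^2 * eps^2 * (eps + 1 / eps - (1 - mu^2))
    }
    st <- stats::integrate(dsig, -1, 1, rel.tol = 1e-10)$value
    str <- stats::integrate(function(mu) dsig(mu) * (1 - 1 / (1 + a * (1 - mu))),
                            -1, 1, rel.tol = 1e-10)$value
    kn <- kn_cross_sections(E)
    expect_equal(kn$sigma_total, st, tolerance = 1e-6)
    expect_equal(kn$sigma_transfer, str, tolerance = 1e-6)
  }
  # brute-force sampling: inverse-CDF draw of scattering angles, mean energy
  # fraction transferred to the electron vs sigma_tr/sigma
  set.seed(42)
  E <- 4; a <- E / 0.51099895
  mu <- seq(-1, 1, length.out = 20001)
  eps <- 1 / (1 + a * (1 - mu))
  w <- eps^2 * (eps + 1 / eps - (1 - mu^2))
  cdf <- cumsum(w) / sum(w)
  draw <- stats::approx(c(0, cdf), c(mu[1], mu), runif(1e6),
                        ties = "ordered")$y
  fbar_mc <- mean(1 - 1 / (1 + a * (1 - draw)))
  se <- stats::sd(1 - 1 / (1 + a * (1 - draw))) / sqrt(1e6)
  kn <- kn_cross_sections(E)
  expect_lt(abs(fbar_mc - kn$sigma_transfer / kn$sigma_total), 3 * se + 1e-4)
})

test_that("mean secondary-electron energy follows its defining formula", {
  # degenerate single-bin spectrum: exact reduction to the monoenergetic case
  hv <- 2.5
  kn <- kn_cross_sections(hv)
  expect_equal(mean_secondary_electron_energy(photon_spectrum(hv, 1)),
               0.5 * hv * kn$sigma_transfer / kn$sigma_total,
               tolerance = 1e-12)
  # two equal-weight bins: evaluated at the mean energy, not bin-averaged
  e1 <- 1; e2 <- 4
  sp <- photon_spectrum(c(e1, e2), c(0.5, 0.5))
  knm <- kn_cross_sections((e1 + e2) / 2)
  expect_equal(mean_secondary_electron_energy(sp),
               0.5 * (e1 + e2) / 2 * knm$sigma_transfer / knm$sigma_total,
               tolerance = 1e-12)
  binwise <- mean(vapply(c(e1, e2), function(e) {
    k <- kn_cross_sections(e); 0.5 * e * k$sigma_transfer / k$sigma_total
  }, numeric(1)))
  expect_false(isTRUE(all.equal(mean_secondary_electron_energy(sp), binwise,
                                tolerance = 1e-3)))
  expect_error(kn_cross_sections(-1), "> 0")
})

test_that("material table lookup is exact at grid points, geometric at
           log-midpoints, monotone in between, and range-checked", {
  w <- get_material("water")
  tab <- w$stopping_power
  i <- 40
  expect_identical(lookup(w, tab$energy_MeV[i], "stopping_power"),
                   tab$value[i])
  emid <- sqrt(tab$energy_MeV[i] * tab$energy_MeV[i + 1])
  expect_equal(lookup(w, emid, "stopping_power"),
               sqrt(tab$value[i] * tab$value[i + 1]), tolerance = 1e-12)
  # monotone between grid points on a monotone segment (low-energy falloff)
  es <- seq(0.011, 0.05, length.out = 50)
  expect_true(all(diff(lookup(w, es, "stopping_power")) < 0))
  expect_error(lookup(w, 25, "stopping_power"), "outside table range")
  expect_error(lookup(w, 0.001, "attenuation"), "outside table range")
})

test_that("packaged materials satisfy their invariants", {
  for (nm in list_materials()) {
    m <- get_material(nm)
    expect_lt(abs(sum(m$composition) - 1), 1e-6)
    expect_gt(m$density, 0)
    for (q in c("stopping_power", "attenuation")) {
      expect_true(all(diff(m[[q]]$energy_MeV) > 0))
      expect_true(all(m[[q]]$value > 0))
    }
  }
  expect_error(material("bad", 1, c(H = 0.5, O = 0.4),
                        get_material("water")$stopping_power,
                        get_material("water")$attenuation),
               "sum to 1")
})
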