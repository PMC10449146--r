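# Material tables, interpolation, Compton kinematics, angular densities.

test_that("attenuation components interpolate log-log with exact knots", {
  al <- default_materials()[["aluminium"]]
  # knot identity, bit for bit
  i <- c(1, 10, 50, length(al$energy))
  mc <- mu_components(al, al$energy[i])
  expect_identical(mc$mu_pe, al$mu_pe[i])
  expect_identical(mc$mu_compton, al$mu_compton[i])
  expect_identical(mc$mu_rayleigh, al$mu_rayleigh[i])
  expect_equal(mc$mu_tot, al$mu_pe[i] + al$mu_compton[i] + al$mu_rayleigh[i])
  # midway between knots: hand log-log interpolation oracle
  E1 <- al$energy[20]; E2 <- al$energy[21]; Em <- sqrt(E1 * E2)
  hand <- 10^((log10(al$mu_pe[20]) *
                 (log10(E2) - log10(Em)) + log10(al$mu_pe[21]) *
                 (log10(Em) - log10(E1))) / (log10(E2) - log10(E1)))
  got <- mu_components(al, Em)$mu_pe
  expect_equal(got, hand, tolerance = 1e-12)
  expect_gt(got, min(al$mu_pe[20:21]))
  expect_lt(got, max(al$mu_pe[20:21]))
  # out-of-range energies are an error, not an extrapolation
  expect_error(mu_components(al, 15), "outside")
  expect_error(mu_components(al, 121), "outside")
})

test_that("vacuum material has zero attenuation everywhere", {
  v <- vacuum_material()
  expect_equal(unlist(mu_components(v, 60)), c(mu_pe = 0, mu_compton = 0,
                                               mu_rayleigh = 0, mu_tot = 0))
})

test_that("mu_tot additivity holds at every grid energy of every material", {
  for (m in default_materials()) {
    mc <- mu_components(m, m$energy)
    expect_identical(mc$mu_tot, mc$mu_pe + mc$mu_compton + mc$mu_rayleigh)
    expect_true(all(mc$mu_pe >= 0 & mc$mu_compton >= 0 & mc$mu_rayleigh >= 0))
  }
})

test_that("Compton kinematics match the closed forms and are monotone", {
  expect_equal(compton_energy(100, 1), 100)
  expect_equal(compton_energy(511, -1), 511 / (1 + (511 / 510.99895) * 2))
  expect_equal(compton_energy(60, 0), 60 / (1 + 60 / 510.99895))
  ct <- seq(1, -1, length.out = 101)
  Ep <- compton_energy(80, ct)
  expect_true(all(diff(Ep) <= 0))      # non-increasing in (1 - cos theta)
  expect_true(all(Ep <= 80 & Ep > 0))
})

test_that("angular densities are normalized over the sphere to 1e-6", {
  mats <- default_materials()
  for (E in c(20, 60, 120)) {
    for (kind in c("compton", "rayleigh")) {
      f <- function(ct) angular_pdf(kind, mats[["aluminium"]], E, ct)
      I <- 2 * pi * integrate(f, -1, 1, rel.tol = 1e-9)$value
      expect_equal(I, 1, tolerance = 1e-6)
    }
  }
})

test_that("Klein-Nishina limits: Thomson symmetry at low E, forward peak at 100 keV", {
  al <- default_materials()[["aluminium"]]
  lo <- angular_pdf("compton", al, 0.01, c(-0.7, 0.7))
  expect_equal(lo[1], lo[2], tolerance = 1e-4)
  th <- angular_pdf("compton", al, 0.01, c(0, 1))
  expect_equal(th[2] / th[1], 2, tolerance = 1e-3)   # (1+cos^2) shape
  hi <- angular_pdf("compton", al, 100, c(0.9, -0.9))
  expect_gt(hi[1], hi[2])
  # against the independent R formula
  ct <- seq(-1, 1, by = 0.25)
  expect_equal(angular_pdf("compton", al, 60, ct), kn_pdf_oracle(60, ct),
               tolerance = 1e-6)
})

test_that("scatter type probabilities follow the component ratios", {
  mats <- default_materials()
  al <- mats[["aluminium"]]
  p <- scatter_type_probs(al, 60)
  mc <- mu_components(al, 60)
  expect_equal(p$p_compton, mc$mu_compton / mc$mu_tot)
  expect_equal(p$p_rayleigh, mc$mu_rayleigh / mc$mu_tot)
  expect_true(p$p_compton + p$p_rayleigh <= 1)
  # no photoelectric -> probabilities sum to one; Compton-only -> (1, 0)
  nope <- xray_material("nope", c(16, 120), c(0, 0), c(0.1, 0.05), c(0.02, 0.01), 10)
  pp <- scatter_type_probs(nope, 60)
  expect_equal(pp$p_compton + pp$p_rayleigh, 1)
  conly <- xray_material("conly", c(16, 120), c(0, 0), c(0.1, 0.05), c(0, 0), 10)
  expect_equal(unlist(scatter_type_probs(conly, 60)),
               c(p_compton = 1, p_rayleigh = 0))
  expect_error(scatter_type_probs(vacuum_material(), 60), "undefined")
})

test_that("spectra normalize, validate and round-trip through CSV", {
  sp <- default_spectrum()
  expect_true(all(sp$energies >= 16 & sp$energies <= 120))
  expect_true(all(diff(sp$energies) > 0))
  expect_equal(sum(normalize_spectrum(sp)$weights), 1, tolerance = 1e-12)
  expect_error(energy_spectrum(c(20, 30), c(-1, 2)))
  expect_error(energy_spectrum(c(30, 20), c(1, 1)))
  path <- tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$energies, sp$energies)
  expect_equal(sp2$weights, sp$weights, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("kev,w", "60,1"), bad)
  expect_error(read_spectrum(bad), "header")
})
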