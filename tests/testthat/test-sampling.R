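# Sobol' streams, Walker alias tables, source-cone sampling, RITA.

test_that("Sobol' streams are reproducible and stratified", {
  s1 <- sample_stream("sobol", 8, seed = 5)
  s2 <- sample_stream("sobol", 8, seed = 5)
  expect_identical(next_point(s1, 16), next_point(s2, 16))
  # consecutive draws continue the sequence
  s3 <- sample_stream("sobol", 8, seed = 5)
  a <- next_point(s3, 10); b <- next_point(s3, 6)
  expect_identical(rbind(a, b), next_point(sample_stream("sobol", 8, seed = 5), 16))
  # base-2 stratification: 1024 points split 32 equal bins exactly evenly
  u <- next_point(sample_stream("sobol", 8, seed = 9), 1024)
  for (j in c(1, 4, 8)) {
    counts <- table(findInterval(u[, j], seq(0, 1, length.out = 33),
                                 rightmost.closed = TRUE))
    expect_true(all(counts == 32))
  }
  # distinct scramble ids decorrelate
  expect_false(identical(next_point(sample_stream("sobol", 8, seed = 1), 4),
                         next_point(sample_stream("sobol", 8, seed = 2), 4)))
  expect_error(sample_stream("sobol", 1000, seed = 1) |> next_point(1), "maximum")
})

test_that("pseudorandom streams have the right mean and leave the RNG alone", {
  set.seed(1234); before <- runif(1)
  set.seed(1234)
  st <- sample_stream("pseudorandom", 4, seed = 77)
  u <- next_point(st, 25000)
  expect_equal(colMeans(u), rep(0.5, 4), tolerance = 0.01)
  expect_equal(runif(1), before)    # global RNG stream undisturbed
  st2 <- sample_stream("pseudorandom", 4, seed = 77)
  expect_identical(next_point(st2, 25000), u)
})

test_that("Walker alias tables reproduce their source distribution exactly", {
  # degenerate and uniform cases
  t1 <- build_alias(1)
  expect_true(all(alias_sample(t1, c(0, 0.3, 0.999)) == 1))
  t2 <- build_alias(c(1, 1))
  expect_equal(alias_sample(t2, 0.25), 1)
  expect_equal(alias_sample(t2, 0.75), 2)
  # exact reconstruction invariant
  w <- c(0.2, 0.3, 0.5)
  tb <- build_alias(w)
  induced <- vapply(seq_along(w), function(b) {
    (tb$cut[b] + sum(1 - tb$cut[tb$alias == b - 1L])) / tb$K
  }, 0)
  expect_equal(induced, w, tolerance = 1e-12)
  # brute-force sweep of the unit interval
  u <- (seq_len(1e6) - 0.5) / 1e6
  freq <- tabulate(alias_sample(tb, u), 3) / 1e6
  expect_equal(freq, w, tolerance = 2e-6)
  expect_error(build_alias(c(0, 0)), "positive")
})

test_that("energy sampling follows the spectrum weights", {
  expect_equal(sample_energy(energy_spectrum(60, 1), 0.42), 60)
  two <- energy_spectrum(c(40, 80), c(1, 1))
  expect_equal(sample_energy(two, 0.49), 40)
  expect_equal(sample_energy(two, 0.51), 80)
  sp <- normalize_spectrum(default_spectrum())
  u <- (seq_len(1e5) - 0.5) / 1e5
  freq <- tabulate(match(sample_energy(sp, u), sp$energies),
                   length(sp$energies)) / 1e5
  expect_lt(max(abs(freq - sp$weights)), 2e-3)
})

test_that("source-cone sampling targets the phantom bounding box", {
  ph <- cached("al_phantom", build_al_phantom())
  src <- c(0, 0, 0)
  d_mid <- sample_direction_source(0.5, 0.5, src, ph)
  expect_equal(d_mid, c(0, 1, 0), tolerance = 1e-12)   # central axis
  # corner variates aim at opposite corners of the bounding rectangle
  d00 <- sample_direction_source(0, 0, src, ph)
  d11 <- sample_direction_source(1, 1, src, ph)
  expect_lt(sum(d00 * d11), 1)
  expect_equal(abs(d00[1]), abs(d11[1]), tolerance = 1e-9)
  set.seed(31)
  hits <- vapply(seq_len(1e4), function(i) {
    d <- sample_direction_source(runif(1), runif(1), src, ph)
    intersect_phantom(ph, src, d)$hit
  }, TRUE)
  expect_true(all(hits))
})

test_that("scatter-type sampling splits at the importance threshold", {
  expect_equal(sample_scatter_type(0.6, 0, 0.99),
               list(kind = "compton", weight_factor = 0.6))
  expect_equal(sample_scatter_type(0.3, 0.3, 0.49)$kind, "compton")
  expect_equal(sample_scatter_type(0.3, 0.3, 0.51)$kind, "rayleigh")
  expect_equal(sample_scatter_type(0.3, 0.3, 0.51)$weight_factor, 0.6)
  expect_error(sample_scatter_type(0, 0, 0.5), "p_T0")
  # the weighted estimator reproduces p_T0 over a stratified sweep
  u <- (seq_len(1e4) - 0.5) / 1e4
  draws <- vapply(u, function(ui) {
    s <- sample_scatter_type(0.45, 0.15, ui)
    s$weight_factor * (s$kind == "compton")
  }, 0)
  expect_equal(mean(draws), 0.45, tolerance = 1e-3)
})

test_that("RITA tables invert continuous densities to tolerance", {
  # uniform density: identity inverse 2u - 1
  tab <- build_rita(function(x) rep(0.5, length(x)), tolerance = 1e-4)
  u <- seq(0, 0.999, length.out = 101)
  expect_equal(sample_cos_theta(tab, u), 2 * u - 1, tolerance = 1e-4)
  # Thomson kernel: quantiles against a dense numeric inverse CDF
  thomson <- function(x) 3 / 16 * (1 + x^2)   # normalized on [-1, 1] x 2pi... shape
  tabT <- build_rita(thomson, tolerance = 1e-4)
  xs <- seq(-1, 1, length.out = 1e5 + 1)
  fs <- thomson(xs)
  cdf <- c(0, cumsum((fs[-1] + fs[-length(fs)]) / 2) * diff(xs)[1])
  cdf <- cdf / cdf[length(cdf)]
  uq <- seq(0.001, 0.999, length.out = 199)
  xref <- approx(cdf, xs, xout = uq, ties = "ordered")$y
  expect_lt(max(abs(sample_cos_theta(tabT, uq) - xref)), 2e-3)
  # CDF-space tolerance: sup |F(xhat) - u| below 2 x tolerance
  Fhat <- approx(xs, cdf, xout = sample_cos_theta(tabT, uq))$y
  expect_lt(max(abs(Fhat - uq)), 2e-4)
  # monotone in u
  smp <- sample_cos_theta(tabT, seq(0, 0.9999, length.out = 500))
  expect_true(all(diff(smp) >= 0))
  # physical kernel from the package physics
  kern <- deflection_kernel("rayleigh", default_materials()[["aluminium"]], 60)
  tabR <- build_rita(kern, tolerance = 1e-4)
  expect_lt(tabR$sup_error, 1e-4)
  expect_error(build_rita(function(x) rep(-1, length(x))), "normalizable")
})
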