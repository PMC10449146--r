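# Voxel traversal, radiological paths, escape probabilities and forced
# interaction sampling.

test_that("bounding-box intersection handles hits, misses and interior starts", {
  ph <- cached("al_phantom", build_al_phantom())
  hit <- intersect_phantom(ph, c(0, 0, 0), c(0, 1, 0))
  expect_true(hit$hit)
  expect_equal(hit$t_exit - hit$t_entry, 28)
  # parallel to a face, outside the box
  expect_false(intersect_phantom(ph, c(0, 0, 200), c(0, 1, 0))$hit)
  # starting inside: entry at t = 0
  inside <- intersect_phantom(ph, c(0, 500, 0), c(0, 1, 0))
  expect_equal(inside$t_entry, 0)
})

test_that("radiological path is exact on homogeneous media and additive", {
  ph <- cached("al_phantom", build_al_phantom())
  al <- ph$materials[["aluminium"]]
  mu <- mu_total(al, 60)
  tau <- radiological_path(ph, c(0, 0, 0), c(0, 1, 0), Inf, 60)
  expect_equal(tau, mu * 28, tolerance = 1e-12)
  expect_equal(radiological_path(ph, c(0, 0, 0), c(0, 1, 0), 0, 60), 0)
  # additivity in path segments
  o <- c(3.3, 0, -7.7); d <- c(0.1, 0.99, -0.05); d <- d / sqrt(sum(d^2))
  t_mid <- 505
  tau_a <- radiological_path(ph, o, d, t_mid, 60)
  tau_b <- radiological_path(ph, o + t_mid * d, d, Inf, 60)
  tau_ab <- radiological_path(ph, o, d, Inf, 60)
  expect_equal(tau_a + tau_b, tau_ab, tolerance = 1e-9)
})

test_that("oblique paths through the BT cylinder match independent oracles", {
  ph <- cached("bt_phantom", build_bt_cylinder())
  set.seed(7)
  for (i in 1:5) {
    o <- c(runif(1, -80, 80), 0, runif(1, -40, 40))
    tgt <- c(runif(1, -15, 15), 500, runif(1, -15, 15))
    d <- tgt - o; d <- d / sqrt(sum(d^2))
    E <- runif(1, 20, 110)
    tau <- radiological_path(ph, o, d, Inf, E)
    # exact analytic-crossing oracle
    expect_equal(tau, tau_crossing_oracle(ph, o, d, E), tolerance = 1e-6)
  }
})

test_that("traversal is watertight: chords sum to the in-box segment length", {
  ph <- cached("bt_phantom", build_bt_cylinder())
  set.seed(11)
  for (i in 1:8) {
    o <- c(runif(1, -50, 50), runif(1, 440, 470), runif(1, -20, 20))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    hit <- intersect_phantom(ph, o, d)
    if (!hit$hit) next
    L <- xscatter:::cpp_chords(ph$ids, xscatter:::phantom_bricks(ph), 4L,
                               dim(ph$ids), ph$voxel_size, ph$origin,
                               length(ph$materials), o, d, hit$t_entry, hit$t_exit)
    expect_equal(sum(L), hit$t_exit - hit$t_entry, tolerance = 1e-9)
  }
})

test_that("escape probability equals exp(-radiological path), 1 in vacuum", {
  ph <- cached("al_phantom", build_al_phantom())
  p <- c(5, 495, -12); d <- c(0.2, 0.9, 0.1); d <- d / sqrt(sum(d^2))
  expect_identical(escape_probability(ph, p, d, 50),
                   exp(-radiological_path(ph, p, d, Inf, 50)))
  expect_equal(escape_probability(vacuum_phantom(), c(0, 100, 0), d, 50), 1)
})

test_that("forced interaction sampling inverts the truncated exponential", {
  ph <- cached("al_phantom", build_al_phantom())
  al <- ph$materials[["aluminium"]]
  mu <- mu_total(al, 60)
  p0 <- c(0, 486.5, 0); d <- c(0, 1, 0)     # 27.5 mm to the boundary
  cc <- 27.5
  for (u in c(0, 0.111, 0.5, 0.93, 0.999999)) {
    s <- sample_forced_interaction(ph, p0, d, 60, u)
    t_ref <- -log(1 - (1 - exp(-mu * cc)) * u) / mu
    expect_equal(s$t, t_ref, tolerance = 1e-8)
  }
  expect_equal(sample_forced_interaction(ph, p0, d, 60, 0)$t, 0)
  # stratified grid reproduces the truncated exponential CDF
  G <- 1024
  u <- (seq_len(G) - 0.5) / G
  tt <- vapply(u, function(ui) sample_forced_interaction(ph, p0, d, 60, ui)$t, 0)
  Fdist <- (1 - exp(-mu * tt)) / (1 - exp(-mu * cc))
  Fhat <- (seq_len(G) - 0.5) / G
  expect_lt(max(abs(sort(Fdist) - Fhat)), 1 / sqrt(G))
  # vacuum segment cannot be forced
  expect_error(sample_forced_interaction(vacuum_phantom(), c(0, 100, 0), d, 60, 0.5),
               "cannot force")
})

test_that("forced sampling in heterogeneous media matches a bisection oracle", {
  ph <- cached("bt_phantom", build_bt_cylinder())
  E <- 45
  p0 <- c(-45, 470, 3)
  d <- c(0.6, 0.8, 0); d <- d / sqrt(sum(d^2))
  tau_tot <- radiological_path(ph, p0, d, Inf, E)
  expect_gt(tau_tot, 0)
  for (u in c(0.2, 0.55, 0.9)) {
    s <- sample_forced_interaction(ph, p0, d, E, u)
    target <- -log(1 - (1 - exp(-tau_tot)) * u)
    # bisection on the monotone cumulative optical depth
    lo <- 0; hi <- intersect_phantom(ph, p0, d)$t_exit
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (radiological_path(ph, p0, d, mid, E) < target) lo <- mid else hi <- mid
    }
    expect_equal(s$t, (lo + hi) / 2, tolerance = 1e-8)
  }
})
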