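# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; expensive runs are memoised per session.

.xs_test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.xs_test_cache[[key]])) .xs_test_cache[[key]] <- force(expr)
  .xs_test_cache[[key]]
}

# small homogeneous cube scene: water cube, 4x4 coarse detector, n = 2
tiny_scene <- function(material = "water", dims = c(8, 8, 8), vox = 2,
                       E = 60, n_order = 2L, det_coarse = c(4, 4),
                       det_pitch = 1.5, dist = 100) {
  mats <- default_materials()
  ids <- array(match(material, names(mats)) - 1L, dim = as.integer(dims))
  ext <- dims * vox
  ph <- voxel_phantom(ids, vox, c(-ext[1] / 2, dist - ext[2] / 2, -ext[3] / 2), mats)
  det <- detector_geometry(distance = dist, pixels = as.integer(det_coarse * 4),
                           pitch_mm = det_pitch, coarse = as.integer(det_coarse))
  make_scene(ph, energy_spectrum(E, 1), n_order = n_order, detector = det)
}

# a phantom made of a single zero-attenuation material
vacuum_phantom <- function(dims = c(8, 8, 8), vox = 2, dist = 100) {
  mats <- material_table(vacuum_material())
  ext <- dims * vox
  voxel_phantom(array(0L, dim = as.integer(dims)), vox,
                c(-ext[1] / 2, dist - ext[2] / 2, -ext[3] / 2), mats)
}

# exact radiological-path oracle: analytic voxel-boundary crossings in R,
# independent of the package's incremental traversal
tau_crossing_oracle <- function(ph, o, d, E, t_max = Inf) {
  hit <- intersect_phantom(ph, o, d)
  if (!hit$hit) return(0)
  t0 <- hit$t_entry; t1 <- min(hit$t_exit, t_max)
  if (t1 <= t0) return(0)
  ts <- c(t0, t1)
  for (a in 1:3) {
    if (abs(d[a]) > 1e-12) {
      planes <- ph$origin[a] + (0:dim(ph$ids)[a]) * ph$voxel_size[a]
      tt <- (planes - o[a]) / d[a]
      ts <- c(ts, tt[tt > t0 & tt < t1])
    }
  }
  ts <- sort(unique(ts))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  P <- t(o + t(outer(mid, d)))
  ii <- floor(sweep(sweep(P, 2, ph$origin), 2, ph$voxel_size, "/"))
  ii <- pmin(pmax(ii, 0), matrix(dim(ph$ids) - 1L, nrow(ii), 3, byrow = TRUE))
  id <- ph$ids[1 + ii[, 1] + dim(ph$ids)[1] * (ii[, 2] + dim(ph$ids)[2] * ii[, 3])]
  mu <- vapply(ph$materials, function(m) mu_total(m, E), 0)
  sum(mu[id + 1] * diff(ts))
}

# independent angular densities (plain R formulas, normalized by quadrature)
kn_pdf_oracle <- function(E, ct) {
  f <- function(c_) {
    k <- E / 510.99895
    ik <- 1 + k * (1 - c_)
    (1 / ik)^2 * (ik + 1 / ik - (1 - c_^2))
  }
  nrm <- 2 * pi * integrate(f, -1, 1, rel.tol = 1e-10)$value
  f(ct) / nrm
}

ray_pdf_oracle <- function(E, ct, Z) {
  f <- function(c_) {
    q <- 0.536367 * E * sqrt(pmax(0, (1 - c_) / 2))
    b <- c(6, 1.2, 0.3) * Z^(1 / 3) / 0.88534
    Fq <- Z * (0.1 * b[1]^2 / (b[1]^2 + q^2) + 0.55 * b[2]^2 / (b[2]^2 + q^2) +
               0.35 * b[3]^2 / (b[3]^2 + q^2))
    (1 + c_^2) * Fq^2
  }
  nrm <- 2 * pi * integrate(f, -1, 1, rel.tol = 1e-10)$value
  f(ct) / nrm
}

# exit distance from a point inside an axis-aligned box (closed form)
box_exit_dist <- function(lo, hi, p, d) {
  tt <- rep(Inf, 3)
  for (a in 1:3) {
    if (d[a] > 1e-12) tt[a] <- (hi[a] - p[a]) / d[a]
    else if (d[a] < -1e-12) tt[a] <- (lo[a] - p[a]) / d[a]
  }
  min(tt)
}

# build a bare scatter_image for metric tests
fake_scatter_image <- function(orders, pixels = dim(orders)[1:2] * 4L) {
  structure(list(orders = orders, sumsq = NULL, N = 1L, sampler = "sobol",
                 seed = 1L, scramble = TRUE, kind = "ffd",
                 n_order = dim(orders)[3], coarse = dim(orders)[1:2],
                 coarse_pitch = 1, pixels = as.integer(pixels), pitch = 0.25),
            class = "scatter_image")
}
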