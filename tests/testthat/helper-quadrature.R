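# Deterministic brute-force quadrature of the order-1 detected-scatter
# probability for a homogeneous monoenergetic scene: integrates over the
# source-cone rectangle and the forced first-interaction depth with
# midpoint rules, using closed-form attenuation and independently
# normalized angular densities.  Serves as the order-1 oracle for the
# estimator-correctness check.
order1_quadrature <- function(sc, n_ab = 48, n_t = 96) {
  ph <- sc$phantom
  stopifnot(length(unique(as.vector(ph$ids))) == 1,
            length(sc$spectrum$energies) == 1)
  E <- sc$spectrum$energies[1]
  mat <- ph$materials[[ph$ids[1, 1, 1] + 1]]
  mu <- mu_total(mat, E)
  pt <- scatter_type_probs(mat, E)
  Z <- mat$z_eff
  # angular normalization constants, computed once by adaptive quadrature
  kn_sh <- function(c_) {
    k <- E / 510.99895; ik <- 1 + k * (1 - c_)
    (1 / ik)^2 * (ik + 1 / ik - (1 - c_^2))
  }
  ray_sh <- function(c_) {
    q <- 0.536367 * E * sqrt(pmax(0, (1 - c_) / 2))
    b <- c(6, 1.2, 0.3) * Z^(1 / 3) / 0.88534
    Fq <- Z * (0.1 * b[1]^2 / (b[1]^2 + q^2) + 0.55 * b[2]^2 / (b[2]^2 + q^2) +
               0.35 * b[3]^2 / (b[3]^2 + q^2))
    (1 + c_^2) * Fq^2
  }
  knn <- 2 * pi * integrate(kn_sh, -1, 1, rel.tol = 1e-10)$value
  rnn <- 2 * pi * integrate(function(t) 4 * t * ray_sh(1 - 2 * t^2), 0, 1,
                            rel.tol = 1e-10)$value
  cone <- xscatter:::cone_geometry(c(0, 0, 0), ph)
  b <- phantom_box(ph)
  det <- sc$detector
  pc <- xscatter:::detector_pixel_centers(sc, det$coarse, det$coarse_pitch)
  npix <- ncol(pc)
  area <- det$coarse_pitch^2
  acc <- numeric(npix)
  uu <- (seq_len(n_ab) - 0.5) / n_ab
  for (ia in seq_len(n_ab)) {
    for (ib in seq_len(n_ab)) {
      a <- cone$rect[1] + uu[ia] * (cone$rect[2] - cone$rect[1])
      bb <- cone$rect[3] + uu[ib] * (cone$rect[4] - cone$rect[3])
      d <- cone$w + a * cone$u + bb * cone$v
      d <- d / sqrt(sum(d^2))
      hit <- intersect_phantom(ph, c(0, 0, 0), d)
      if (!hit$hit) next
      tt <- hit$t_entry + (seq_len(n_t) - 0.5) / n_t * (hit$t_exit - hit$t_entry)
      w_t <- (hit$t_exit - hit$t_entry) / n_t * mu * exp(-mu * (tt - hit$t_entry))
      P <- t(outer(d, tt))                       # n_t x 3 interaction points
      for (j in seq_len(npix)) {
        dv <- -sweep(P, 2, pc[, j])
        r2 <- rowSums(dv^2); r <- sqrt(r2)
        dirn <- dv / r
        cosal <- dirn[, 2]
        ok <- cosal > 0
        ct <- rowSums(dirn * matrix(d, n_t, 3, byrow = TRUE))
        Ec <- compton_energy(E, pmin(pmax(ct, -1), 1))
        dex <- rep(Inf, n_t)
        for (ax in 1:3) {
          da <- dirn[, ax]
          tax <- ifelse(da > 1e-12, (b$hi[ax] - P[, ax]) / da,
                        ifelse(da < -1e-12, (b$lo[ax] - P[, ax]) / da, Inf))
          dex <- pmin(dex, tax)
        }
        contrib <- (pt$p_compton * kn_sh(ct) / knn * exp(-mu_total(mat, Ec) * dex) +
                    pt$p_rayleigh * ray_sh(ct) / rnn * exp(-mu * dex)) *
          cosal * area / r2
        acc[j] <- acc[j] + sum(w_t * contrib * ok)
      }
    }
  }
  matrix(acc / n_ab^2, det$coarse[1], det$coarse[2])
}
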