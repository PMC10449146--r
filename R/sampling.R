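# Samplers: low-discrepancy / pseudorandom drivers, Walker alias tables,
# source-cone direction sampling and RITA polar-angle tables.

# ----------------------------------------------------------------- Sobol'
sobol_directions <- function() {
  if (is.null(.xs_env$sobol)) {
    path <- system.file("extdata", "sobol_joe_kuo_64.txt", package = "xscatter")
    tab <- read.table(path, comment.char = "#")
    .xs_env$sobol <- list(poly = as.integer(tab[[2]]),
                          minit = as.matrix(tab[, 3:20]))
  }
  .xs_env$sobol
}

# raw access to the generator: n points, skipping `skip`, dimension dim
sobol_matrix <- function(n, dim, skip = 0L, scramble_seed = 0) {
  dn <- sobol_directions()
  if (dim > length(dn$poly))
    stop(sprintf("Sobol' dimension %d exceeds the supported maximum %d",
                 dim, length(dn$poly)))
  cpp_sobol(as.integer(n), as.integer(skip), as.integer(dim), dn$poly, dn$minit,
            scramble_seed)
}

#' Create a reproducible sample stream
#'
#' A stream emits points in `[0, 1)^dimension`: either a scrambled Sobol'
#' sequence (linear matrix scramble plus digital shift, keyed by `seed`)
#' or i.i.d. pseudorandom uniforms.  Given (kind, dimension, seed,
#' scramble), the i-th emitted point is reproducible bit for bit; distinct
#' seeds give independent randomizations.  With `scramble = FALSE` the
#' plain Sobol' sequence is used, starting at index 1 (skipping the
#' all-zeros point).
#'
#' @param kind `"sobol"` or `"pseudorandom"`.
#' @param dimension point dimension (4n for an n-order history).
#' @param seed integer seed / scramble id.
#' @param scramble logical; scramble the Sobol' sequence (ignored for
#'   pseudorandom streams).
#' @return an object of class `sample_stream`.
#' @export
sample_stream <- function(kind = c("sobol", "pseudorandom"), dimension, seed = 1L,
                          scramble = TRUE) {
  kind <- match.arg(kind)
  st <- new.env(parent = emptyenv())
  st$kind <- kind
  st$dimension <- as.integer(dimension)
  st$seed <- as.integer(seed)
  st$scramble <- isTRUE(scramble)
  st$counter <- if (kind == "sobol" && !st$scramble) 1L else 0L
  if (kind == "pseudorandom") {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    st$rng_state <- globalenv()$.Random.seed
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
  class(st) <- "sample_stream"
  st
}

#' Draw the next point(s) from a stream
#'
#' Advancing the counter is the only state change.
#'
#' @param stream a [sample_stream()].
#' @param n number of points.
#' @return an `n` x `dimension` matrix with entries in `[0, 1)`.
#' @export
next_point <- function(stream, n = 1L) {
  n <- as.integer(n)
  if (stream$kind == "sobol") {
    u <- sobol_matrix(n, stream$dimension, skip = stream$counter,
                      scramble_seed = if (stream$scramble) stream$seed else 0)
  } else {
    old <- globalenv()$.Random.seed
    assign(".Random.seed", stream$rng_state, envir = globalenv())
    u <- matrix(runif(n * stream$dimension), n, stream$dimension)
    stream$rng_state <- globalenv()$.Random.seed
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  stream$counter <- stream$counter + n
  u
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("<sample_stream> %s, dimension %d, seed %d, at point %d\n",
              x$kind, x$dimension, x$seed, x$counter))
  invisible(x)
}

# ----------------------------------------------------------------- alias
#' Walker alias table for discrete sampling
#'
#' Builds the cut/alias table of Walker's method; sampling consumes a
#' single uniform variate and reproduces the normalized weights exactly.
#'
#' @param weights non-negative weights, at least one positive.
#' @return an object of class `alias_table`.
#' @export
build_alias <- function(weights) {
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be >= 0 with positive sum")
  K <- length(weights)
  p <- weights / sum(weights) * K
  cut <- numeric(K)
  alias <- seq_len(K) - 1L
  small <- which(p < 1)
  large <- which(p >= 1)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    cut[s] <- p[s]
    alias[s] <- l - 1L
    p[l] <- p[l] - (1 - p[s])
    if (p[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  cut[c(small, large)] <- 1
  structure(list(cut = cut, alias = as.integer(alias), K = K,
                 weights = weights / sum(weights)),
            class = "alias_table")
}

#' Sample bin indices from an alias table
#' @param table an [build_alias()] table.
#' @param u uniform variate(s) in `[0, 1)`.
#' @return 1-based bin indices.
#' @export
alias_sample <- function(table, u) {
  s <- u * table$K
  j <- pmin(floor(s), table$K - 1)
  ifelse(s - j < table$cut[j + 1], j, table$alias[j + 1]) + 1L
}

#' Sample a source energy from a spectrum
#'
#' Alias-samples a spectrum bin with a single variate and returns its
#' energy, as in the first step of the history algorithm.
#'
#' @param spectrum an [energy_spectrum()].
#' @param u uniform variate(s).
#' @return energies, keV.
#' @export
sample_energy <- function(spectrum, u) {
  at <- attr(spectrum, "alias")
  if (is.null(at)) at <- build_alias(spectrum$weights)
  spectrum$energies[alias_sample(at, u)]
}

# ----------------------------------------------------------------- source cone
# gnomonic rectangle subtending the phantom bounding box from the source;
# shared by the R-level sampler, the transport engine pack and the oracles
cone_geometry <- function(source, phantom) {
  w <- phantom_center(phantom) - source
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(a[2] * w[3] - a[3] * w[2], a[3] * w[1] - a[1] * w[3], a[1] * w[2] - a[2] * w[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3], w[1] * u[2] - w[2] * u[1])
  b <- phantom_box(phantom)
  corners <- as.matrix(expand.grid(b$lo[1] + c(0, 1) * (b$hi[1] - b$lo[1]),
                                   b$lo[2] + c(0, 1) * (b$hi[2] - b$lo[2]),
                                   b$lo[3] + c(0, 1) * (b$hi[3] - b$lo[3])))
  al <- be <- numeric(8)
  for (i in 1:8) {
    d <- corners[i, ] - source
    dw <- sum(d * w)
    al[i] <- sum(d * u) / dw
    be[i] <- sum(d * v) / dw
  }
  list(w = w, u = u, v = v, rect = c(min(al), max(al), min(be), max(be)))
}

# solid angle of the gnomonic rectangle (standard rectangle formula)
cone_solid_angle <- function(cone) {
  r <- cone$rect
  f <- function(a, b) atan(a * b / sqrt(1 + a^2 + b^2))
  f(r[2], r[4]) - f(r[1], r[4]) - f(r[2], r[3]) + f(r[1], r[3])
}

#' Sample a source direction covering the phantom
#'
#' Maps two uniform variates to a unit direction in the rectangular cone
#' that subtends the phantom's bounding box from the source (uniform over
#' the gnomonic-plane rectangle); every emitted ray intersects the
#' bounding box of a convex phantom seen face-on, and `(0.5, 0.5)` maps to
#' the central source-to-phantom axis.
#'
#' @param u2,u3 uniform variates in `[0, 1)`.
#' @param source source position, mm.
#' @param phantom a `voxel_phantom`.
#' @return unit direction vector.
#' @export
sample_direction_source <- function(u2, u3, source, phantom) {
  cone <- cone_geometry(source, phantom)
  a <- cone$rect[1] + u2 * (cone$rect[2] - cone$rect[1])
  b <- cone$rect[3] + u3 * (cone$rect[4] - cone$rect[3])
  d <- cone$w + a * cone$u + b * cone$v
  d / sqrt(sum(d^2))
}

#' Sample the scatter type by importance sampling
#'
#' Chooses Compton with probability `p_T0 / (p_T0 + p_T1)`, Rayleigh
#' otherwise; the returned weight factor `p_T0 + p_T1` is the probability
#' that the forced interaction is a scatter rather than photoelectric
#' absorption.
#'
#' @param p_T0,p_T1 Compton and Rayleigh interaction probabilities.
#' @param u uniform variate.
#' @return list with `kind` ("compton"/"rayleigh") and `weight_factor`.
#' @export
sample_scatter_type <- function(p_T0, p_T1, u) {
  s <- p_T0 + p_T1
  if (s <= 0) stop("no scatter interaction possible: p_T0 + p_T1 = 0")
  list(kind = if (u * s < p_T0) "compton" else "rayleigh", weight_factor = s)
}

# ----------------------------------------------------------------- RITA
#' Deflection kernel of a scatter interaction
#'
#' Packages the normalized polar-angle density of a Compton or Rayleigh
#' event at one energy, as consumed by [build_rita()].
#'
#' @param kind `"compton"` or `"rayleigh"`.
#' @param material an `xray_material`.
#' @param E photon energy, keV.
#' @return an object of class `deflection_kernel` with a `pdf(cos_theta)`
#'   density over cos(theta) (integrating to 1 on `[-1, 1]`).
#' @export
deflection_kernel <- function(kind = c("compton", "rayleigh"), material, E) {
  kind <- match.arg(kind)
  k <- if (kind == "compton") 0L else 1L
  z <- material$z_eff
  tq <- seq(0, 1, length.out = 4097)
  w <- c(1, rep(c(4, 2), length.out = 4095), 1) * (tq[2] - tq[1]) / 3
  nrm <- sum(w * 4 * tq * cpp_dcs(k, E, z, 1 - 2 * tq^2))
  structure(list(kind = kind, energy = E, z_eff = z,
                 pdf = function(x) cpp_dcs(k, E, z, x) / nrm),
            class = "deflection_kernel")
}

#' Build a RITA sampling table
#'
#' Rational inverse transform with aliasing: tabulates the inverse CDF of
#' a continuous density on `[-1, 1]` with per-interval rational
#' interpolation whose derivative matches `1/pdf` at both interval ends,
#' refining the grid adaptively until the sup-norm deviation of the
#' induced CDF from the target CDF is below `tolerance`.
#'
#' @param kernel a [deflection_kernel()] or a plain density function of
#'   cos(theta) (need not be normalized).
#' @param tolerance sup-norm CDF tolerance (default 1e-4).
#' @param max_points grid-size cap for the refinement.
#' @param dense_x optional dense reference grid on `[-1, 1]` used to
#'   tabulate the target CDF; supply a grid concentrated where the density
#'   peaks (e.g. toward `cos = 1` for coherent scatter) when the default
#'   uniform grid under-resolves it.
#' @return an object of class `rita_table`.
#' @export
build_rita <- function(kernel, tolerance = 1e-4, max_points = 512L,
                       dense_x = NULL) {
  pdf <- if (inherits(kernel, "deflection_kernel")) kernel$pdf else kernel
  xs <- if (is.null(dense_x)) seq(-1, 1, length.out = 8193) else sort(dense_x)
  fs <- pdf(xs)
  if (any(!is.finite(fs)) || any(fs < 0) || sum(fs) <= 0)
    stop("kernel density is not normalizable on [-1, 1]")
  cdf <- cumsum((fs[-1] + fs[-length(fs)]) / 2 * diff(xs))
  fs <- fs / cdf[length(cdf)]                            # normalized density
  cdf <- c(0, cdf / cdf[length(cdf)])
  cdf_at <- function(x) approx(xs, cdf, xout = x, rule = 2)$y
  pdf_at <- function(x) approx(xs, fs, xout = x, rule = 2)$y
  grid <- seq(-1, 1, length.out = 33)
  uf <- seq(0.1, 0.9, by = 0.2)
  repeat {
    xi <- cdf_at(grid)
    p <- pdf_at(grid)
    nseg <- length(grid) - 1
    h <- diff(grid); dxi <- diff(xi)
    b <- 1 - (dxi / h)^2 / pmax(p[-length(p)] * p[-1], 1e-300)
    a <- dxi / (h * pmax(p[-length(p)], 1e-300)) - 1 - b
    # induced-CDF error at interior probe points, all segments at once
    nu <- outer(uf, dxi)                                 # probes x segments
    dxim <- rep(dxi, each = length(uf))
    tt <- rep(1 + a + b, each = length(uf)) * dxim * nu /
      (dxim^2 + rep(a, each = length(uf)) * dxim * nu +
         rep(b, each = length(uf)) * nu^2)
    tt[!is.finite(tt)] <- 0
    xhat <- rep(grid[-length(grid)], each = length(uf)) +
      pmin(pmax(tt, 0), 1) * rep(h, each = length(uf))
    e <- abs(cdf_at(xhat) - (rep(xi[-length(xi)], each = length(uf)) + nu))
    err <- apply(matrix(e, nrow = length(uf)), 2, max)
    err[dxi <= 0] <- 0
    if (max(err) < tolerance || length(grid) >= max_points) break
    worst <- order(err, decreasing = TRUE)[seq_len(min(8, sum(err >= tolerance)))]
    grid <- sort(c(grid, (grid[worst] + grid[worst + 1]) / 2))
  }
  structure(list(x = grid, xi = xi, a = a, b = b, tolerance = tolerance,
                 sup_error = max(err)),
            class = "rita_table")
}

#' Sample cos(theta) from a RITA table
#' @param table a [build_rita()] table.
#' @param u uniform variate(s) in `[0, 1)`.
#' @return sampled cos(theta) values (monotone in `u`).
#' @export
sample_cos_theta <- function(table, u) {
  cpp_rita_sample(table$x, table$xi, table$a, table$b, u)
}
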