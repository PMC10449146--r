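# Transport drivers: forced-fixed-detection estimator, single-history
# simulation, analog Monte Carlo oracle, primary projector, upsampling.

new_scatter_image <- function(orders, scene, N, sampler, seed, scramble,
                              sumsq = NULL, kind = "ffd") {
  det <- scene$detector
  structure(list(orders = orders, sumsq = sumsq, N = N, sampler = sampler,
                 seed = seed, scramble = scramble, kind = kind,
                 n_order = scene$n_order, coarse = det$coarse,
                 coarse_pitch = det$coarse_pitch, pixels = det$pixels,
                 pitch = det$pitch),
            class = "scatter_image")
}

#' @export
print.scatter_image <- function(x, ...) {
  cat(sprintf("<scatter_image> %s, %d orders on %dx%d grid, N = %d (%s)\n",
              x$kind, dim(x$orders)[3], dim(x$orders)[1], dim(x$orders)[2],
              x$N, x$sampler))
  cat(sprintf("  total detected scatter probability: %.6g\n", sum(x$orders)))
  invisible(x)
}

#' Estimate per-order scatter images by forced fixed detection
#'
#' Runs `N` photon histories, each driven by one 4n-dimensional point of
#' the stream: the first four coordinates sample the source energy, the
#' source-cone direction and the first forced interaction depth; each
#' further block of four samples the scatter type, the polar and azimuthal
#' scatter angles and the next forced depth.  At every interaction the
#' analytic probability of scattering toward each (coarse) detector pixel
#' and escaping the phantom is accumulated.  The result is the mean
#' per-history contribution image per scatter order; it is bit-identical
#' for identical configuration and seed.
#'
#' @param scene an [make_scene()] scene.
#' @param N number of histories.
#' @param sampler `"sobol"` (quasi-Monte Carlo) or `"pseudorandom"`.
#' @param seed seed / scramble id.
#' @param scramble scramble the Sobol' stream (default `TRUE`).
#' @param moments accumulate second moments so that [std_error()] works.
#' @param stream optionally, an existing [sample_stream()] to consume.
#' @return a `scatter_image`: per-order stack `orders[nu, nv, n]` of mean
#'   probability contributions per source photon.
#' @export
estimate_scatter <- function(scene, N, sampler = c("sobol", "pseudorandom"),
                             seed = 1L, scramble = TRUE, moments = FALSE,
                             stream = NULL) {
  sampler <- match.arg(sampler)
  stopifnot(N >= 1)
  if (is.null(stream))
    stream <- sample_stream(sampler, 4L * scene$n_order, seed = seed,
                            scramble = scramble)
  U <- next_point(stream, N)
  pk <- scene_pack(scene)
  res <- cpp_transport(pk, U, moments, FALSE)
  nuv <- scene$detector$coarse
  orders <- array(res$acc / N, dim = c(nuv[1], nuv[2], scene$n_order))
  sumsq <- if (moments) array(res$sumsq, dim = dim(orders)) else NULL
  new_scatter_image(orders, scene, N, stream$kind, seed, scramble, sumsq)
}

#' Standard error of the per-pixel, per-order mean of a scatter image
#'
#' Requires `moments = TRUE` at estimation time.  For pseudorandom
#' sampling this is the usual i.i.d. standard error of the mean; for
#' scrambled Sobol' points it is only an indicative scale (replicate
#' scrambles give the proper QMC error estimate).
#'
#' @param image a `scatter_image`.
#' @return array like `image$orders`.
#' @export
std_error <- function(image) {
  if (is.null(image$sumsq)) stop("image was estimated without moments = TRUE")
  N <- image$N
  v <- pmax(0, (image$sumsq - N * image$orders^2) / (N - 1))
  sqrt(v / N)
}

#' Simulate a single forced-fixed-detection history
#'
#' @param point a vector in `[0,1)^(4n)`.
#' @param scene the scene.
#' @return list with `contributions` (array `[nu, nv, n]` of
#'   weight-multiplied splat contributions, equal to [estimate_scatter()]
#'   with `N = 1`) and `trace` (a data.frame with one row per attempted
#'   order: weight, energy, escape probability, survival factor, sampled
#'   deflection and interaction position).
#' @export
simulate_history <- function(point, scene) {
  stopifnot(length(point) == 4L * scene$n_order)
  pk <- scene_pack(scene)
  res <- cpp_transport(pk, matrix(point, nrow = 1), FALSE, TRUE)
  nuv <- scene$detector$coarse
  list(contributions = array(res$acc, dim = c(nuv[1], nuv[2], scene$n_order)),
       trace = res$trace)
}

#' Forced-fixed-detection splat of one photon state
#'
#' For a photon about to interact at `position` with incoming direction
#' `direction` and energy `energy`, returns the per-pixel probability
#' `P(A_i -> D_j)` of scattering toward pixel j and escaping the phantom
#' unattenuated: the sum over Compton/Rayleigh of (type probability) x
#' (polar-angle density toward the pixel) x (escape factor at the
#' post-scatter energy) x (pixel solid angle `cos(alpha) h^2 / r^2`).
#' The caller multiplies by the photon weight when accumulating.
#'
#' @param state list with `position`, `direction`, `energy`.
#' @param scene the scene.
#' @param kernel `"physical"` or `"isotropic"` (a 1/4pi stub without the
#'   type split, useful for geometry tests).
#' @return matrix `[nu, nv]` of per-pixel probabilities.
#' @export
ffd_splat <- function(state, scene, kernel = c("physical", "isotropic")) {
  kernel <- match.arg(kernel)
  pk <- scene_pack(scene)
  pk$kernel_mode <- if (kernel == "physical") 0L else 1L
  out <- cpp_ffd_splat(pk, state$position, state$direction, state$energy)
  matrix(out, scene$detector$coarse[1], scene$detector$coarse[2])
}

#' Analog Monte Carlo scatter estimate (validation oracle)
#'
#' Unbiased analog transport with the same source, physics tables and
#' geometry: free paths are drawn from the untruncated exponential law,
#' photons are absorbed at photoelectric events, scatter angles are drawn
#' by rejection from the exact angular distributions, and an escaping
#' photon scores a binary hit in the detector pixel its straight exit ray
#' crosses, binned by scatter order.  The per-pixel, per-order hit rate
#' estimates the same expectation as [estimate_scatter()].
#'
#' @param scene the scene.
#' @param N number of analog histories.
#' @param seed RNG seed.
#' @return a `scatter_image` whose `orders` hold hit rates; `counts`
#'   carries the raw integer hits.
#' @export
analog_scatter <- function(scene, N, seed = 1L) {
  pk <- scene_pack(scene)
  res <- cpp_analog(pk, as.integer(N), as.numeric(seed))
  nuv <- scene$detector$coarse
  img <- new_scatter_image(array(res$counts / N, dim = c(nuv[1], nuv[2], scene$n_order)),
                           scene, N, "analog", seed, FALSE, kind = "analog")
  img$counts <- array(res$counts, dim = dim(img$orders))
  img$absorbed <- res$absorbed
  img$primary_escapes <- res$primary_escapes
  img
}

#' Deterministic primary (unscattered) projection
#'
#' Beer-Lambert quadrature per detector pixel: for the ray from the
#' source through each pixel centre, sums spectrum-weighted transmission
#' `sum_E phi(E) exp(-tau(E))`.  No sampling and no geometric falloff
#' term (the image is transmission per pixel, flat at 1 for an empty
#' phantom).
#'
#' @param scene the scene.
#' @param resolution `"fine"` (full detector resolution) or `"coarse"`.
#' @return matrix of per-pixel primary transmission.
#' @export
primary_projection <- function(scene, resolution = c("fine", "coarse")) {
  resolution <- match.arg(resolution)
  det <- scene$detector
  nuv <- if (resolution == "fine") det$pixels else det$coarse
  pitch <- if (resolution == "fine") det$pitch else det$coarse_pitch
  pixc <- detector_pixel_centers(scene, nuv, pitch)
  sp <- scene$spectrum
  pk <- scene_pack(scene)
  mats <- scene$phantom$materials[pk$active]   # the pack's compacted id set
  mu_bins <- do.call(rbind, lapply(sp$energies, function(E) mu_vector(mats, E)))
  out <- cpp_primary(pk, as.vector(pixc), sp$weights, mu_bins)
  matrix(out, nuv[1], nuv[2])
}

#' Bilinearly upsample a coarse detector image
#'
#' Interpolates pixel-centre values from the coarse grid to the fine
#' grid (linear extrapolation in the boundary half-pixels, so affine
#' images are reproduced exactly and a constant image stays constant).
#' Values keep their per-coarse-pixel scale; the integrated intensity
#' (value times pixel area) is preserved for smooth images.
#'
#' @param x a matrix, a 3-D array (last dimension = order), or a
#'   `scatter_image`.
#' @param fine target dimensions (must be multiples of the coarse ones);
#'   defaults to the full detector resolution of a `scatter_image`.
#' @return object of the same kind on the fine grid.
#' @export
upsample_detector <- function(x, fine = NULL) {
  if (inherits(x, "scatter_image")) {
    if (is.null(fine)) fine <- x$pixels
    out <- x
    out$orders <- upsample_detector(x$orders, fine)
    out$sumsq <- NULL
    out$coarse <- as.integer(fine)
    out$coarse_pitch <- x$coarse_pitch * dim(x$orders)[1] / fine[1]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3) {
    out <- array(0, c(fine[1], fine[2], d[3]))
    for (k in seq_len(d[3])) out[, , k] <- upsample_detector(x[, , k], fine)
    return(out)
  }
  if (any(fine %% d[1:2] != 0)) stop("fine dimensions must be multiples of the coarse ones")
  up1 <- function(n_c, n_f) {
    g <- ((seq_len(n_f) - 0.5) * n_c / n_f) - 0.5
    i0 <- pmin(pmax(floor(g), 0), n_c - 2)
    list(i = i0 + 1L, w = g - i0)      # weight may fall outside [0,1]: extrapolation
  }
  a <- up1(d[1], fine[1]); b <- up1(d[2], fine[2])
  x00 <- x[a$i, b$i, drop = FALSE];     x10 <- x[a$i + 1L, b$i, drop = FALSE]
  x01 <- x[a$i, b$i + 1L, drop = FALSE]; x11 <- x[a$i + 1L, b$i + 1L, drop = FALSE]
  wa <- matrix(a$w, fine[1], fine[2]); wb <- matrix(b$w, fine[1], fine[2], byrow = TRUE)
  (1 - wa) * (1 - wb) * x00 + wa * (1 - wb) * x10 + (1 - wa) * wb * x01 + wa * wb * x11
}

#' Plot a scatter image
#'
#' @param x a `scatter_image`.
#' @param order which order slice to show; `NULL` (default) shows the sum
#'   over orders.
#' @param ... passed to [graphics::image()].
#' @export
plot.scatter_image <- function(x, order = NULL, ...) {
  img <- if (is.null(order)) apply(x$orders, c(1, 2), sum) else x$orders[, , order]
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                  xlab = "detector u", ylab = "detector v",
                  main = if (is.null(order)) "total scatter" else
                    sprintf("order-%d scatter", order), ...)
  invisible(x)
}
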