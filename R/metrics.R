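# Evaluation metrics: relative difference, figure of merit, efficiency
# improvement factor, scatter-order tables and replicate standard
# deviations.

#' Relative difference between two images
#'
#' `||r - t||_2 / ||r||_2` over all pixels.
#'
#' @param r reference image (matrix or array).
#' @param t test image of the same shape.
#' @return non-negative scalar.
#' @export
relative_difference <- function(r, t) {
  if (!identical(dim(r), dim(t))) stop("images must have identical shape")
  nr <- sqrt(sum(r^2))
  if (nr <= 0) stop("zero reference image")
  sqrt(sum((r - t)^2)) / nr
}

#' Figure of merit
#'
#' `FOM = 1 / (T sigma^2)` with `T` the runtime in minutes.
#'
#' @param T_minutes runtime, minutes (> 0).
#' @param sigma replicate standard deviation (> 0).
#' @export
figure_of_merit <- function(T_minutes, sigma) {
  if (any(T_minutes <= 0) || any(sigma <= 0)) stop("T and sigma must be positive")
  1 / (T_minutes * sigma^2)
}

#' Efficiency improvement factor
#'
#' Ratio of figures of merit of a method and a reference method.
#'
#' @param fom_a figure of merit of the method under study (> 0).
#' @param fom_ref figure of merit of the reference (> 0).
#' @export
efficiency_improvement <- function(fom_a, fom_ref) {
  if (any(fom_a <= 0) || any(fom_ref <= 0)) stop("figures of merit must be positive")
  fom_a / fom_ref
}

#' Per-order scatter table at a detector pixel
#'
#' Reports, for each scatter order, the estimated probability
#' contribution at one full-resolution detector pixel, its fraction of
#' the summed total and the running cumulative sum.  A coarse-grid image
#' is bilinearly upsampled to the full detector resolution first.
#'
#' @param image a `scatter_image`.
#' @param pixel full-resolution pixel index `c(iu, iv)` (1-based); the
#'   default is the central pixel of a 512 x 512 detector.
#' @return a data.frame with columns `order`, `value`, `fraction`,
#'   `cumulative`.
#' @export
order_table <- function(image, pixel = c(256, 256)) {
  stopifnot(inherits(image, "scatter_image"))
  fine <- image$pixels
  if (any(pixel < 1) || any(pixel > fine)) stop("pixel index out of range")
  ups <- if (all(dim(image$orders)[1:2] == fine)) image$orders else
    upsample_detector(image$orders, fine)
  v <- ups[pixel[1], pixel[2], ]
  tot <- sum(v)
  data.frame(order = seq_along(v), value = v,
             fraction = if (tot > 0) v / tot else rep(0, length(v)),
             cumulative = cumsum(v))
}

#' Replicate standard deviation of the total detected scatter probability
#'
#' Runs `replicates` independent estimates (distinct seeds / scramble
#' ids), summarizes each by the scalar total detected scatter probability
#' over the detector, and returns the sample standard deviation across
#' replicates.  This is the sigma entering the figure of merit.
#'
#' @param scene the scene.
#' @param N histories per replicate.
#' @param replicates number of replicates (>= 2).
#' @param sampler `"sobol"` or `"pseudorandom"`.
#' @param seed base seed; replicate r uses `seed + 7919 * r`.
#' @param scramble scramble Sobol' streams (must be `TRUE` for a
#'   meaningful QMC sigma).
#' @return list with `sigma`, `mean` and the replicate `values`.
#' @export
replicate_sigma <- function(scene, N, replicates = 20L,
                            sampler = c("sobol", "pseudorandom"), seed = 1L,
                            scramble = TRUE) {
  sampler <- match.arg(sampler)
  stopifnot(replicates >= 2)
  vals <- vapply(seq_len(replicates), function(r) {
    img <- estimate_scatter(scene, N, sampler, seed = seed + 7919L * r,
                            scramble = scramble)
    sum(img$orders)
  }, 0.0)
  list(sigma = sd(vals), mean = mean(vals), values = vals)
}

#' Comparison report between two scatter images
#'
#' @param ref,test `scatter_image`s of identical shape.
#' @param labels character length-2 labels.
#' @return list with the relative difference of the total images and
#'   per-order relative differences.
#' @export
comparison_report <- function(ref, test, labels = c("reference", "test")) {
  rd <- relative_difference(apply(ref$orders, c(1, 2), sum),
                            apply(test$orders, c(1, 2), sum))
  per_order <- vapply(seq_len(dim(ref$orders)[3]), function(i) {
    r <- ref$orders[, , i]
    if (sum(r^2) > 0) relative_difference(r, test$orders[, , i]) else NA_real_
  }, 0.0)
  list(reference = labels[1], test = labels[2], rd = rd, rd_per_order = per_order)
}
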