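# Ray-phantom geometry: bounding-box intersection, radiological path
# integrals, escape probabilities and forced interaction-point sampling.
# All path integrals are exact sums of mu * chord over traversed voxels
# (incremental Siddon/Amanatides-Woo stepping with half-open voxels);
# attenuation outside the phantom box is zero.

# per-material total attenuation at one energy, exact log-log interpolation
mu_vector <- function(materials, E) {
  vapply(materials, function(m) mu_total(m, E), 0.0)
}

#' Intersect a ray with the phantom bounding box
#'
#' Slab-method AABB intersection clamped to `t >= 0`; a miss is a value,
#' not an error.
#'
#' @param phantom a `voxel_phantom`.
#' @param origin ray origin, mm.
#' @param direction unit direction.
#' @return list with `hit` (logical) and, when hit, `t_entry`, `t_exit`
#'   (mm along the ray).
#' @export
intersect_phantom <- function(phantom, origin, direction) {
  stopifnot(abs(sum(direction^2) - 1) < 1e-9)
  b <- phantom_box(phantom)
  r <- cpp_box_intersect(b$lo, b$hi, origin, direction)
  if (r[1] < 0.5) list(hit = FALSE) else list(hit = TRUE, t_entry = r[2], t_exit = r[3])
}

#' Radiological path (optical depth) along a ray segment
#'
#' The line integral of `mu_tot` from the ray origin to parameter `t_max`,
#' computed by exact incremental voxel traversal.
#'
#' @inheritParams intersect_phantom
#' @param t_max end of the integration segment, mm (may be `Inf`).
#' @param E photon energy, keV.
#' @param materials material table (defaults to the phantom's).
#' @return optical depth, unitless.
#' @export
radiological_path <- function(phantom, origin, direction, t_max, E,
                              materials = phantom$materials) {
  hit <- intersect_phantom(phantom, origin, direction)
  if (!hit$hit) return(0)
  t1 <- min(t_max, hit$t_exit)
  if (t1 <= hit$t_entry) return(0)
  L <- cpp_chords(phantom$ids, phantom_bricks(phantom), 4L, dim(phantom$ids),
                  phantom$voxel_size, phantom$origin, length(materials),
                  origin, direction, hit$t_entry, t1)
  sum(L * mu_vector(materials, E))
}

#' Probability of escaping the phantom along a direction
#'
#' `exp(-tau)` with `tau` the optical depth from `position` to the phantom
#' boundary; equals 1 in vacuum.
#'
#' @inheritParams radiological_path
#' @param position start point, mm (inside the phantom box).
#' @export
escape_probability <- function(phantom, position, direction, E,
                               materials = phantom$materials) {
  exp(-radiological_path(phantom, position, direction, Inf, E, materials))
}

#' Sample a forced interaction point along a ray
#'
#' Inverts the cumulative optical depth of the in-phantom segment:
#' the returned `t` satisfies `tau(0, t) = -log(1 - (1 - exp(-tau_total)) u)`,
#' i.e. the free path is drawn from the exponential law truncated to the
#' segment.  The inversion is analytic within the voxel where the target
#' depth falls (no iterative solver).
#'
#' @inheritParams escape_probability
#' @param u uniform variate in `[0, 1)`.
#' @return list with `t` (mm), `position`, and `tau_total` of the segment.
#' @export
sample_forced_interaction <- function(phantom, position, direction, E, u,
                                      materials = phantom$materials) {
  stopifnot(u >= 0, u < 1)
  hit <- intersect_phantom(phantom, position, direction)
  if (!hit$hit) stop("ray does not intersect the phantom: cannot force an interaction")
  mu <- mu_vector(materials, E)
  tau_total <- radiological_path(phantom, position, direction, Inf, E, materials)
  if (tau_total <= 0)
    stop("zero optical depth along the segment: cannot force an interaction")
  target <- -log1p(-(1 - exp(-tau_total)) * u)
  t <- cpp_invert_tau(phantom$ids, phantom_bricks(phantom), 4L, dim(phantom$ids),
                      phantom$voxel_size, phantom$origin, mu, position, direction,
                      hit$t_entry, hit$t_exit, target)
  if (t < 0) t <- hit$t_exit  # numerical guard at u -> 1
  list(t = t, position = position + t * direction, tau_total = tau_total)
}
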