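# Scene assembly: source, phantom, spectrum, detector and the packed,
# cached numerical tables consumed by the transport engine.

#' Detector geometry
#'
#' A flat ideal detector perpendicular to the beam axis.  The full
#' resolution is `pixels` at `pitch_mm`; during transport the
#' forced-detection splat targets the `coarse` grid (same physical
#' extent, proportionally larger pixels), as in the sparse-matrix method;
#' coarse images can be bilinearly upsampled with [upsample_detector()].
#'
#' @param distance phantom-centre to detector distance, mm.
#' @param pixels full-resolution pixel counts, length 2.
#' @param pitch_mm full-resolution pixel pitch, mm.
#' @param coarse transport-time splat grid, must divide `pixels`.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(distance = 500, pixels = c(512, 512), pitch_mm = 0.8,
                              coarse = c(64, 64)) {
  if (any(pixels %% coarse != 0))
    stop("coarse grid dimensions must divide the full pixel dimensions")
  structure(list(distance = distance, pixels = as.integer(pixels),
                 pitch = pitch_mm, coarse = as.integer(coarse),
                 coarse_pitch = pitch_mm * pixels[1] / coarse[1]),
            class = "detector_geometry")
}

#' Assemble a simulation scene
#'
#' @param phantom a `voxel_phantom`.
#' @param spectrum an `energy_spectrum` (default bundled 120 kVp model).
#' @param n_order maximum scatter order n; each history consumes a
#'   4n-dimensional point.
#' @param source source position, mm (default the world origin, 500 mm
#'   from the phantom centre of the bundled phantoms).
#' @param detector a [detector_geometry()].
#' @param w0 initial photon weight `W_0 = I_0(u_2, u_3)`; the default 1
#'   reports probabilities per photon emitted into the source cone.  Use
#'   `cone_solid_angle / 4 pi` semantics via `w0 = "isotropic"` for an
#'   isotropic-source normalization.
#' @param kill_floor if `TRUE`, photons whose Compton energy falls below
#'   the attenuation-table floor are terminated instead of clamped.
#' @param rita_tolerance sup-norm CDF tolerance of the polar-angle tables.
#' @param rita_energies number of table energies on a log grid.
#' @return an object of class `xscatter_scene`.
#' @export
make_scene <- function(phantom, spectrum = default_spectrum(), n_order = 10L,
                       source = c(0, 0, 0), detector = detector_geometry(),
                       w0 = 1, kill_floor = FALSE, rita_tolerance = 1e-4,
                       rita_energies = 64L) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(spectrum, "energy_spectrum"),
            inherits(detector, "detector_geometry"), n_order >= 1)
  cone <- cone_geometry(source, phantom)
  if (identical(w0, "isotropic")) w0 <- cone_solid_angle(cone) / (4 * pi)
  sc <- structure(list(phantom = phantom, spectrum = normalize_spectrum(spectrum),
                       n_order = as.integer(n_order), source = as.numeric(source),
                       detector = detector, cone = cone, w0 = w0,
                       kill_floor = isTRUE(kill_floor),
                       rita_tolerance = rita_tolerance,
                       rita_energies = as.integer(rita_energies),
                       cache = new.env(parent = emptyenv())),
                  class = "xscatter_scene")
  sc
}

#' @export
print.xscatter_scene <- function(x, ...) {
  cat(sprintf("<xscatter_scene> n_order %d, %d spectrum lines, detector %dx%d (%dx%d coarse)\n",
              x$n_order, length(x$spectrum$energies), x$detector$pixels[1],
              x$detector$pixels[2], x$detector$coarse[1], x$detector$coarse[2]))
  print(x$phantom)
  invisible(x)
}

# basis and pixel centres of the detector plane
detector_frame <- function(scene) {
  cen <- phantom_center(scene$phantom) + scene$detector$distance * scene$cone$w
  list(center = cen, normal = scene$cone$w, uaxis = scene$cone$u, vaxis = scene$cone$v)
}

detector_pixel_centers <- function(scene, n_uv, pitch) {
  fr <- detector_frame(scene)
  iu <- (seq_len(n_uv[1]) - 0.5) - n_uv[1] / 2
  iv <- (seq_len(n_uv[2]) - 0.5) - n_uv[2] / 2
  offu <- outer(iu * pitch, rep(1, n_uv[2]))
  offv <- outer(rep(1, n_uv[1]), iv * pitch)
  px <- fr$center[1] + offu * fr$uaxis[1] + offv * fr$vaxis[1]
  py <- fr$center[2] + offu * fr$uaxis[2] + offv * fr$vaxis[2]
  pz <- fr$center[3] + offu * fr$uaxis[3] + offv * fr$vaxis[3]
  rbind(as.vector(px), as.vector(py), as.vector(pz))
}

# mirror of the C++ angular-distribution formulas, used to precompute
# normalization tables on the transport energy grid
kn_unnorm_r <- function(E, ct) {
  k <- E / 510.99895
  ik <- 1 + outer(1 - ct, k)
  r <- 1 / ik
  r^2 * (ik + r - (1 - ct^2))
}

ray_unnorm_r <- function(E, ct, Z) {
  q <- 0.536367 * outer(sqrt(pmax(0, (1 - ct) / 2)), E)
  z3 <- Z^(1 / 3) / 0.88534
  b1 <- 6 * z3; b2 <- 1.2 * z3; b3 <- 0.3 * z3
  Fq <- Z * (0.10 * b1^2 / (b1^2 + q^2) + 0.55 * b2^2 / (b2^2 + q^2) +
             0.35 * b3^2 / (b3^2 + q^2))
  (1 + ct^2) * Fq^2
}

# cached RITA table for (kind, z_eff, energy)
rita_table_cached <- function(kind, z_eff, E, tol) {
  key <- sprintf("rita|%s|%.4f|%.6g|%g", kind, z_eff, E, tol)
  if (is.null(.xs_env[[key]])) {
    kidx <- if (kind == "compton") 0L else 1L
    # dense grid concentrated toward cos = 1 for the coherent forward lobe
    xs <- sort(unique(c(1 - 2 * seq(0, 1, length.out = 6145)^2,
                        seq(-1, 1, length.out = 2049))))
    fs <- cpp_dcs(kidx, E, z_eff, xs)
    nrm <- sum((fs[-1] + fs[-length(fs)]) / 2 * diff(xs))
    .xs_env[[key]] <- build_rita(function(x) cpp_dcs(kidx, E, z_eff, x) / nrm,
                                 tol, dense_x = xs)
  }
  .xs_env[[key]]
}

# full numerical pack for the C++ engine, cached per scene
scene_pack <- function(scene) {
  if (!is.null(scene$cache$pack)) return(scene$cache$pack)
  ph <- scene$phantom
  # compact the material table to the ids actually present in the phantom
  active <- sort(unique(as.vector(ph$ids)))
  ids <- if (length(active) == length(ph$materials)) ph$ids else
    array(match(ph$ids, active) - 1L, dim = dim(ph$ids))
  mats <- ph$materials[active + 1L]
  M <- length(mats)
  # common transport energy grid (0.1 keV): log-log resampled tables
  e_lo <- max(vapply(mats, function(m) min(m$energy), 0))
  e_hi <- min(vapply(mats, function(m) max(m$energy), 0))
  eg <- seq(e_lo, e_hi, by = 0.1)
  ne <- length(eg)
  comp <- lapply(mats, mu_components, E = eg)
  mu_pe <- unlist(lapply(comp, `[[`, "mu_pe"), use.names = FALSE)
  mu_co <- unlist(lapply(comp, `[[`, "mu_compton"), use.names = FALSE)
  mu_ra <- unlist(lapply(comp, `[[`, "mu_rayleigh"), use.names = FALSE)
  mu_tot <- mu_pe + mu_co + mu_ra
  zeff <- vapply(mats, function(m) m$z_eff, 0)
  # angular normalization constants over the sphere.  Substituting
  # cos(theta) = 1 - 2 t^2 concentrates quadrature points in the narrow
  # forward lobe of the coherent form factor (d cos = -4 t dt).
  tq <- seq(0, 1, length.out = 2049)
  ct <- 1 - 2 * tq^2
  sw <- c(1, rep(c(4, 2), length.out = 2047), 1) * (tq[2] - tq[1]) / 3 * 4 * tq
  kn_norm <- 2 * pi * as.vector(sw %*% kn_unnorm_r(eg, ct))
  ray_norm <- unlist(lapply(zeff, function(z)
    2 * pi * as.vector(sw %*% ray_unnorm_r(eg, ct, z))), use.names = FALSE)
  # spectrum alias table
  sp <- scene$spectrum
  al <- build_alias(sp$weights)
  # RITA tables: Compton per energy, then Rayleigh per material per energy
  ner <- scene$rita_energies
  re <- exp(seq(log(e_lo), log(e_hi), length.out = ner))
  tabs <- c(lapply(re, function(E) rita_table_cached("compton", zeff[1], E,
                                                     scene$rita_tolerance)),
            unlist(lapply(seq_len(M), function(m)
              lapply(re, function(E) rita_table_cached("rayleigh", zeff[m], E,
                                                       scene$rita_tolerance))),
              recursive = FALSE))
  off <- cumsum(c(0L, vapply(tabs, function(t) length(t$x), 0L)))
  det <- scene$detector
  fr <- detector_frame(scene)
  pack <- list(
    ids = as.raw(ids), bricks = cpp_build_bricks(ids, dim(ids), 4L), B = 4L,
    dims = dim(ids), bdims = as.integer(ceiling(dim(ids) / 4)),
    h = ph$voxel_size, origin = ph$origin,
    M = M, ne = ne, e_lo = e_lo, e_step = 0.1,
    mu_pe = mu_pe, mu_co = mu_co, mu_ra = mu_ra, mu_tot = mu_tot,
    kn_norm = kn_norm, ray_norm = ray_norm, zeff = zeff,
    sp_e = sp$energies, sp_cut = al$cut, sp_alias = al$alias,
    src = scene$source, cone_w = scene$cone$w, cone_u = scene$cone$u,
    cone_v = scene$cone$v, cone_rect = scene$cone$rect,
    pixc = as.vector(detector_pixel_centers(scene, det$coarse, det$coarse_pitch)),
    ndet_u = det$coarse[1], ndet_v = det$coarse[2],
    det_normal = fr$normal, pix_area = det$coarse_pitch^2,
    det_center = fr$center, det_uaxis = fr$uaxis, det_vaxis = fr$vaxis,
    det_pitch = det$coarse_pitch,
    rita_x = unlist(lapply(tabs, `[[`, "x"), use.names = FALSE),
    rita_xi = unlist(lapply(tabs, `[[`, "xi"), use.names = FALSE),
    rita_a = unlist(lapply(tabs, function(t) c(t$a, 0)), use.names = FALSE),
    rita_b = unlist(lapply(tabs, function(t) c(t$b, 0)), use.names = FALSE),
    rita_off = as.integer(off), rita_ne = ner, rita_loge0 = log(e_lo),
    rita_dloge = (log(e_hi) - log(e_lo)) / (ner - 1),
    active = active + 1L,
    uniform_id = if (length(active) == 1L) 0L else -1L,
    n_order = scene$n_order, kernel_mode = 0L,
    kill_floor = as.integer(scene$kill_floor), w0 = scene$w0)
  scene$cache$pack <- pack
  pack
}
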