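# Voxel phantoms: data model, reference phantom builders and file I/O.
#
# World frame: right-handed, millimetres, the X-ray point source at the
# origin and the beam axis along +y.  Phantoms are centred on the beam
# axis 500 mm downstream of the source; voxel (i, j, k) spans the
# half-open interval [origin + i*h, origin + (i+1)*h) on each axis
# (0-based indices).

#' Construct a voxel phantom
#'
#' @param material_ids 3-D integer array of 0-based indices into
#'   `materials`; dimension order (x, y, z) with +y the beam axis.
#' @param voxel_size voxel edge lengths in mm, length 1 or 3.
#' @param origin world position (mm) of the low corner of voxel (0,0,0).
#' @param materials a [material_table()].
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material_ids, voxel_size, origin, materials) {
  stopifnot(length(dim(material_ids)) == 3, all(voxel_size > 0),
            inherits(materials, "material_table"))
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  storage.mode(material_ids) <- "integer"
  if (min(material_ids) < 0 || max(material_ids) >= length(materials))
    stop("material ids out of range of the material table")
  structure(list(ids = material_ids, voxel_size = voxel_size,
                 origin = as.numeric(origin), materials = materials,
                 cache = new.env(parent = emptyenv())),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$ids)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels of %g x %g x %g mm, materials: %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              paste(names(x$materials), collapse = ", ")))
  invisible(x)
}

#' Phantom bounding box in world coordinates
#' @param phantom a `voxel_phantom`.
#' @return list with `lo` and `hi` corners (mm).
#' @export
phantom_box <- function(phantom) {
  lo <- phantom$origin
  list(lo = lo, hi = lo + dim(phantom$ids) * phantom$voxel_size)
}

phantom_center <- function(phantom) {
  b <- phantom_box(phantom)
  (b$lo + b$hi) / 2
}

# cached uniform-brick grid used by the accelerated traversal
phantom_bricks <- function(phantom, B = 4L) {
  key <- paste0("bricks", B)
  if (is.null(phantom$cache[[key]]))
    phantom$cache[[key]] <- cpp_build_bricks(phantom$ids, dim(phantom$ids), B)
  phantom$cache[[key]]
}

# world positions of voxel centers along one axis
axis_centers <- function(phantom, axis) {
  n <- dim(phantom$ids)[axis]
  phantom$origin[axis] + (seq_len(n) - 0.5) * phantom$voxel_size[axis]
}

#' Homogeneous aluminium slab phantom
#'
#' A 160 x 28 x 160 voxel aluminium box with 1 mm voxels, 28 mm thick
#' along the beam axis, centred 500 mm from the source (and 500 mm from
#' the detector plane in the default scene).
#'
#' @param materials material table to reference (default bundled set).
#' @return a `voxel_phantom`.
#' @export
build_al_phantom <- function(materials = default_materials()) {
  dims <- c(160L, 28L, 160L)
  ids <- array(match("aluminium", names(materials)) - 1L, dim = dims)
  voxel_phantom(ids, c(1, 1, 1), c(-80, 500 - 14, -80), materials)
}

#' Bone-tissue cylinder phantom
#'
#' A cylinder of radius 30 mm and height 54 mm on a 0.5 mm voxel grid
#' (bounding grid 120 x 120 x 108): a 5 mm thick cortical-bone annulus
#' between radii 25 and 30 mm, soft tissue inside radius 25 mm, air
#' outside.  The cylinder axis is vertical (z), perpendicular to the beam.
#' A voxel takes the material of its centre point.
#'
#' @param voxel_mm voxel edge length, mm (0.5 default; smaller values test
#'   volume convergence).
#' @param materials material table to reference.
#' @return a `voxel_phantom`.
#' @export
build_bt_cylinder <- function(voxel_mm = 0.5, materials = default_materials()) {
  r_in <- 25; r_out <- 30; height <- 54
  n_xy <- ceiling(2 * r_out / voxel_mm)
  n_z <- ceiling(height / voxel_mm)
  origin <- c(-r_out, 500 - r_out, -height / 2)
  cx <- origin[1] + (seq_len(n_xy) - 0.5) * voxel_mm
  cy <- origin[2] + (seq_len(n_xy) - 0.5) * voxel_mm
  r <- sqrt(outer((cx - 0)^2, (cy - 500)^2, `+`))
  slice <- matrix(0L, n_xy, n_xy)
  slice[r < r_in] <- match("tissue", names(materials)) - 1L
  slice[r >= r_in & r < r_out] <- match("bone", names(materials)) - 1L
  ids <- array(slice, dim = c(n_xy, n_xy, n_z))
  voxel_phantom(ids, voxel_mm, origin, materials)
}

# standard 3-D Shepp-Logan ellipsoid set in unit coordinates:
# columns x0, y0, z0, a, b, c, phi_deg (rotation about z)
shepp_logan_ellipsoids <- function() {
  matrix(c(
      0,     0,      0,    0.69,   0.92,  0.90,   0,
      0,    -0.0184, 0,    0.6624, 0.874, 0.88,   0,
      0.22,  0,      0,    0.11,   0.31,  0.22, -18,
     -0.22,  0,      0,    0.16,   0.41,  0.28,  18,
      0,     0.35,  -0.15, 0.21,   0.25,  0.41,   0,
      0,     0.1,    0.25, 0.046,  0.046, 0.05,   0,
      0,    -0.1,    0.25, 0.046,  0.046, 0.05,   0,
     -0.08, -0.605,  0,    0.046,  0.023, 0.05,   0,
      0,    -0.606,  0,    0.023,  0.023, 0.02,   0,
      0.06, -0.605,  0,    0.023,  0.046, 0.02,   0),
    ncol = 7, byrow = TRUE)
}

#' Three-dimensional Shepp-Logan head phantom
#'
#' The standard ten-ellipsoid Shepp-Logan set rasterized to materials:
#' the outer shell (first ellipsoid minus the second) is cortical bone,
#' the interior is water, the two large oblique "ventricle" ellipsoids
#' are air, and the background is air.  At full scale the grid is
#' 320 x 400 x 360 voxels of 0.5 mm (160 x 200 x 180 mm extent), centred
#' 500 mm from the source.  This ellipsoid-to-material mapping is this
#' package's own convention.
#'
#' @param scale grid scale factor in (0, 1]; the physical extent is kept
#'   and the voxel size grows as `0.5 / scale` mm (small scales are for
#'   tests).
#' @param materials material table to reference.
#' @return a `voxel_phantom`.
#' @export
build_shepp_logan <- function(scale = 1, materials = default_materials()) {
  stopifnot(scale > 0, scale <= 1)
  dims <- as.integer(round(c(320, 400, 360) * scale))
  half <- c(80, 100, 90)               # mm semi-extents of the unit cube
  vox <- 2 * half / dims
  origin <- c(-half[1], 500 - half[2], -half[3])
  ell <- shepp_logan_ellipsoids()
  id_bone <- match("bone", names(materials)) - 1L
  id_water <- match("water", names(materials)) - 1L
  xs <- (origin[1] + (seq_len(dims[1]) - 0.5) * vox[1]) / half[1]
  ys <- (origin[2] + (seq_len(dims[2]) - 0.5) * vox[2] - 500) / half[2]
  zs <- (origin[3] + (seq_len(dims[3]) - 0.5) * vox[3]) / half[3]
  inside <- function(e, X, Y, Z) {
    ph <- e[7] * pi / 180
    xr <- (X - e[1]) * cos(ph) + (Y - e[2]) * sin(ph)
    yr <- -(X - e[1]) * sin(ph) + (Y - e[2]) * cos(ph)
    (xr / e[4])^2 + (yr / e[5])^2 + ((Z - e[3]) / e[6])^2 <= 1
  }
  ids <- array(0L, dim = dims)
  X <- matrix(xs, dims[1], dims[2])
  Y <- matrix(ys, dims[1], dims[2], byrow = TRUE)
  for (k in seq_len(dims[3])) {
    Z <- zs[k]
    sl <- matrix(0L, dims[1], dims[2])
    in1 <- inside(ell[1, ], X, Y, Z)
    in2 <- inside(ell[2, ], X, Y, Z)
    sl[in1] <- id_bone
    sl[in2] <- id_water
    for (e in 3:4) sl[in2 & inside(ell[e, ], X, Y, Z)] <- 0L   # ventricles: air
    ids[, , k] <- sl
  }
  voxel_phantom(ids, vox, origin, materials)
}

#' Write / read a phantom (JSON header + raw index volume)
#'
#' `write_phantom()` writes the little-endian raw index volume (z index
#' fastest) to `path` and a JSON sidecar header to `paste0(path, ".json")`
#' holding the shape, voxel size, origin, material names, dtype and byte
#' order.  `read_phantom()` reverses this; round trips are bit-exact.
#'
#' @param phantom a `voxel_phantom`.
#' @param path path of the raw volume file.
#' @param materials material table used to resolve the header's material
#'   names; every name must be present.
#' @return `read_phantom()` returns a `voxel_phantom`.
#' @export
write_phantom <- function(phantom, path) {
  d <- dim(phantom$ids)
  dtype <- if (length(phantom$materials) > 256) "uint16" else "uint8"
  hdr <- list(shape = d, voxel_size_mm = phantom$voxel_size,
              origin_mm = phantom$origin, materials = names(phantom$materials),
              dtype = dtype, byte_order = "little", storage = "z-fastest")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(aperm(phantom$ids, c(3, 2, 1))), con,
           size = if (dtype == "uint8") 1L else 2L, endian = "little")
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path, materials = default_materials()) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(hdr$shape)
  n <- prod(d)
  sz <- if (hdr$dtype == "uint8") 1L else 2L
  if (file.info(path)$size != n * sz)
    stop(sprintf("raw payload is %d bytes but the header implies %d",
                 file.info(path)$size, n * sz))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_ids <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                     endian = "little")
  idx <- match(hdr$materials, names(materials))
  if (anyNA(idx))
    stop("unknown material name(s) in header: ",
         paste(hdr$materials[is.na(idx)], collapse = ", "))
  # remap ids from the file's material list into the supplied table
  ids <- array(as.integer(idx[raw_ids + 1L] - 1L), dim = rev(d))
  voxel_phantom(aperm(ids, c(3, 2, 1)), hdr$voxel_size_mm, hdr$origin_mm, materials)
}
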