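# Materials: attenuation-coefficient tables and photon interaction physics.

#' Construct a material from attenuation tables
#'
#' A material holds photoelectric, Compton (incoherent) and Rayleigh
#' (coherent) linear attenuation coefficients in 1/mm on an ascending
#' energy grid in keV, together with an effective atomic number used by
#' the coherent-scatter form factor.  The total attenuation coefficient is
#' defined as the sum of the three components at every energy.
#'
#' @param name material name.
#' @param energy_keV ascending energy grid, keV.
#' @param mu_pe,mu_compton,mu_rayleigh component linear attenuation
#'   coefficients, 1/mm, one value per grid point; all non-negative.
#' @param z_eff effective atomic number for the coherent form factor.
#' @param density_g_cm3 mass density, informational.
#' @return an object of class `xray_material`.
#' @export
xray_material <- function(name, energy_keV, mu_pe, mu_compton, mu_rayleigh,
                          z_eff, density_g_cm3 = NA_real_) {
  stopifnot(length(energy_keV) >= 2, all(diff(energy_keV) > 0),
            length(mu_pe) == length(energy_keV),
            length(mu_compton) == length(energy_keV),
            length(mu_rayleigh) == length(energy_keV),
            all(mu_pe >= 0), all(mu_compton >= 0), all(mu_rayleigh >= 0))
  structure(list(name = name, energy = as.numeric(energy_keV),
                 mu_pe = as.numeric(mu_pe), mu_compton = as.numeric(mu_compton),
                 mu_rayleigh = as.numeric(mu_rayleigh),
                 z_eff = as.numeric(z_eff), density = density_g_cm3),
            class = "xray_material")
}

#' @export
print.xray_material <- function(x, ...) {
  cat(sprintf("<xray_material> %s: %d energies in [%g, %g] keV, z_eff %.2f\n",
              x$name, length(x$energy), min(x$energy), max(x$energy), x$z_eff))
  invisible(x)
}

#' Read a material table from a text file
#'
#' The format is a CSV with comment header lines `# name:`,
#' `# density_g_cm3:` and `# z_eff:`, then a header row
#' `energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm`.
#'
#' @param path file path.
#' @return an `xray_material`.
#' @export
read_material <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  tab <- read.csv(text = lines[!grepl("^#", lines)])
  xray_material(name = get("name", basename(path)),
                energy_keV = tab[[1]], mu_pe = tab[[2]],
                mu_compton = tab[[3]], mu_rayleigh = tab[[4]],
                z_eff = as.numeric(get("z_eff", 10)),
                density_g_cm3 = as.numeric(get("density_g_cm3")))
}

#' A material with no attenuation (vacuum), useful for tests
#' @param energy_keV energy grid to carry.
#' @export
vacuum_material <- function(energy_keV = c(16, 120)) {
  xray_material("vacuum", energy_keV, 0 * energy_keV, 0 * energy_keV,
                0 * energy_keV, z_eff = 1, density_g_cm3 = 0)
}

#' Ordered material lookup table
#'
#' Index 0 is reserved for the air/vacuum entry, which must have negligible
#' attenuation; voxel phantoms store 0-based indices into this table.
#'
#' @param ... `xray_material` objects; the first is index 0.
#' @return a `material_table` (a list with unique names).
#' @export
material_table <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !inherits(mats[[1]], "xray_material"))
    mats <- mats[[1]]
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "xray_material")))
  nms <- vapply(mats, function(m) m$name, "")
  if (anyDuplicated(nms)) stop("material names must be unique")
  m0 <- mats[[1]]
  if (max(m0$mu_pe + m0$mu_compton + m0$mu_rayleigh) > 1e-3)
    stop("material index 0 must be air or vacuum (negligible attenuation)")
  names(mats) <- nms
  structure(mats, class = "material_table")
}

#' Bundled material set: air, aluminium, bone, tissue, water
#'
#' Reads the attenuation tables shipped with the package (16-120 keV,
#' generated from analytic/semi-empirical photon cross sections calibrated
#' against standard reference attenuation values).  Air is index 0.
#' @return a `material_table`.
#' @export
default_materials <- function() {
  if (!is.null(.xs_env$materials)) return(.xs_env$materials)
  dir <- system.file("extdata", "materials", package = "xscatter")
  mats <- lapply(c("air", "aluminium", "bone", "tissue", "water"),
                 function(nm) read_material(file.path(dir, paste0(nm, ".txt"))))
  .xs_env$materials <- material_table(mats)
  .xs_env$materials
}

# log-log interpolation with exact values at grid knots; zeros handled linearly
loglog_interp <- function(x, y, xi) {
  out <- if (all(y > 0)) {
    10^(approx(log10(x), log10(y), xout = log10(xi))$y)
  } else {
    approx(x, y, xout = xi)$y
  }
  hit <- match(xi, x)
  out[!is.na(hit)] <- y[hit[!is.na(hit)]]
  out
}

#' Attenuation coefficient components of a material
#'
#' Log-log interpolates the stored tables at the requested energies.
#' Energies outside the table range are an error (no extrapolation).
#'
#' @param material an `xray_material`.
#' @param E energies, keV.
#' @return a data.frame with columns `mu_pe`, `mu_compton`, `mu_rayleigh`
#'   and `mu_tot` (their sum), one row per energy.
#' @export
mu_components <- function(material, E) {
  stopifnot(inherits(material, "xray_material"))
  if (any(E < min(material$energy) - 1e-12 | E > max(material$energy) + 1e-12))
    stop(sprintf("energy outside the [%g, %g] keV table range of material '%s'",
                 min(material$energy), max(material$energy), material$name))
  pe <- loglog_interp(material$energy, material$mu_pe, E)
  co <- loglog_interp(material$energy, material$mu_compton, E)
  ra <- loglog_interp(material$energy, material$mu_rayleigh, E)
  data.frame(mu_pe = pe, mu_compton = co, mu_rayleigh = ra, mu_tot = pe + co + ra)
}

#' Total linear attenuation coefficient
#' @inheritParams mu_components
#' @return numeric vector, 1/mm.
#' @export
mu_total <- function(material, E) mu_components(material, E)$mu_tot

#' Compton-scattered photon energy
#'
#' Free-electron Compton kinematics: `E' = E / (1 + (E/mec2)(1 - cos theta))`.
#'
#' @param E incident energy, keV (> 0).
#' @param cos_theta cosine of the polar scatter angle, in `[-1, 1]`.
#' @return scattered energy, keV.
#' @export
compton_energy <- function(E, cos_theta) {
  stopifnot(all(E > 0), all(cos_theta >= -1 & cos_theta <= 1))
  E / (1 + (E / 510.99895) * (1 - cos_theta))
}

#' Angular probability density of Compton or Rayleigh scatter
#'
#' Returns the normalized polar-angle density per steradian: Klein-Nishina
#' for Compton scatter (optionally weighted by a crude incoherent scattering
#' function), Thomson times the squared Moliere/Thomas-Fermi atomic form
#' factor for Rayleigh scatter.  The density integrates to 1 over the full
#' sphere.
#'
#' @param kind `"compton"` or `"rayleigh"`.
#' @param material an `xray_material` (supplies the effective Z).
#' @param E photon energy, keV.
#' @param cos_theta cosine(s) of the polar angle.
#' @param use_sfun logical; if `TRUE` the Compton density is weighted by the
#'   approximate incoherent scattering function `S(q) = Z (1 - (F/Z)^2)`.
#'   The transport engine always uses the free-electron default.
#' @return density values, 1/steradian.
#' @export
angular_pdf <- function(kind = c("compton", "rayleigh"), material, E, cos_theta,
                        use_sfun = FALSE) {
  kind <- match.arg(kind)
  k <- if (kind == "compton") 0L else 1L
  f <- function(ct) {
    v <- cpp_dcs(k, E, material$z_eff, ct)
    if (kind == "compton" && use_sfun) {
      Z <- material$z_eff
      q <- 0.536367 * E * sqrt(pmax(0, (1 - ct) / 2))
      b <- c(6, 1.2, 0.3) * Z^(1 / 3) / 0.88534
      Fq <- Z * (0.10 * b[1]^2 / (b[1]^2 + q^2) + 0.55 * b[2]^2 / (b[2]^2 + q^2) +
                 0.35 * b[3]^2 / (b[3]^2 + q^2))
      v <- v * Z * (1 - (Fq / Z)^2)
    }
    v
  }
  # normalize over the sphere; the substitution cos = 1 - 2 t^2 resolves
  # the narrow forward lobe of the coherent form factor
  tq <- seq(0, 1, length.out = 4097)
  w <- c(1, rep(c(4, 2), length.out = 4095), 1) * (tq[2] - tq[1]) / 3
  nrm <- 2 * pi * sum(w * 4 * tq * f(1 - 2 * tq^2))
  f(cos_theta) / nrm
}

#' Compton and Rayleigh interaction probabilities at an interaction point
#'
#' `p_T0 = mu_compton / mu_tot`, `p_T1 = mu_rayleigh / mu_tot`; the
#' remainder `1 - p_T0 - p_T1` is the photoelectric absorption probability.
#'
#' @inheritParams mu_components
#' @return a list with `p_compton` and `p_rayleigh`.
#' @export
scatter_type_probs <- function(material, E) {
  mc <- mu_components(material, E)
  if (any(mc$mu_tot <= 0))
    stop("mu_tot is zero at the requested energy: interaction probabilities undefined")
  list(p_compton = mc$mu_compton / mc$mu_tot, p_rayleigh = mc$mu_rayleigh / mc$mu_tot)
}
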