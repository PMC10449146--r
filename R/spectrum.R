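# Source energy spectra.

#' Discrete X-ray source energy spectrum
#'
#' @param energies ascending photon energies, keV.
#' @param weights non-negative relative fluence per energy; at least one
#'   must be positive.  Weights are stored as given; [normalize_spectrum()]
#'   returns a copy summing to one.
#' @return an object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, weights) {
  stopifnot(length(energies) == length(weights), length(energies) >= 1,
            all(weights >= 0), any(weights > 0),
            length(energies) == 1 || all(diff(energies) > 0))
  structure(list(energies = as.numeric(energies), weights = as.numeric(weights)),
            class = "energy_spectrum")
}

#' Normalize spectrum weights to sum to one
#' @param spectrum an `energy_spectrum`.
#' @export
normalize_spectrum <- function(spectrum) {
  energy_spectrum(spectrum$energies, spectrum$weights / sum(spectrum$weights))
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d lines in [%g, %g] keV, mean %.1f keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              sum(x$energies * x$weights) / sum(x$weights)))
  invisible(x)
}

#' Read / write a spectrum as a two-column CSV
#'
#' The file has a required header line `energy_keV,weight` and ascending
#' energies.
#' @param path file path.
#' @export
read_spectrum <- function(path) {
  tab <- read.csv(path)
  if (!identical(names(tab)[1:2], c("energy_keV", "weight")))
    stop("spectrum CSV must have header 'energy_keV,weight'")
  energy_spectrum(tab$energy_keV, tab$weight)
}

#' @param spectrum an `energy_spectrum`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(data.frame(energy_keV = spectrum$energies, weight = spectrum$weights),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled 120 kVp-like tungsten-anode spectrum, 16-120 keV
#'
#' A declared, swappable model spectrum: Kramers continuum `(E_max - E)/E`
#' filtered by 2.5 mm of aluminium (using the bundled attenuation table),
#' plus tungsten K-characteristic lines at 58, 59, 67 and 69 keV with
#' fixed relative intensities.  Weights are normalized to sum to one.
#'
#' @param kvp tube potential, keV (spectrum end point).
#' @param filtration_mm_al aluminium filtration thickness, mm.
#' @return an `energy_spectrum` on a 1 keV grid from 16 keV to `kvp`.
#' @export
default_spectrum <- function(kvp = 120, filtration_mm_al = 2.5) {
  E <- seq(16, kvp, by = 1)
  al <- default_materials()[["aluminium"]]
  mu <- mu_total(al, E)
  w <- (kvp - E) / E * exp(-mu * filtration_mm_al)
  lines <- c("58" = 0.5, "59" = 0.9, "67" = 0.25, "69" = 0.12)
  for (le in names(lines)) {
    i <- match(as.numeric(le), E)
    if (!is.na(i)) w[i] <- w[i] + lines[[le]] * max(w)
  }
  energy_spectrum(E, w / sum(w))
}
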