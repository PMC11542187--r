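## TD-DFT post-processing: nm <-> eV conversion, Gaussian broadening of
## oscillator-strength sticks into an absorbance curve, peak extraction
## and before/after peak-shift reporting.

#' Convert between wavelength and photon energy
#'
#' `E(eV) = 1239.84198 / lambda(nm)` and its inverse.
#'
#' @param wavelength_nm Wavelengths in nm, `> 0`.
#' @return Energies in eV (or wavelengths in nm for the inverse).
#' @examples
#' wavelength_to_energy(350) # 3.54 eV
#' @export
wavelength_to_energy <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) abort_domain("wavelength must be > 0")
  .cs_const$hc_ev_nm / wavelength_nm
}

#' @rdname wavelength_to_energy
#' @param energy_ev Photon energies in eV, `> 0`.
#' @export
energy_to_wavelength <- function(energy_ev) {
  if (any(energy_ev <= 0)) abort_domain("energy must be > 0")
  .cs_const$hc_ev_nm / energy_ev
}

#' Gaussian-broadened absorption spectrum
#'
#' Convolves a list of electronic transitions with unit-area Gaussians in
#' *energy* space (Gaussian line shapes are symmetric in eV, not nm), each
#' line carrying an area proportional to its oscillator strength, then
#' samples the curve on a wavelength grid.
#'
#' @param transitions Data frame with columns `wavelength_nm` and `f`
#'   (oscillator strength); must be non-empty.
#' @param fwhm Full width at half maximum of the broadening Gaussian, eV
#'   (default 0.33, a conventional TD-DFT visualisation width).
#' @param grid Strictly increasing wavelength grid in nm (default 150 to
#'   650 nm in 0.5 nm steps).
#' @return A tibble of class `cage_spectrum` with columns `wavelength`,
#'   `energy`, `absorbance` and attributes `fwhm` and `n_lines`.
#' @examples
#' sp <- broaden_spectrum(tibble::tibble(wavelength_nm = 250.8, f = 0.27))
#' lambda_max(sp)
#' @export
broaden_spectrum <- function(transitions, fwhm = 0.33,
                             grid = seq(150, 650, by = 0.5)) {
  if (nrow(transitions) == 0) {
    abort_validation("empty transition list")
  }
  if (fwhm <= 0) abort_domain("fwhm must be > 0")
  if (any(diff(grid) <= 0)) {
    abort_validation("wavelength grid must be strictly increasing")
  }
  e_lines <- wavelength_to_energy(transitions$wavelength_nm)
  f <- transitions$f
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  e_grid <- wavelength_to_energy(grid)
  absorbance <- vapply(e_grid, function(e) {
    sum(f * dnorm(e, mean = e_lines, sd = sigma))
  }, numeric(1))
  out <- tibble(wavelength = grid, energy = e_grid, absorbance = absorbance)
  attr(out, "fwhm") <- fwhm
  attr(out, "n_lines") <- nrow(transitions)
  class(out) <- c("cage_spectrum", class(out))
  out
}

#' Wavelength of maximum absorbance
#'
#' @param spectrum A `cage_spectrum`.
#' @return The grid wavelength (nm) of the absorbance maximum.
#' @export
lambda_max <- function(spectrum) {
  a <- spectrum$absorbance
  if (diff(range(a)) <= .Machine$double.eps * max(abs(a), 1)) {
    abort_validation("flat spectrum: no absorbance peak")
  }
  spectrum$wavelength[which.max(a)]
}

#' Signed absorption peak shift
#'
#' `lambda_max(after) - lambda_max(before)` in nm; positive means a shift
#' toward longer wavelength (red), negative toward shorter wavelength
#' (blue).  The interpretation is left to the caller.
#'
#' @param before,after `cage_spectrum` objects on overlapping grids.
#' @return Signed shift in nm.
#' @export
peak_shift <- function(before, after) {
  lo <- max(min(before$wavelength), min(after$wavelength))
  hi <- min(max(before$wavelength), max(after$wavelength))
  if (lo >= hi) {
    abort_validation("spectra do not share an overlapping wavelength range")
  }
  lambda_max(after) - lambda_max(before)
}

#' Integrated absorbance in energy space
#'
#' Trapezoidal integral of the absorbance over photon energy.  With
#' unit-area Gaussian broadening this equals the summed oscillator
#' strength of the lines (up to grid truncation), independent of the
#' broadening width.
#'
#' @param spectrum A `cage_spectrum`.
#' @return The integral (dimensionless, oscillator-strength units).
#' @export
spectrum_area <- function(spectrum) {
  ord <- order(spectrum$energy)
  e <- spectrum$energy[ord]
  a <- spectrum$absorbance[ord]
  sum(diff(e) * (head(a, -1) + a[-1]) / 2)
}

#' @rdname broaden_spectrum
#' @param object A `cage_spectrum`.
#' @param ... Unused.
#' @method autoplot cage_spectrum
#' @export
autoplot.cage_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wavelength, y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (arb. units)") +
    ggplot2::theme_minimal()
}
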