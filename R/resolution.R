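#' Instrument resolution models
#'
#' The instrument line shape `R(omega)` that every model component is convolved
#' with. Two kinds are supported: an analytic Gaussian of given full width at
#' half maximum (the usual description of a cold-neutron time-of-flight
#' spectrometer close to the elastic line), and a tabulated curve, e.g. a
#' measured vanadium spectrum, interpolated linearly and treated as a unit-area
#' density.
#'
#' @param fwhm_meV full width at half maximum of the Gaussian, in meV.
#' @param energy_meV,density tabulated resolution curve: energies (strictly
#'   increasing, meV) and non-negative densities.
#' @param renormalize if `TRUE` (default) a tabulated curve is rescaled to unit
#'   trapezoidal area; if `FALSE` a curve whose area deviates from 1 by more
#'   than `1e-6` is rejected.
#' @return an object of class `qens_resolution`.
#' @examples
#' res <- resolution_gaussian(0.010)
#' omega <- seq(-0.05, 0.05, length.out = 11)
#' resolution_profile(res, omega)
#' @export
resolution_gaussian <- function(fwhm_meV) {
  if (!is.numeric(fwhm_meV) || length(fwhm_meV) != 1 || !is.finite(fwhm_meV) ||
      fwhm_meV <= 0) {
    abort("`fwhm_meV` must be a single positive number.")
  }
  structure(
    list(kind = "gaussian", fwhm_meV = fwhm_meV),
    class = "qens_resolution"
  )
}

#' @rdname resolution_gaussian
#' @export
resolution_tabulated <- function(energy_meV, density, renormalize = TRUE) {
  if (length(energy_meV) != length(density) || length(energy_meV) < 4) {
    abort("Tabulated resolution needs >= 4 (energy, density) pairs of equal length.")
  }
  if (any(diff(energy_meV) <= 0)) abort("Tabulated energies must be strictly increasing.")
  if (any(density < 0)) abort("Tabulated resolution densities must be non-negative.")
  area <- pracma::trapz(energy_meV, density)
  if (area <= 0) abort("Tabulated resolution has non-positive area.")
  if (renormalize) {
    density <- density / area
  } else if (abs(area - 1) > 1e-6) {
    abort(sprintf("Tabulated resolution area is %.8f, not 1 within 1e-6.", area))
  }
  structure(
    list(kind = "tabulated",
         table = tibble(energy_meV = as.numeric(energy_meV),
                        density = as.numeric(density))),
    class = "qens_resolution"
  )
}

is_qens_resolution <- function(x) inherits(x, "qens_resolution")

#' @export
print.qens_resolution <- function(x, ...) {
  if (x$kind == "gaussian") {
    cat(sprintf("<qens_resolution> gaussian, FWHM = %g meV\n", x$fwhm_meV))
  } else {
    cat(sprintf("<qens_resolution> tabulated, %d points on [%g, %g] meV\n",
                nrow(x$table), min(x$table$energy_meV), max(x$table$energy_meV)))
  }
  invisible(x)
}

#' Evaluate the resolution line shape
#'
#' @param resolution a `qens_resolution`.
#' @param energy_meV energies at which to evaluate, in meV.
#' @param center center of the line, in meV.
#' @return numeric vector of densities (1/meV), unit area over the real line
#'   (Gaussian) or over the tabulated support.
#' @export
resolution_profile <- function(resolution, energy_meV, center = 0) {
  stopifnot(is_qens_resolution(resolution))
  if (resolution$kind == "gaussian") {
    dnorm(energy_meV, mean = center, sd = fwhm_to_sigma(resolution$fwhm_meV))
  } else {
    approx(resolution$table$energy_meV + center, resolution$table$density,
           xout = energy_meV, yleft = 0, yright = 0)$y
  }
}

# Discrete convolution of a profile with the resolution on a uniform grid,
# used for tabulated resolutions where no closed form exists.
convolve_with_resolution <- function(intensity, energy_meV, resolution) {
  h <- diff(energy_meV)
  if (max(h) - min(h) > 1e-9 * max(abs(h))) {
    abort("Numeric resolution convolution requires a uniform energy grid.")
  }
  step <- h[1]
  kernel <- resolution_profile(resolution, energy_meV - mean(range(energy_meV)))
  out <- stats::convolve(intensity, rev(kernel), type = "open") * step
  n <- length(intensity)
  lead <- (length(out) - n) %/% 2
  out[(lead + 1):(lead + n)]
}
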