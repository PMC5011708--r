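# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no stored data.

# A reduced instrument configuration for fast unit tests: fewer detector
# groups and energy bins than the full preset, same resolution.
small_preset <- function(n_q = 5, n_bins = 151) {
  instrument_preset(
    name = "small",
    q_values = seq(0.3, 1.1, length.out = n_q),
    energy_window_meV = c(-1.5, 1.5),
    n_energy_bins = n_bins,
    resolution = resolution_gaussian(0.010)
  )
}

# Single-population parameter sets used to build targeted spectra.
bulk_only_params <- function(d_t = 1.98e-5, tau_ps = 1.05, d_r = 0) {
  cell_params(
    p_elastic = 0, p_bulk = 1, p_hyd = 0, p_proteome = 0,
    bulk = water_params(d_t, tau_ps, d_r),
    hyd = water_params(5e-7, 0, 0),
    gamma_proteome_meV = 0.4
  )
}

# Independent quadrature oracle for Lorentzian (x) Gaussian at a single
# energy: the convolution integral in the substituted variable
# u = (omega - t)/sd, so that both factors stay O(1)-scaled for the
# adaptive rule whatever the width ratio. Split at the positions of the
# Gaussian and Lorentzian peaks.
conv_lorentz_gauss_point <- function(omega, hwhm, fwhm_gauss) {
  sd <- fwhm_gauss / (2 * sqrt(2 * log(2)))
  f <- function(u) {
    t <- omega - sd * u
    (hwhm / pi) / (t^2 + hwhm^2) * stats::dnorm(u)
  }
  cuts <- sort(unique(c(-Inf, 0, omega / sd, Inf)))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(f, cuts[i], cuts[i + 1],
                                      rel.tol = 1e-11, abs.tol = 0)$value
  }
  total
}

# FFT oracle: discrete (open) convolution of two profiles sampled on a
# uniform grid, returned on the same grid.
fft_convolve <- function(y1, y2, step) {
  out <- stats::convolve(y1, rev(y2), type = "open") * step
  n <- length(y1)
  lead <- (length(out) - n) %/% 2
  out[(lead + 1):(lead + n)]
}

trapz_area <- function(x, y) pracma::trapz(x, y)

# Truth vector (reporting units) for a scenario, including derived p_bulk.
scenario_truth_vector <- function(name) {
  p <- scenario_params(name)
  v <- qenscell:::cell_params_to_vector(p)
  c(v, p_bulk = unname(1 - v[["p_elastic"]] - v[["p_hyd"]] - v[["p_proteome"]]))
}
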