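# Model-free per-Q fits: elastic + n Lorentzians + background, resolution
# convolved. Spectra are built directly from the forward components so the
# generator is the oracle.

make_slice <- function(intensity, grid = seq(-1.5, 1.5, length.out = 301),
                       q = 0.5, sigma = 1e-4) {
  as_qens_spectra(
    tibble::tibble(q = q, energy_meV = grid, intensity = intensity,
                   sigma = sigma),
    resolution = resolution_gaussian(0.010))
}

test_that("a single Lorentzian width is recovered to a fraction of a percent", {
  grid <- seq(-1.5, 1.5, length.out = 301)
  truth <- 0.05
  sl <- make_slice(voigt_profile(grid, truth, 0.010))
  out <- fit_model_free(sl, n_lorentzians = 1)
  expect_true(all(out$converged))
  expect_equal(out$hwhm_meV, truth, tolerance = 0.005)
  expect_lt(out$elastic_amplitude, 0.01)
})

test_that("a pure resolution line yields a pure elastic fit with no quasi-elastic weight", {
  grid <- seq(-1.5, 1.5, length.out = 301)
  y <- resolution_profile(resolution_gaussian(0.010), grid)
  sl <- make_slice(y)
  out <- fit_model_free(sl, n_lorentzians = 1)
  expect_true(all(out$converged))
  # all the weight sits on the elastic line; its amplitude is 1 over the
  # trapezoidal window area of the input (the line is one bin wide, so that
  # area differs measurably from the analytic unit area)
  expect_equal(out$elastic_amplitude, 1 / trapz_area(grid, y),
               tolerance = 0.01)
  expect_lt(out$amplitude, 0.01)
})

test_that("two well-separated Lorentzians are resolved within 2%, widths ascending", {
  grid <- seq(-1.5, 1.5, length.out = 301)
  y <- 0.5 * voigt_profile(grid, 0.005, 0.010) +
       0.5 * voigt_profile(grid, 0.4, 0.010)
  out <- fit_model_free(make_slice(y), n_lorentzians = 2)
  expect_true(all(out$converged))
  expect_equal(out$hwhm_meV, c(0.005, 0.4), tolerance = 0.02)
  expect_true(!is.unsorted(out$hwhm_meV))
  # the slice is area-normalized before fitting, so the recovered
  # amplitudes are the generating weights rescaled by the window area
  window_area <- trapz_area(grid, y)
  expect_equal(out$amplitude, c(0.5, 0.5) / window_area, tolerance = 0.02)
})

test_that("multi-Q input returns one block per slice and respects bounds", {
  preset <- small_preset(n_q = 3, n_bins = 151)
  set <- generate_spectra(bulk_only_params(), preset)
  out <- fit_model_free(set, n_lorentzians = 1)
  expect_equal(nrow(out), 3)
  expect_setequal(out$q, preset$q_values)
  truth <- jump_diffusion_hwhm(1.98e-5, 1.05, preset$q_values)
  expect_equal(out$hwhm_meV[order(out$q)], truth, tolerance = 0.005)
  expect_error(fit_model_free(set, n_lorentzians = 0), "between 1 and 4")
  expect_error(fit_model_free(set, n_lorentzians = 5), "between 1 and 4")
})
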