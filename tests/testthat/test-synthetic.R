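test_that("the IN5-like preset matches the stated configuration", {
  p <- preset_in5()
  expect_length(p$q_values, 19)
  expect_equal(min(p$q_values), 0.20)
  expect_equal(max(p$q_values), 1.10)
  expect_equal(p$resolution$fwhm_meV, 0.010)
  expect_equal(p$energy_window_meV, c(-1.5, 1.5))
  expect_equal(p$n_energy_bins, 301L)
  grid <- qenscell:::preset_grid(p)
  expect_true(any(grid == 0))
})

test_that("scenario parameter sets carry the published values", {
  tb <- scenario_params("Tb_0.1MPa")
  expect_equal(tb$bulk$d_t, 1.98e-5)
  expect_equal(tb$bulk$tau_ps, 1.05)
  expect_equal(tb$hyd$d_t, 5.17e-7)
  expect_equal(tb$hyd$tau_ps, 0)
  expect_equal(tb$gamma_proteome_meV, 0.431)
  tk <- scenario_params("Tk_0.1MPa")
  scale <- attr(tk, "fraction_scale")
  # printed fractions are recovered after undoing the renormalization
  expect_equal(tk$p_hyd * scale, 0.17)
  expect_equal(tk$p_elastic * scale, 0.03)
  for (nm in c("Tb_0.1MPa", "Tb_40MPa", "Tk_0.1MPa", "Tk_40MPa")) {
    s <- scenario_params(nm)
    expect_equal(s$p_elastic + s$p_bulk + s$p_hyd + s$p_proteome, 1,
                 tolerance = 1e-12)
  }
  expect_error(scenario_params("nonsense"))
})

test_that("noiseless generation is exactly the forward model", {
  preset <- small_preset()
  pars <- scenario_params("Tb_40MPa")
  set <- generate_spectra(pars, preset)
  grid <- qenscell:::preset_grid(preset)
  for (qv in preset$q_values) {
    # the batched and the scalar evaluation differ only in summation order
    expect_equal(set$intensity[set$q == qv],
                 composite_model(pars, qv, grid, preset$resolution),
                 tolerance = 1e-12)
  }
  expect_true(all(set$sigma == 1e-4))
})

test_that("Poisson generation is seeded and reproducible", {
  preset <- small_preset()
  pars <- scenario_params("Tb_0.1MPa")
  a <- generate_spectra(pars, preset, noise = "poisson",
                        counts_per_spectrum = 1e4, seed = 3)
  b <- generate_spectra(pars, preset, noise = "poisson",
                        counts_per_spectrum = 1e4, seed = 3)
  c <- generate_spectra(pars, preset, noise = "poisson",
                        counts_per_spectrum = 1e4, seed = 4)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$sigma, b$sigma)
  expect_false(identical(a$intensity, c$intensity))
  expect_true(all(a$sigma > 0))
})

test_that("counting noise has the Poisson amplitude", {
  preset <- small_preset()
  pars <- scenario_params("Tb_0.1MPa")
  noisy <- generate_spectra(pars, preset, noise = "poisson",
                            counts_per_spectrum = 1e6, seed = 5)
  clean <- generate_spectra(pars, preset)
  grid <- qenscell:::preset_grid(preset)
  z <- unlist(lapply(preset$q_values, function(qv) {
    mu <- clean$intensity[clean$q == qv]
    mu_norm <- mu / pracma::trapz(grid, mu)
    sl <- noisy[noisy$q == qv, ]
    (sl$intensity - mu_norm) / sl$sigma
  }))
  expect_lt(abs(mean(z)), 0.05)
  expect_equal(stats::var(z), 1, tolerance = 0.05)
})
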