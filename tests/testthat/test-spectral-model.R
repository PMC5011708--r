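test_that("lorentzian has the closed-form peak, half-maximum and unit area", {
  grid <- seq(-5, 5, by = 0.001)
  y <- lorentzian(grid, hwhm_meV = 0.1)
  expect_equal(max(y), 1 / (pi * 0.1), tolerance = 1e-10)
  # half the peak exactly one HWHM away from the center
  expect_equal(lorentzian(c(-0.1, 0.1), 0.1), rep(0.5 / (pi * 0.1), 2),
               tolerance = 1e-12)
  # brute-force quadrature over +/- 50 HWHM matches the closed-form mass
  # (2/pi) atan(50) of that window; the full-line area is 1
  expect_equal(trapz_area(grid, y), 2 / pi * atan(50), tolerance = 1e-6)
  wide <- seq(-20, 20, by = 0.001)
  expect_equal(trapz_area(wide, lorentzian(wide, 0.1)), 1, tolerance = 0.01)
  # off-center
  expect_equal(which.max(lorentzian(grid, 0.1, center = 0.5)),
               which.min(abs(grid - 0.5)))
  expect_error(lorentzian(grid, 0), "positive")
  expect_error(lorentzian(grid, -0.1), "positive")
})

test_that("voigt profile agrees with direct numerical convolution", {
  withr::local_seed(11)
  n <- 8
  hwhms <- 10^stats::runif(n, -3, 0)
  fwhms <- 10^stats::runif(n, -3, 0)
  for (i in seq_len(n)) {
    peak <- voigt_profile(0, hwhms[i], fwhms[i])
    ref <- conv_lorentz_gauss_point(0, hwhms[i], fwhms[i])
    expect_equal(peak, ref, tolerance = 1e-6)
  }
  # off-center values for one representative pair
  for (om in c(-0.3, 0.02, 0.5)) {
    expect_equal(voigt_profile(om, 0.05, 0.01),
                 conv_lorentz_gauss_point(om, 0.05, 0.01), tolerance = 1e-6)
  }
  # degenerate limits collapse to the pure profiles
  g <- seq(-1, 1, by = 0.01)
  expect_equal(voigt_profile(g, 0.05, 0), lorentzian(g, 0.05))
  expect_equal(voigt_profile(g, 0, 0.01),
               dnorm(g, sd = 0.01 / (2 * sqrt(2 * log(2)))))
})

test_that("convolving two Lorentzians adds their widths", {
  a <- 0.03; b <- 0.07
  step <- 1e-4
  grid <- seq(-20, 20, by = step)
  conv <- fft_convolve(lorentzian(grid, a), lorentzian(grid, b), step)
  direct <- lorentzian(grid, a + b)
  core <- abs(grid) <= 0.5
  expect_lt(max(abs(conv[core] - direct[core])) / max(direct), 1e-6)
})

test_that("jump-diffusion dispersion has the closed form and its limits", {
  # frozen from independent high-precision arithmetic
  expect_equal(jump_diffusion_hwhm(1.98e-5, 1.05, 0.5), 0.030971735893486,
               tolerance = 1e-12)
  expect_identical(jump_diffusion_hwhm(1.98e-5, 1.05, 0), 0)
  # high-Q plateau hbar/tau (frozen: 0.6268685303809524)
  expect_equal(jump_diffusion_hwhm(1.98e-5, 1.05, 100), 0.62686853038095,
               tolerance = 1e-3)
  # low-Q limit: Gamma / (hbar Q^2) -> D (A^2/ps) within 0.1% at Q = 0.01
  q <- 0.01
  expect_equal(jump_diffusion_hwhm(1.98e-5, 1.05, q) / (0.6582119569 * q^2),
               0.198, tolerance = 1e-3)
  # plateau within 0.1% where D Q^2 tau = 1e3
  q_hi <- sqrt(1e3 / (0.198 * 1.05))
  expect_equal(jump_diffusion_hwhm(1.98e-5, 1.05, q_hi),
               0.6582119569 / 1.05, tolerance = 1e-3)
  # monotone non-decreasing in Q
  g <- jump_diffusion_hwhm(1.98e-5, 1.05, seq(0, 5, by = 0.05))
  expect_true(all(diff(g) >= 0))
  expect_error(jump_diffusion_hwhm(-1e-5, 1, 0.5), "non-negative")
  expect_error(jump_diffusion_hwhm(1e-5, -1, 0.5), "non-negative")
  expect_error(jump_diffusion_hwhm(1e-5, 1, -0.5), "non-negative")
})

test_that("rotational weights are a probability decomposition", {
  w0 <- rotational_weights(0, 0.98, 5)
  expect_equal(unname(w0), c(1, rep(0, 5)))
  # partial sum at l_max = 5 essentially closes the series at Q a ~ 1
  expect_gte(sum(rotational_weights(1.0, 0.98, 5)), 0.9999)
  # closure to l = 50 over the experimentally relevant x range
  for (x in seq(0, 2, by = 0.25)) {
    expect_equal(sum(rotational_weights(x, 1, 50)), 1, tolerance = 1e-8)
  }
  # non-negativity and monotone partial sums
  w <- rotational_weights(1.7, 0.98, 12)
  expect_true(all(w >= 0))
  expect_true(all(diff(cumsum(w)) >= 0))
})

test_that("water component equals translational (x) rotational convolution", {
  water <- water_params(1.98e-5, 1.05, 0.11)
  q <- 0.9
  # rotation off: a single translational Lorentzian
  w_norot <- water_params(1.98e-5, 1.05, 0)
  area_grid <- seq(-60, 60, by = 5e-3)
  expect_equal(water_component_spectrum(w_norot, q, area_grid),
               lorentzian(area_grid, jump_diffusion_hwhm(1.98e-5, 1.05, q)))
  # unit area by quadrature on a wide grid
  expect_equal(trapz_area(area_grid,
                          water_component_spectrum(water, q, area_grid)),
               1, tolerance = 0.01)
  # analytic width addition vs explicit FFT convolution of the translational
  # line with each rotational Lorentzian, fixed truncation on both sides
  grid <- seq(-15, 15, by = 2.5e-4)
  l_max <- 8
  y_analytic <- water_component_spectrum(water, q, grid, l_max = l_max)
  gamma_t <- jump_diffusion_hwhm(water$d_t, water$tau_ps, q)
  w <- rotational_weights(q, water$radius_A, l_max)
  w <- w / sum(w)
  trans <- lorentzian(grid, gamma_t)
  y_fft <- w[1] * trans
  step <- grid[2] - grid[1]
  for (l in 1:l_max) {
    rot_l <- lorentzian(grid, 0.6582119569 * l * (l + 1) * water$d_r)
    y_fft <- y_fft + w[l + 1] * fft_convolve(trans, rot_l, step)
  }
  core <- abs(grid) <= 1.5
  expect_lt(max(abs(y_analytic[core] - y_fft[core])) / max(y_fft), 1e-6)
})

test_that("immobile water is flagged as a delta, not a zero-width line", {
  grid <- seq(-1, 1, length.out = 101)
  still <- water_params(0, 0, 0)
  out <- water_component_spectrum(still, 0.5, grid)
  expect_true(is_delta_marker(out))
})

test_that("composite model: elastic limit, Voigt component, unit area", {
  res <- resolution_gaussian(0.010)
  grid <- seq(-1.5, 1.5, length.out = 301)
  mk <- function(p_el, p_bulk, p_hyd, p_prot, gamma = 0.363) {
    cell_params(p_el, p_bulk, p_hyd, p_prot,
                bulk = water_params(1.98e-5, 1.05, 0.11),
                hyd = water_params(5.17e-7, 0, 0.06),
                gamma_proteome_meV = gamma)
  }
  # pure elastic returns exactly the resolution line
  expect_equal(composite_model(mk(1, 0, 0, 0), 0.5, grid, res),
               resolution_profile(res, grid))
  # proteome-only is a Voigt profile: check against the quadrature oracle
  y <- composite_model(mk(0, 0, 0, 1, gamma = 0.363), 0.5, grid, res)
  ref_peak <- conv_lorentz_gauss_point(0, 0.363, 0.010)
  expect_equal(max(y), ref_peak, tolerance = 1e-6)
  expect_equal(y[30], conv_lorentz_gauss_point(grid[30], 0.363, 0.010),
               tolerance = 1e-6)
  # background-free model integrates to ~1 on a wide grid
  wide <- seq(-60, 60, by = 0.002)
  y_wide <- composite_model(scenario_params("Tb_0.1MPa"), 0.75, wide, res)
  expect_equal(trapz_area(wide, y_wide), 1, tolerance = 0.01)
  # fraction constraint is enforced
  expect_error(
    cell_params(0.2, 0.2, 0.2, 0.2,
                bulk = water_params(1e-5), hyd = water_params(1e-7),
                gamma_proteome_meV = 0.4),
    "sum to 1")
})

test_that("tabulated resolution reproduces the analytic Gaussian path", {
  fwhm <- 0.1
  tab_grid <- seq(-1.5, 1.5, by = 0.005)
  tab <- resolution_tabulated(tab_grid,
                              dnorm(tab_grid, sd = fwhm / (2 * sqrt(2 * log(2)))))
  grid <- seq(-1.5, 1.5, by = 0.005)
  pars <- bulk_only_params(d_r = 0.11)
  y_tab <- composite_model(pars, 0.7, grid, tab)
  y_voigt <- composite_model(pars, 0.7, grid, resolution_gaussian(fwhm))
  core <- abs(grid) <= 1.0
  expect_lt(max(abs(y_tab[core] - y_voigt[core])) / max(y_voigt), 2e-3)
  # validation of the tabulated curve
  expect_error(resolution_tabulated(tab_grid, -dnorm(tab_grid)), "non-negative")
  expect_error(resolution_tabulated(tab_grid, 2 * dnorm(tab_grid, sd = 0.04),
                                    renormalize = FALSE), "not 1")
})

test_that("normalization is idempotent, exact and scale invariant", {
  set <- generate_spectra(scenario_params("Tb_0.1MPa"), small_preset())
  norm1 <- normalize_spectra(set)
  for (qv in unique(norm1$q)) {
    sl <- norm1[norm1$q == qv, ]
    expect_equal(trapz_area(sl$energy_meV, sl$intensity), 1, tolerance = 1e-9)
  }
  norm2 <- normalize_spectra(norm1)
  expect_equal(norm1$intensity, norm2$intensity, tolerance = 1e-12)
  scaled <- set
  scaled$intensity <- scaled$intensity * 7
  scaled$sigma <- scaled$sigma * 7
  norm_scaled <- normalize_spectra(as_qens_spectra(scaled))
  expect_equal(norm_scaled$intensity, norm1$intensity, tolerance = 1e-12)
  expect_equal(norm_scaled$sigma, norm1$sigma, tolerance = 1e-12)
  # degenerate input
  zero <- set
  zero$intensity <- 0
  expect_error(normalize_spectra(as_qens_spectra(zero)), "area")
})
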