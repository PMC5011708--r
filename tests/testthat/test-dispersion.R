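fake_mf <- function(q, hwhm, converged = TRUE) {
  tibble::tibble(q = q, component = 1L, hwhm_meV = hwhm, hwhm_err = 1e-4,
                 amplitude = 1, amplitude_err = 1e-4, elastic_amplitude = 0,
                 background = 0, chi2_reduced = 1, converged = converged)
}

test_that("dispersion extraction is plain bookkeeping in Q^2", {
  mf <- fake_mf(c(0.3, 0.6, 0.9), c(0.01, 0.02, 0.03))
  curve <- extract_dispersion(mf, 1)
  expect_equal(curve$q2, c(0.09, 0.36, 0.81))
  expect_equal(curve$hwhm_meV, c(0.01, 0.02, 0.03))
})

test_that("failed per-Q fits are omitted with a warning", {
  q <- seq(0.2, 1.1, by = 0.1)
  mf <- fake_mf(q, 0.01 * seq_along(q), converged = c(rep(TRUE, 4), FALSE,
                                                      rep(TRUE, 5)))
  expect_warning(curve <- extract_dispersion(mf, 1), "Omitting 1")
  expect_equal(nrow(curve), 9)
  expect_false(q[5]^2 %in% curve$q2)
})

test_that("jump-diffusion fitting inverts the dispersion law", {
  q <- seq(0.2, 1.1, length.out = 10)
  curve <- tibble::tibble(q2 = q^2,
                          hwhm_meV = jump_diffusion_hwhm(1.98e-5, 1.05, q),
                          hwhm_err = 1e-4)
  fit <- fit_jump_diffusion(curve)
  expect_true(fit$tau_free)
  expect_equal(fit$d_t, 1.98e-5, tolerance = 1e-6)
  expect_equal(fit$tau_ps, 1.05, tolerance = 1e-6)
})

test_that("a linear curve keeps tau at zero with the slope-determined D", {
  q <- seq(0.2, 1.1, length.out = 8)
  d_t <- 2.5e-5
  curve <- tibble::tibble(q2 = q^2,
                          hwhm_meV = jump_diffusion_hwhm(d_t, 0, q),
                          hwhm_err = 1e-4)
  fit <- fit_jump_diffusion(curve)
  expect_false(fit$tau_free)
  expect_identical(fit$tau_ps, 0)
  expect_equal(fit$d_t, d_t, tolerance = 1e-8)
  td <- tidy(fit)
  expect_true(td$fixed[td$term == "tau_ps"])
})

test_that("the law depends on D Q^2 only through their product", {
  q <- seq(0.2, 1.1, length.out = 6)
  g1 <- jump_diffusion_hwhm(1.98e-5, 1.05, q)
  g2 <- jump_diffusion_hwhm(0.99e-5, 1.05, sqrt(2) * q)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("degenerate curves are rejected", {
  expect_error(fit_jump_diffusion(tibble::tibble(q2 = c(1, 2),
                                                 hwhm_meV = c(1, 2))),
               "at least 3")
  expect_error(fit_jump_diffusion(tibble::tibble(q2 = 1:4,
                                                 hwhm_meV = rep(0, 4))),
               "zero")
})

test_that("model-free + dispersion + jump fit recovers the generator", {
  preset <- small_preset(n_q = 8, n_bins = 151)
  set <- generate_spectra(bulk_only_params(), preset)
  mf <- fit_model_free(set, n_lorentzians = 1)
  curve <- extract_dispersion(mf, 1, component_label = "bulk translational")
  fit <- fit_jump_diffusion(curve)
  expect_equal(fit$d_t, 1.98e-5, tolerance = 0.01)
  expect_equal(fit$tau_ps, 1.05, tolerance = 0.01)
})
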