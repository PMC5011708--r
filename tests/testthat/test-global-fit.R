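# Global four-component fits on a reduced detector configuration; the full
# instrument configuration is exercised in test-acceptance.R.

test_that("noiseless spectra return the generating parameters within 2%", {
  preset <- small_preset()
  truth <- scenario_truth_vector("Tb_0.1MPa")
  set <- generate_spectra(scenario_params("Tb_0.1MPa"), preset)
  fit <- fit_global(set, seed = 1)
  expect_true(fit$converged)
  est <- fit$estimates
  free <- setdiff(c(qenscell:::.shared_par_names, "p_bulk"), "tau_hyd")
  for (nm in free) {
    expect_equal(est[[nm]], truth[[nm]], tolerance = 0.02, label = nm)
  }
  # standard errors are defined and non-negative
  expect_true(all(fit$stderr[free] >= 0))
  td <- tidy(fit)
  expect_true(td$fixed[td$term == "tau_hyd"])
})

test_that("a fit with everything held at truth has chi2 ~ 0 (noiseless) and ~1 (noisy)", {
  preset <- small_preset(n_q = 4, n_bins = 121)
  pars <- scenario_params("Tk_40MPa")
  truth_vec <- qenscell:::cell_params_to_vector(pars)
  set_clean <- generate_spectra(pars, preset)
  fit_clean <- fit_global(set_clean, init = pars, fixed = truth_vec,
                          n_starts = 1, seed = 1)
  expect_lt(fit_clean$chi2_reduced, 1e-6)
  set_noisy <- generate_spectra(pars, preset, noise = "poisson",
                                counts_per_spectrum = 1e5, seed = 2)
  fit_noisy <- fit_global(set_noisy, init = pars, fixed = truth_vec,
                          n_starts = 1, seed = 1)
  # chi2_red fluctuates by ~sqrt(2/n) and carries a small upward bias from
  # the sqrt(counts) sigma estimate; a 15% band covers both
  expect_equal(fit_noisy$chi2_reduced, 1, tolerance = 0.15)
})

test_that("fits are reproducible bit-for-bit under a fixed seed", {
  preset <- small_preset(n_q = 4, n_bins = 121)
  set <- generate_spectra(scenario_params("Tb_40MPa"), preset,
                          noise = "poisson", counts_per_spectrum = 1e4,
                          seed = 9)
  f1 <- fit_global(set, n_starts = 2, seed = 7)
  f2 <- fit_global(set, n_starts = 2, seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$deviance, f2$deviance)
  expect_identical(glance(f1), glance(f2))
})

test_that("noisy estimates are unbiased within the replicate spread", {
  preset <- small_preset(n_q = 4, n_bins = 121)
  pars <- scenario_params("Tb_0.1MPa")
  truth <- scenario_truth_vector("Tb_0.1MPa")
  seeds <- 1:6
  ests <- sapply(seeds, function(s) {
    set <- generate_spectra(pars, preset, noise = "poisson",
                            counts_per_spectrum = 1e5, seed = s)
    fit <- fit_global(set, n_starts = 1, seed = 1)
    fit$estimates[c("d_t_bulk", "gamma_proteome", "p_bulk")]
  })
  for (nm in rownames(ests)) {
    bias <- abs(stats::median(ests[nm, ]) - truth[[nm]])
    spread <- stats::sd(ests[nm, ])
    expect_lt(bias, max(spread, 0.02 * truth[[nm]]))
  }
})

test_that("recovery error shrinks as counting statistics grow", {
  preset <- small_preset(n_q = 4, n_bins = 121)
  pars <- scenario_params("Tb_0.1MPa")
  truth <- scenario_truth_vector("Tb_0.1MPa")
  key <- c("p_elastic", "p_hyd", "p_proteome", "p_bulk", "d_t_bulk",
           "tau_bulk", "d_r_bulk", "d_t_hyd", "d_r_hyd", "gamma_proteome")
  med_err <- function(counts) {
    errs <- sapply(1:10, function(s) {
      set <- generate_spectra(pars, preset, noise = "poisson",
                              counts_per_spectrum = counts, seed = s)
      fit <- fit_global(set, n_starts = 1, seed = 1)
      abs(fit$estimates[key] / truth[key] - 1)
    })
    apply(errs, 1, stats::median)
  }
  lo <- med_err(1e4)
  hi <- med_err(1e6)
  expect_true(all(hi < lo))
})

test_that("invalid inputs are rejected cleanly", {
  preset <- small_preset(n_q = 4, n_bins = 121)
  set <- generate_spectra(scenario_params("Tb_0.1MPa"), preset)
  attr(set, "resolution") <- NULL
  expect_error(fit_global(set, resolution = NULL), "resolution")
})
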