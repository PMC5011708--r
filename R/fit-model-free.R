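# Per-Q "model-free" fits: elastic line + a small number of Lorentzians
# (each convolved with the resolution) + flat background, with no dynamical
# model linking the widths across Q.

#' Model-free per-Q Lorentzian fit
#'
#' Fits each Q slice independently with
#' `a_el * R(omega) + sum_i a_i * [L(Gamma_i) (x) R](omega) + b`,
#' by weighted least squares: an elastic line, `n_lorentzians` quasi-elastic
#' Lorentzians of free width and amplitude, and a flat background. Widths are
#' reported sorted ascending. This is the classic first-pass analysis from
#' which dispersion curves (HWHM vs Q^2) are built.
#'
#' @param spectra a [as_qens_spectra()] tibble (one or many Q slices); each
#'   slice is area-normalized before fitting.
#' @param n_lorentzians number of quasi-elastic Lorentzians, 1 to 4.
#' @param resolution instrument resolution; defaults to the attached one.
#' @param n_starts multi-start budget per slice (first start from the default
#'   initialization, the rest jittered, seeded).
#' @param seed RNG seed for the jitter.
#' @return a tibble with one row per (Q, component): `q`, `component`,
#'   `hwhm_meV`, `hwhm_err`, `amplitude`, `amplitude_err`,
#'   `elastic_amplitude`, `background`, `chi2_reduced`, `converged`.
#'   Non-convergence is flagged per slice, never raised as an error.
#' @examples
#' \donttest{
#' one_l <- cell_params(0, 1, 0, 0,
#'   bulk = water_params(1.98e-5, 1.05, 0),
#'   hyd = water_params(5e-7, 0, 0), gamma_proteome_meV = 0.4)
#' set <- generate_spectra(one_l)
#' fit_model_free(set, n_lorentzians = 1)
#' }
#' @export
fit_model_free <- function(spectra, n_lorentzians = 1,
                           resolution = attr(spectra, "resolution"),
                           n_starts = 3, seed = 1) {
  if (is.null(resolution)) abort("No resolution attached to `spectra`; pass one.")
  if (n_lorentzians < 1 || n_lorentzians > 4) {
    abort("`n_lorentzians` must be between 1 and 4.")
  }
  n_lorentzians <- as.integer(n_lorentzians)
  spectra <- normalize_spectra(as_qens_spectra(spectra, resolution = resolution))
  qs <- spectra_q_values(spectra)
  purrr::map_dfr(qs, function(qv) {
    sl <- spectra[spectra$q == qv, ]
    fit_model_free_slice(sl$energy_meV, sl$intensity, sl$sigma, qv,
                         resolution, n_lorentzians, n_starts, seed)
  })
}

fit_model_free_slice <- function(energy, intensity, sigma, qv, resolution,
                                 n, n_starts, seed) {
  rprof <- resolution_profile(resolution, energy)
  res_fwhm <- if (resolution$kind == "gaussian") resolution$fwhm_meV else {
    # effective width for initialization purposes
    diff(range(resolution$table$energy_meV)) / 10
  }
  gauss_fwhm <- if (resolution$kind == "gaussian") resolution$fwhm_meV else 0

  eval_model <- function(theta) {
    a_el <- theta[1]
    gam <- theta[1 + seq_len(n)]
    amp <- theta[1 + n + seq_len(n)]
    bg <- theta[2 * n + 2]
    quasi <- numeric(length(energy))
    for (i in seq_len(n)) {
      quasi <- quasi + amp[i] * voigt_profile(energy, gam[i], gauss_fwhm)
    }
    if (resolution$kind == "tabulated") {
      quasi <- convolve_with_resolution(quasi, energy, resolution)
    }
    a_el * rprof + quasi + bg
  }
  # The tiny amplitude penalty breaks the degeneracy between the elastic
  # line and a Lorentzian much narrower than the resolution: on data with no
  # quasi-elastic broadening both describe the spectrum equally well, and
  # the penalty routes the tied weight to the elastic channel. Its scale
  # (1e-2 * amplitude against residuals of order intensity/sigma) is far too
  # small to bias any resolvable component.
  resid_fn <- function(theta) {
    c((eval_model(theta) - intensity) / sigma,
      1e-2 * theta[1 + n + seq_len(n)])
  }

  gam0 <- exp(seq(log(max(res_fwhm, 2e-3)), log(max(energy) / 3),
                  length.out = n + 1))[seq_len(n)]
  # start with half the weight on the elastic line: amplitudes enter the
  # model linearly, so the optimizer reassigns them cheaply, and an
  # elastic-dominated start avoids trading the elastic line for a
  # resolution-narrow Lorentzian on quasi-elastic-free data
  theta0 <- c(0.5, gam0, rep(0.5 / n, n), 0)
  lower <- c(0, rep(1e-5, n), rep(0, n), 0)
  upper <- c(2, rep(10, n), rep(2, n), 10)

  starts <- list(theta0)
  if (n_starts > 1) {
    starts <- c(starts, withr::with_seed(seed + round(qv * 1000), {
      lapply(seq_len(n_starts - 1), function(i) {
        v <- theta0 * exp(stats::runif(length(theta0), -1, 1) * log(1.5))
        pmin(pmax(v, lower), upper)
      })
    }))
  }

  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      # non-convergence is tracked through the info code, not the warning
      suppressWarnings(
        minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10, maxiter = 200,
                             maxfev = 20000))),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
    if (f$deviance / length(energy) < 1e-12) break
  }
  if (is.null(best)) {
    return(tibble(q = qv, component = seq_len(n), hwhm_meV = NA_real_,
                  hwhm_err = NA_real_, amplitude = NA_real_,
                  amplitude_err = NA_real_, elastic_amplitude = NA_real_,
                  background = NA_real_, chi2_reduced = NA_real_,
                  converged = FALSE))
  }

  theta_hat <- best$par
  n_free <- length(theta_hat)
  chi2_red <- best$deviance / max(length(energy) - n_free, 1)
  converged <- best$info %in% 1:3

  J <- numeric_jacobian(resid_fn, theta_hat)
  cov <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, n_free) else sqrt(pmax(diag(cov), 0))

  gam <- theta_hat[1 + seq_len(n)]
  amp <- theta_hat[1 + n + seq_len(n)]
  gam_se <- se[1 + seq_len(n)]
  amp_se <- se[1 + n + seq_len(n)]
  ord <- order(gam)

  tibble(
    q = qv,
    component = seq_len(n),
    hwhm_meV = gam[ord],
    hwhm_err = gam_se[ord],
    amplitude = amp[ord],
    amplitude_err = amp_se[ord],
    elastic_amplitude = theta_hat[1],
    background = theta_hat[2 * n + 2],
    chi2_reduced = chi2_red,
    converged = converged
  )
}
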