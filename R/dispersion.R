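# Dispersion curves: quasi-elastic HWHM versus Q^2, and the jump-diffusion
# fit that turns a curve into (D_T, tau).

#' Assemble a dispersion curve from model-free fits
#'
#' Collects the width of one component across Q into a (Q^2, HWHM, error)
#' curve, the representation in which Brownian diffusion is a straight line
#' of slope \eqn{\hbar D_T} and jump diffusion bends towards the plateau
#' \eqn{\Gamma_\infty = \hbar/\tau}. Slices whose model-free fit failed are
#' omitted with a warning.
#'
#' @param fits output of [fit_model_free()].
#' @param component_index which width (1 = narrowest) to track.
#' @param component_label free-text label stored on the curve.
#' @return a tibble of class `qens_dispersion` with columns `q`, `q2`,
#'   `hwhm_meV`, `hwhm_err`, ordered by `q`.
#' @export
extract_dispersion <- function(fits, component_index = 1,
                               component_label = paste0("component_", component_index)) {
  sel <- fits[fits$component == component_index, , drop = FALSE]
  if (!nrow(sel)) abort("No rows for the requested component index.")
  bad <- !sel$converged | !is.finite(sel$hwhm_meV)
  if (any(bad)) {
    warn(sprintf("Omitting %d Q point(s) with failed model-free fits (q = %s).",
                 sum(bad), paste(format(sel$q[bad]), collapse = ", ")))
    sel <- sel[!bad, , drop = FALSE]
  }
  sel <- sel[order(sel$q), , drop = FALSE]
  out <- tibble(q = sel$q, q2 = sel$q^2,
                hwhm_meV = sel$hwhm_meV, hwhm_err = sel$hwhm_err)
  attr(out, "component_label") <- component_label
  class(out) <- unique(c("qens_dispersion", class(out)))
  out
}

#' Fit the jump-diffusion law to a dispersion curve
#'
#' Weighted least squares of \eqn{\Gamma(Q) = \hbar D Q^2 / (1 + D Q^2 \tau)}
#' to an (HWHM, Q^2) curve. Whether the residence time is a free parameter is
#' decided by `tau`: with `"auto"` (default) an F-test compares the purely
#' linear (Fickian, `tau = 0`) fit against the jump model and frees `tau`
#' only when the curvature is significant at the 5% level — over a
#' restricted Q range the plateau may simply not be visible, in which case
#' `tau` is reported as 0 with `tau_free = FALSE`.
#'
#' @param curve a [extract_dispersion()] tibble (or any data frame with
#'   columns `q2`, `hwhm_meV` and optionally `hwhm_err`); >= 3 points.
#' @param tau `"auto"`, `"free"` or `"zero"`.
#' @return an object of class `qens_jump_fit` with elements `d_t` (cm^2/s),
#'   `tau_ps`, `stderr`, `tau_free`, `f_pvalue`, `chi2_reduced`, `n_points`.
#' @examples
#' curve <- tibble::tibble(q2 = seq(0.04, 1.21, length.out = 10))
#' curve$hwhm_meV <- jump_diffusion_hwhm(1.98e-5, 1.05, sqrt(curve$q2))
#' curve$hwhm_err <- 1e-4
#' fit_jump_diffusion(curve)
#' @export
fit_jump_diffusion <- function(curve, tau = c("auto", "free", "zero")) {
  tau <- match.arg(tau)
  if (!all(c("q2", "hwhm_meV") %in% names(curve))) {
    abort("`curve` needs columns `q2` and `hwhm_meV`.")
  }
  n <- nrow(curve)
  if (n < 3) abort("Need at least 3 dispersion points.")
  g <- curve$hwhm_meV
  if (all(g == 0)) abort("All widths are zero; nothing to fit.")
  if (any(g < 0)) abort("Widths must be non-negative.")
  err <- curve$hwhm_err
  w <- if (!is.null(err) && all(is.finite(err)) && all(err > 0)) 1 / err^2
       else rep(1, n)
  q2 <- curve$q2

  # Fickian fit Gamma = hbar * d * q2 (closed form weighted LS; d in A^2/ps)
  d_lin <- sum(w * g * q2) / (HBAR_MEV_PS * sum(w * q2^2))
  rss_lin <- sum(w * (HBAR_MEV_PS * d_lin * q2 - g)^2)

  resid_fn <- function(p) sqrt(w) * (HBAR_MEV_PS * p[1] * q2 / (1 + p[1] * q2 * p[2]) - g)
  # plateau-based initialization for tau
  g_hi <- g[which.max(q2)]
  tau0 <- if (g_hi > 0 && HBAR_MEV_PS * d_lin * max(q2) > g_hi) {
    (HBAR_MEV_PS * d_lin * max(q2) / g_hi - 1) / (d_lin * max(q2))
  } else 0.1
  jump <- suppressWarnings(minpack.lm::nls.lm(
    par = c(max(d_lin, 1e-8), max(tau0, 1e-3)), fn = resid_fn,
    lower = c(0, 0), upper = c(Inf, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500)))
  rss_jump <- jump$deviance

  f_pvalue <- NA_real_
  if (n > 2 && rss_jump > 0) {
    fstat <- (rss_lin - rss_jump) / (rss_jump / (n - 2))
    f_pvalue <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  } else if (rss_jump == 0 && rss_lin > 0) {
    f_pvalue <- 0
  }

  tau_free <- switch(tau,
    free = TRUE,
    zero = FALSE,
    auto = is.finite(f_pvalue) && f_pvalue < 0.05)

  if (tau_free) {
    d_hat <- jump$par[1]; tau_hat <- jump$par[2]
    J <- numeric_jacobian(resid_fn, jump$par)
    cov <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    se <- if (is.null(cov)) c(NA_real_, NA_real_) else sqrt(pmax(diag(cov), 0))
    rss <- rss_jump; n_free <- 2
  } else {
    d_hat <- d_lin; tau_hat <- 0
    se_d <- 1 / sqrt(HBAR_MEV_PS^2 * sum(w * q2^2))
    se <- c(se_d, 0)
    rss <- rss_lin; n_free <- 1
  }

  structure(
    list(d_t = d_hat / CM2S_TO_A2PS,
         tau_ps = tau_hat,
         stderr = c(d_t = se[1] / CM2S_TO_A2PS, tau_ps = se[2]),
         tau_free = tau_free,
         f_pvalue = f_pvalue,
         chi2_reduced = rss / max(n - n_free, 1),
         n_points = n,
         curve = curve),
    class = "qens_jump_fit"
  )
}

#' @export
print.qens_jump_fit <- function(x, ...) {
  cat(sprintf("<qens_jump_fit> D_T = %.4g cm^2/s, tau = %.4g ps%s, chi2_red = %.3g\n",
              x$d_t, x$tau_ps,
              if (x$tau_free) "" else " (held at 0: no significant curvature)",
              x$chi2_reduced))
  invisible(x)
}

#' @method tidy qens_jump_fit
#' @export
tidy.qens_jump_fit <- function(x, ...) {
  tibble(
    term = c("d_t", "tau_ps"),
    estimate = c(x$d_t, x$tau_ps),
    std.error = unname(x$stderr),
    unit = c("cm2/s", "ps"),
    fixed = c(FALSE, !x$tau_free)
  )
}

#' @method glance qens_jump_fit
#' @export
glance.qens_jump_fit <- function(x, ...) {
  tibble(chi2_reduced = x$chi2_reduced, n_points = x$n_points,
         tau_free = x$tau_free, f_pvalue = x$f_pvalue)
}

#' Evaluate a fitted jump-diffusion dispersion law
#'
#' @param fit a `qens_jump_fit`.
#' @param q momentum transfers, 1/Angstrom.
#' @return HWHM in meV.
#' @export
predict_jump_hwhm <- function(fit, q) {
  jump_diffusion_hwhm(fit$d_t, fit$tau_ps, q)
}
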