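#' Lorentzian line shape
#'
#' Unit-area Lorentzian \eqn{(1/\pi)\,\Gamma / ((\omega - \omega_0)^2 +
#' \Gamma^2)} with half width at half maximum \eqn{\Gamma}. Each diffusive
#' motion contributes one such quasi-elastic line to the structure factor.
#'
#' @param energy_meV energy-transfer values, meV.
#' @param hwhm_meV half width at half maximum, meV (> 0).
#' @param center line center, meV.
#' @return numeric vector of intensities (1/meV); the analytic area over the
#'   whole real line is 1.
#' @examples
#' lorentzian(seq(-1, 1, by = 0.01), hwhm_meV = 0.1)
#' @export
lorentzian <- function(energy_meV, hwhm_meV, center = 0) {
  if (!is.numeric(hwhm_meV) || length(hwhm_meV) != 1 || !is.finite(hwhm_meV) ||
      hwhm_meV <= 0) {
    abort("`hwhm_meV` must be a single positive number.")
  }
  (hwhm_meV / pi) / ((energy_meV - center)^2 + hwhm_meV^2)
}

#' Voigt line shape
#'
#' Convolution of a unit-area Lorentzian of HWHM `hwhm_meV` with a unit-area
#' Gaussian of full width `fwhm_gauss_meV`, evaluated analytically through the
#' Faddeeva function. This is the closed form of every resolution-broadened
#' quasi-elastic component when the resolution is Gaussian.
#'
#' @inheritParams lorentzian
#' @param fwhm_gauss_meV Gaussian full width at half maximum, meV; `0` falls
#'   back to the bare Lorentzian.
#' @return numeric vector of intensities (1/meV), unit analytic area.
#' @export
voigt_profile <- function(energy_meV, hwhm_meV, fwhm_gauss_meV, center = 0) {
  if (hwhm_meV < 0) abort("`hwhm_meV` must be non-negative.")
  if (fwhm_gauss_meV < 0) abort("`fwhm_gauss_meV` must be non-negative.")
  if (fwhm_gauss_meV == 0) return(lorentzian(energy_meV, hwhm_meV, center))
  sigma <- fwhm_to_sigma(fwhm_gauss_meV)
  if (hwhm_meV == 0) return(dnorm(energy_meV, mean = center, sd = sigma))
  z <- ((energy_meV - center) + 1i * hwhm_meV) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

#' Jump-diffusion dispersion law
#'
#' HWHM of the translational quasi-elastic line under the jump-diffusion
#' (Singwi–Sjölander) model,
#' \eqn{\Gamma(Q) = \hbar D Q^2 / (1 + D Q^2 \tau)}: linear in \eqn{Q^2} with
#' slope \eqn{\hbar D} at low Q, saturating at the plateau
#' \eqn{\Gamma_\infty = \hbar/\tau} at high Q. With `tau_ps = 0` it reduces to
#' Fickian (Brownian) diffusion.
#'
#' @param d_t translational diffusion coefficient, cm^2/s.
#' @param tau_ps residence time, ps.
#' @param q momentum-transfer modulus (vector allowed), 1/Angstrom.
#' @return HWHM in meV, same length as `q`.
#' @examples
#' jump_diffusion_hwhm(1.98e-5, 1.05, q = c(0.2, 0.5, 1.1))
#' @export
jump_diffusion_hwhm <- function(d_t, tau_ps, q) {
  if (!is.numeric(d_t) || length(d_t) != 1 || d_t < 0) {
    abort("`d_t` must be a single non-negative number (cm^2/s).")
  }
  if (!is.numeric(tau_ps) || length(tau_ps) != 1 || tau_ps < 0) {
    abort("`tau_ps` must be a single non-negative number (ps).")
  }
  if (any(q < 0)) abort("`q` must be non-negative.")
  d <- d_t * CM2S_TO_A2PS            # A^2/ps
  dq2 <- d * q^2
  HBAR_MEV_PS * dq2 / (1 + dq2 * tau_ps)
}

# Spherical Bessel function of the first kind j_l(x), via half-integer-order
# Bessel J. Stable for the small orders (l <= ~10) used here.
sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    out[pos] <- sqrt(pi / (2 * x[pos])) * besselJ(x[pos], l + 0.5)
  }
  if (any(!pos)) out[!pos] <- if (l == 0) 1 else 0
  out
}

#' Rotational (isotropic rotational diffusion) line weights
#'
#' Weights of the rotational expansion of a scatterer on a sphere of radius
#' `radius_A`: \eqn{w_l(Q) = (2l+1)\, j_l^2(Q a)} for \eqn{l = 0 \dots
#' l_{max}}, where \eqn{j_l} is the spherical Bessel function. The \eqn{l = 0}
#' term is the elastic (purely translational) channel; term \eqn{l} carries a
#' Lorentzian of HWHM \eqn{\hbar\, l(l+1)\, D_R}. The full series sums to 1.
#'
#' @param q momentum transfer, 1/Angstrom (scalar).
#' @param radius_A rotation radius, Angstrom.
#' @param l_max highest order retained.
#' @return numeric vector of length `l_max + 1` with names `l0`, `l1`, ...
#' @examples
#' rotational_weights(1.0, 0.98, l_max = 5)
#' @export
rotational_weights <- function(q, radius_A = 0.98, l_max = 5L) {
  if (q < 0) abort("`q` must be non-negative.")
  if (radius_A <= 0) abort("`radius_A` must be positive.")
  if (l_max < 0) abort("`l_max` must be >= 0.")
  x <- q * radius_A
  l <- 0:l_max
  w <- vapply(l, function(ll) (2 * ll + 1) * sph_bessel_j(ll, x)^2, numeric(1))
  names(w) <- paste0("l", l)
  w
}

# Smallest l_max whose discarded tail weight is below `tail_tol`, capped.
choose_l_max <- function(q, radius_A, tail_tol = 1e-4, l_cap = 10L) {
  for (lm in 0:l_cap) {
    if (1 - sum(rotational_weights(q, radius_A, lm)) < tail_tol) return(lm)
  }
  l_cap
}

# Truncated, tail-renormalized rotational weights, memoised on (q, radius):
# they do not depend on any fitted parameter, and the fitters re-evaluate
# the model thousands of times at the same Q values.
.rot_cache <- new.env(parent = emptyenv())

rot_weights_cached <- function(q, radius_A) {
  key <- sprintf("%.12g|%.12g", q, radius_A)
  w <- .rot_cache[[key]]
  if (is.null(w)) {
    lm <- choose_l_max(q, radius_A)
    w <- rotational_weights(q, radius_A, lm)
    w <- unname(w / sum(w))
    .rot_cache[[key]] <- w
  }
  w
}

# One water population at one Q as a table of Lorentzian lines:
# weight w_l(Q) and HWHM Gamma_T(Q) + hbar l(l+1) D_R. The translational and
# rotational convolution is exact by Lorentzian width addition. Lines with
# zero width (no translation and l = 0) are delta functions and flagged so
# that callers can route them to the elastic channel.
water_lines <- function(water, q, l_max = NULL) {
  stopifnot(inherits(water, "qens_water"))
  gamma_t <- jump_diffusion_hwhm(water$d_t, water$tau_ps, q)
  if (water$d_r == 0) {
    return(tibble(l = 0L, weight = 1, hwhm_meV = gamma_t))
  }
  if (is.null(l_max)) {
    w <- rot_weights_cached(q, water$radius_A)
  } else {
    w <- rotational_weights(q, water$radius_A, l_max)
    # renormalize the truncated series so the population keeps unit weight
    w <- unname(w / sum(w))
  }
  l <- seq_along(w) - 1L
  tibble(l = l, weight = w,
         hwhm_meV = gamma_t + HBAR_MEV_PS * l * (l + 1) * water$d_r)
}

#' Spectrum of one water population
#'
#' Evaluates the (resolution-free) dynamic structure factor of one water
#' population at momentum transfer `q`: a jump-diffusion translational
#' Lorentzian convolved with the isotropic rotational-diffusion series. The
#' convolution is performed analytically via Lorentzian width addition, giving
#' \eqn{\sum_l w_l(Q)\, L(\omega;\, \Gamma_T(Q) + \hbar l(l+1) D_R)}.
#'
#' @param water a [water_params()] object.
#' @param q momentum transfer, 1/Angstrom.
#' @param energy_meV energy grid, meV.
#' @param l_max rotational series truncation; `NULL` (default) picks the
#'   smallest order leaving a tail weight below 1e-4 (at most 10).
#' @return numeric intensity vector, unit analytic area.
#' @export
water_component_spectrum <- function(water, q, energy_meV, l_max = NULL) {
  lines <- water_lines(water, q, l_max)
  if (all(lines$hwhm_meV == 0)) {
    return(structure(list(q = q), class = "qens_delta_marker"))
  }
  zero <- lines$hwhm_meV == 0
  if (any(zero)) {
    warn("Zero-width water line dropped; its weight belongs to the elastic channel.")
    lines <- lines[!zero, , drop = FALSE]
  }
  out <- numeric(length(energy_meV))
  for (i in seq_len(nrow(lines))) {
    out <- out + lines$weight[i] * lorentzian(energy_meV, lines$hwhm_meV[i])
  }
  out
}

#' Is an object the delta-function marker?
#'
#' [water_component_spectrum()] returns this marker instead of a zero-width
#' Lorentzian when a population has neither translational nor rotational
#' motion; the caller must route its weight to the elastic channel.
#'
#' @param x object to test.
#' @export
is_delta_marker <- function(x) inherits(x, "qens_delta_marker")

# All quasi-elastic Lorentzian lines of the cell model at one Q, as plain
# numeric vectors (this sits inside the fitters' hot loop): fraction-weighted
# line weights and HWHMs, plus the elastic weight (p_elastic and any
# delta-like water lines routed to the elastic channel).
cell_model_lines <- function(p_elastic, p_bulk, p_hyd, p_proteome,
                             bulk, hyd, gamma_proteome_meV, q, l_max = NULL) {
  elastic <- p_elastic
  weight <- numeric(0)
  hwhm <- numeric(0)
  for (comp in list(list(p = p_bulk, w = bulk), list(p = p_hyd, w = hyd))) {
    if (comp$p == 0) next
    wl <- comp$w
    gamma_t <- jump_diffusion_hwhm(wl$d_t, wl$tau_ps, q)
    if (wl$d_r == 0) {
      w <- 1
      g <- gamma_t
    } else {
      w <- if (is.null(l_max)) rot_weights_cached(q, wl$radius_A) else {
        wr <- rotational_weights(q, wl$radius_A, l_max)
        unname(wr / sum(wr))
      }
      l <- seq_along(w) - 1L
      g <- gamma_t + HBAR_MEV_PS * l * (l + 1) * wl$d_r
    }
    zero <- g <= 0
    if (any(zero)) {
      elastic <- elastic + comp$p * sum(w[zero])
      w <- w[!zero]; g <- g[!zero]
    }
    weight <- c(weight, comp$p * w)
    hwhm <- c(hwhm, g)
  }
  if (p_proteome > 0) {
    weight <- c(weight, p_proteome)
    hwhm <- c(hwhm, gamma_proteome_meV)
  }
  list(elastic = elastic, weight = weight, hwhm = hwhm)
}

#' Four-component cell model spectrum
#'
#' Evaluates the full resolution-convolved structure factor of the cell model
#' at one Q:
#' \deqn{S(Q,\omega) = p_{el} R(\omega) + [\,p_{bulk} S_1 + p_{hyd} S_2 +
#'   p_{prot} S_3\,] \otimes R + B(Q),}
#' where \eqn{S_1, S_2} are the two water populations (jump diffusion plus
#' free rotation), \eqn{S_3} is the Q-independent proteome Lorentzian and `R`
#' the instrument resolution. For a Gaussian resolution every Lorentzian
#' \eqn{\otimes} Gaussian is evaluated analytically as a Voigt profile and the
#' elastic delta function becomes exactly `p_elastic * R`; for a tabulated
#' resolution the convolution is numeric on the (uniform) grid.
#'
#' @param params a [cell_params()] object (fractions summing to 1).
#' @param q momentum transfer, 1/Angstrom.
#' @param energy_meV energy grid, meV (strictly increasing, >= 32 points,
#'   containing 0 in its range).
#' @param resolution a [resolution_gaussian()] or [resolution_tabulated()].
#' @param l_max optional rotational truncation override.
#' @return numeric intensity vector on `energy_meV`.
#' @examples
#' pars <- scenario_params("Tb_0.1MPa")
#' omega <- seq(-1.5, 1.5, length.out = 301)
#' s <- composite_model(pars, q = 0.75, omega, resolution_gaussian(0.010))
#' @export
composite_model <- function(params, q, energy_meV, resolution, l_max = NULL) {
  stopifnot(is_cell_params(params))
  validate_energy_grid(energy_meV)
  cm <- cell_model_lines(params$p_elastic, params$p_bulk, params$p_hyd,
                         params$p_proteome, params$bulk, params$hyd,
                         params$gamma_proteome_meV, q, l_max)
  bg <- background_at(params, q)
  quasi <- numeric(length(energy_meV))
  if (resolution$kind == "gaussian") {
    fw <- resolution$fwhm_meV
    for (i in seq_along(cm$weight)) {
      quasi <- quasi + cm$weight[i] * voigt_profile(energy_meV, cm$hwhm[i], fw)
    }
  } else {
    for (i in seq_along(cm$weight)) {
      quasi <- quasi + cm$weight[i] * lorentzian(energy_meV, cm$hwhm[i])
    }
    quasi <- convolve_with_resolution(quasi, energy_meV, resolution)
  }
  cm$elastic * resolution_profile(resolution, energy_meV) + quasi + bg
}

validate_energy_grid <- function(energy_meV) {
  if (length(energy_meV) < 32) abort("Energy grid needs at least 32 points.")
  if (any(diff(energy_meV) <= 0)) abort("Energy grid must be strictly increasing.")
  if (min(energy_meV) > 0 || max(energy_meV) < 0) {
    abort("Energy grid must contain 0 within its range.")
  }
  invisible(energy_meV)
}

# Vectorized evaluation of the cell model over many Q slices with a Gaussian
# resolution: all Lorentzian lines of all slices go through one Faddeeva call.
# Returns a length(energy) x length(qs) matrix. Used by the fitters, where
# this evaluation dominates the run time.
composite_model_matrix <- function(p_elastic, p_bulk, p_hyd, p_proteome,
                                   bulk, hyd, gamma_proteome_meV,
                                   backgrounds, qs, energy_meV, resolution) {
  nq <- length(qs)
  ne <- length(energy_meV)
  out <- matrix(0, nrow = ne, ncol = nq)
  if (resolution$kind != "gaussian") {
    # fall back on the scalar path
    for (j in seq_len(nq)) {
      cm <- cell_model_lines(p_elastic, p_bulk, p_hyd, p_proteome,
                             bulk, hyd, gamma_proteome_meV, qs[j])
      quasi <- numeric(ne)
      for (i in seq_along(cm$weight)) {
        quasi <- quasi + cm$weight[i] * lorentzian(energy_meV, cm$hwhm[i])
      }
      out[, j] <- cm$elastic * resolution_profile(resolution, energy_meV) +
        convolve_with_resolution(quasi, energy_meV, resolution) + backgrounds[j]
    }
    return(out)
  }
  sigma <- fwhm_to_sigma(resolution$fwhm_meV)
  weights <- list(); hwhms <- list(); slice <- list(); elastic <- numeric(nq)
  for (j in seq_len(nq)) {
    cm <- cell_model_lines(p_elastic, p_bulk, p_hyd, p_proteome,
                           bulk, hyd, gamma_proteome_meV, qs[j])
    elastic[j] <- cm$elastic
    weights[[j]] <- cm$weight
    hwhms[[j]] <- cm$hwhm
    slice[[j]] <- rep.int(j, length(cm$weight))
  }
  w <- unlist(weights); g <- unlist(hwhms); sl <- unlist(slice)
  nl <- length(g)
  if (nl) {
    z <- (rep(energy_meV, times = nl) + 1i * rep(g, each = ne)) / (sigma * sqrt(2))
    v <- matrix(Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi)), nrow = ne)
    vw <- sweep(v, 2, w, `*`)
    for (j in seq_len(nq)) {
      cols <- which(sl == j)
      out[, j] <- if (length(cols) == 1) vw[, cols] else rowSums(vw[, cols, drop = FALSE])
    }
  }
  rprof <- dnorm(energy_meV, sd = sigma)
  out + outer(rprof, elastic) + rep(backgrounds, each = ne)
}

#' Area-normalize spectra
#'
#' Scales each Q slice to unit trapezoidal area over its measured energy
#' window, dividing the uncertainties by the same factor. Normalizing per
#' spectrum removes overall intensity factors (e.g. Debye–Waller attenuation,
#' detector efficiency), so that only line shapes and relative proportions are
#' fitted.
#'
#' @param spectra a tidy spectrum table with columns `q`, `energy_meV`,
#'   `intensity`, `sigma` (see [generate_spectra()] / [read_spectrum_set()]).
#' @return the same table with each Q slice at unit area; attributes are
#'   preserved.
#' @export
normalize_spectra <- function(spectra) {
  spectra <- validate_spectra(spectra)
  res <- attr(spectra, "resolution")
  lab <- attr(spectra, "label")
  out <- spectra |>
    dplyr::group_by(.data$q) |>
    dplyr::group_modify(function(df, key) {
      area <- pracma::trapz(df$energy_meV, df$intensity)
      if (!is.finite(area) || area <= 0) {
        abort(sprintf("Spectrum at q = %g has non-positive area; cannot normalize.",
                      key$q))
      }
      df$intensity <- df$intensity / area
      df$sigma <- df$sigma / area
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("q")
  as_qens_spectra(out, resolution = res, label = lab)
}
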