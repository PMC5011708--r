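#' Water component parameters
#'
#' Parameters of one mobile water population: translational jump diffusion
#' (Singwi–Sjölander) characterized by a diffusion coefficient `d_t` and a
#' residence time `tau_ps`, convolved with isotropic rotational diffusion of
#' coefficient `d_r` on a sphere of radius `radius_A`.
#'
#' @param d_t translational diffusion coefficient, cm^2/s.
#' @param tau_ps residence time between diffusive jumps, ps; `0` means pure
#'   Fickian diffusion.
#' @param d_r rotational diffusion coefficient, 1/ps; `0` switches rotation off.
#' @param radius_A rotation radius, Angstrom. Defaults to 0.98, the water O–H
#'   distance.
#' @return an object of class `qens_water`.
#' @examples
#' water_params(d_t = 1.98e-5, tau_ps = 1.05, d_r = 0.11)
#' @export
water_params <- function(d_t, tau_ps = 0, d_r = 0, radius_A = 0.98) {
  for (nm in c("d_t", "tau_ps", "d_r", "radius_A")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (d_t < 0 || tau_ps < 0 || d_r < 0) {
    abort("`d_t`, `tau_ps` and `d_r` must be non-negative.")
  }
  if (radius_A <= 0) abort("`radius_A` must be positive.")
  structure(
    list(d_t = d_t, tau_ps = tau_ps, d_r = d_r, radius_A = radius_A),
    class = "qens_water"
  )
}

#' @export
print.qens_water <- function(x, ...) {
  cat(sprintf(
    "<qens_water> D_T = %.4g cm^2/s, tau = %.4g ps, D_R = %.4g 1/ps, a = %.3g A\n",
    x$d_t, x$tau_ps, x$d_r, x$radius_A))
  invisible(x)
}

#' Full cell-model parameter set
#'
#' The parameter vector of the four-component structure factor used for live
#' cells: an elastic fraction, bulk water, hydration water (each a
#' [water_params()] object) and a broad Q-independent "proteome" Lorentzian,
#' plus a flat per-Q background. The four fractions must sum to 1 (within
#' 1e-9): they are proportions of the scattering hydrogens.
#'
#' @param p_elastic,p_bulk,p_hyd,p_proteome fractions in `[0, 1]` summing to 1.
#' @param bulk,hyd [water_params()] for the two water populations.
#' @param gamma_proteome_meV HWHM of the proteome Lorentzian, meV.
#' @param background flat background level(s): a single number applied at every
#'   Q, or a numeric vector named by Q value (as formatted by `format()`).
#' @return an object of class `qens_cell_params`.
#' @examples
#' cell_params(
#'   p_elastic = 0.01, p_bulk = 0.66, p_hyd = 0.10, p_proteome = 0.23,
#'   bulk = water_params(1.98e-5, 1.05, 0.11),
#'   hyd = water_params(5.17e-7, 0, 0.06),
#'   gamma_proteome_meV = 0.431
#' )
#' @export
cell_params <- function(p_elastic, p_bulk, p_hyd, p_proteome,
                        bulk, hyd, gamma_proteome_meV, background = 0) {
  p <- c(p_elastic, p_bulk, p_hyd, p_proteome)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("All fractions must lie in [0, 1].")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf(
      "Fractions must sum to 1 within 1e-9 (got %.12f). Renormalize first.",
      sum(p)))
  }
  if (!inherits(bulk, "qens_water") || !inherits(hyd, "qens_water")) {
    abort("`bulk` and `hyd` must be water_params() objects.")
  }
  if (!is.numeric(gamma_proteome_meV) || length(gamma_proteome_meV) != 1 ||
      gamma_proteome_meV <= 0) {
    abort("`gamma_proteome_meV` must be a single positive number.")
  }
  if (any(background < 0)) abort("Backgrounds must be non-negative.")
  structure(
    list(p_elastic = p_elastic, p_bulk = p_bulk, p_hyd = p_hyd,
         p_proteome = p_proteome, bulk = bulk, hyd = hyd,
         gamma_proteome_meV = gamma_proteome_meV,
         background = background),
    class = "qens_cell_params"
  )
}

is_cell_params <- function(x) inherits(x, "qens_cell_params")

#' @export
print.qens_cell_params <- function(x, ...) {
  cat("<qens_cell_params>\n")
  cat(sprintf("  fractions: elastic %.3f | bulk %.3f | hyd %.3f | proteome %.3f\n",
              x$p_elastic, x$p_bulk, x$p_hyd, x$p_proteome))
  cat(sprintf("  bulk:  D_T %.4g cm^2/s, tau %.3g ps, D_R %.3g 1/ps\n",
              x$bulk$d_t, x$bulk$tau_ps, x$bulk$d_r))
  cat(sprintf("  hyd:   D_T %.4g cm^2/s, tau %.3g ps, D_R %.3g 1/ps\n",
              x$hyd$d_t, x$hyd$tau_ps, x$hyd$d_r))
  cat(sprintf("  proteome: Gamma %.4g meV\n", x$gamma_proteome_meV))
  invisible(x)
}

# Flat background level for one Q slice; `background` may be scalar or a
# vector named by formatted Q values.
background_at <- function(params, q) {
  b <- params$background
  if (length(b) == 1 && is.null(names(b))) return(unname(b))
  nm <- format(q)
  if (!is.null(names(b)) && nm %in% names(b)) return(unname(b[[nm]]))
  unname(b[[1]])
}

#' Tidy a cell-model parameter set
#'
#' Returns the parameters as one row per term in the conventional reporting
#' units: fractions dimensionless, `d_t_bulk` in 1e-5 cm^2/s, `d_t_hyd` in
#' 1e-7 cm^2/s, residence times in ps, rotational coefficients in 1/ps,
#' `gamma_proteome` in meV.
#'
#' @param x a `qens_cell_params` object.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `unit`.
#' @method tidy qens_cell_params
#' @export
tidy.qens_cell_params <- function(x, ...) {
  tibble(
    term = c("p_elastic", "p_hyd", "p_bulk", "p_proteome",
             "d_t_bulk", "tau_bulk", "d_r_bulk",
             "d_t_hyd", "tau_hyd", "d_r_hyd", "gamma_proteome"),
    estimate = c(x$p_elastic, x$p_hyd, x$p_bulk, x$p_proteome,
                 x$bulk$d_t / 1e-5, x$bulk$tau_ps, x$bulk$d_r,
                 x$hyd$d_t / 1e-7, x$hyd$tau_ps, x$hyd$d_r,
                 x$gamma_proteome_meV),
    unit = c("", "", "", "",
             "1e-5 cm2/s", "ps", "1/ps",
             "1e-7 cm2/s", "ps", "1/ps", "meV")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
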