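# Global weighted least-squares fit of the four-component cell model over all
# (Q, omega) points of a spectrum set.
#
# Shared across Q: the three free fractions (p_bulk is derived from the sum
# constraint), both water parameter triplets, and Gamma_proteome. Per Q: one
# flat background. Both the data and the model prediction are area-normalized
# per Q slice over the measured window, so that only line shapes and relative
# proportions are compared; this mirrors the per-spectrum normalization
# applied to measured data and makes the fractions well defined despite the
# finite energy window.

.shared_par_names <- c("p_elastic", "p_hyd", "p_proteome",
                       "d_t_bulk", "tau_bulk", "d_r_bulk",
                       "d_t_hyd", "tau_hyd", "d_r_hyd", "gamma_proteome")

.par_units <- c(
  p_elastic = "", p_hyd = "", p_bulk = "", p_proteome = "",
  d_t_bulk = "1e-5 cm2/s", tau_bulk = "ps", d_r_bulk = "1/ps",
  d_t_hyd = "1e-7 cm2/s", tau_hyd = "ps", d_r_hyd = "1/ps",
  gamma_proteome = "meV")

#' Default starting values and box bounds for the global fit
#'
#' Starting values reflect the typical composition of a cell pellet (about
#' two thirds bulk-like water, a tenth hydration water, a quarter
#' biomolecules) and the pure-water diffusion coefficient 2.3e-5 cm^2/s;
#' bounds span roughly an order of magnitude around published whole-cell
#' values. `d_t_bulk` is expressed in 1e-5 cm^2/s, `d_t_hyd` in 1e-7 cm^2/s
#' (the natural magnitudes of the two populations); times in ps, rotational
#' coefficients in 1/ps, widths in meV.
#'
#' @return a named numeric vector (`default_global_init`) or a list with
#'   `lower` and `upper` named vectors (`default_global_bounds`).
#' @export
default_global_init <- function() {
  c(p_elastic = 0.02, p_hyd = 0.12, p_proteome = 0.21,
    d_t_bulk = 2.3, tau_bulk = 1.0, d_r_bulk = 0.10,
    d_t_hyd = 5.0, tau_hyd = 0.0, d_r_hyd = 0.05, gamma_proteome = 0.4)
}

#' @rdname default_global_init
#' @export
default_global_bounds <- function() {
  list(
    lower = c(p_elastic = 0, p_hyd = 0, p_proteome = 0,
              d_t_bulk = 0.5, tau_bulk = 0, d_r_bulk = 0,
              d_t_hyd = 0.5, tau_hyd = 0, d_r_hyd = 0, gamma_proteome = 0.05),
    upper = c(p_elastic = 1, p_hyd = 1, p_proteome = 1,
              d_t_bulk = 5, tau_bulk = 10, d_r_bulk = 1,
              d_t_hyd = 50, tau_hyd = 10, d_r_hyd = 1, gamma_proteome = 2)
  )
}

cell_params_to_vector <- function(params) {
  c(p_elastic = params$p_elastic, p_hyd = params$p_hyd,
    p_proteome = params$p_proteome,
    d_t_bulk = params$bulk$d_t / 1e-5, tau_bulk = params$bulk$tau_ps,
    d_r_bulk = params$bulk$d_r,
    d_t_hyd = params$hyd$d_t / 1e-7, tau_hyd = params$hyd$tau_ps,
    d_r_hyd = params$hyd$d_r,
    gamma_proteome = params$gamma_proteome_meV)
}

vector_to_cell_params <- function(theta, backgrounds = 0, radius_A = 0.98) {
  p_bulk <- 1 - theta[["p_elastic"]] - theta[["p_hyd"]] - theta[["p_proteome"]]
  cell_params(
    p_elastic = theta[["p_elastic"]], p_bulk = p_bulk,
    p_hyd = theta[["p_hyd"]], p_proteome = theta[["p_proteome"]],
    bulk = water_params(theta[["d_t_bulk"]] * 1e-5, theta[["tau_bulk"]],
                        theta[["d_r_bulk"]], radius_A),
    hyd = water_params(theta[["d_t_hyd"]] * 1e-7, theta[["tau_hyd"]],
                       theta[["d_r_hyd"]], radius_A),
    gamma_proteome_meV = theta[["gamma_proteome"]],
    background = backgrounds
  )
}

# Model matrix (ne x nq), area-normalized per Q slice, from the full
# parameter vector theta = (shared, bg_1..bg_nq).
.global_model_matrix <- function(theta, qs, grid, resolution, radius_A) {
  p_el <- theta[["p_elastic"]]; p_hyd <- theta[["p_hyd"]]
  p_prot <- theta[["p_proteome"]]
  p_bulk <- 1 - p_el - p_hyd - p_prot
  if (p_bulk < 0) return(NULL)
  bgs <- theta[grepl("^bg_", names(theta))]
  bulk <- water_params(theta[["d_t_bulk"]] * 1e-5, theta[["tau_bulk"]],
                       theta[["d_r_bulk"]], radius_A)
  hyd <- water_params(theta[["d_t_hyd"]] * 1e-7, theta[["tau_hyd"]],
                      theta[["d_r_hyd"]], radius_A)
  m <- composite_model_matrix(p_el, p_bulk, p_hyd, p_prot, bulk, hyd,
                              theta[["gamma_proteome"]], unname(bgs),
                              qs, grid, resolution)
  areas <- as.numeric(crossprod(m, trapz_weights(grid)))
  sweep(m, 2, areas, `/`)
}

# Quadrature weights such that sum(w * y) is the trapezoidal integral of y
# over the (possibly non-uniform) grid.
trapz_weights <- function(grid) {
  n <- length(grid)
  h <- diff(grid)
  c(h[1] / 2, (h[-1] + h[-(n - 1)]) / 2, h[n - 1] / 2)
}

#' Global fit of the four-component cell model
#'
#' Simultaneous weighted least squares over every (Q, energy) point of a
#' spectrum set. The fractions, both water components and the proteome width
#' are shared across Q; one flat background is fitted per Q slice. The
#' fraction-sum constraint is enforced by fitting `p_elastic`, `p_hyd`,
#' `p_proteome` and deriving `p_bulk = 1 - sum`. Optimization uses
#' Levenberg–Marquardt with box bounds and a seeded multi-start (the supplied
#' start plus jittered copies), keeping the best final cost; standard errors
#' come from the inverse weighted normal-equations curvature at the optimum.
#'
#' @param spectra a [as_qens_spectra()] tibble; it is area-normalized per Q
#'   internally before fitting.
#' @param init starting values: a [cell_params()] object, a named vector in
#'   the units of [default_global_init()], or `NULL` for the defaults.
#' @param fixed named numeric vector of parameters to hold fixed at the given
#'   values (same units as `init`). Default holds the hydration residence
#'   time at 0, which is not identifiable over a restricted Q range.
#' @param bounds list with `lower`/`upper` named vectors; defaults from
#'   [default_global_bounds()].
#' @param n_starts number of multi-starts (first = `init`, rest jittered by
#'   up to ±20%, log-uniform, seeded); at most 5.
#' @param seed RNG seed controlling the jitter (reproducible bit-for-bit).
#' @param resolution instrument resolution; defaults to the one attached to
#'   `spectra`.
#' @param radius_A rotation radius used for both water components.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `qens_fit`; see [tidy.qens_fit()],
#'   [glance.qens_fit()], [derived_quantities()], [autoplot.qens_fit()].
#' @examples
#' \donttest{
#' set <- generate_spectra(scenario_params("Tb_0.1MPa"))
#' fit <- fit_global(set, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_global <- function(spectra, init = NULL, fixed = c(tau_hyd = 0),
                       bounds = default_global_bounds(),
                       n_starts = 3, seed = 1,
                       resolution = attr(spectra, "resolution"),
                       radius_A = 0.98,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10,
                         maxiter = 200, maxfev = 100000)) {
  if (is.null(resolution)) abort("No resolution attached to `spectra`; pass one.")
  n_starts <- max(1L, min(5L, as.integer(n_starts)))
  spectra <- normalize_spectra(as_qens_spectra(spectra, resolution = resolution))
  qs <- spectra_q_values(spectra)
  grid <- spectra_grid(spectra)
  ord <- order(spectra$q, spectra$energy_meV)
  spectra <- spectra[ord, ]
  obs <- matrix(spectra$intensity, nrow = length(grid))
  wts <- matrix(1 / spectra$sigma, nrow = length(grid))

  if (is.null(init)) init <- default_global_init()
  if (is_cell_params(init)) init <- cell_params_to_vector(init)
  theta0 <- default_global_init()
  theta0[names(init)[names(init) %in% names(theta0)]] <-
    init[names(init) %in% names(theta0)]
  bg0 <- setNames(rep(0, length(qs)), paste0("bg_", seq_along(qs)))
  theta0 <- c(theta0, bg0)

  lower <- c(bounds$lower, setNames(rep(0, length(qs)), names(bg0)))
  upper <- c(bounds$upper, setNames(rep(10, length(qs)), names(bg0)))
  lower <- lower[names(theta0)]; upper <- upper[names(theta0)]

  fixed <- fixed[names(fixed) %in% names(theta0)]
  theta0[names(fixed)] <- fixed
  free_names <- setdiff(names(theta0), names(fixed))

  resid_fn <- function(free) {
    theta <- theta0
    theta[free_names] <- free
    m <- .global_model_matrix(theta, qs, grid, resolution, radius_A)
    if (is.null(m)) {
      pb <- 1 - theta[["p_elastic"]] - theta[["p_hyd"]] - theta[["p_proteome"]]
      return(rep(1e3 * (1 - pb), length(obs)))
    }
    as.numeric((m - obs) * wts)
  }

  starts <- list(theta0[free_names])
  if (n_starts > 1) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        v <- theta0[free_names] *
          exp(stats::runif(length(free_names), -1, 1) * log(1.2))
        pmin(pmax(v, lower[free_names]), upper[free_names])
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  trace <- list()
  n_evaluations <- 0L
  for (k in seq_along(starts)) {
    fit_k <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[[k]], fn = resid_fn,
                           lower = lower[free_names],
                           upper = upper[free_names],
                           control = control)),
      error = function(e) NULL)
    if (is.null(fit_k)) {
      trace[[k]] <- tibble(start = k, deviance = NA_real_, converged = FALSE)
      next
    }
    n_evaluations <- n_evaluations + fit_k$niter
    conv_k <- fit_k$info %in% 1:3
    trace[[k]] <- tibble(start = k, deviance = fit_k$deviance, converged = conv_k)
    if (is.null(best) || fit_k$deviance < best$deviance) best <- fit_k
    # a numerically perfect fit cannot be improved upon by further starts
    if (fit_k$deviance / length(obs) < 1e-8) break
  }
  if (is.null(best)) {
    abort("Global fit failed in every start (optimizer error).")
  }

  theta_hat <- theta0
  theta_hat[free_names] <- best$par
  n_free <- length(free_names)
  n_points <- length(obs)
  chi2_reduced <- best$deviance / (n_points - n_free)

  J <- numeric_jacobian(resid_fn, best$par)
  cov <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  stderr_free <- if (is.null(cov)) setNames(rep(NA_real_, n_free), free_names)
                 else setNames(sqrt(pmax(diag(cov), 0)), free_names)
  stderr <- setNames(rep(NA_real_, length(theta_hat)), names(theta_hat))
  stderr[free_names] <- stderr_free
  stderr[names(fixed)] <- 0

  # derived bulk fraction and its error by linear propagation
  p_bulk <- 1 - theta_hat[["p_elastic"]] - theta_hat[["p_hyd"]] -
    theta_hat[["p_proteome"]]
  se_p_bulk <- NA_real_
  if (!is.null(cov)) {
    fr <- intersect(c("p_elastic", "p_hyd", "p_proteome"), free_names)
    if (length(fr)) {
      idx <- match(fr, free_names)
      se_p_bulk <- sqrt(max(sum(cov[idx, idx]), 0))
    } else se_p_bulk <- 0
  }

  at_bound <- (abs(theta_hat[free_names] - lower[free_names]) < 1e-8 &
                 lower[free_names] != 0) |
              abs(theta_hat[free_names] - upper[free_names]) < 1e-8
  if (any(at_bound)) {
    warn(paste0("Parameter(s) pinned at a bound: ",
                paste(free_names[at_bound], collapse = ", ")))
  }

  bgs <- setNames(theta_hat[grepl("^bg_", names(theta_hat))], format(qs))
  params_hat <- vector_to_cell_params(theta_hat, backgrounds = bgs,
                                      radius_A = radius_A)

  m_hat <- .global_model_matrix(theta_hat, qs, grid, resolution, radius_A)
  res_mat <- (m_hat - obs) * wts
  per_q <- tibble(
    q = qs,
    n = length(grid),
    rss = colSums(res_mat^2),
    chi2_reduced = colSums(res_mat^2) / length(grid)
  )

  structure(
    list(params = params_hat,
         estimates = c(theta_hat[.shared_par_names], p_bulk = unname(p_bulk),
                       theta_hat[grepl("^bg_", names(theta_hat))]),
         stderr = c(stderr[.shared_par_names], p_bulk = unname(se_p_bulk),
                    stderr[grepl("^bg_", names(stderr))]),
         fixed = fixed,
         free_names = free_names,
         at_bound = at_bound,
         chi2_reduced = unname(chi2_reduced),
         deviance = best$deviance,
         n_points = n_points,
         n_free = n_free,
         n_evaluations = n_evaluations,
         seed = seed,
         converged = best$info %in% 1:3,
         info = best$info,
         multi_start = dplyr::bind_rows(trace),
         per_q_residuals = per_q,
         data = spectra,
         resolution = resolution,
         radius_A = radius_A,
         qs = qs, grid = grid),
    class = "qens_fit"
  )
}

# Forward-difference Jacobian of a residual function, step scaled to the
# parameter magnitude.
numeric_jacobian <- function(fn, par) {
  r0 <- fn(par)
  J <- matrix(0, nrow = length(r0), ncol = length(par))
  for (i in seq_along(par)) {
    h <- 1e-6 * max(abs(par[i]), 1e-3)
    p2 <- par; p2[i] <- p2[i] + h
    J[, i] <- (fn(p2) - r0) / h
  }
  J
}

#' @export
print.qens_fit <- function(x, ...) {
  cat(sprintf("<qens_fit> %d points, %d free parameters, chi2_red = %.4g%s\n",
              x$n_points, x$n_free, x$chi2_reduced,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' Tidy a global fit
#'
#' One row per model parameter (shared parameters first, then the derived
#' `p_bulk`, then per-Q backgrounds) with curvature-based standard errors.
#'
#' @param x a `qens_fit` from [fit_global()].
#' @param backgrounds include per-Q background rows? Default `FALSE`.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`, `unit`,
#'   `fixed`, `at_bound`.
#' @method tidy qens_fit
#' @export
tidy.qens_fit <- function(x, backgrounds = FALSE, ...) {
  terms <- c(.shared_par_names, "p_bulk")
  if (backgrounds) terms <- c(terms, grep("^bg_", names(x$estimates), value = TRUE))
  ab <- setNames(rep(FALSE, length(terms)), terms)
  common <- intersect(terms, names(x$at_bound))
  ab[common] <- x$at_bound[common]
  tibble(
    term = terms,
    estimate = unname(x$estimates[terms]),
    std.error = unname(x$stderr[terms]),
    unit = unname(.par_units[sub("^bg_.*", "", terms)]) %|NA|% "",
    fixed = terms %in% names(x$fixed),
    at_bound = unname(ab)
  )
}

`%|NA|%` <- function(x, y) { x[is.na(x)] <- y; x }

#' Fit summary
#'
#' @param x a `qens_fit`.
#' @param ... unused.
#' @return a one-row tibble: reduced chi-squared, problem size, optimizer
#'   effort, convergence flag and seed.
#' @method glance qens_fit
#' @export
glance.qens_fit <- function(x, ...) {
  tibble(chi2_reduced = x$chi2_reduced, deviance = x$deviance,
         n_points = x$n_points, n_free = x$n_free,
         n_evaluations = x$n_evaluations, converged = x$converged,
         seed = x$seed)
}

#' Fitted model spectra
#'
#' Evaluates the fitted (area-normalized) model on the data grid.
#'
#' @param fit a `qens_fit`.
#' @return a tibble with columns `q`, `energy_meV`, `fitted`.
#' @export
fitted_spectra <- function(fit) {
  stopifnot(inherits(fit, "qens_fit"))
  theta <- c(cell_params_to_vector(fit$params),
             setNames(fit$estimates[grepl("^bg_", names(fit$estimates))],
                      grep("^bg_", names(fit$estimates), value = TRUE)))
  m <- .global_model_matrix(theta, fit$qs, fit$grid, fit$resolution, fit$radius_A)
  tibble(
    q = rep(fit$qs, each = length(fit$grid)),
    energy_meV = rep(fit$grid, times = length(fit$qs)),
    fitted = as.numeric(m)
  )
}
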