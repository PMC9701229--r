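#' Series coefficient recursions
#'
#' The steady-state density on one symmetric inter-kinetochore cell
#' \eqn{[-d, d]} (kinetochores at \eqn{\pm d}, cell center at 0) is expanded
#' in even powers, \eqn{\rho_f(x) = a_0 + a_2 x^2/2! + a_4 x^4/4! +
#' a_6 x^6/6!}. Substituting into the steady-state equation and matching
#' powers of \eqn{x} determines the higher coefficients from
#' \eqn{(a_0, a_2)}:
#' \deqn{a_4 = \frac{1}{\kappa M_\rho}\left(3 w M_\rho a_0^2 a_2
#'   - 2\zeta\psi M_\rho a_2 + \bar\omega_{on} - \omega_{off} a_0\right),}
#' \deqn{a_6 = \frac{2}{\kappa M_\rho}\left[w M_\rho\left(9 a_0 a_2^2 +
#'   \tfrac{3}{2} a_0^2 a_4\right) - \zeta\psi M_\rho a_4 -
#'   \tfrac{\omega_{off}}{2} a_2\right].}
#' The uniform solution \eqn{a_0 = \bar\omega_{on}/\omega_{off}},
#' \eqn{a_2 = 0} annihilates both.
#'
#' @param a0,a2,a4 lower-order coefficients
#'   (\eqn{\mu m^{-1}}, \eqn{\mu m^{-3}}, \eqn{\mu m^{-5}}).
#' @param params a [model_params()].
#' @return The next coefficient (\eqn{\mu m^{-5}} resp. \eqn{\mu m^{-7}}).
#' @export
coeff_a4 <- function(a0, a2, params) {
  with(params, (3 * w * m_rho * a0^2 * a2 - 2 * zeta * psi * m_rho * a2 +
                  omega_on_bar - omega_off * a0) / (kappa * m_rho))
}

#' @rdname coeff_a4
#' @export
coeff_a6 <- function(a0, a2, a4, params) {
  with(params, 2 / (kappa * m_rho) *
         (w * m_rho * (9 * a0 * a2^2 + 1.5 * a0^2 * a4) -
            zeta * psi * m_rho * a4 - omega_off / 2 * a2))
}

# Build a truncated solution object from the free constants.
series_solution <- function(a0, a2, params, order) {
  stopifnot(order %in% c(4L, 6L))
  a4 <- coeff_a4(a0, a2, params)
  a6 <- if (order == 6) coeff_a6(a0, a2, a4, params) else 0
  structure(list(a0 = a0, a2 = a2, a4 = a4, a6 = a6,
                 order = as.integer(order), d = params$d, params = params),
            class = "kb_series")
}

#' @export
print.kb_series <- function(x, ...) {
  cat(sprintf("Series steady state (order %d, cell half-width d = %g um):\n",
              x$order, x$d))
  cat(sprintf("  a0 = %.6g, a2 = %.6g, a4 = %.6g, a6 = %.6g\n",
              x$a0, x$a2, x$a4, x$a6))
  cat(sprintf("  rho(0) = %.5g, rho(d) = %.5g um^-1, cell mass = %.6g\n",
              eval_series(x, 0), eval_series(x, x$d), cell_mass(x)))
  invisible(x)
}

#' Evaluate the series solution
#'
#' `eval_series()` gives \eqn{\rho_f(x)} on the cell, `eval_series_deriv()`
#' and `eval_series_deriv2()` its first and second derivatives, and
#' `cell_mass()` the closed-form integral
#' \eqn{\int_{-d}^{d}\rho_f = 2(a_0 d + a_2 d^3/6 + a_4 d^5/120 +
#' a_6 d^7/5040)}.
#'
#' @param sol a `kb_series` solution.
#' @param x positions with \eqn{|x| \le d} (outside the cell is an error).
#' @return Density (\eqn{\mu m^{-1}}), derivative (\eqn{\mu m^{-2}}), second
#'   derivative (\eqn{\mu m^{-3}}), or mass (dimensionless count).
#' @export
eval_series <- function(sol, x) {
  if (any(abs(x) > sol$d + 1e-12)) stop("x outside the cell [-d, d]")
  sol$a0 + sol$a2 * x^2 / 2 + sol$a4 * x^4 / 24 + sol$a6 * x^6 / 720
}

#' @rdname eval_series
#' @export
eval_series_deriv <- function(sol, x) {
  if (any(abs(x) > sol$d + 1e-12)) stop("x outside the cell [-d, d]")
  sol$a2 * x + sol$a4 * x^3 / 6 + sol$a6 * x^5 / 120
}

#' @rdname eval_series
#' @export
eval_series_deriv2 <- function(sol, x) {
  if (any(abs(x) > sol$d + 1e-12)) stop("x outside the cell [-d, d]")
  sol$a2 + sol$a4 * x^2 / 2 + sol$a6 * x^4 / 24
}

#' @rdname eval_series
#' @export
cell_mass <- function(sol) {
  d <- sol$d
  2 * (sol$a0 * d + sol$a2 * d^3 / 6 + sol$a4 * d^5 / 120 +
         sol$a6 * d^7 / 5040)
}

#' Boundary residuals of the series solution
#'
#' Two conditions fix the free constants \eqn{(a_0, a_2)}. First, each
#' kinetochore delta imposes a slope discontinuity
#' \eqn{\kappa[\rho_f'(d^+) - \rho_f'(d^-)] = -2\alpha\rho_f(d)}; since the
#' tiled solution is mirror-symmetric about the kinetochore,
#' \eqn{\rho_f'(d^+) = -\rho_f'(d^-)}, and the jump condition reduces to the
#' one-sided form \eqn{\kappa\rho_f'(d) = \alpha\rho_f(d)}. Second,
#' turnover balance fixes the cell mass,
#' \eqn{\int_{-d}^{d}\rho_f = 2 d\,\bar\omega_{on}/\omega_{off}}.
#'
#' @param a0,a2 trial free constants.
#' @param params a [model_params()].
#' @param order truncation order, 4 or 6.
#' @return Named numeric vector `c(jump = , mass = )`:
#'   \eqn{\kappa\rho_f'(d) - \alpha\rho_f(d)} and
#'   \eqn{\int\rho_f - 2d\bar\omega_{on}/\omega_{off}}.
#' @export
boundary_residuals <- function(a0, a2, params, order = 6) {
  sol <- series_solution(a0, a2, params, order)
  d <- params$d
  c(jump = params$kappa * eval_series_deriv(sol, d) -
      params$alpha * eval_series(sol, d),
    mass = cell_mass(sol) - 2 * d * mean_density(params))
}

#' Solve the steady-state series
#'
#' Damped Newton iteration on [boundary_residuals()] with a numeric
#' (symmetric-difference) Jacobian, started from the uniform solution
#' \eqn{a_0 = \bar\omega_{on}/\omega_{off}} with a small positive \eqn{a_2}.
#' The root found this way is the branch continuously connected to the
#' uniform state as \eqn{\alpha} grows from 0; `continuation = TRUE` makes
#' that construction explicit by stepping \eqn{\alpha} up from 0 and is used
#' as a fallback when the direct solve stalls.
#'
#' @param params a [model_params()].
#' @param order truncation order, 4 or 6.
#' @param a2_init initial curvature guess (\eqn{\mu m^{-3}}).
#' @param tol convergence threshold on both residuals (natural units).
#' @param max_iter Newton iteration cap.
#' @param continuation solve by stepping \eqn{\alpha} from 0 in `n_steps`
#'   increments.
#' @param n_steps continuation steps.
#' @return A `kb_series` solution; its residuals are stored in
#'   `attr(, "residuals")`. Errors on non-convergence (reporting the final
#'   residuals) and on a negative density anywhere on 1001 cell points
#'   (unphysical branch).
#' @export
#' @examples
#' sol <- solve_series(kb_preset("fig5b"), order = 6)
#' eval_series(sol, sol$d) / eval_series(sol, 0)  # peak-to-valley ratio
solve_series <- function(params, order = 6, a2_init = 1e-2, tol = 1e-9,
                         max_iter = 200, continuation = FALSE, n_steps = 8) {
  stopifnot(order %in% c(4, 6))
  if (continuation && params$alpha > 0) {
    start <- c(mean_density(params), a2_init)
    for (a in seq(0, params$alpha, length.out = n_steps + 1)[-1]) {
      pa <- params; pa$alpha <- a
      start <- newton_series(pa, order, start, tol, max_iter)
    }
    root <- start
  } else {
    root <- newton_series(params, order, c(mean_density(params), a2_init),
                          tol, max_iter)
  }
  sol <- series_solution(root[1], root[2], params, order)
  xs <- seq(-params$d, params$d, length.out = 1001)
  if (min(eval_series(sol, xs)) < 0) {
    stop("solved series branch has negative density on the cell (unphysical)")
  }
  attr(sol, "residuals") <- boundary_residuals(root[1], root[2], params, order)
  sol
}

# Damped Newton core; returns c(a0, a2) or errors with the final residuals.
newton_series <- function(params, order, start, tol, max_iter) {
  p <- start
  res <- function(v) boundary_residuals(v[1], v[2], params, order)
  r <- res(p)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) return(p)
    h <- 1e-6 * pmax(abs(p), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- p; dn <- p
      up[j] <- up[j] + h[j]; dn[j] <- dn[j] - h[j]
      J[, j] <- (res(up) - res(dn)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("singular Jacobian in series Newton iteration"))
    lam <- 1
    repeat {
      r_new <- res(p + lam * step)
      if (sum(r_new^2) < sum(r^2) || lam < 1e-10) break
      lam <- lam / 2
    }
    p <- p + lam * step
    r <- r_new
  }
  if (max(abs(r)) < tol) return(p)
  stop(sprintf(
    "series solver did not converge in %d iterations (residuals: jump %.3g, mass %.3g)",
    max_iter, r[1], r[2]))
}

#' Truncation error of the series solution
#'
#' Solves the steady state at orders 4 and 6 and reports their relative
#' difference, the internal consistency check for the truncated expansion.
#' The default metric compares the profiles at the kinetochore
#' (\eqn{x = d}), where the truncation bites hardest; `metric = "linf"`
#' takes the maximum pointwise relative difference over the cell.
#'
#' @param params a [model_params()].
#' @param metric `"kinetochore"` or `"linf"`.
#' @return Relative difference as a fraction (dimensionless).
#' @export
truncation_error <- function(params, metric = c("kinetochore", "linf")) {
  metric <- match.arg(metric)
  s4 <- solve_series(params, order = 4)
  s6 <- solve_series(params, order = 6)
  if (metric == "kinetochore") {
    abs(eval_series(s4, params$d) - eval_series(s6, params$d)) /
      eval_series(s6, params$d)
  } else {
    xs <- seq(-params$d, params$d, length.out = 1001)
    max(abs(eval_series(s4, xs) - eval_series(s6, xs)) / eval_series(s6, xs))
  }
}

#' Tile a cell solution around the ring
#'
#' Replicates the symmetric cell solution periodically across the `n_kt`
#' cells of the ring, producing a [density_profile()] with kinetochores at
#' the cell boundaries \eqn{(2i-1)d} (matching [build_lattice()]). The
#' generating lattice is attached as `attr(, "lattice")`.
#'
#' @param sol a `kb_series` solution.
#' @param n_kt number of cells; defaults to the solution's parameter set.
#' @param dx_frac grid step as a fraction of `d`.
#' @return A `kb_profile` on the ring \eqn{[0, 2 d\, n_{kt})}.
#' @export
tile_ring <- function(sol, n_kt = sol$params$n_kt, dx_frac = 1 / 64) {
  d <- sol$d
  m <- round(2 / dx_frac)            # nodes per cell
  dx <- 2 * d / m
  x <- (0:(n_kt * m - 1)) * dx
  u <- ((x + d) %% (2 * d)) - d      # cell-local coordinate in [-d, d)
  prof <- density_profile(eval_series(sol, u), dx)
  pa <- sol$params
  pa$n_kt <- as.integer(n_kt)
  attr(prof, "lattice") <- build_lattice(pa)
  prof
}
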