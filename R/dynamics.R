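#' Time-integration settings
#'
#' Discretization controls for [evolve()]. The integrator is a spectral
#' IMEX (implicit-explicit) scheme: the stiff linear operators -- the
#' \eqn{\kappa} fourth derivative, the crosslinker second derivative, the
#' turnover decay, and a stabilizing linear split of the cubic term -- are
#' treated implicitly in Fourier space, while the nonlinear flux and the
#' kinetochore attraction are explicit. A fully explicit scheme would
#' require \eqn{dt \propto dx^4 / (M_\rho \kappa)}; the IMEX scheme is
#' stable at the default \eqn{dt = 10^{-3}} s with \eqn{dx = d/64}, and in
#' practice far beyond.
#'
#' @param params a [model_params()] (sets the grid from `d`).
#' @param dt time step (s).
#' @param t_end integration horizon (s).
#' @param dx grid step (\eqn{\mu m}); default `d / 64`.
#' @param delta_width attraction regularization width \eqn{\sigma_\delta}
#'   (\eqn{\mu m}); default `2 * dx`, must be >= `dx`.
#' @param scheme integrator label; only `"spectral_imex"` is implemented.
#' @param tol_steady steady-state criterion on the density change rate
#'   (\eqn{\mu m^{-1} s^{-1}}).
#' @param seed integer seed for randomized initial conditions.
#' @return An object of class `kb_settings`.
#' @export
evolution_settings <- function(params, dt = 1e-3, t_end = 2000,
                               dx = params$d / 64, delta_width = 2 * dx,
                               scheme = "spectral_imex", tol_steady = 1e-8,
                               seed = NULL) {
  stopifnot(dt > 0, t_end > 0, dx > 0)
  if (delta_width < dx) stop("delta_width must be >= dx")
  if (!identical(scheme, "spectral_imex")) {
    stop("unknown scheme: ", scheme, " (only 'spectral_imex' is implemented)")
  }
  structure(list(dt = dt, t_end = t_end, dx = dx, delta_width = delta_width,
                 scheme = scheme, tol_steady = tol_steady, seed = seed),
            class = "kb_settings")
}

# One-shot setup of the spectral operators for a given grid/lattice.
imex_setup <- function(params, lattice, settings, n) {
  L <- lattice$length
  x <- (0:(n - 1)) * (L / n)
  q <- spectral_wavenumbers(n, L)
  comb <- if (params$alpha > 0) {
    regularized_delta_comb(lattice, x, settings$delta_width)
  } else numeric(n)
  list(x = x, q = q, q2 = q^2, q4 = q^4, comb = comb, n = n, L = L)
}

# Advance `nsteps` IMEX steps; the cubic term is split as
# w rho^3 = A rho + (w rho^3 - A rho) with A = 3 w max(rho)^2 treated
# implicitly, which keeps the explicit part non-stiff (standard stabilized
# splitting for Cahn-Hilliard-type equations).
imex_advance <- function(rho, op, params, settings, nsteps, turnover = TRUE,
                         t0 = 0) {
  dt <- settings$dt
  M <- params$m_rho
  zp2 <- 2 * params$zeta * params$psi
  om <- if (turnover) params$omega_on_bar else 0
  ooff <- if (turnover) params$omega_off else 0
  for (s in seq_len(nsteps)) {
    A <- 3 * params$w * max(rho)^2
    g <- params$w * rho^3 - A * rho - 2 * params$alpha * rho * op$comb
    num <- stats::fft(rho) - dt * M * op$q2 * stats::fft(g)
    num[1] <- num[1] + dt * om * op$n
    den <- 1 + dt * (M * A * op$q2 - M * zp2 * op$q2 + M * params$kappa * op$q4 + ooff)
    if (any(den <= 0)) {
      stop("IMEX step became non-contractive; reduce dt (stability contract)")
    }
    rho <- Re(stats::fft(num / den, inverse = TRUE)) / op$n
    if (!all(is.finite(rho))) {
      stop(sprintf("non-finite density at t = %.6g s; reduce dt", t0 + s * dt))
    }
  }
  rho
}

#' Integrate the conserved dynamics with turnover
#'
#' Advances
#' \deqn{\partial_t\rho = M_\rho\,\partial_x^2\!\left[w\rho^3 - 2\zeta\psi\rho
#'   - 2\alpha\rho\Delta_\sigma\right] - M_\rho\kappa\,\partial_x^4\rho
#'   + \bar\omega_{on} - \omega_{off}\,\rho}
#' on the periodic ring. The transport part is in flux (spectral) form, so
#' it conserves total mass to machine precision; only the turnover terms
#' change the mass, following
#' \eqn{\dot m = \bar\omega_{on} L - \omega_{off}\, m} exactly in the
#' continuum.
#'
#' @param init a [density_profile()] on the ring of `params` (its grid
#'   overrides `settings$dx`).
#' @param lattice a `kb_lattice`; defaults to the regular lattice.
#' @param params a [model_params()].
#' @param settings an [evolution_settings()].
#' @param turnover logical; `FALSE` integrates the pure conserved gradient
#'   flow (mass constant, free energy non-increasing).
#' @param n_frames number of stored frames (including the initial one).
#' @return An object of class `kb_trajectory`: `times`, `frames` (list of
#'   `kb_profile`), `mass`.
#' @export
evolve <- function(init, lattice = NULL, params, settings = NULL,
                   turnover = TRUE, n_frames = 41) {
  if (is.null(lattice)) lattice <- build_lattice(params)
  if (is.null(settings)) settings <- evolution_settings(params)
  check_geometry(init, lattice)
  n <- length(init$rho)
  settings$dx <- profile_length(init) / n
  op <- imex_setup(params, lattice, settings, n)
  total_steps <- max(1, round(settings$t_end / settings$dt))
  frame_steps <- unique(round(seq(0, total_steps, length.out = n_frames)))
  rho <- init$rho
  frames <- list(density_profile(rho, init$dx))
  times <- 0
  done <- 0
  for (target in frame_steps[-1]) {
    rho <- imex_advance(rho, op, params, settings, target - done,
                        turnover = turnover, t0 = done * settings$dt)
    done <- target
    frames[[length(frames) + 1]] <- density_profile(rho, init$dx)
    times <- c(times, done * settings$dt)
  }
  structure(list(times = times, frames = frames,
                 mass = vapply(frames, profile_mass, numeric(1)),
                 params = params, lattice = lattice, settings = settings),
            class = "kb_trajectory")
}

#' @export
print.kb_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames over %g s (%d nodes)\n",
              length(x$times), max(x$times), length(x$frames[[1]]$rho)))
  cat(sprintf("  mass %.6g -> %.6g\n", x$mass[1], x$mass[length(x$mass)]))
  invisible(x)
}

#' Relax the dynamics to steady state
#'
#' Runs the IMEX integrator until the density change rate
#' \eqn{\max_x |\rho(t + \Delta) - \rho(t)| / \Delta} falls below
#' `settings$tol_steady` (checked every `check_interval` seconds of model
#' time) or `t_end` is reached. The result carries attributes `converged`,
#' `t_stop` and `rate`; non-convergence is flagged, never silent.
#'
#' @inheritParams evolve
#' @param init optional initial [density_profile()]; default is the uniform
#'   turnover fixed point (plus seeded Gaussian noise of relative amplitude
#'   `noise` when `noise > 0` and `settings$seed` is set).
#' @param noise relative amplitude of seeded initial noise.
#' @param check_interval steady-check spacing (s of model time).
#' @return A `kb_profile` with convergence attributes.
#' @export
relax_to_steady <- function(params, settings = NULL, init = NULL,
                            lattice = NULL, noise = 0, check_interval = 1) {
  if (is.null(settings)) settings <- evolution_settings(params)
  if (is.null(lattice)) lattice <- build_lattice(params)
  if (is.null(init)) {
    n <- round(lattice$length / settings$dx)
    rho0 <- rep(mean_density(params), n)
    if (noise > 0) {
      rho0 <- rho0 * (1 + with_seed(settings$seed, function()
        stats::rnorm(n, 0, noise)))
    }
    init <- density_profile(rho0, lattice$length / n)
  }
  check_geometry(init, lattice)
  n <- length(init$rho)
  settings$dx <- profile_length(init) / n
  op <- imex_setup(params, lattice, settings, n)
  chunk <- max(1L, round(check_interval / settings$dt))
  total <- max(1, round(settings$t_end / settings$dt))
  rho <- init$rho
  done <- 0
  converged <- FALSE
  rate <- Inf
  while (done < total) {
    nstep <- min(chunk, total - done)
    rho_new <- imex_advance(rho, op, params, settings, nstep,
                            t0 = done * settings$dt)
    rate <- max(abs(rho_new - rho)) / (nstep * settings$dt)
    rho <- rho_new
    done <- done + nstep
    if (rate < settings$tol_steady) {
      converged <- TRUE
      break
    }
  }
  out <- density_profile(rho, init$dx)
  attr(out, "converged") <- converged
  attr(out, "t_stop") <- done * settings$dt
  attr(out, "rate") <- rate
  attr(out, "lattice") <- lattice
  out
}

#' Linear growth rate of density modes
#'
#' Dispersion relation of the dynamics linearized about the uniform state
#' \eqn{\bar\rho = \bar\omega_{on}/\omega_{off}} with the kinetochore
#' attraction absent (\eqn{\alpha} is ignored: the uniform state is only a
#' fixed point at \eqn{\alpha = 0}). Writing
#' \eqn{\rho = \bar\rho + \varepsilon e^{\lambda t}\cos(qx)} and keeping
#' first order in \eqn{\varepsilon}: the cubic term linearizes to
#' \eqn{3w\bar\rho^2}, each \eqn{\partial_x^2} brings \eqn{-q^2}, so
#' \deqn{\lambda(q) = M_\rho\left[\left(2\zeta\psi - 3w\bar\rho^2\right)q^2
#'   - \kappa q^4\right] - \omega_{off}.}
#' At \eqn{q = 0} only turnover relaxation survives
#' (\eqn{\lambda = -\omega_{off}}); the uniform state is unstable when the
#' crosslinker attraction \eqn{2\zeta\psi} exceeds the local repulsion
#' \eqn{3w\bar\rho^2} by enough to overcome stiffness and turnover.
#'
#' @param q wavenumber(s) (\eqn{\mu m^{-1}}).
#' @param params a [model_params()].
#' @return \eqn{\lambda(q)} (\eqn{s^{-1}}), vectorized over `q`.
#' @export
#' @examples
#' p <- kb_preset("fig5b")
#' max(dispersion_rate(seq(0, 10, 0.01), p)) < 0  # uniform state stable
dispersion_rate <- function(q, params) {
  rb <- mean_density(params)
  params$m_rho * ((2 * params$zeta * params$psi - 3 * params$w * rb^2) * q^2 -
                    params$kappa * q^4) - params$omega_off
}
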