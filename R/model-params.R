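#' Model parameters
#'
#' Bundles the full parameter set of the continuum bundling model in
#' micrometer / second / \eqn{k_B T} units. The inverse temperature
#' \eqn{\beta} is fixed to 1 throughout the package, i.e. all energies are
#' already expressed in \eqn{k_B T}. The ring length is always derived as
#' \eqn{L = 2 d N} and never stored independently.
#'
#' Defaults combine the biologically estimated couplings (see
#' [estimate_parameters()]) with the fixed rates used for the steady-state
#' parameter sweeps: \eqn{\zeta = 0.016\ \mu m^2},
#' \eqn{\bar\omega_{on} = 0.8\ \mu m^{-1} s^{-1}},
#' \eqn{\omega_{off} = 0.02\ s^{-1}}, \eqn{M_\rho = 0.02\ \mu m\, s^{-1}}.
#'
#' @param w quartic local-repulsion coefficient (\eqn{\mu m^3}).
#' @param kappa gradient-stiffness / nonlocal-repulsion coefficient
#'   \eqn{\kappa} (\eqn{\mu m^3}).
#' @param zeta crosslinker coupling \eqn{\zeta} (\eqn{\mu m^2}).
#' @param psi crosslinker linear density \eqn{\psi} (\eqn{\mu m^{-1}}),
#'   constant along the ring.
#' @param alpha kinetochore-microtubule attraction \eqn{\alpha}
#'   (\eqn{\mu m^2}).
#' @param d kinetochore half-spacing (\eqn{\mu m}); adjacent kinetochores sit
#'   \eqn{2d} apart.
#' @param n_kt number of kinetochores on the ring (integer \eqn{\ge 1}).
#' @param omega_on_bar nucleation rate per unit length \eqn{\bar\omega_{on}}
#'   (\eqn{\mu m^{-1} s^{-1}}).
#' @param omega_off disassembly rate \eqn{\omega_{off}} (\eqn{s^{-1}}).
#' @param m_rho microtubule mobility \eqn{M_\rho} (\eqn{\mu m\, s^{-1}}).
#' @return An object of class `kb_params`.
#' @seealso [kb_preset()] for the published parameter-sweep panels.
#' @export
#' @examples
#' p <- model_params(alpha = 10)
#' ring_length(p)       # 2 * d * n_kt
#' mean_density(p)      # omega_on_bar / omega_off
model_params <- function(w = 1, kappa = 10, zeta = 0.016, psi = 1e4,
                         alpha = 1.25, d = 2, n_kt = 2,
                         omega_on_bar = 0.8, omega_off = 0.02,
                         m_rho = 0.02) {
  p <- list(w = w, kappa = kappa, zeta = zeta, psi = psi, alpha = alpha,
            d = d, n_kt = n_kt, omega_on_bar = omega_on_bar,
            omega_off = omega_off, m_rho = m_rho)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("all model parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "))
  }
  # alpha = 0 is the physically meaningful detached-kinetochore limit
  pos <- setdiff(names(p), "alpha")
  bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad)) stop("parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (p$alpha < 0) stop("alpha must be nonnegative")
  if (p$n_kt != round(p$n_kt) || p$n_kt < 1) stop("n_kt must be an integer >= 1")
  p$n_kt <- as.integer(p$n_kt)
  class(p) <- "kb_params"
  p
}

#' @export
print.kb_params <- function(x, ...) {
  cat("Bundling-model parameters (um, s, k_BT; beta = 1):\n")
  cat(sprintf("  w = %g um^3, kappa = %g um^3, zeta = %g um^2, psi = %g um^-1\n",
              x$w, x$kappa, x$zeta, x$psi))
  cat(sprintf("  alpha = %g um^2, d = %g um, n_kt = %d (ring L = %g um)\n",
              x$alpha, x$d, x$n_kt, ring_length(x)))
  cat(sprintf("  omega_on_bar = %g um^-1 s^-1, omega_off = %g s^-1, M_rho = %g um s^-1\n",
              x$omega_on_bar, x$omega_off, x$m_rho))
  cat(sprintf("  mean density omega_on_bar/omega_off = %g um^-1\n", mean_density(x)))
  invisible(x)
}

#' Ring length and mean density
#'
#' `ring_length()` returns the derived periodic-domain length
#' \eqn{L = 2 d N}; `mean_density()` returns the turnover fixed point
#' \eqn{\bar\rho = \bar\omega_{on}/\omega_{off}}, the spatial mean enforced
#' by microtubule birth-death balance.
#'
#' @param params a [model_params()] object.
#' @return A scalar (\eqn{\mu m}, resp. \eqn{\mu m^{-1}}).
#' @export
ring_length <- function(params) 2 * params$d * params$n_kt

#' @rdname ring_length
#' @export
mean_density <- function(params) params$omega_on_bar / params$omega_off

#' Kinetochore lattice on the midplane ring
#'
#' Places the `n_kt` kinetochores at the regular positions
#' \eqn{x_i = (2i - 1) d}, \eqn{i = 1, \dots, N}, on the periodic ring
#' \eqn{[0, L)} with \eqn{L = 2 d N}, so adjacent kinetochores are \eqn{2d}
#' apart and the points \eqn{x = 0, 2d, 4d, \dots} are cell centers.
#'
#' @param params a [model_params()] object.
#' @return An object of class `kb_lattice` with fields `positions`
#'   (\eqn{\mu m}), `spacing` (\eqn{= 2d}) and `length` (\eqn{= L}).
#' @export
#' @examples
#' build_lattice(model_params(d = 2, n_kt = 5))
build_lattice <- function(params) {
  L <- ring_length(params)
  pos <- (2 * seq_len(params$n_kt) - 1) * params$d
  kb_lattice(pos, spacing = 2 * params$d, length = L)
}

# Low-level lattice constructor; positions need not be regular (the
# perturbed-lattice analysis and jittered fixtures use irregular ones).
kb_lattice <- function(positions, spacing, length) {
  stopifnot(is.numeric(positions), length > 0)
  positions <- sort(positions %% length)
  structure(list(positions = positions, spacing = spacing, length = length),
            class = "kb_lattice")
}

#' @export
print.kb_lattice <- function(x, ...) {
  cat(sprintf("Kinetochore lattice: %d positions on ring of %g um (spacing %g um)\n",
              length(x$positions), x$length, x$spacing))
  cat(" ", paste(signif(x$positions, 6), collapse = ", "), "\n")
  invisible(x)
}

# Consecutive gaps around the ring; they always sum to the ring length.
lattice_gaps <- function(lattice) {
  p <- lattice$positions
  diff(c(p, p[1] + lattice$length))
}

#' Microtubule density profile on the ring
#'
#' A density field \eqn{\rho(x)} sampled on a uniform periodic grid
#' \eqn{x = 0, dx, \dots, L - dx}. Negative excursions beyond
#' \eqn{10^{-6}\ \mu m^{-1}} are flagged with a warning -- never silently
#' clipped -- because the model density is a physical count per length.
#'
#' @param rho density samples (\eqn{\mu m^{-1}}).
#' @param dx grid step (\eqn{\mu m}).
#' @return An object of class `kb_profile` with fields `x`, `rho`, `dx`.
#' @export
density_profile <- function(rho, dx) {
  stopifnot(is.numeric(rho), length(rho) >= 4, dx > 0)
  if (min(rho) < -1e-6) {
    warning(sprintf("density has negative excursions down to %.3g um^-1", min(rho)))
  }
  structure(list(x = (seq_along(rho) - 1) * dx, rho = as.numeric(rho), dx = dx),
            class = "kb_profile")
}

#' @export
print.kb_profile <- function(x, ...) {
  cat(sprintf("Density profile: %d nodes, dx = %g um, ring L = %g um\n",
              length(x$rho), x$dx, profile_length(x)))
  cat(sprintf("  rho in [%.4g, %.4g] um^-1, mass %.6g\n",
              min(x$rho), max(x$rho), profile_mass(x)))
  invisible(x)
}

#' @rdname density_profile
#' @param params a [model_params()] object.
#' @param dx_frac grid step as a fraction of the half-spacing `d`.
#' @export
uniform_profile <- function(params, dx_frac = 1 / 64) {
  dx <- params$d * dx_frac
  n <- round(ring_length(params) / dx)
  density_profile(rep(mean_density(params), n), ring_length(params) / n)
}

# Ring length and total mass of a sampled profile.
profile_length <- function(profile) length(profile$rho) * profile$dx
profile_mass <- function(profile) sum(profile$rho) * profile$dx

# Index of the grid node nearest to ring position `pos`.
nearest_node <- function(profile, pos) {
  n <- length(profile$rho)
  (round((pos %% profile_length(profile)) / profile$dx) %% n) + 1
}

check_geometry <- function(profile, lattice) {
  if (abs(profile_length(profile) - lattice$length) > profile$dx / 2) {
    stop(sprintf("inconsistent geometry: profile ring %g um vs lattice ring %g um",
                 profile_length(profile), lattice$length))
  }
  invisible(TRUE)
}
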