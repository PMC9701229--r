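#' Regularized kinetochore attraction comb
#'
#' The point attractors enter the dynamics through the term
#' \eqn{-2\alpha \partial_x^2 [\rho\, \Delta_\sigma(x)]}, where
#' \eqn{\Delta_\sigma} replaces the Dirac comb by a sum of periodic Gaussians
#' of standard deviation `delta_width`, each normalized to unit integral on
#' the grid so the attached attraction strength is exactly \eqn{\alpha} per
#' kinetochore regardless of resolution.
#'
#' @param lattice a `kb_lattice`.
#' @param x grid node positions (uniform, periodic).
#' @param delta_width regularization width \eqn{\sigma_\delta} (\eqn{\mu m});
#'   must be at least the grid step.
#' @return Numeric vector: the comb sampled at `x` (\eqn{\mu m^{-1}}).
#' @export
regularized_delta_comb <- function(lattice, x, delta_width) {
  dx <- x[2] - x[1]
  if (delta_width < dx) stop("delta_width must be >= the grid step dx")
  L <- length(x) * dx
  comb <- numeric(length(x))
  for (p in lattice$positions) {
    u <- ring_distance(x, p, L)
    g <- exp(-u^2 / (2 * delta_width^2))
    comb <- comb + g / (sum(g) * dx)
  }
  comb
}

# Centered periodic first derivative, O(dx^2).
ddx_periodic <- function(y, dx) {
  n <- length(y)
  (y[c(2:n, 1)] - y[c(n, 1:(n - 1))]) / (2 * dx)
}

# Fourth-order-accurate periodic second derivative.
d2dx2_periodic4 <- function(y, dx) {
  n <- length(y)
  ip1 <- c(2:n, 1); ip2 <- c(3:n, 1, 2)
  im1 <- c(n, 1:(n - 1)); im2 <- c(n - 1, n, 1:(n - 2))
  (-y[im2] + 16 * y[im1] - 30 * y + 16 * y[ip1] - y[ip2]) / (12 * dx^2)
}

#' Free energy of a density profile
#'
#' Evaluates the discretized Ginzburg-Landau functional
#' \deqn{\beta F[\rho] = \oint dx \left\{ \frac{w}{4}\rho^4 +
#'   \frac{\kappa}{2}\left(\rho'\right)^2 - \zeta\psi\rho^2 \right\}
#'   - \alpha \sum_i \rho(x_i)^2,}
#' in \eqn{k_B T} units (\eqn{\beta = 1}). The quartic term is the local
#' excluded-volume repulsion, the gradient term the chromosome-mediated
#' nonlocal repulsion, the \eqn{\zeta\psi} term the crosslinker attraction,
#' and the last sum the kinetochore point attraction.
#'
#' By default the point-attractor term is evaluated exactly at the grid node
#' nearest each kinetochore (the energy of a delta attractor is well defined
#' without smearing); `delta = "regularized"` instead integrates
#' \eqn{-\alpha \rho^2 \Delta_\sigma}, which is the Lyapunov functional of
#' the regularized dynamics in [evolve()] and is the right choice when
#' checking energy decay along trajectories.
#'
#' @param profile a [density_profile()].
#' @param lattice a `kb_lattice` on the same ring (mismatch beyond `dx/2`
#'   is an error).
#' @param params a [model_params()].
#' @param delta `"exact"` (node sampling) or `"regularized"`.
#' @param delta_width width for `delta = "regularized"`; default `2 * dx`.
#' @return Scalar energy (\eqn{k_B T}).
#' @export
#' @examples
#' p <- model_params(alpha = 0)
#' prof <- uniform_profile(p)
#' # closed form for a uniform profile: L * (w c^4 / 4 - zeta psi c^2)
#' free_energy(prof, build_lattice(p), p)
free_energy <- function(profile, lattice, params,
                        delta = c("exact", "regularized"),
                        delta_width = 2 * profile$dx) {
  delta <- match.arg(delta)
  check_geometry(profile, lattice)
  rho <- profile$rho
  dx <- profile$dx
  grad <- ddx_periodic(rho, dx)
  bulk <- sum(params$w / 4 * rho^4 + params$kappa / 2 * grad^2 -
                params$zeta * params$psi * rho^2) * dx
  attract <- if (params$alpha == 0) {
    0
  } else if (delta == "exact") {
    params$alpha * sum(rho[nearest_node(profile, lattice$positions)]^2)
  } else {
    comb <- regularized_delta_comb(lattice, profile$x, delta_width)
    params$alpha * sum(rho^2 * comb) * dx
  }
  bulk - attract
}

#' Chemical potential
#'
#' Functional derivative of the free energy with the regularized attraction
#' comb,
#' \deqn{\mu(x) = w\rho^3 - \kappa\rho'' - 2\zeta\psi\rho
#'   - 2\alpha\rho\,\Delta_\sigma(x),}
#' using a fourth-order periodic second derivative. The conserved dynamics
#' transports density down gradients of \eqn{\mu}.
#'
#' @inheritParams free_energy
#' @param delta_width regularization width (\eqn{\mu m}), at least `dx`.
#' @return Numeric vector: \eqn{\mu} on the grid (\eqn{\mu m^{-2}}, energies
#'   per \eqn{k_B T}).
#' @export
chemical_potential <- function(profile, lattice, params,
                               delta_width = 2 * profile$dx) {
  check_geometry(profile, lattice)
  rho <- profile$rho
  comb <- regularized_delta_comb(lattice, profile$x, delta_width)
  params$w * rho^3 - params$kappa * d2dx2_periodic4(rho, profile$dx) -
    2 * params$zeta * params$psi * rho - 2 * params$alpha * rho * comb
}
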