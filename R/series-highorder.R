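# Generic even-power series solver to arbitrary truncation order.
#
# Used as an internal oracle: the closed-form order-4/6 recursions must
# coincide with this independent construction (coefficient matching done
# numerically by truncated Taylor convolution rather than hand-derived
# formulas), and the trend of the solution with increasing order indicates
# how far the order-6 truncation is from the converged expansion.

#' Steady-state series at arbitrary even order
#'
#' Generalization of [solve_series()] to truncation order \eqn{2K}: the
#' coefficient of \eqn{x^{2k}} in the steady-state equation is matched for
#' \eqn{k = 0, \dots, K-2} by computing \eqn{(\rho^3)''} through truncated
#' polynomial convolution, which yields each \eqn{b_{k+2}} (coefficient of
#' \eqn{x^{2k+4}}) from the lower ones. The same two boundary conditions as
#' in [boundary_residuals()] then fix \eqn{(b_0, b_1)} by damped Newton.
#'
#' This solver is deliberately independent of the closed-form order-4/6
#' recursions and serves as a cross-check; it becomes numerically fragile
#' beyond order ~16 where the Newton system is ill-conditioned.
#'
#' @param params a [model_params()].
#' @param order even truncation order (>= 4).
#' @param tol,max_iter Newton controls.
#' @return A list with `coef` (coefficients of \eqn{x^{0}, x^{2}, \dots}),
#'   `rho_d`, `rho_0`, and `residuals`.
#' @export
solve_series_general <- function(params, order = 8, tol = 1e-9,
                                 max_iter = 400) {
  stopifnot(order >= 4, order %% 2 == 0)
  K <- order / 2
  d <- params$d
  w <- params$w; kap <- params$kappa; zp <- params$zeta * params$psi
  om <- params$omega_on_bar; ooff <- params$omega_off; M <- params$m_rho

  build <- function(b0, b1) {
    b <- numeric(K + 1)
    b[1] <- b0; b[2] <- b1
    for (k in 0:(K - 2)) {
      bb <- b[1:(k + 2)]
      c2 <- convolve_poly(bb, bb)
      c3 <- convolve_poly(c2, bb)
      r3pp <- c3[k + 2] * (2 * k + 2) * (2 * k + 1)
      rpp <- b[k + 2] * (2 * k + 2) * (2 * k + 1)
      rhs <- M * (w * r3pp - 2 * zp * rpp) + (if (k == 0) om else 0) - ooff * b[k + 1]
      b[k + 3] <- rhs / (M * kap * (2 * k + 4) * (2 * k + 3) * (2 * k + 2) * (2 * k + 1))
    }
    b
  }
  evb <- function(b, x) {
    s <- 0
    for (j in seq_along(b)) s <- s + b[j] * x^(2 * (j - 1))
    s
  }
  res <- function(p) {
    b <- build(p[1], p[2])
    j <- seq_len(K)
    dr <- sum(2 * j * b[j + 1] * d^(2 * j - 1))
    mass <- 2 * sum(b * d^(2 * (0:K) + 1) / (2 * (0:K) + 1))
    c(kap * dr - params$alpha * evb(b, d), mass - 2 * d * mean_density(params))
  }

  p <- c(mean_density(params), 1e-3)
  r <- res(p)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    h <- 1e-7 * pmax(abs(p), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- p; dn <- p
      up[j] <- up[j] + h[j]; dn[j] <- dn[j] - h[j]
      J[, j] <- (res(up) - res(dn)) / (2 * h[j])
    }
    step <- solve(J, -r)
    lam <- 1
    repeat {
      r_new <- res(p + lam * step)
      if (sum(r_new^2) < sum(r^2) || lam < 1e-10) break
      lam <- lam / 2
    }
    p <- p + lam * step
    r <- r_new
  }
  if (max(abs(r)) >= tol) {
    stop(sprintf("general series solver (order %d) did not converge (res %.3g, %.3g)",
                 order, r[1], r[2]))
  }
  b <- build(p[1], p[2])
  list(coef = b, rho_d = evb(b, d), rho_0 = b[1], residuals = res(p))
}

# Plain polynomial product in the even-power basis.
convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}
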