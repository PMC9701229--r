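test_that("coefficient recursions vanish on the uniform solution", {
  p <- fig5b()
  rb <- mean_density(p)
  expect_equal(coeff_a4(rb, 0, p), 0)
  expect_equal(coeff_a6(rb, 0, coeff_a4(rb, 0, p), p), 0)
  expect_equal(coeff_a6(1, 0, 0, p), 0)  # a2 = a4 = 0 cascades
})

test_that("coefficient recursions match independent arithmetic", {
  p <- fig5b()  # w=1, kappa=10, zeta*psi=160, om=0.8, ooff=0.02, M=0.02
  a0 <- 40; a2 <- 1
  # direct evaluation of the printed formula, spelled out term by term
  a4_expect <- (3 * 1 * 0.02 * 40^2 * 1 - 2 * 160 * 0.02 * 1 +
                  0.8 - 0.02 * 40) / (10 * 0.02)
  expect_equal(coeff_a4(a0, a2, p), a4_expect)  # = 448
  expect_equal(a4_expect, 448)
  a6_expect <- 2 / (10 * 0.02) *
    (1 * 0.02 * (9 * 40 * 1^2 + 1.5 * 40^2 * 448) - 160 * 0.02 * 448 -
       0.02 / 2 * 1)
  expect_equal(coeff_a6(a0, a2, 448, p), a6_expect)

  # when omega_on_bar = omega_off * a0 the M_rho dependence cancels
  p2 <- fig5b(); p2$m_rho <- 2 * p$m_rho
  expect_equal(coeff_a4(rb <- mean_density(p), 3, p), coeff_a4(rb, 3, p2))
})

test_that("series evaluation, derivative and mass have the stated closed forms", {
  p <- fig5b()
  sol <- solve_series(p)
  expect_equal(eval_series(sol, 0), sol$a0)
  expect_error(eval_series(sol, p$d * 1.01), "outside")

  # pure-curvature cell: mass = 2 * a2 d^3 / 6
  pure <- structure(list(a0 = 0, a2 = 6, a4 = 0, a6 = 0, d = 1,
                         order = 6L), class = "kb_series")
  expect_equal(cell_mass(pure), 2)

  # derivative vs centered finite differences, O(h^2)
  h <- 1e-5
  x0 <- 0.8 * p$d
  fd <- (eval_series(sol, x0 + h) - eval_series(sol, x0 - h)) / (2 * h)
  expect_equal(eval_series_deriv(sol, x0), fd, tolerance = 1e-8)
  fd2 <- (eval_series(sol, x0 + h) - 2 * eval_series(sol, x0) +
            eval_series(sol, x0 - h)) / h^2
  expect_equal(eval_series_deriv2(sol, x0), fd2, tolerance = 1e-5)
})

test_that("the uniform solution satisfies both boundary conditions exactly", {
  p <- fig5b(alpha = 0)
  r <- boundary_residuals(mean_density(p), 0, p, order = 6)
  expect_identical(unname(r), c(0, 0))
})

test_that("solve_series recovers the uniform state as alpha -> 0", {
  p <- fig5b(alpha = 0)
  sol <- solve_series(p)
  expect_equal(sol$a0, mean_density(p), tolerance = 1e-10)
  expect_lt(abs(sol$a2), 1e-10)

  # solved curvature vanishes linearly in alpha for small alpha
  a2_small <- vapply(c(1e-3, 2e-3), function(a)
    solve_series(fig5b(alpha = a))$a2, numeric(1))
  expect_equal(a2_small[2] / a2_small[1], 2, tolerance = 0.02)
})

test_that("solved roots satisfy the boundary conditions to tolerance", {
  for (p in list(fig5b(), fig5e(d = 1), fig5c())) {
    sol <- solve_series(p)
    r <- boundary_residuals(sol$a0, sol$a2, p, order = 6)
    expect_lt(max(abs(r)), 1e-9)
    # mass conservation holds by construction at every converged root
    expect_equal(cell_mass(sol), 2 * p$d * mean_density(p), tolerance = 1e-9)
    # physical branch: positive density, peak at the kinetochore
    xs <- seq(-p$d, p$d, length.out = 1001)
    expect_gt(min(eval_series(sol, xs)), 0)
    expect_gt(eval_series(sol, p$d), eval_series(sol, 0))
  }
})

test_that("alpha-continuation lands on the same branch as the direct solve", {
  p <- fig5b(alpha = 20)
  direct <- solve_series(p)
  cont <- solve_series(p, continuation = TRUE)
  expect_equal(cont$a0, direct$a0, tolerance = 1e-8)
  expect_equal(cont$a2, direct$a2, tolerance = 1e-8)
})

test_that("closed-form recursions agree with the generic series solver", {
  for (p in list(fig5b(), fig5e(d = 0.5), fig5c())) {
    g4 <- solve_series_general(p, order = 4)
    g6 <- solve_series_general(p, order = 6)
    s4 <- solve_series(p, order = 4)
    s6 <- solve_series(p, order = 6)
    expect_equal(g4$rho_d, eval_series(s4, p$d), tolerance = 1e-7)
    expect_equal(g6$rho_d, eval_series(s6, p$d), tolerance = 1e-7)
    # matching coefficients, converted from the x^(2j) basis
    expect_equal(g6$coef[2] * 2, s6$a2, tolerance = 1e-6)
  }
})

test_that("higher truncation orders move the peak toward the converged value", {
  p <- fig5b()
  rho_d <- vapply(c(4, 6, 8, 10), function(k)
    solve_series_general(p, order = k)$rho_d, numeric(1))
  expect_true(all(diff(rho_d) < 0))   # monotone from above
  # successive corrections shrink
  expect_true(all(diff(abs(diff(rho_d))) < 0))
})

test_that("truncation error metrics behave as documented", {
  expect_equal(truncation_error(fig5b(alpha = 0)), 0)
  tr_kt <- truncation_error(fig5b())
  tr_li <- truncation_error(fig5b(), metric = "linf")
  # the kinetochore point dominates the profile difference
  expect_equal(tr_kt, tr_li, tolerance = 1e-6)
  # error shrinks steeply with the cell half-width
  expect_gt(tr_kt, truncation_error(fig5e(d = 1)))
  expect_gt(truncation_error(fig5e(d = 1)), truncation_error(fig5e(d = 0.5)))
})

test_that("steady-state trends follow the published sweeps", {
  # peak grows and valley deepens with kinetochore attraction
  peaks <- vapply(c(1.25, 5, 10, 20), function(a) {
    s <- solve_series(fig5b(alpha = a)); eval_series(s, s$d)
  }, numeric(1))
  valleys <- vapply(c(1.25, 5, 10, 20), function(a) {
    s <- solve_series(fig5b(alpha = a)); eval_series(s, 0)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(valleys) < 0))

  # peak non-decreasing in crosslinker density
  pk_psi <- vapply(c(5e3, 1e4, 2e4), function(ps) {
    s <- solve_series(fig5c(psi = ps)); eval_series(s, s$d)
  }, numeric(1))
  expect_true(all(diff(pk_psi) >= 0))

  # larger kinetochore spacing attracts more microtubules to the peak
  pk_d <- vapply(c(0.5, 1, 2), function(dd) {
    s <- solve_series(fig5e(d = dd)); eval_series(s, s$d)
  }, numeric(1))
  vl_d <- vapply(c(0.5, 1, 2), function(dd) {
    s <- solve_series(fig5e(d = dd)); eval_series(s, 0)
  }, numeric(1))
  expect_true(all(diff(pk_d) > 0))
  expect_true(all(diff(vl_d) < 0))
})

test_that("tile_ring replicates the cell consistently around the ring", {
  p <- fig5b()
  sol <- solve_series(p)

  prof1 <- tile_ring(sol, n_kt = 1)
  expect_equal(length(prof1$rho) * prof1$dx, 2 * p$d)

  prof <- tile_ring(sol, n_kt = 10)
  lat <- attr(prof, "lattice")
  expect_length(lat$positions, 10)
  # the profile at every kinetochore node equals rho_f(d)
  expect_equal(value_at(prof, lat$positions),
               rep(eval_series(sol, p$d), 10), tolerance = 1e-10)
  # total mass = L * omega_on_bar / omega_off (from the mass condition);
  # the Riemann sum of the kinked profile converges to it at O(dx^2)
  L <- length(prof$rho) * prof$dx
  expect_equal(sum(prof$rho) * prof$dx, L * mean_density(p),
               tolerance = 1e-4)
  fine <- tile_ring(sol, n_kt = 10, dx_frac = 1 / 128)
  err <- function(pr) abs(sum(pr$rho) * pr$dx - L * mean_density(p))
  expect_equal(err(fine) / err(prof), 0.25, tolerance = 0.1)
})
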