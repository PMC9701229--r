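test_that("the regularized delta comb is normalized and scales correctly", {
  p <- fig5b()
  lat <- build_lattice(p)
  dx <- p$d / 64
  x <- seq(0, ring_length(p) - dx, by = dx)
  comb <- regularized_delta_comb(lat, x, 2 * dx)
  expect_equal(sum(comb) * dx, p$n_kt, tolerance = 1e-8)

  # peak value ~ 1/(sigma sqrt(2 pi)) within discretization error
  sig <- 4 * dx
  comb2 <- regularized_delta_comb(lat, x, sig)
  idx <- round(lat$positions[1] / dx) + 1
  expect_equal(comb2[idx], 1 / (sig * sqrt(2 * pi)), tolerance = 0.01)

  # halving sigma doubles the peak while each kinetochore keeps unit mass
  comb1 <- regularized_delta_comb(lat, x, sig / 2)
  expect_equal(comb1[idx] / comb2[idx], 2, tolerance = 0.02)
  expect_equal(sum(comb1) * dx, p$n_kt, tolerance = 1e-8)

  expect_error(regularized_delta_comb(lat, x, dx / 2), "delta_width")
})

test_that("the uniform turnover fixed point is preserved exactly", {
  p <- model_params(alpha = 0)
  set <- evolution_settings(p, dt = 0.01, t_end = 100)
  tr <- evolve(uniform_profile(p), params = p, settings = set, n_frames = 3)
  dev <- max(abs(tr$frames[[3]]$rho - mean_density(p)))
  expect_lt(dev, 1e-10)
})

test_that("total mass follows the turnover exponential", {
  p <- model_params(alpha = 0)
  init <- density_profile(rep(20, 256), ring_length(p) / 256)
  set <- evolution_settings(p, dt = 5e-3, t_end = 60)
  tr <- evolve(init, params = p, settings = set, n_frames = 13)
  m_inf <- ring_length(p) * mean_density(p)
  pred <- (tr$mass[1] - m_inf) * exp(-p$omega_off * tr$times) + m_inf
  expect_lt(max(abs(tr$mass - pred) / pred), 1e-4)
})

test_that("the transport term conserves mass with turnover off", {
  p <- fig5b()
  init <- uniform_profile(p)
  rho0 <- init$rho * (1 + 0.05 * cos(2 * pi * init$x / ring_length(p)))
  set <- evolution_settings(p, dt = 0.01, t_end = 20)
  tr <- evolve(density_profile(rho0, init$dx), params = p, settings = set,
               turnover = FALSE, n_frames = 5)
  expect_lt(max(abs(tr$mass - tr$mass[1])) / tr$mass[1], 1e-10)
})

test_that("free energy is a Lyapunov functional of the pure gradient flow", {
  p <- fig5b()
  lat <- build_lattice(p)
  set <- evolution_settings(p, dt = 0.01, t_end = 60)
  tr <- evolve(uniform_profile(p), params = p, settings = set,
               turnover = FALSE, n_frames = 13)
  fs <- vapply(tr$frames, function(f)
    free_energy(f, lat, p, delta = "regularized", delta_width = 2 * f$dx),
    numeric(1))
  expect_true(all(diff(fs) <= 1e-8 * abs(fs[1])))
  expect_lt(fs[length(fs)], fs[1])  # strictly lower than the start
})

test_that("the gradient-flow steady state has spatially constant chemical potential", {
  p <- fig5b()
  lat <- build_lattice(p)
  set <- evolution_settings(p, dt = 0.01, t_end = 60)
  tr <- evolve(uniform_profile(p), params = p, settings = set,
               turnover = FALSE, n_frames = 2)
  fin <- tr$frames[[2]]
  mu <- chemical_potential(fin, lat, p, delta_width = 2 * fin$dx)
  expect_lt(diff(range(mu)) / abs(mean(mu)), 1e-3)
})

test_that("the bundled steady state beats the uniform profile energetically", {
  p <- fig5b()
  lat <- build_lattice(p)
  set <- quick_settings(p)
  steady <- relax_to_steady(p, set)
  expect_true(attr(steady, "converged"))
  uni <- uniform_profile(p)
  # equal mass by construction (turnover pins the mean)
  expect_equal(sum(steady$rho) * steady$dx, sum(uni$rho) * uni$dx,
               tolerance = 1e-6)
  expect_lt(free_energy(steady, lat, p, delta = "regularized",
                        delta_width = 2 * steady$dx),
            free_energy(uni, lat, p, delta = "regularized",
                        delta_width = 2 * uni$dx))
})

test_that("relaxed steady states agree with the series solution at the kinetochore", {
  # independent dynamical route vs the truncated series, within twice the
  # order-4/order-6 truncation difference
  for (dd in c(2, 1, 0.5)) {
    p <- fig5e(d = dd)
    sol <- solve_series(p)
    bound <- 2 * truncation_error(p)
    set <- quick_settings(p, dx = dd / 128)
    steady <- relax_to_steady(p, set)
    expect_true(attr(steady, "converged"))
    pk <- value_at(steady, build_lattice(p)$positions[1])
    expect_lt(abs(eval_series(sol, dd) - pk) / pk, bound)
  }
})

test_that("the steady profile is insensitive to grid and step refinement", {
  p <- fig5b()
  sw <- 2 * p$d / 64  # fixed physical regularization width
  s1 <- relax_to_steady(p, quick_settings(p, dt = 0.02, dx = p$d / 64,
                                          delta_width = sw))
  s2 <- relax_to_steady(p, quick_settings(p, dt = 0.01, dx = p$d / 128,
                                          delta_width = sw))
  r1 <- s1$rho[seq(1, length(s1$rho))]
  r2 <- s2$rho[seq(1, length(s2$rho), by = 2)]
  expect_lt(max(abs(r1 - r2)) / max(r2), 0.005)
})

test_that("steady peak mass is robust to the regularization width", {
  p <- fig5b()
  dx <- p$d / 64
  kt <- build_lattice(p)$positions[1]
  peak_mass <- function(sw) {
    s <- relax_to_steady(p, quick_settings(p, delta_width = sw))
    win <- ring_dist(s$x, kt, length(s$rho) * s$dx) <= 0.5
    sum((s$rho[win] - min(s$rho))) * s$dx
  }
  pm <- vapply(c(2 * dx, 3 * dx, 4 * dx), peak_mass, numeric(1))
  expect_lt(max(abs(pm - pm[1])) / pm[1], 0.03)
})

test_that("mode growth rates match the dispersion relation up to half Nyquist", {
  p <- model_params(alpha = 0)  # uniform background
  expect_equal(dispersion_rate(0, p), -p$omega_off)

  # published backbone is linearly stable ... (3 w rhobar^2 = 4800 > 2 zeta psi)
  qs <- seq(0.01, 60, by = 0.01)
  expect_true(all(dispersion_rate(qs, fig5b()) < 0))
  # ... while the low-repulsion sweep backbone is unstable
  expect_gt(max(dispersion_rate(qs, fig5c())), 0)

  n <- 256
  dx <- ring_length(p) / n   # Nyquist q ~ 100 um^-1
  x <- (0:(n - 1)) * dx
  for (m in c(2, 8, 32, 64)) {
    q <- 2 * pi * m / ring_length(p)
    lam <- dispersion_rate(q, p)
    dt <- min(1e-3, 0.01 / abs(lam))
    set <- evolution_settings(p, dt = dt, t_end = 400 * dt, dx = dx)
    rho0 <- mean_density(p) + 1e-3 * mean_density(p) * cos(q * x)
    tr <- evolve(density_profile(rho0, dx), params = p, settings = set,
                 n_frames = 2)
    amp <- function(v) 2 * abs(sum(v * exp(-1i * q * x))) / n
    rate <- log(amp(tr$frames[[2]]$rho) / amp(tr$frames[[1]]$rho)) /
      (tr$times[2] - tr$times[1])
    expect_lt(abs(rate - lam) / abs(lam), 0.05)
  }
})

test_that("integration guards report actionable errors", {
  # dt far beyond the contract in the linearly unstable regime makes the
  # implicit update non-contractive
  p <- fig5c()
  set_bad <- evolution_settings(p, dt = 0.5, t_end = 5)
  expect_error(evolve(uniform_profile(p), params = p, settings = set_bad),
               "reduce dt")
  expect_error(evolution_settings(p, delta_width = p$d / 1000), "delta_width")
  expect_error(evolution_settings(p, scheme = "explicit"), "scheme")
})

test_that("non-convergence by t_end is flagged, not silent", {
  p <- fig5b()
  set <- evolution_settings(p, dt = 0.01, t_end = 0.05, tol_steady = 1e-14)
  s <- relax_to_steady(p, set)
  expect_false(attr(s, "converged"))
  expect_equal(attr(s, "t_stop"), 0.05)
})
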