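test_that("trace rendering is seed-deterministic and leaves the RNG alone", {
  p <- fig5b()
  prof <- tile_ring(solve_series(p), n_kt = p$n_kt)
  t1 <- render_trace(prof, seed = 42)
  t2 <- render_trace(prof, seed = 42)
  expect_identical(t1$intensity, t2$intensity)
  expect_false(identical(render_trace(prof, seed = 43)$intensity, t1$intensity))
  expect_true(all(t1$intensity >= 0))
  expect_type(t1$intensity, "integer")

  # the generator restores the caller's RNG stream
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(render_trace(prof, seed = 1)); after <- rnorm(3)
  expect_identical(before, after)

  # truth is sufficient to regenerate bit-for-bit
  tr <- t1$truth
  t3 <- render_trace(tr$profile, tr$photon_budget, tr$background_fraction,
                     tr$psf_sigma, tr$seed)
  expect_identical(t3$intensity, t1$intensity)
})

test_that("the large-budget limit recovers the blurred density", {
  p <- fig5b()
  prof <- tile_ring(solve_series(p), n_kt = 2)
  tr <- render_trace(prof, photon_budget = 1e8, background_fraction = 0,
                     psf_sigma = 0.1, seed = 5)
  blurred <- kinebundle:::fft_gaussian_blur(prof$rho, 0.1, prof$dx)
  obs <- tr$intensity / sum(tr$intensity)
  expt <- blurred / sum(blurred)
  expect_lt(max(abs(obs - expt)) / max(expt), 0.01)
})

test_that("a background-dominated trace yields no detected peaks", {
  p <- fig5b()
  prof <- tile_ring(solve_series(p), n_kt = 10)
  tr <- render_trace(prof, background_fraction = 1 - 1e-9, seed = 3)
  expect_equal(count_peaks(tr, smooth_sigma = 0.4)$n_peaks, 0)
  expect_error(render_trace(prof, background_fraction = 1), "background_fraction")
})

test_that("lattice jitter is seeded, bounded and ring-closed", {
  p <- model_params(d = 2, n_kt = 400)
  lat <- build_lattice(p)
  expect_identical(jitter_lattice(lat, 0), lat)
  j1 <- jitter_lattice(lat, 0.1, seed = 9)
  expect_identical(j1$positions, jitter_lattice(lat, 0.1, seed = 9)$positions)
  gaps <- diff(c(j1$positions, j1$positions[1] + j1$length))
  expect_equal(sum(gaps), lat$length)
  expect_error(jitter_lattice(lat, p$d / 2), "sigma_jitter")

  # half-normal mean displacement: sigma * sqrt(2/pi) over many draws
  big <- build_lattice(model_params(d = 2, n_kt = 5000))
  disp <- unlist(lapply(1:2, function(s) {
    jb <- jitter_lattice(big, 0.1, seed = s)
    d <- (jb$positions - big$positions + big$length / 2) %% big$length -
      big$length / 2
    d
  }))
  expect_equal(mean(abs(disp)), 0.1 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("assay schedules are validated and reproducible", {
  p0 <- fig5b(alpha = 0)
  p1 <- fig5b(alpha = 10)
  expect_error(generate_assay(p1, p0, n_frames = 3), "non-decreasing")
  p_bad <- fig5b(alpha = 10, kappa = 5)
  expect_error(generate_assay(p0, p_bad, n_frames = 3), "only in alpha")

  a <- generate_assay(p0, p1, n_frames = 3, seed = 11)
  b <- generate_assay(p0, p1, n_frames = 3, seed = 11)
  expect_identical(lapply(a$frames, `[[`, "intensity"),
                   lapply(b$frames, `[[`, "intensity"))
  expect_equal(a$schedule, c(0, 5, 10))
  expect_equal(a$times, c(0, 5.4, 10.8))
})

test_that("a null assay has unit contrast ratios within Poisson tolerance", {
  p <- fig5b(alpha = 5)
  a <- generate_assay(p, p, n_frames = 2, seed = 21)
  cr <- contrast_ratio(a$frames[[2]], a$frames[[1]])
  expect_equal(cr$mean_ratio, 1, tolerance = 0.02)
  expect_equal(cr$sd_ratio, 1, tolerance = 0.1)
})

test_that("bundling assays show the growing-contrast signature", {
  p0 <- model_params(w = 1, kappa = 10, zeta = 0.016, psi = 1e4, alpha = 0,
                     d = 2, n_kt = 10)
  smooth_cr <- function(assay, sigma = 0.4) {
    f <- function(tr) kinebundle:::fft_gaussian_blur(
      as.numeric(tr$intensity), sigma, tr$position[2] - tr$position[1])
    contrast_ratio(f(assay$frames[[length(assay$frames)]]),
                   f(assay$frames[[1]]))
  }
  a <- generate_assay(p0, model_params(w = 1, kappa = 10, zeta = 0.016,
                                       psi = 1e4, alpha = 10, d = 2, n_kt = 10),
                      n_frames = 2, seed = 1)
  cr <- smooth_cr(a)
  expect_equal(cr$mean_ratio, 1, tolerance = 0.02)
  expect_gt(cr$sd_ratio, 2)

  # contrast grows with the final engagement strength (median over seeds)
  med_sd <- vapply(c(2.5, 5, 10), function(af) {
    pl <- p0; pl$alpha <- af
    stats::median(vapply(1:5, function(s)
      smooth_cr(generate_assay(p0, pl, n_frames = 2, seed = s))$sd_ratio,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_sd) > 0))
})

test_that("the attraction strength is recoverable from peak-to-valley contrast", {
  p <- fig5b()
  for (a_true in c(5, 20)) {
    pt <- fig5b(alpha = a_true)
    prof <- tile_ring(solve_series(pt), n_kt = pt$n_kt)
    sig <- kinebundle:::fft_gaussian_blur(prof$rho, 0.1, prof$dx)
    a_hat <- recover_alpha(max(sig) / min(sig), p)
    expect_lt(abs(a_hat - a_true) / a_true, 0.1)
  }
})

test_that("the detection pipeline recovers kinetochore count and positions", {
  # reduced-seed version of the acceptance Monte Carlo
  p <- fig5b(n_kt = 10)
  prof <- tile_ring(solve_series(p), n_kt = 10)
  lat <- attr(prof, "lattice")
  hits <- vapply(1:20, function(s) {
    tr <- render_trace(prof, photon_budget = 1e5, seed = s)
    pk <- count_peaks(tr, smooth_sigma = 0.4)
    pk$n_peaks == 10 && all(dist_to_lattice(pk$peak_positions, lat) <= 0.2)
  }, logical(1))
  expect_gte(sum(hits), 19)
})
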