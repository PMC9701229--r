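# Synthetic imaging layer: forward model from a model density to a noisy
# fluorescence rim trace, quasi-static bundling-assay time series, and
# jittered lattices for robustness fixtures. All randomness flows from
# explicit seeds; the caller's RNG state is never disturbed.

#' Render a noisy fluorescence trace from a density profile
#'
#' Forward imaging model for a rim line profile: the density is blurred
#' with a periodic Gaussian PSF of width `psf_sigma`, scaled so the total
#' expected signal photons equal `photon_budget * (1 - background_fraction)`,
#' a uniform background of `photon_budget * background_fraction` expected
#' photons is added, and each sample draws from a Poisson law with that
#' expectation. Photon counting only -- no read noise (hooks for it belong
#' in the config layer, not the physics).
#'
#' @param profile a [density_profile()] (typically from [tile_ring()] or
#'   [relax_to_steady()]).
#' @param photon_budget total expected photons over the trace (> 0).
#' @param background_fraction fraction of the budget in the uniform
#'   background, in \eqn{[0, 1)}.
#' @param psf_sigma PSF standard deviation (\eqn{\mu m}).
#' @param seed integer seed; the same seed regenerates the trace
#'   bit-for-bit.
#' @return An object of class `kb_trace`: `position` (\eqn{\mu m}),
#'   `intensity` (integer photon counts), and a `truth` list carrying the
#'   generating profile, kinetochore positions (when the profile has a
#'   lattice attached), seed, budget, background and PSF.
#' @export
render_trace <- function(profile, photon_budget = 1e5,
                         background_fraction = 0.1, psf_sigma = 0.1,
                         seed = 1) {
  stopifnot(photon_budget > 0)
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must lie in [0, 1)")
  }
  n <- length(profile$rho)
  signal <- fft_gaussian_blur(profile$rho, psf_sigma, profile$dx)
  lam <- photon_budget * (1 - background_fraction) * signal / sum(signal) +
    photon_budget * background_fraction / n
  counts <- with_seed(seed, function() stats::rpois(n, lam))
  lat <- attr(profile, "lattice")
  structure(list(
    position = profile$x,
    intensity = as.integer(counts),
    truth = list(profile = profile,
                 kinetochores = if (!is.null(lat)) lat$positions else NULL,
                 seed = seed, photon_budget = photon_budget,
                 background_fraction = background_fraction,
                 psf_sigma = psf_sigma,
                 noise_model = "poisson (emulation assumption)")),
    class = "kb_trace")
}

#' @export
print.kb_trace <- function(x, ...) {
  seed_lab <- if (is.null(x$truth$seed)) "unknown" else format(x$truth$seed)
  cat(sprintf("Intensity trace: %d samples over %g um, %d photons (seed %s)\n",
              length(x$intensity),
              length(x$intensity) * (x$position[2] - x$position[1]),
              sum(x$intensity), seed_lab))
  invisible(x)
}

#' Synthetic bundling-assay time series
#'
#' Emulates the live-imaging bundling assay: a time-lapse of rim intensity
#' traces in which kinetochore engagement gradually strengthens. The
#' kinetochore attraction is interpolated linearly from `params_early` to
#' `params_late` across frames (a quasi-static schedule standing in for the
#' unmodelled engagement kinetics -- the model itself has a static
#' \eqn{\alpha}); each frame's steady state is re-solved with the series
#' solver, tiled, and rendered with a per-frame seed `seed + frame - 1`.
#' The defaults mirror the published protocol: 9 min at 5.4 s intervals
#' (100 frames).
#'
#' @param params_early,params_late [model_params()] differing only in
#'   `alpha` (and optionally `psi`), with
#'   `params_early$alpha <= params_late$alpha` (engagement only accrues).
#' @param n_frames number of frames (>= 2).
#' @param photon_budget photons per frame.
#' @param seed base seed.
#' @param frame_interval frame spacing (s).
#' @param ... further arguments passed to [render_trace()].
#' @return An object of class `kb_assay`: `frames` (list of `kb_trace`),
#'   `schedule` (\eqn{\alpha} per frame), `times` (s), `frame_interval`.
#' @export
generate_assay <- function(params_early, params_late, n_frames = 100,
                           photon_budget = 1e5, seed = 1,
                           frame_interval = 5.4, ...) {
  stopifnot(n_frames >= 2)
  fixed <- setdiff(names(params_early)[!vapply(seq_along(params_early),
    function(i) identical(params_early[[i]], params_late[[i]]), logical(1))],
    c("alpha", "psi"))
  if (length(fixed)) {
    stop("early/late parameters may differ only in alpha (and psi): ",
         paste(fixed, collapse = ", "))
  }
  if (params_early$alpha > params_late$alpha) {
    stop("schedule must be non-decreasing: alpha_early <= alpha_late")
  }
  alphas <- seq(params_early$alpha, params_late$alpha, length.out = n_frames)
  psis <- seq(params_early$psi, params_late$psi, length.out = n_frames)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pf <- params_early
    pf$alpha <- alphas[f]
    pf$psi <- psis[f]
    sol <- tryCatch(solve_series(pf, order = 6),
                    error = function(e) stop(sprintf(
                      "steady-state solve failed at frame %d (alpha = %g): %s",
                      f, alphas[f], conditionMessage(e))))
    prof <- tile_ring(sol, n_kt = pf$n_kt)
    frames[[f]] <- render_trace(prof, photon_budget = photon_budget,
                                seed = seed + f - 1, ...)
  }
  structure(list(frames = frames, schedule = alphas,
                 times = (seq_len(n_frames) - 1) * frame_interval,
                 frame_interval = frame_interval, seed = seed),
            class = "kb_assay")
}

#' @export
print.kb_assay <- function(x, ...) {
  cat(sprintf("Bundling assay: %d frames, %g s apart, alpha %g -> %g\n",
              length(x$frames), x$frame_interval,
              x$schedule[1], x$schedule[length(x$schedule)]))
  invisible(x)
}

#' Jitter a kinetochore lattice
#'
#' Adds independent truncated-Gaussian displacements (s.d. `sigma_jitter`,
#' truncated at \eqn{\pm d/2}) to each kinetochore, wrapping around the
#' ring. A robustness fixture: the model itself keeps kinetochores fixed
#' during a run.
#'
#' @param lattice a `kb_lattice`.
#' @param sigma_jitter displacement s.d. (\eqn{\mu m}), `< d/3`.
#' @param seed integer seed.
#' @return A jittered `kb_lattice` (gaps still sum to the ring length).
#' @export
jitter_lattice <- function(lattice, sigma_jitter, seed = 1) {
  d <- lattice$spacing / 2
  if (sigma_jitter < 0 || sigma_jitter >= d / 3) {
    stop("sigma_jitter must lie in [0, d/3)")
  }
  if (sigma_jitter == 0) return(lattice)
  n <- length(lattice$positions)
  disp <- with_seed(seed, function() {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        z <- stats::rnorm(1, 0, sigma_jitter)
        if (abs(z) <= d / 2) break
      }
      out[i] <- z
    }
    out
  })
  kb_lattice(lattice$positions + disp, spacing = lattice$spacing,
             length = lattice$length)
}

#' Recover the kinetochore attraction from a peak-to-valley ratio
#'
#' One-parameter inverse problem on the series description: finds the
#' \eqn{\alpha} whose noiseless rendered profile (PSF-blurred tiled steady
#' state) has the observed peak-to-valley intensity ratio. The ratio is
#' strictly increasing in \eqn{\alpha}, so a bounded 1D minimization of the
#' squared mismatch on a log grid suffices.
#'
#' @param pv_ratio observed peak-to-valley ratio (> 1).
#' @param params template [model_params()] (all fields except `alpha`).
#' @param interval search interval for \eqn{\alpha} (\eqn{\mu m^2}).
#' @param psf_sigma PSF width used for the noiseless render.
#' @return Estimated \eqn{\alpha} (\eqn{\mu m^2}).
#' @export
recover_alpha <- function(pv_ratio, params, interval = c(0.25, 40),
                          psf_sigma = 0.1) {
  stopifnot(pv_ratio > 1)
  pv_of <- function(la) {
    p <- params
    p$alpha <- exp(la)
    prof <- tile_ring(solve_series(p, order = 6), n_kt = p$n_kt)
    sig <- fft_gaussian_blur(prof$rho, psf_sigma, prof$dx)
    max(sig) / min(sig)
  }
  opt <- stats::optimize(function(la) (pv_of(la) - pv_ratio)^2,
                         interval = log(interval), tol = 1e-6)
  exp(opt$minimum)
}
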