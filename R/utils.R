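# Internal numerical helpers shared across modules.

# Angular wavenumbers of an n-point periodic grid of physical length L,
# in fft() storage order.
spectral_wavenumbers <- function(n, L) {
  m <- if (n %% 2 == 0) c(0:(n / 2), -(n / 2 - 1):-1) else c(0:((n - 1) / 2), -((n - 1) / 2):-1)
  2 * pi * m / L
}

# Periodic Gaussian smoothing by multiplication with the kernel's exact
# frequency response; sigma in the same units as dx. sigma = 0 is a no-op.
fft_gaussian_blur <- function(y, sigma, dx) {
  if (sigma <= 0) return(y)
  n <- length(y)
  q <- spectral_wavenumbers(n, n * dx)
  Re(stats::fft(stats::fft(y) * exp(-q^2 * sigma^2 / 2), inverse = TRUE)) / n
}

# Fraction of white-noise standard deviation surviving the blur (Parseval).
blur_noise_attenuation <- function(n, sigma, dx) {
  if (sigma <= 0) return(1)
  q <- spectral_wavenumbers(n, n * dx)
  sqrt(mean(exp(-q^2 * sigma^2)))
}

# Evaluate f() with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators have no hidden global side effects.
with_seed <- function(seed, f) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  f()
}

#' Round to significant figures, halves away from zero
#'
#' Base `signif()` rounds halves to even; the arithmetic used to derive the
#' biological parameter estimates rounds halves away from zero, and this
#' helper pins that convention. The operation is idempotent.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (>= 1).
#' @return `x` rounded to `digits` significant figures.
#' @export
#' @examples
#' signif_half_up(111.6, 2)  # 110
#' signif_half_up(0.01746, 1)  # 0.02
signif_half_up <- function(x, digits) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    k <- digits - 1 - floor(log10(abs(x[nz])))
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * 10^k + 0.5) / 10^k
  }
  out
}

# Round to `decimals` decimal places, halves away from zero.
round_half_up <- function(x, decimals = 0) {
  sign(x) * floor(abs(x) * 10^decimals + 0.5) / 10^decimals
}

# Simpson quadrature on a uniform grid with an odd number of points.
simpson <- function(y, h) {
  n <- length(y)
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  sum(w * y) * h / 3
}

# Shortest signed/absolute distance on a ring of length L.
ring_distance <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}
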