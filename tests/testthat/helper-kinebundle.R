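# Shared fixtures: published sweep backbones and fast integrator settings.

fig5b <- function(...) kb_preset("fig5b", ...)
fig5c <- function(...) kb_preset("fig5c", ...)
fig5e <- function(...) kb_preset("fig5e", ...)

# Coarser-than-default stepping for relaxation tests: the steady state is
# insensitive to dt (checked by the convergence test) and the IMEX scheme
# is stable far beyond the contract dt.
quick_settings <- function(params, dt = 0.01, t_end = 400, ...) {
  evolution_settings(params, dt = dt, t_end = t_end, ...)
}

ring_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# Ring-aware distance from each position to the nearest lattice position.
dist_to_lattice <- function(pos, lattice) {
  vapply(pos, function(p) min(ring_dist(p, lattice$positions, lattice$length)),
         numeric(1))
}

# Density value at the grid node nearest a ring position.
value_at <- function(profile, pos) {
  L <- length(profile$rho) * profile$dx
  idx <- (round((pos %% L) / profile$dx) %% length(profile$rho)) + 1
  profile$rho[idx]
}

# Session-scoped scratch directory for run artifacts.
withr_like_tempdir <- function() {
  d <- file.path(tempdir(), paste0("kb-", sample.int(1e6, 1)))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
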