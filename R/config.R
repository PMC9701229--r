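# Configuration, presets, serialization, and the run dispatcher.

#' Published parameter-sweep presets
#'
#' Named parameter sets of the steady-state sweep panels:
#' \describe{
#'   \item{fig5b}{kinetochore-attraction sweep backbone:
#'     \eqn{\psi = 10^4\ \mu m^{-1}}, \eqn{d = 2\ \mu m},
#'     \eqn{\kappa = 10\ \mu m^3}, \eqn{w = 1\ \mu m^3}; default
#'     \eqn{\alpha = 10\ \mu m^2}.}
#'   \item{fig5c}{crosslinker-density sweep backbone:
#'     \eqn{\alpha = 20\ \mu m^2}, \eqn{d = 1\ \mu m},
#'     \eqn{\kappa = 5\ \mu m^3}, \eqn{w = 0.01\ \mu m^3} (here the uniform
#'     background is linearly unstable, see [dispersion_rate()]).}
#'   \item{fig5e}{kinetochore-distance sweep backbone:
#'     \eqn{\alpha = 10\ \mu m^2}, \eqn{\psi = 10^4\ \mu m^{-1}},
#'     \eqn{\kappa = 10\ \mu m^3}, \eqn{w = 1\ \mu m^3}; default
#'     \eqn{d = 2\ \mu m}.}
#' }
#' All presets share the fixed \eqn{\zeta = 0.016\ \mu m^2},
#' \eqn{\bar\omega_{on} = 0.8\ \mu m^{-1} s^{-1}},
#' \eqn{\omega_{off} = 0.02\ s^{-1}},
#' \eqn{M_\rho = 0.02\ \mu m\, s^{-1}}.
#'
#' @param name `"fig5b"`, `"fig5c"` or `"fig5e"`.
#' @param ... overrides passed to [model_params()] (e.g. `alpha`, `d`).
#' @return A [model_params()] object.
#' @export
#' @examples
#' kb_preset("fig5b", alpha = 20)
kb_preset <- function(name, ...) {
  base <- switch(name,
    fig5b = list(psi = 1e4, d = 2, kappa = 10, w = 1, alpha = 10),
    fig5c = list(alpha = 20, d = 1, kappa = 5, w = 0.01, psi = 1e4),
    fig5e = list(alpha = 10, psi = 1e4, kappa = 10, w = 1, d = 2),
    stop("unknown preset: ", name, " (available: fig5b, fig5c, fig5e)"))
  over <- list(...)
  do.call(model_params, utils::modifyList(base, over))
}

#' Load a run configuration from JSON
#'
#' Strict-schema JSON configuration for [run_config()]. Recognized top-level
#' keys: `task` (one of `steady-state`, `evolve`, `stability`,
#' `estimate-params`, `synth`, `metrics`), `preset`, `params`, `settings`,
#' `seed`, `out_dir`, `order`, `trace` (for `metrics`), and `synth` options
#' (`alpha_early`, `alpha_late`, `n_frames`, `photon_budget`). Unknown keys
#' -- top-level or nested -- are rejected by name.
#'
#' @param path path to a JSON file.
#' @return An object of class `kb_config` with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("invalid JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (!is.list(raw) || length(raw) == 0) stop("config schema violation: empty or non-object config")
  allowed <- c("task", "preset", "params", "settings", "seed", "out_dir",
               "order", "trace", "synth")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop("config schema violation: unknown key(s) ",
                            paste(unknown, collapse = ", "))
  tasks <- c("steady-state", "evolve", "stability", "estimate-params",
             "synth", "metrics")
  if (is.null(raw$task) || !raw$task %in% tasks) {
    stop("config schema violation: 'task' must be one of ",
         paste(tasks, collapse = ", "))
  }
  params <- if (!is.null(raw$preset)) kb_preset(raw$preset) else model_params()
  if (!is.null(raw$params)) {
    unknown <- setdiff(names(raw$params), names(model_params()))
    if (length(unknown)) stop("config schema violation: unknown params key(s) ",
                              paste(unknown, collapse = ", "))
    params <- do.call(model_params,
                      utils::modifyList(unclass(params), as.list(raw$params)))
  }
  settings <- evolution_settings(params)
  if (!is.null(raw$settings)) {
    known <- setdiff(names(unclass(settings)), "scheme")
    unknown <- setdiff(names(raw$settings), c(known, "scheme"))
    if (length(unknown)) stop("config schema violation: unknown settings key(s) ",
                              paste(unknown, collapse = ", "))
    args <- utils::modifyList(list(params = params), as.list(raw$settings))
    settings <- do.call(evolution_settings, args)
  }
  if (!is.null(raw$synth)) {
    unknown <- setdiff(names(raw$synth),
                       c("alpha_early", "alpha_late", "n_frames",
                         "photon_budget", "background_fraction", "psf_sigma"))
    if (length(unknown)) stop("config schema violation: unknown synth key(s) ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(task = raw$task, params = params, settings = settings,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 order = if (is.null(raw$order)) 6L else as.integer(raw$order),
                 trace = raw$trace,
                 synth = raw$synth),
            class = "kb_config")
}

#' Execute a configured run
#'
#' Dispatches to the task named in the configuration and writes its
#' artifacts (CSV data plus a JSON report) under `out_dir`, together with a
#' resolved copy of the configuration. Every JSON artifact records the
#' package version and the seed, so identical configurations reproduce
#' byte-identical outputs.
#'
#' @param config a `kb_config` from [load_config()] (or built in code).
#' @return Invisibly, a character vector of the files written.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "kb_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  meta <- list(package = "kinebundle",
               version = as.character(utils::packageVersion("kinebundle")),
               task = config$task, seed = config$seed,
               params = unclass(config$params))
  write_json <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_json(meta, out("resolved-config.json"))
  written <- out("resolved-config.json")

  if (config$task == "steady-state") {
    sol <- solve_series(config$params, order = config$order)
    prof <- tile_ring(sol, n_kt = config$params$n_kt)
    write_profile_csv(prof, out("profile.csv"))
    report <- c(meta, list(
      coefficients = list(a0 = sol$a0, a2 = sol$a2, a4 = sol$a4, a6 = sol$a6),
      residuals = as.list(attr(sol, "residuals")),
      rho_kinetochore = eval_series(sol, sol$d),
      rho_center = eval_series(sol, 0),
      truncation_error = truncation_error(config$params)))
    write_json(report, out("report.json"))
    written <- c(written, out("profile.csv"), out("report.json"))
  } else if (config$task == "evolve") {
    traj <- evolve(uniform_profile(config$params,
                                   config$settings$dx / config$params$d),
                   params = config$params, settings = config$settings)
    df <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
      data.frame(time = traj$times[i], x = traj$frames[[i]]$x,
                 rho = traj$frames[[i]]$rho)
    }))
    utils::write.csv(df, out("frames.csv"), row.names = FALSE)
    write_json(c(meta, list(mass = traj$mass, times = traj$times)),
               out("run-log.json"))
    written <- c(written, out("frames.csv"), out("run-log.json"))
  } else if (config$task == "stability") {
    st <- lattice_stability(config$params)
    write_json(c(meta, list(
      stiffness_analytic = st$stiffness_analytic,
      stiffness_fit = st$stiffness_fit,
      epsilon = st$table$epsilon, delta_f = st$table$delta_f,
      verdict = st$verdict)), out("stability.json"))
    written <- c(written, out("stability.json"))
  } else if (config$task == "estimate-params") {
    est <- estimate_parameters()
    write_json(c(meta, list(raw = est$raw, rounded = est$rounded,
                            provenance = as.list(est$provenance))),
               out("parameter-estimates.json"))
    written <- c(written, out("parameter-estimates.json"))
  } else if (config$task == "synth") {
    so <- config$synth
    p_early <- config$params
    p_early$alpha <- if (is.null(so$alpha_early)) 0 else so$alpha_early
    p_late <- config$params
    p_late$alpha <- if (is.null(so$alpha_late)) 10 else so$alpha_late
    assay <- generate_assay(
      p_early, p_late,
      n_frames = if (is.null(so$n_frames)) 10 else so$n_frames,
      photon_budget = if (is.null(so$photon_budget)) 1e5 else so$photon_budget,
      seed = config$seed)
    paths <- character(0)
    for (f in seq_along(assay$frames)) {
      pth <- out(sprintf("frame-%03d.csv", f))
      write_trace_csv(assay$frames[[f]], pth)
      paths <- c(paths, pth)
    }
    write_json(c(meta, list(schedule = assay$schedule, times = assay$times,
                            frame_seeds = config$seed + seq_along(assay$frames) - 1,
                            files = basename(paths))),
               out("manifest.json"))
    written <- c(written, paths, out("manifest.json"))
  } else if (config$task == "metrics") {
    if (is.null(config$trace)) stop("metrics task requires a 'trace' path")
    tr <- read_trace_csv(config$trace)
    pk <- count_peaks(tr, smooth_sigma = 0.4)
    write_json(c(meta, list(n_peaks = pk$n_peaks,
                            peak_positions = pk$peak_positions,
                            peak_heights = pk$peak_heights,
                            valley_floor = pk$valley_floor,
                            prominence_threshold = pk$prominence_threshold)),
               out("metrics.json"))
    written <- c(written, out("metrics.json"))
  }
  invisible(written)
}

#' Profile and trace serialization
#'
#' Density profiles go to CSV with columns `x_um`, `rho_per_um` (plus a JSON
#' sidecar carrying `dx` and any attached lattice); intensity traces use
#' columns `position_um`, `intensity`.
#'
#' @param profile a [density_profile()].
#' @param path output CSV path (sidecar written next to it as
#'   `<path>.meta.json`).
#' @return Invisibly, the path written / the object read.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_um = profile$x, rho_per_um = profile$rho),
                   path, row.names = FALSE)
  lat <- attr(profile, "lattice")
  jsonlite::write_json(
    list(dx = profile$dx,
         kinetochores = if (!is.null(lat)) lat$positions else NULL),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_um", "rho_per_um") %in% names(df)))
  density_profile(df$rho_per_um, df$x_um[2] - df$x_um[1])
}

#' @rdname write_profile_csv
#' @param trace a `kb_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(position_um = trace$position,
                              intensity = trace$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("position_um", "intensity") %in% names(df)))
  structure(list(position = df$position_um, intensity = df$intensity,
                 truth = NULL), class = "kb_trace")
}
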