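#' Measured biological quantities behind the model parameters
#'
#' Container for the printed measurements from which the model couplings and
#' rates are derived: EB1 comet counts through the spindle midplane, the
#' microtubule growth velocity, electron-tomography microtubule counts, the
#' PRC1 dimer geometry and binding energy, and the kinetochore binding-site
#' properties. Defaults are the published values.
#'
#' @param spot_count EB1 comet count through the midplane zone.
#' @param zone_thickness midplane zone thickness (\eqn{\mu m}).
#' @param n_frames number of imaging frames pooled.
#' @param n_cells number of cells pooled.
#' @param v_g microtubule growth velocity (\eqn{\mu m\, s^{-1}}).
#' @param n_mt_total total number of spindle microtubules.
#' @param e_crosslink PRC1 pair binding energy (\eqn{k_B T}).
#' @param x_prc1 PRC1 dimer length (\eqn{\mu m}).
#' @param n_site number of microtubule binding sites per kinetochore.
#' @param e_bar per-microtubule kinetochore binding energy (\eqn{k_B T}).
#' @param rho_site saturating microtubule surface density at the kinetochore
#'   (\eqn{\mu m^{-2}}).
#' @return An object of class `kb_bio_inputs`.
#' @export
biological_inputs <- function(spot_count = 27000, zone_thickness = 0.5,
                              n_frames = 75, n_cells = 3, v_g = 0.465,
                              n_mt_total = 6300, e_crosslink = 10,
                              x_prc1 = 0.04, n_site = 10, e_bar = 10,
                              rho_site = 80) {
  p <- list(spot_count = spot_count, zone_thickness = zone_thickness,
            n_frames = n_frames, n_cells = n_cells, v_g = v_g,
            n_mt_total = n_mt_total, e_crosslink = e_crosslink,
            x_prc1 = x_prc1, n_site = n_site, e_bar = e_bar,
            rho_site = rho_site)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                           !is.finite(v) || v < 0, logical(1))]
  if (length(bad)) stop("inputs must be nonnegative scalars: ",
                        paste(bad, collapse = ", "))
  pos <- c("zone_thickness", "n_frames", "n_cells", "n_mt_total", "rho_site")
  bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad)) stop("inputs must be strictly positive: ",
                        paste(bad, collapse = ", "))
  structure(p, class = "kb_bio_inputs")
}

#' Midplane plus-end flux
#'
#' Current of growing microtubule plus-ends through the spindle midplane,
#' \eqn{J_c = \rho_c v_g} with the comet linear density
#' \eqn{\rho_c = \mathrm{spots} / (\mathrm{thickness} \times \mathrm{frames}
#' \times \mathrm{cells})}. With the default inputs the unrounded value is
#' 111.6 \eqn{s^{-1}}, printed as 110 \eqn{s^{-1}} at two significant
#' figures.
#'
#' @param inputs a [biological_inputs()] object.
#' @param sig_figs significant figures for the returned value; `NULL` leaves
#'   it unrounded. Halves round away from zero ([signif_half_up()]).
#' @return \eqn{J_c} (\eqn{s^{-1}}).
#' @export
midplane_flux <- function(inputs = biological_inputs(), sig_figs = 2) {
  rho_c <- inputs$spot_count /
    (inputs$zone_thickness * inputs$n_frames * inputs$n_cells)
  j <- rho_c * inputs$v_g
  if (is.null(sig_figs)) j else signif_half_up(j, sig_figs)
}

#' Nucleation rate on the kinetochore rim
#'
#' The rim where the kinetochores lie covers about one third of the midplane
#' cross-section, so of the plus-end flux \eqn{J_c} only that fraction feeds
#' the ring: \eqn{\omega_{on} = J_c \cdot \mathrm{fraction}}. The published
#' chain uses the rounded \eqn{J_c = 110\ s^{-1}} and one significant
#' figure, giving \eqn{\omega_{on} = 40\ s^{-1}}.
#'
#' @param j_c midplane flux (\eqn{s^{-1}}).
#' @param fraction area fraction in \eqn{(0, 1]} (default 1/3).
#' @param sig_figs significant figures, `NULL` for unrounded.
#' @return \eqn{\omega_{on}} (\eqn{s^{-1}}).
#' @export
nucleation_rate <- function(j_c, fraction = 1 / 3, sig_figs = 1) {
  if (j_c < 0) stop("j_c must be nonnegative")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  w <- j_c * fraction
  if (is.null(sig_figs)) w else signif_half_up(w, sig_figs)
}

#' Disassembly rate from the microtubule census
#'
#' At steady state the total microtubule number satisfies
#' \eqn{N = J_c / \omega_{off}}; inverting with the tomography census
#' \eqn{N = 6300} gives \eqn{\omega_{off} = J_c / N}, printed as
#' 0.02 \eqn{s^{-1}}.
#'
#' @inheritParams nucleation_rate
#' @param n_mt_total total spindle microtubule count (> 0).
#' @return \eqn{\omega_{off}} (\eqn{s^{-1}}).
#' @export
disassembly_rate <- function(j_c, n_mt_total = 6300, sig_figs = 1) {
  if (n_mt_total <= 0) stop("n_mt_total must be positive")
  w <- j_c / n_mt_total
  if (is.null(sig_figs)) w else signif_half_up(w, sig_figs)
}

#' Crosslinker coupling from PRC1 geometry
#'
#' \eqn{\zeta = \beta e\, x_{PRC1}^2} with \eqn{\beta = 1}: the pair binding
#' energy times the squared dimer length, the probability scale for two
#' microtubules coming within crosslinking reach. Defaults give exactly
#' \eqn{0.016\ \mu m^2}.
#'
#' @param e_crosslink pair binding energy (\eqn{k_B T}).
#' @param x_prc1 PRC1 dimer length (\eqn{\mu m}).
#' @return \eqn{\zeta} (\eqn{\mu m^2}), unrounded (the product is exact).
#' @export
crosslinker_coupling <- function(e_crosslink = 10, x_prc1 = 0.04) {
  if (e_crosslink < 0 || x_prc1 <= 0) stop("inputs must be positive")
  e_crosslink * x_prc1^2
}

#' Kinetochore coupling from binding-site properties
#'
#' \eqn{\alpha = n_{site} \beta \bar e / \rho_{site}} with \eqn{\beta = 1}:
#' binding sites times per-microtubule binding energy, normalized by the
#' saturating microtubule surface density. Defaults give exactly
#' \eqn{1.25\ \mu m^2}.
#'
#' @param n_site binding sites per kinetochore.
#' @param e_bar per-microtubule binding energy (\eqn{k_B T}).
#' @param rho_site saturating surface density (\eqn{\mu m^{-2}}).
#' @return \eqn{\alpha} (\eqn{\mu m^2}), unrounded.
#' @export
kinetochore_coupling <- function(n_site = 10, e_bar = 10, rho_site = 80) {
  if (n_site < 0 || e_bar < 0 || rho_site <= 0) stop("inputs must be positive")
  n_site * e_bar / rho_site
}

#' Full parameter-estimation chain
#'
#' Runs the derivation chain from measured quantities to model parameters,
#' reporting both the raw arithmetic and the values rounded with the printed
#' conventions (flux to 2 significant figures; rates to 1). The nucleation
#' rate per unit length \eqn{\bar\omega_{on} = \omega_{on}/L} is reported
#' only when a ring length `L` is supplied -- the parameter sweeps use the
#' fixed \eqn{\bar\omega_{on} = 0.8\ \mu m^{-1} s^{-1}} directly.
#'
#' @param inputs a [biological_inputs()] object.
#' @param fraction rim area fraction passed to [nucleation_rate()].
#' @param L optional ring length (\eqn{\mu m}) for \eqn{\bar\omega_{on}}.
#' @return A list of class `kb_param_report` with components `raw`,
#'   `rounded` and `provenance`.
#' @export
#' @examples
#' estimate_parameters()$rounded
estimate_parameters <- function(inputs = biological_inputs(),
                                fraction = 1 / 3, L = NULL) {
  j_raw <- midplane_flux(inputs, sig_figs = NULL)
  j <- signif_half_up(j_raw, 2)
  # printed chain propagates the rounded flux
  won_raw <- nucleation_rate(j, fraction, sig_figs = NULL)
  won <- signif_half_up(won_raw, 1)
  woff_raw <- disassembly_rate(j, inputs$n_mt_total, sig_figs = NULL)
  woff <- signif_half_up(woff_raw, 1)
  zeta <- crosslinker_coupling(inputs$e_crosslink, inputs$x_prc1)
  alpha <- kinetochore_coupling(inputs$n_site, inputs$e_bar, inputs$rho_site)
  raw <- list(j_c = j_raw, omega_on = won_raw, omega_off = woff_raw,
              zeta = zeta, alpha = alpha)
  rounded <- list(j_c = j, omega_on = won, omega_off = woff,
                  zeta = zeta, alpha = alpha)
  if (!is.null(L)) {
    raw$omega_on_bar <- won_raw / L
    rounded$omega_on_bar <- won / L
  }
  structure(list(
    raw = raw, rounded = rounded,
    provenance = c(
      j_c = "comet density x growth velocity, 2 s.f.",
      omega_on = "J_c x rim area fraction, 1 s.f.",
      omega_off = "J_c / total microtubule count, 1 s.f.",
      zeta = "pair binding energy x PRC1 dimer length squared (exact)",
      alpha = "binding sites x per-MT energy / saturating density (exact)")),
    class = "kb_param_report")
}

#' @export
print.kb_param_report <- function(x, ...) {
  cat("Parameter estimates (raw -> rounded):\n")
  for (k in names(x$raw)) {
    cat(sprintf("  %-12s %.6g -> %g\n", k, x$raw[[k]], x$rounded[[k]]))
  }
  invisible(x)
}
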