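---
title: "A continuum model of kinetochore-driven microtubule bundling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuum model of kinetochore-driven microtubule bundling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinebundle)
```

## The model

During spindle assembly, microtubules crossing the spindle midplane first
form a loose, nearly uniform network held together by the crosslinker PRC1,
and then coarsen into discrete bundles, each associated with a kinetochore
on the rim of the midplane cross-section. `kinebundle` implements a
one-dimensional continuum description of this transition on the periodic
rim coordinate $x \in [0, L)$, with the microtubule linear density
$\rho(x)$ (units $\mu m^{-1}$) as the only field.

The energetics is a Ginzburg–Landau functional (all energies in $k_BT$,
i.e. $\beta = 1$ package-wide):

$$\beta F[\rho] = \oint dx \left\{ \frac{w}{4}\rho^4
  + \frac{\kappa}{2}\left(\frac{\partial\rho}{\partial x}\right)^2
  - \zeta\psi\rho^2 \right\}
  - \alpha \sum_{i=1}^{N} \rho(x_i)^2 .$$

The quartic term is local excluded-volume repulsion ($w$), the gradient
term a nonlocal repulsion mediated by the chromosomes attached to the
bundles ($\kappa$), the $\zeta\psi$ term the crosslinker-mediated
attraction (crosslinkers are taken uniformly distributed at constant
density $\psi$), and the point terms the lateral kinetochore–microtubule
attraction of strength $\alpha$ at the evenly spaced kinetochore positions
$x_i = (2i-1)d$, spacing $2d = L/N$.

Density moves conservatively down gradients of the chemical potential
$\mu = \delta(\beta F)/\delta\rho$, and microtubules additionally turn over
by nucleation and disassembly:

$$\frac{\partial\rho}{\partial t}
 = M_\rho \frac{\partial^2}{\partial x^2}
   \left[ w\rho^3 - 2\zeta\psi\rho - 2\alpha\rho\,\Delta(x) \right]
 - M_\rho \kappa \frac{\partial^4 \rho}{\partial x^4}
 + \bar\omega_{on} - \omega_{off}\,\rho ,$$

where $\Delta$ is the kinetochore delta comb. Turnover pins the mean
density to $\bar\rho = \bar\omega_{on}/\omega_{off}$ and makes the steady
states nonequilibrium ones, which is why lattice comparisons below speak of
an *effective* free energy.

### Parameters

| parameter | meaning | unit | default | origin |
|---|---|---|---|---|
| `w` | local repulsion | $\mu m^3$ | 1 | sweep panels |
| `kappa` | gradient stiffness | $\mu m^3$ | 10 | sweep panels |
| `zeta` | crosslinker coupling | $\mu m^2$ | 0.016 | $e\,x_{PRC1}^2$ = 10 $\times$ 0.04$^2$ |
| `psi` | crosslinker density | $\mu m^{-1}$ | $10^4$ | sweep panels |
| `alpha` | kinetochore attraction | $\mu m^2$ | 1.25 | $n_{site}\bar e/\rho_{site}$ = 10·10/80 |
| `d` | kinetochore half-spacing | $\mu m$ | 2 | rosette geometry |
| `omega_on_bar` | nucleation per length | $\mu m^{-1}s^{-1}$ | 0.8 | sweep panels |
| `omega_off` | disassembly | $s^{-1}$ | 0.02 | flux / census |
| `m_rho` | mobility | $\mu m\,s^{-1}$ | 0.02 | sweep panels |

`estimate_parameters()` reproduces the chain from measured quantities (EB1
comet statistics, electron-tomography microtubule counts, PRC1 geometry,
kinetochore binding sites) to these couplings, reporting raw and rounded
values. The printed values arise only under explicit
significant-figure rounding with halves away from zero (110 is 2 s.f. of
111.6; 40 is 1 s.f. of 36.7; 0.02 is 1 s.f. of 0.0175), so every estimator
takes `sig_figs` explicitly and also exposes the raw number.

One bookkeeping subtlety: with $\omega_{on} = 40\ s^{-1}$, the per-length
rate $\bar\omega_{on} = \omega_{on}/L$ equals the sweep panels' fixed
$0.8\ \mu m^{-1}s^{-1}$ only for $L = 50\ \mu m$, whereas a rim of radius
$5\ \mu m$ has $L \approx 31\ \mu m$. The package does not resolve this
tension: `estimate_parameters()` divides by a user-supplied `L` only when
one is given, and all sweep computations use $\bar\omega_{on} = 0.8$
directly.

## The steady-state series solver

On one symmetric inter-kinetochore cell $[-d, d]$ the steady state is
expanded in even powers, $\rho_f(x) = a_0 + a_2 x^2/2! + a_4 x^4/4! + a_6
x^6/6!$ (mirror symmetry removes odd terms). Matching powers of $x$ in the
steady-state equation yields the recursions implemented in `coeff_a4()` and
`coeff_a6()`; the remaining constants $(a_0, a_2)$ are fixed by two
boundary conditions:

* **Slope jump.** Each delta attractor kinks the profile:
  $\kappa[\rho_f'(d^+) - \rho_f'(d^-)] = -2\alpha\rho_f(d)$. Because the
  tiled solution is mirror-symmetric about the kinetochore,
  $\rho_f'(d^+) = -\rho_f'(d^-)$, and the condition reduces to the
  one-sided form $\kappa\rho_f'(d) = \alpha\rho_f(d)$ used in
  `boundary_residuals()`.
* **Mass.** Turnover balance fixes the cell mass,
  $\int_{-d}^{d}\rho_f = 2d\,\bar\omega_{on}/\omega_{off}$, applied per
  cell (the form on $[-d,d]$ generalizes unambiguously to any $N$).

`solve_series()` runs a damped Newton iteration (numeric symmetric
Jacobian, step halving, residual tolerance $10^{-9}$) from the uniform
state $a_0 = \bar\rho$, $a_2 = 10^{-2}\,\mu m^{-3}$. Where several roots
might coexist, the physical branch is the one continuously connected to the
uniform solution as $\alpha$ grows from zero; `continuation = TRUE` makes
that construction explicit, and the test suite verifies both routes land on
the same root. A solved root is rejected if the density is negative
anywhere on 1001 cell points.

### Truncation behavior, and a boundary layer

`truncation_error()` compares the order-4 and order-6 solutions; the
default metric is the relative difference at the kinetochore, where
truncation bites hardest (the $L^\infty$ metric is exposed as an
alternative and agrees to numerical precision on the cases studied).

```{r truncation}
p <- kb_preset("fig5b")          # alpha = 10, d = 2
100 * truncation_error(p)
100 * truncation_error(kb_preset("fig5b", d = 0.5))
```

These values are large, and deliberately reported as measured. The reason
is structural: with the sweep-panel parameters the coefficient
$3w\bar\rho^2 - 2\zeta\psi = 4480\ \mu m^{-2} \gg 0$, so the true steady
state is a nearly uniform background decorated with boundary-layer peaks of
width $\sqrt{\kappa/(3w\bar\rho^2 - 2\zeta\psi)} \approx 0.05\ \mu m$ at
the kinetochores. A global even-power polynomial on a cell of half-width
$2\ \mu m$ cannot represent such a layer; the truncated series instead
spreads the peak over the cell and overshoots its height. The package makes
this visible in three independent ways: the generic arbitrary-order solver
`solve_series_general()` shows the peak value falling monotonically as the
truncation order grows; the PDE relaxation (next section) resolves the
layer directly; and the order-4/6 disagreement quantifies the truncation
scale. The series description remains the model's own reduced description
-- all published sweep trends (peak growth with $\alpha$, $\psi$ and $d$,
valley deepening) hold in it and are tested -- but its pointwise accuracy
at large $d$ should not be overestimated.

## The dynamics integrator

`evolve()` advances the conserved dynamics with a spectral IMEX scheme. In
Fourier space the stiff linear operators -- $-M_\rho\kappa q^4$, the
crosslinker $+2M_\rho\zeta\psi q^2$, turnover decay $-\omega_{off}$, and a
stabilizing linear split $A = 3w\,\max\rho^2$ of the cubic term -- are
implicit; the nonlinear remainder $w\rho^3 - A\rho$ and the kinetochore
attraction are explicit. This is the standard stabilized splitting for
Cahn–Hilliard-type equations: the explicit part is non-stiff whenever
$3w\rho^2 \gtrsim 2\zeta\psi$, and the scheme is stable at the contract
point ($dt = 10^{-3}$ s, $dx = d/64$) and far beyond; the relaxation
helpers default to $dt = 10^{-2}$ s, which the grid/step convergence test
shows changes the steady profile by well under 0.5%. The transport term is
applied in flux form in Fourier space, so it conserves mass to machine
precision; mass changes only through turnover and follows its exponential
law to better than $10^{-4}$.

The delta comb is regularized as periodic Gaussians of width
$\sigma_\delta$ (default $2dx$), each normalized to unit discrete integral
so the attached attraction is exactly $\alpha$ per kinetochore at any
resolution. The energy bookkeeping uses exact node sampling (a point
attractor has a well-defined energy), while the PDE needs the smooth comb;
`free_energy(delta = "regularized")` provides the matching Lyapunov
functional for trajectory tests. The width that best mimics a true point
attractor is not knowable from the model alone; the suite therefore checks
that the steady peak *mass* moves by under 3% as $\sigma_\delta$ spans
$[2dx, 4dx]$, and the oracle-agreement tests run at $dx = d/128$ where
smearing bias is small.

Linearizing about the uniform state (attraction off) gives the dispersion
relation implemented in `dispersion_rate()`:
$\lambda(q) = M_\rho[(2\zeta\psi - 3w\bar\rho^2)q^2 - \kappa q^4] -
\omega_{off}$. The `fig5b`/`fig5e` backbone is linearly stable at every
$q$; the low-repulsion `fig5c` backbone ($w = 0.01$) is unstable in a band,
which is why its cross-checks use the high-order series rather than
relaxation (relaxation may coarsen away from the symmetric branch there).
Measured mode growth rates match $\lambda(q)$ well within the 5% tolerance
the suite enforces, up to half the grid Nyquist, when the step is scaled as
$dt \sim 0.01/|\lambda|$.

## Lattice stability

The stability of the evenly spaced kinetochore arrangement is probed on a
two-kinetochore ring of length $4d$ with the kinetochores displaced to
$-d+\epsilon$ and $d-\epsilon$. The closed-form curvature
$\beta\Delta F_{eff} = [2\alpha\rho_0\rho_0'']_{x=d}\,\epsilon^2$
(`analytic_lattice_stiffness()`, using the order-6 series $\rho_0$) is
positive on the sweep backbone: the even lattice sits at a local minimum of
effective free energy.

For the numeric counterpart, the design space was genuinely open and two
routes are implemented:

* `method = "series"` (default): re-solve each deformed cell (half-widths
  $d \mp \epsilon$) with the series solver, Simpson-integrate the bulk
  functional over each cell, and sample the delta terms with the mean of
  the adjoining edge densities. This stays inside the series description,
  is exactly $\epsilon$-symmetric by construction, and yields a cleanly
  quadratic, strictly positive $\Delta F_{eff}$.
* `method = "relax"`: relax the full PDE on the deformed ring (with
  $\epsilon$ snapped to the grid so exact node sampling is unambiguous)
  and difference the effective free energies. In the boundary-layer regime
  the displaced peaks simply do not interact -- their separation is tens of
  decay lengths -- so this route returns values at numerical-noise level.
  It is retained as a diagnostic of that physics, not as the stiffness
  estimator.

The two stiffness numbers that *are* well defined -- the analytic
$2\alpha\rho_0\rho_0''$ and the deformed-cell quadratic fit -- differ by
about a factor of 4.5 on the backbone: in the deformed-cell construction
the bulk terms contribute at order $\epsilon^2$ rather than cancelling.
The package reports both, and the acceptance suite records the
disagreement rather than hiding it; the *sign* (stability), symmetry and
quadratic scaling are unambiguous and tested.

## Observables and the synthetic imaging layer

`render_trace()` is the forward model from a density profile to a
fluorescence line profile along the rim: periodic Gaussian PSF blur
(default $\sigma = 0.1\ \mu m$), scaling to a photon budget with a uniform
background fraction, and per-sample Poisson draws. The published intensity
plots come with no stated noise model; Poisson photon counting is an
emulation assumption and is labelled as such in the trace metadata. All
randomness flows from explicit seeds (per-frame seeds in an assay are
`seed + frame - 1`), and generators restore the caller's RNG state.

`generate_assay()` emulates the live bundling assay -- 9 minutes of rim
cross-sections at 5.4 s intervals -- as a quasi-static schedule: the
kinetochore attraction is interpolated linearly between an early and a late
value and each frame's steady state is re-solved. This stands in for
engagement kinetics the model does not contain; it is an emulation choice,
not a mechanistic claim.

`count_peaks()` is a transparent periodic prominence counter (the
published segment counts came from a 2D segmentation plugin, out of scope
for 1D rims). Two design points matter for noisy traces. First, detection
of bundle-scale structure in photon noise needs a matched filter: the
pipeline analyses smooth with $\sigma = 0.4\ \mu m$, between the PSF scale
(0.1) and the inter-kinetochore spacing (4). Second, a purely relative
prominence rule cannot report "no peaks" on a pure-noise trace (the global
maximum of noise has prominence equal to the noise range by definition), so
a structure gate precedes counting: if the smoothed dynamic range is under
`noise_z = 10` robust noise sigmas, the trace is declared structureless.
The suite verifies both sides of the gate: pure-noise traces report zero
peaks, and at a $10^5$ photon budget the pipeline recovers all 10 bundles
in at least 95 of 100 seeds with at least 95% of detected peaks within one
PSF sigma of a kinetochore.

The contrast signature of bundling -- mean intensity ratio near 1, standard
deviation ratio well above 1 between late and early frames -- is computed
by `contrast_ratio()`. At a $10^5$ photon budget the raw early-frame
standard deviation is dominated by shot noise, so the assay tests evaluate
the ratio on matched-filtered traces, where the late/early
standard-deviation ratio exceeds 2 and grows with the final attraction
strength. The in-cell measured value of the corresponding ratio is a
property of the data, not a package target.

What the generator does *not* emulate: 2D/3D image formation, optical
aberrations and read noise, kinetochore motion within a run, bundle
merging/splitting dynamics, and cell-to-cell variability beyond the photon
noise. Passing recovery tests therefore demonstrate internal consistency of
the pipeline under the stated forward model, not performance on real
micrographs.

## Problem sizes and numerical tolerances used by the test suite

The suite runs in a few seconds on one core with: rings of 2–10 cells at
$dx = d/64$ (oracle comparisons at $d/128$); relaxation at $dt = 10^{-2}$ s
with steady tolerance $10^{-8}\ \mu m^{-1}s^{-1}$; Newton residual
tolerance $10^{-9}$; 100-seed Monte Carlo for the detection pipeline;
20-seed reduced versions of the stochastic properties in the unit files.
These sizes are the package's chosen desk-scale study conditions; the
generator defaults (photon budget $10^5$, 10 kinetochores, $\alpha: 0 \to
10$) are fixed by the emulated protocol and are not tuned.

## Known limitations

* The even-power series is a poor pointwise approximation at large cell
  half-widths (boundary-layer regime); its order-4/6 self-consistency
  figure substantially understates the true error there.
* The analytic lattice stiffness and any honest numeric deformation energy
  differ by a multiplicative factor on the sweep backbone; only the sign
  and scaling are robust.
* The quasi-static assay schedule ignores transport-limited lag between
  attraction changes and density response.
* `psi` is a constant; a crosslinker field with its own dynamics is out of
  scope.
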