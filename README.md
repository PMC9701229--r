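# kinebundle

Continuum modeling of how spindle microtubules, crosslinked by PRC1, go
from a loose uniform network to discrete bundles anchored at kinetochores
during early mitosis. The package is for biophysicists and quantitative
cell biologists who want to explore the bundling transition on the rim of
the spindle midplane: solve the model's steady states, integrate its
dynamics, test the stability of the kinetochore lattice, derive the model
parameters from measured quantities, and exercise the whole analysis on
synthetic fluorescence traces with known ground truth.

## The model

The microtubule linear density $\rho(x)$ on the periodic rim $[0, L)$
carries a Ginzburg–Landau free energy (energies in $k_BT$, $\beta = 1$)

$$\beta F[\rho] = \oint dx\left\{\tfrac{w}{4}\rho^4
 + \tfrac{\kappa}{2}(\rho')^2 - \zeta\psi\rho^2\right\}
 - \alpha\sum_{i=1}^{N}\rho(x_i)^2,$$

with local excluded-volume repulsion $w$, chromosome-mediated nonlocal
repulsion $\kappa$, crosslinker attraction $\zeta\psi$, and point
attractors of strength $\alpha$ at the kinetochores $x_i = (2i-1)d$.
Conserved transport down gradients of $\mu = \delta(\beta F)/\delta\rho$
combines with microtubule turnover:

$$\partial_t\rho = M_\rho\,\partial_x^2\!\left[w\rho^3 - 2\zeta\psi\rho
 - 2\alpha\rho\Delta\right] - M_\rho\kappa\,\partial_x^4\rho
 + \bar\omega_{on} - \omega_{off}\rho .$$

Steady states on one inter-kinetochore cell are solved by a truncated
even-power series $\rho_f = a_0 + a_2x^2/2! + a_4x^4/4! + a_6x^6/6!$ with
recursive coefficients and two boundary conditions (the delta-induced slope
jump $\kappa\rho_f'(d) = \alpha\rho_f(d)$ and per-cell mass
$\int\rho_f = 2d\,\bar\omega_{on}/\omega_{off}$); a spectral
implicit–explicit integrator provides the independent dynamical route.

## Worked example

```r
library(kinebundle)

p <- kb_preset("fig5b")          # sweep backbone: alpha = 10, d = 2 um
sol <- solve_series(p, order = 6)
sol
#> Series steady state (order 6, cell half-width d = 2 um):
#>   a0 = 37.2898, a2 = 0.000696647, a4 = 0.539344, a6 = 207.732
#>   rho(0) = 37.29, rho(d) = 56.116 um^-1, cell mass = 160
```

The solved cell has mean density 40 $\mu m^{-1}$ (nucleation/disassembly
balance), a valley of 37.3 between kinetochores and a peak of 56.1 at the
kinetochore: the attraction piles microtubules onto the kinetochore at the
expense of the inter-kinetochore space. Increasing `alpha` sharpens this
contrast; `relax_to_steady(p)` gives the same fixed point through the
dynamics.

```r
estimate_parameters()
#> Parameter estimates (raw -> rounded):
#>   j_c          111.6 -> 110
#>   omega_on     36.6667 -> 40
#>   omega_off    0.0174603 -> 0.02
#>   zeta         0.016 -> 0.016
#>   alpha        1.25 -> 1.25
```

The estimation chain goes from EB1 comet statistics and the microtubule
census to the turnover rates, and from PRC1 geometry and kinetochore
binding sites to the couplings, with the printed rounding conventions made
explicit (raw on the left, rounded on the right).

```r
lattice_stability(p)
#> Kinetochore-lattice stability:
#>   analytic stiffness  156639 k_BT/um^2
#>   quadratic-fit value 703192 k_BT/um^2
#>  epsilon   delta_f
#>    -0.10 7032.2130
#>    ...
#>   verdict: stable
```

Displacing the two kinetochores of a $4d$ ring by $\pm\epsilon$ always
raises the effective free energy ($\Delta F > 0$, quadratic in
$\epsilon$): the evenly spaced lattice is a local minimum. The analytic
and fitted stiffness values are both positive but differ by a known factor
discussed in the vignette.

```r
prof <- tile_ring(sol, n_kt = 10)                  # 10-kinetochore ring
tr <- render_trace(prof, photon_budget = 1e5, seed = 1)
count_peaks(tr, smooth_sigma = 0.4)
#> 10 peak(s); prominence threshold 3.806, valley floor 71.23
#>   positions (um): 2.0312, 6.0312, 9.9688, 14.062, ...
```

A synthetic Poisson-noise fluorescence trace of the 10-bundle ring gives
back all 10 peaks, each within one PSF width of its kinetochore (truth is
carried in `tr$truth`).

The methods vignette (`vignettes/bundling-model.Rmd`) documents the model
assumptions, the numerics, and the design decisions, including known
discrepancies that the package reports rather than hides.

## Command line

A thin wrapper over the configured-run interface lives in
`inst/cli/kinebundle.R`:

```sh
Rscript inst/cli/kinebundle.R --config cfg.json --seed 3 --out out/
```

with JSON configs selecting a task (`steady-state`, `evolve`, `stability`,
`estimate-params`, `synth`, `metrics`), a parameter preset and overrides;
every run writes its resolved configuration next to its outputs.
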