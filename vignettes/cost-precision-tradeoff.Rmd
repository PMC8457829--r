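---
title: "The cost-precision trade-off of morphogen gradient formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cost-precision trade-off of morphogen gradient formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotradeoff)
```

## The model

Developing tissues read position from morphogen concentration profiles. In
the synthesis-diffusion-depletion (SDD) picture, a morphogen is produced at a
localized source at one end of a 1D array of cells, spreads by diffusion
($D$), and is removed everywhere at a first-order rate ($k_d$):

$$\partial_t \rho = D\,\partial_x^2 \rho - k_d\,\rho,
\qquad -D\,\partial_x\rho|_{x=0} = j_{in}, \quad D\,\partial_x\rho|_{x=L} = 0 .$$

The stationary profile decays with the characteristic length
$\lambda = \sqrt{D/k_d}$,

$$\rho_{ss}(x) = \frac{j_{in}}{\sqrt{D k_d}}
\frac{\cosh((L-x)/\lambda)}{\sinh(L/\lambda)}
\;\approx\; \frac{j_{in}}{\sqrt{D k_d}}\, e^{-x/\lambda}
\quad (L \gg \lambda).$$

A target boundary forms at $x_b$, where the concentration crosses the
threshold that switches a target gene. Two quantities characterize the
profile there:

* **Cost.** Forming the gradient takes molecules: the local accumulation
  time is $\tau(x) = f(x;\lambda)/k_d$ with
  $f = \tfrac{1}{2}\!\left[1 + \tfrac{L}{\lambda}\coth\tfrac{L}{\lambda}
  - \tfrac{L-x}{\lambda}\tanh\tfrac{L-x}{\lambda}\right]$,
  and the molecules produced over that time cost
  $C(x) = \alpha_o\, n_m\, f(x;\lambda)$ ATP-equivalents, where
  $n_m = v_{cell} j_{in}/(l_{cell} k_d)$ is the production scale and
  $\alpha_o$ the per-molecule synthesis-plus-degradation cost
  ($\approx 494 \times 4 \approx 2\times10^3$ ATP for Bicoid).

* **Precision.** All reactions are of zeroth or first order, so stationary
  copy numbers are Poisson; concentration noise translated through the
  profile slope gives the squared relative positional error
  $\epsilon^2(x) = \frac{\lambda^3}{x^2 l_{cell}}\,\frac{1}{n_m}\,
  \frac{\sinh(L/\lambda)\cosh((L-x)/\lambda)}{\sinh^2((L-x)/\lambda)}$.

Cost rises with production while precision improves with it, so their
product $\pi_o = C\,\epsilon^2$ is production-independent: it depends only on
the geometry $(x_b/L, \lambda/L)$. Minimizing over $\lambda$ yields the
optimal decay length. In the large-system limit the product is
$\propto (1+s)\,s^{-3} e^{s}$ with $s = x_b/\lambda$, whose stationary point
solves $s^2 - s - 3 = 0$, i.e.

$$\lambda_{min} = \frac{2}{1+\sqrt{13}}\,x_b \approx 0.4343\,x_b ,$$

and the boundary concentration at the optimum is
$e^{-s} \approx 0.10$ of the source amplitude: **optimal boundaries form
where the profile has decayed to about a tenth of its amplitude**.

```{r}
optimal_lambda_point(1, 50)$lambda_min   # numerical
optimal_lambda_ratio_closed_form()        # closed form
threshold_fraction(1, optimal_lambda_ratio_closed_form())
```

## Two measurement models

The *point measurement* above is an instantaneous single-location readout.
Alternatively a cell may average: a sensor of half-width $a$ integrates
counts over $(x-a, x+a)$ for a duration $T$. On a long domain the windowed
count has mean $\langle m\rangle = 2(j_{in}/k_d) e^{-x/\lambda}
\sinh(a/\lambda)$ (here $j_{in}$ is in molecules/time) and, for
$T \gg k_d^{-1}$, squared relative error

$$\epsilon_T^2(x) = \frac{(\lambda/x)^2 e^{x/\lambda}}{j_{in} T}\, B(a/\lambda),
\qquad B(u) = \frac{e^{-u} + 3e^{3u} - 4(1+u)e^{u}}{2\,(e^{2u}-1)^2},$$

with $B \in (0,1]$, $B(u) = 1 - \tfrac{2}{3}u + O(u^2)$. The cost is simply
the production during the measurement, $C_T = \alpha_o j_{in} T$, so the
product $\pi_T = C_T\,\epsilon_T^2$ again cancels production. Its minimizer
always lies in $[(x_b-a)/2,\; x_b/2]$ and tends to $x_b/2$ for small
sensors. The two models bracket real readout mechanisms, and their optima
nearly coincide: $\lambda_{min} \approx (0.43\text{--}0.50)\,x_b$.

A worked example: at $x_b = 60a$ with $\lambda = 30a$, pushing the error to
$\epsilon_T = 0.1$ requires $j_{in}T = \pi_T/\epsilon_T^2 \approx 181$
molecules:

```{r}
min_production_for_error(xb = 60, a = 1, epsilon_target = 0.1, lam = 30)
```

## What the stochastic generator emulates

`simulate_ssa()` runs an exact event-driven simulation of the particle-level
lattice whose continuum limit is the SDD equation: injection into the first
cell, symmetric nearest-neighbor hopping at $D/l_{cell}^2$ per molecule,
first-order removal, reflecting walls. It reproduces the statistical
structure the analytic formulas assume -- Poisson stationary copy numbers,
the exponential mean profile, the accumulation time, and the windowed-count
moments -- and therefore serves as the package's independent oracle.

Windowed time averages deserve care: the sensor reading is a *continuous*
time integral, and averaging discrete snapshots overestimates its variance
unless snapshots are spaced well below the window's correlation time (which
is set by the diffusive escape time $\sim a^2/D$, much shorter than
$1/k_d$). The simulator therefore accumulates exact per-cell occupancy-time
integrals during the run, and `window_average_counts()` uses them when
available.

What the generator does **not** emulate: real morphogen transport
(cytonemes, transcytosis, regulated degradation), 2D/3D geometry, nuclear
import/export, or receptor kinetics. Passing oracle tests shows the analytic
formulas describe the idealized SDD lattice, not that any particular tissue
obeys them.

Fixture sizes were chosen so each statistical check resolves its target: the
standard fixture (50 cells, $\lambda = 5\,l_{cell}$, $n_m = 10^3$, seed
20210817) is sampled for $10^4/k_d$ (about 5000 decorrelated snapshots) for
the Poisson checks; 800 independent runs for the accumulation-time check;
500 runs of a finer lattice ($\lambda = 10\,l_{cell}$) for the
window-variance check. Occupancy-stratified assertions are used for the
Fano factor: cells holding fewer than ~0.5 molecules on average cannot
resolve a $\pm 0.1$ band with any feasible sample size (the estimator's
sampling SD is $\sqrt{(2 + 1/\mu)/n}$), so those cells are tested against
three standard errors instead.

## Reversible kinetics and entropy production

Replacing the one-way steps with reversible pairs (synthesis/re-uptake at
the source cell, degradation/spontaneous creation, forward/backward hops)
keeps the network linear, so the stationary law stays Poisson and everything
reduces to small tridiagonal solves. The thermodynamic cost is then the
entropy production rate of the stationary state,

$$\dot S_{tot} = \sum_{\text{edges}} (J^+ - J^-)\,\ln\frac{J^+}{J^-} \ge 0,$$

zero exactly at detailed balance (for symmetric hops:
`synth_fwd*deg_fwd == synth_rev*deg_rev`) and divergent in the strictly
irreversible limit -- which is the classic SDD model, so that limit is
reported as a structured flag rather than an error. The three-way trade-off
$\pi_{o,rev}(x_b) = \dot S_{tot}\,\tau_{rev}(x_b)\,\epsilon^2_{rev}(x_b)$
couples dissipation, formation speed and precision; its $\lambda$-minimized
value grows with $x_b$, and at detailed balance it degenerates to zero
because the equilibrium profile is flat and carries no positional
information. Entropy is reported in $k_B$ per unit time; converting to ATP
equivalents requires the affinity per synthesis-degradation cycle, which is
left to the user. Relaxation times are computed through the generator's
resolvent ($\tau = (-A^{-1} n_{ss})_x/(n_{ss})_x$), the exact time integral
of the relaxation deficit, rather than by quadrature.

## Other geometries

For a spatially distributed 1D source the steady state is assembled from the
localized-source Green's function; for diffusion-depletion on a spherical
surface with a polar source cap, a conservative finite-volume solve on a
staggered polar grid handles both poles without special-casing and balances
production against degradation to machine precision. Because no closed forms
exist for cost and precision in these geometries, the package defines them
by direct generalization: cost is $\alpha_o$ times total production times
the local relaxation time (again via the resolvent); precision is the
Poisson error of a sensor-patch count ($v_{cell}$ in 1D, an $l_{cell}^2$
patch on the sphere) with the lever arm measured from the edge of the
source region. With a narrow source these definitions reproduce the
localized-model product to $10^{-4}$, and a large sphere reproduces the
planar profile near the cap edge to better than 1%.

## Scoring real morphogen systems

The atlas registry carries the measured decay lengths
($\lambda_{Bcd} = 100\,\mu m$, $\lambda_{Wg} = 6\,\mu m$,
$\lambda_{Hh} = 8\,\mu m$, $\lambda_{Dpp} = 20\,\mu m$), the Bcd geometry
($x_b \approx 0.4L$, $L/l_{cell} \approx 50$) and measured precisions
($7\times10^{-4}$ for Bcd, $1.5\times10^{-2}$ for Dpp). Geometry that is not
established in the registry must come from a user configuration -- every
value carries a provenance string, and the shipped demo YAML marks its
wing-disc geometry as synthetic. Boundary ranges are scored at the midpoint
and both endpoints.

```{r}
atlas <- load_atlas()
evaluate_optimality(atlas$Bcd, "point")
bcd_cost_estimate(atlas$Bcd, alpha_o = 494 * 4)
```

## Numerical choices

* **Overflow-free hyperbolics.** All $\cosh/\sinh$ ratios are rewritten in
  terms of decaying exponentials (e.g.
  $\cosh((L-x)/\lambda)/\sinh(L/\lambda) = e^{-x/\lambda}
  (1+e^{-2(L-x)/\lambda})/(1-e^{-2L/\lambda})$), exact for all $L/\lambda$
  and reducing analytically to the large-$L$ forms -- no branch, no
  overflow.
* **Sensor factor.** $B(u)$ cancels catastrophically for small $u$ (both
  numerator and denominator are $8u^2 + O(u^3)$); below $u = 10^{-3}$ the
  series $1 - \tfrac{2}{3}u + \tfrac{1}{6}u^2$ is used.
* **Optimization.** Brent minimization on $\log\lambda$ over
  $[x_b/50,\,10\,x_b]$, followed by a refinement pass on a narrow bracket;
  the space-time optimum is checked against its analytic bracket
  $[(x_b-a)/2, x_b/2]$.
* **Singular inputs.** $\epsilon^2$ diverges at $x = 0$ (no lever arm) and
  $x = L$ (zero slope at the reflecting wall); both are rejected rather than
  regularized. Averaging times below $10/k_d$ are rejected by the
  window-variance formula (its derivation assumes $T \gg 1/k_d$), with a
  warning up to $50/k_d$.
* **Reproducibility.** The simulator draws from R's seeded RNG stream;
  trajectories are bit-exact reproducible from (config, seed), and every
  result records its seed.
* **PDE oracle.** Method-of-lines on cell-centered finite volumes with a
  banded Jacobian (`deSolve::ode`), second-order in the grid spacing; with
  2400 cells on $L = 5\lambda$ the stationary profile matches the closed
  form to $10^{-6}$ and the deficit quadrature matches $\tau(x)$ to
  $10^{-4}$.

## Limitations

The package analyzes the idealized SDD lattice and its stated extensions.
It does not model target-gene readout (no decoding function), does not
extract decay lengths from images, and does not attempt the active-transport
mechanisms suggested for Wg and Hh; the space-time formulas are used in
their long-domain form only (finite-domain users should use the point
model). Optimality claims about real systems are conditional on the
geometric parameters supplied -- only Bicoid's are established in the
registry; the wing-disc demo geometry is illustrative.
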