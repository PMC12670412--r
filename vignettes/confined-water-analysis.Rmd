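---
title: "Estimating confinement, diffusion and reorientation of slit-pore water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating confinement, diffusion and reorientation of slit-pore water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slitwater)
```

## The problem

Water confined between two planar surfaces a nanometer or less apart —
the situation in cellulose fibril aggregates, layered minerals, or
graphene slit pores — behaves very differently from bulk water: both
translation and reorientation slow down, and the molecules acquire
preferential orientations and layered density. Quantifying these effects
requires, first of all, a well-defined measure of *how confined* the
water actually is. Defining the slab width from wall-atom positions is
ambiguous (surface roughness, soft potentials, and the difference
between volume unavailable to the wall and volume available to water all
bite). `slitwater` implements an operational alternative: let the water
itself report the geometry through its restricted diffusion.

## The restricted-diffusion estimator

For a particle with perpendicular diffusion coefficient $D_\perp$
between impenetrable reflecting walls separated by $L$, started from the
stationary (uniform) distribution, the perpendicular MSD is

$$\langle z^2\rangle(t) = \frac{L^2}{6}\left(1 - \frac{48}{\pi^4}
\sum_{n\ \mathrm{odd}} \frac{2}{n^4}
e^{-D_\perp n^2 \pi^2 t / L^2}\right).$$

Only odd $n$ contribute, because the general term carries a factor
$1-(-1)^n$. The constant in the prefactor is *analytically forced*: since
$\sum_{n\ \mathrm{odd}} n^{-4} = \pi^4/96$, the series equals 1 at
$t = 0$ only for the prefactor $48/\pi^4$, which is required for
$\langle z^2\rangle(0) = 0$. (Renderings of this series elsewhere
sometimes lose the exponent on the $\pi$ in typesetting; the package
enforces the $t=0$ identity as a unit test, and the whole curve is
verified against an independent Crank–Nicolson solution of the
reflecting-wall diffusion equation to $10^{-8}$.) The two limits carry
the two parameters:

* $t \to 0$: $\langle z^2\rangle \approx 2 D_\perp t$ — the walls are
  not yet felt;
* $t \to \infty$: $\langle z^2\rangle \to L^2/6$ — the variance of the
  difference of two independent uniforms on $[0, L]$, independent of
  $D_\perp$.

`fitConfinement()` therefore fits $L$ and $D_\perp$ *simultaneously* by
bounded Levenberg–Marquardt least squares ($L \in (0, 10L_0]$,
$D_\perp > 0$), initialized from exactly those limits
($L_0 = \sqrt{6\,\mathrm{msd}(t_{\max})}$, $D_0$ from the early slope).
Because the two parameters are constrained by different parts of the
curve, their estimates are nearly uncorrelated;
`mcParameterCorrelation()` quantifies this empirically by refitting
resampled curves (residual resampling by default, parametric Gaussian
noise as an alternative — the choice is exposed because neither is
canonical) and agrees with the Jacobian-based covariance.

Numerical choices: the series is truncated when the next term falls
below $10^{-12}$ of the plateau (configurable); as $t \to 0$ the series
converges slowly, and when more than $10^5$ odd terms would be needed
the free-diffusion form $2 D_\perp t$ is used instead, which is exact to
far better than the truncation tolerance in that regime. The full lag
range is fitted by default (`lagRange` restricts it). A fit whose
maximum lag is shorter than $\approx 5.5$ fitted relaxation times
$L^2/(\pi^2 D_\perp)$ — the point where the model still rises by more
than 5% per decade — is flagged `noPlateau` and warned about, since
without a sampled plateau $L$ is not actually identified; free
(unconfined) input triggers exactly this warning.

## Parallel diffusion

The lateral MSDs grow linearly, $\langle x^2\rangle = 2 D_{\parallel,x} t$
and $\langle y^2\rangle = 2 D_{\parallel,y} t$, and `fitParallelD()`
estimates each slope over a lag window — by default lags between 10%
and 50% of the maximum, skipping the first 2 ps where MD data are
dominated by ballistic/collision behavior; both choices are exposed and
recorded in the result. The composite $D_\parallel$ is the unweighted
mean of the two components (no formula for the combination is canonical;
the two components should and do agree for an isotropic lateral
continuum). Either fit-then-average (default) or average-then-fit is
available.

Because MSD values at neighbouring lags share time origins, ordinary
least-squares slope errors are far too small. `computeMSD()` therefore
also accumulates MSDs over disjoint particle blocks (8 by default);
independent particles make the block-to-block scatter of the fitted $D$
an honest standard error, and that is what `fitParallelD()` reports when
blocks are available. The pair is flagged discrepant when
$|D_x - D_y| > 3$ combined standard errors.

The MSD estimator itself averages over all particles and all time
origins using the standard FFT decomposition ($O(N\log N)$); a direct
double-loop implementation with optional origin stride is kept both as
an option and as the oracle the FFT path is tested against (equality to
$10^{-10}$). Molecular position means the oxygen position: for water the
oxygen sits within 0.007 nm of the center of mass, far below any length
scale resolved here. The perpendicular component is always computed on
raw coordinates; only lateral axes are unwrapped.

## Reorientation

`computeRACF()` estimates
$C(t) = \langle P_2(\mathbf{u}(t_0)\cdot\mathbf{u}(t_0+t))\rangle_{t_0}$
with $P_2(x) = (3x^2-1)/2$, pooling both O–H bonds of every molecule and
averaging over all time origins (the squared dot product is expanded
into the six quadratic component series so the whole estimator runs on
FFTs; the direct double loop is the test oracle). `fitStretchedExp()`
fits

$$C(t) = S^2 + (1 - S^2)\,e^{-(t/\tau)^\beta},$$

where $\tau$ is the reorientational correlation time, $\beta \le 1$
measures the complexity (distribution of time scales) of the decay, and
the order parameter $S$ is the positive square root of the long-time
plateau — the residual orientational anisotropy that motion does not
average out. Bounds are $\beta \in [0.1, 1]$, $S \in [0, 0.999]$,
$\tau \in [\Delta t, 10^3 t_{\max}]$; initialization takes $S^2$ from
the mean of the last 10% of lags, $\tau$ from the first crossing of
$S^2 + (1-S^2)/e$, and $\beta = 0.8$. The lag grid is log-subsampled
(200 points by default) before fitting so the plateau does not dominate
the objective — the balance between decay and plateau regions is
otherwise arbitrary, and this choice is exposed via `nFitPoints`.

## Orientation and density structure

Orientation is measured relative to the *nearest* confining surface:
molecules below the slab midplane belong to the lower wall, at or above
it to the upper wall (the rule for exactly-midplane molecules is a
convention; nothing physical hinges on a set of measure zero).
$\cos\theta$ is the dot product of the bond vector with the assigned
wall's inward normal. $\phi$ is the signed azimuth of the bond's
in-plane projection measured from the chain direction about the normal.
Both variables — rather than $\theta$ or any 3-D angle to the chain
axis — are used because their distributions are exactly flat for
isotropic orientations, so $\langle\cos\theta\rangle =
\langle\phi\rangle = 0$ is the null reference and any structure in the
histograms is real ordering. (The direct 3-D angle to the chain axis
would *not* be flat for isotropic vectors, which is why the azimuth is
the right in-plane coordinate.)

For the two-wall geometry a convention must fix how the second wall's
frame relates to the first's. `slitwater` uses: parallel arrangements
share one global frame; in the antiparallel arrangement — where the
second wall's chain direction is reversed — the second wall's frame is
the mirror image, so $\phi \to -\phi$ for molecules assigned to that
wall. This makes the sign of $\phi$ diagnostic of chain directionality:
a fixture peaked at $+\phi_0$ registers at $-\phi_0$ when the
arrangement is antiparallel and the molecules sit at the flipped wall,
and pooled distributions from antiparallel systems mirror their parallel
counterparts. Isotropic input remains flat under either convention. The
in-plane projection degenerates for bonds parallel to the normal; bonds
with projection below $10^{-9}$ are skipped and counted.

Density profiles bin along the normal, frame-averaged, with the lateral
area taken from the per-frame box. The mass profile assigns each atom's
mass at its own position — hydrogens stick out of the oxygen plane, so
mass density shows sharper layering than the molecule-count (number)
profile; both are provided precisely because they differ in that
informative way. The average slit density divides the water mass by
lateral area × $L$, with $L$ deliberately *required* from the caller
(normally the fitted confinement width): tying the volume definition to
the restricted-diffusion $L$ is a choice, and alternatives remain
pluggable by passing a different $L$.

## Synthetic ground truth: what it emulates, what it does not

All validation runs on generators whose statistics are known exactly:

* `genSlitBrownian()` — anisotropic Brownian motion with specular
  reflections along the normal. The update folds the free Gaussian
  increment into $[0, L]$ (reflect across the violated wall, repeat):
  this is the exact image-method construction of reflected Brownian
  motion, so the saved-frame law is exact for *any* time step, the
  stationary law is uniform, and the long-time displacement plateau is
  $L^2/6$. Tests exploit all three.
* `genRotor()` — rotational diffusion by small tangent-space Gaussian
  steps with renormalization, giving $C(t) = e^{-6 D_r t}$ for the
  isotropic model; the cone model restricts steps (by rejection) to a
  cone of half-angle $\theta_c$, whose order parameter has the
  closed form $S = \cos\theta_c(1+\cos\theta_c)/2$, giving an analytic
  target for $S$-recovery (e.g. $\theta_c = 30.67°$ for $S = 0.8$).
  The default step is 1% of the isotropic correlation time, stated in
  the parameter object, never silent. Step rejection at the cone
  boundary is a first-order boundary treatment: correctness at small
  steps over speed.
* `genOrientedFrames()` — independent frames with Gaussian-mixture
  layering along the normal and bond vectors drawn from target angular
  distributions; serves the orientation and density analyses.
* `synthRacf()` — direct evaluation of the stretched-exponential model,
  for fit self-consistency.

What passing these tests shows: the estimators and fits recover known
translational and rotational parameters, plateaus, and distributions
from data with the *statistical structure the analysis assumes*. What it
does not show: real MD water has hydrogen-bond networks, jump
reorientation, wall corrugation and genuinely multi-scale (KWW-like)
decay — no generator here produces a true stretched-exponential
*process* ($\beta < 1$ arises only in `synthRacf()` curves, which test
$\beta$-recovery of the fitting code, while the rotors test $\tau$ and
$S$ recovery). Conclusions about real systems still require real
trajectories, which enter through the GRO/columnar readers or a
user-supplied adapter for binary formats.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problem
sizes chosen so that statistical recovery criteria are meaningful at
interactive runtimes: e.g. 150–1000 walkers for $10^3$–$10^5$ steps for
the confinement grid (median $|\hat L/L - 1| < 5\%$ over 4 widths × 2
diffusivities × 10 seeds), 2000 rotors over 100 correlation times for
the $S = 0.8$ recovery, and $10^5$–$10^6$ samples for distributional
checks. Every stochastic component takes an explicit integer seed, and
generators are bit-reproducible given one; the pipeline derives
per-system seeds deterministically from a master seed so a series rerun
is byte-identical.

## Known limitations

* The Jacobian-based uncertainties of the confinement fit inherit the
  optimistic bias of correlated-residual least squares; the Monte Carlo
  analysis and the particle-block errors are the honest alternatives
  provided, and the parameter-recovery tests are phrased against ground
  truth rather than against those bands.
* The no-plateau diagnostic is model-based; pathological inputs that fit
  the model well without being restricted diffusion will not be caught.
* `assignNearestSurface()` uses the midplane split; at extreme
  confinement where a molecule interacts with both walls simultaneously
  the "nearest wall" notion itself blurs.
* Binary trajectory formats (XTC/TRR/DCD) are intentionally not parsed;
  any reader that yields frames in the internal model plugs in.
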