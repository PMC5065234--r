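---
title: "Efficient coding with noisy pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient coding with noisy pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcoding)
```

## The encoding model

A sensory pathway is modelled as a static chain: a scalar stimulus
$s \sim N(0, \sigma_s^2)$ is corrupted by additive Gaussian *upstream* noise
$\eta \sim N(0, \sigma_{up}^2)$ before anything else happens; the total input
$z = s + \eta$ is passed through a bounded transfer function (nonlinearity)
$f(z) \in [0, 1]$; the value $f(z)$ sets the mean of a stochastic response
stage; and the stage output is finally corrupted by additive Gaussian
*downstream* noise $\zeta \sim N(0, \sigma_{down}^2)$, giving the response

$$r = \kappa m + \zeta, \qquad m \mid z \sim \mathrm{Pois}(f(z) / \kappa).$$

The scaled-Poisson stage is motivated by quantal synaptic release: responses
come in integer multiples of a quantum $\kappa$, with conditional mean
$f(z)$ and conditional variance $\kappa f(z)$, so larger quanta mean noisier
responses.  Two alternative stage models with matched conditional moments
are provided (`poisson_variant` in `circuit_params()`): a multiplicative
Gaussian (variance $\kappa f$, *not* clipped to $[0,1]$, since it represents
noise added after the nonlinearity) and a binomial stage
($\mathrm{Bin}(N, f)/N$, variance $f(1-f)/N$).  For the binomial stage the
output is scaled by $1/N$ so that its conditional mean equals $f$ like the
other variants.  Any stage whose mean and variance are proportional to $f$
yields the same optimal nonlinearities, which is why these variants are
interchangeable in the analyses.

For two parallel pathways both channels receive the *same* stimulus; the
upstream noises are jointly Gaussian with common variance and correlation
$\rho_{up}$, the downstream noises likewise with correlation $\rho_{down}$,
and the two response stages are conditionally independent.  Everything is a
random variable, not a process: the model describes a circuit that has
already adapted its nonlinearity to stationary stimulus and noise
statistics, and one draw is one integration window.  Temporal dynamics,
adaptation itself, spiking, and non-Gaussian stimulus distributions are out
of scope.

The saturation level is fixed at 1.  The choice is arbitrary (any other
ceiling rescales the decoding weights) and the data model therefore
hard-codes the range $[0, 1]$ rather than exposing it as a parameter.

## Optimality criteria

The primary criterion is the mean squared error (MSE) of the best *linear*
readout $\hat s = D_0 + \sum_i D_i r_i$, minimized jointly over the weights
and the nonlinearities.  Mutual information (MI) between stimulus and
responses is the secondary criterion; it cannot be handled analytically for
this model, so it enters only through the parametric sweep
(`sweep_logistic(objective = "mi")`).

## Rescaling and the effective input correlation

The optimal encoder normalizes its input by the total input standard
deviation $\sigma_z = \sqrt{\sigma_s^2 + \sigma_{up}^2}$: writing
$\tilde f(x) = f(\sigma_z x)$, the rescaled optimum depends on
$(\kappa, \sigma_{down})$ only (single pathway) or on
$(\rho_{eff}, \kappa, \sigma_{down}, \rho_{down})$ (two pathways), where

$$\rho_{eff} = \frac{\sigma_s^2 + \sigma_{up}^2 \rho_{up}}
                    {\sigma_s^2 + \sigma_{up}^2}$$

is the correlation of the total inputs across the two pathways
(`effective_correlation()`).  Decorrelating the inputs completely
($\rho_{eff} = 0$) requires upstream noise variance at least as large as the
stimulus variance.  `rho_up_for_effective()` inverts this relation, which is
how the strategy maps realize a $\rho_{eff}$ grid at fixed
$\sigma_s = 1, \sigma_{up} = 2$ (the default realization; only MSE
magnitudes, never winners, depend on the realization).

The dual-pathway iteration is implemented directly in rescaled coordinates.
The unrescaled and rescaled fixed-point maps are related by an exact linear
bijection, and working in rescaled form lets a single solve serve every
$(\sigma_s, \sigma_{up})$ realization of the same rescaled parameters —
`rescale_phase_map()` re-expresses a whole computed strategy map at a new
realization without re-solving anything.

## The exact single-pathway solution

Minimizing the MSE functionally in $f$, subject to $0 \le f \le 1$ via
continuous Karush–Kuhn–Tucker conditions, shows the optimum is piecewise
linear: $f(z) = \Xi((z - z_0)/(z_1 - z_0))$ with $\Xi$ clipping to
$[0, 1]$.  In rescaled coordinates the kinks satisfy

$$x_1 - x_0 = \tilde D, \qquad
  x_0 = (x_1 - x_0)\left(\kappa/2 - \langle \tilde f \rangle\right),$$

with the rescaled weight obeying
$\tilde D (\kappa \langle \tilde f \rangle + \mathrm{var}[\tilde f] +
\sigma_{down}^2) = \langle y \tilde f \rangle$.  All expectations of the
clipped ramp against the standard normal have closed forms in $\Phi$ and
$\varphi$ (`effcoding:::ramp_moments()`), so `solve_single()` solves a
two-dimensional transcendental system exactly.

Numerically, the system has spurious quasi-roots far in the tails, where
every expectation is exponentially small and the residuals nearly vanish
without describing an optimum.  The solver therefore first *minimizes* the
closed-form MSE of the best ramp over (midpoint, log-width) — a coarse scan
followed by Nelder–Mead — and only then polishes the root of the
self-consistency system with a damped Newton iteration.  Because the global
optimum over all shapes is itself a ramp, the ramp-family minimizer is the
variational solution, and Newton started there converges quadratically.
The residual tolerance is $10^{-8}$ (the system is two-dimensional and each
evaluation is closed-form, so a strict tolerance is cheap).

One genuine degeneracy exists: with $\kappa = 0$ and $\sigma_{down} = 0$
there is no readout noise, widening the ramp always helps, and the optimal
width diverges while the MSE approaches the upstream-noise floor
$\sigma_s^2 \sigma_{up}^2 / (\sigma_s^2 + \sigma_{up}^2)$.  `solve_single()`
detects this, warns, and returns a non-converged record with the limiting
MSE instead of iterating forever.

```{r single}
sol <- solve_single(circuit_params(sigma_up = 0.375, kappa = 1e-3,
                                   sigma_down = 0.05))
sol
```

## The two-pathway fixed-point iteration

For a pair of pathways the variational conditions are coupled nonlinear
integral equations.  `picard_solve()` iterates them as fixed-point maps:
each sweep recomputes the two decoding weights from the explicit 2×2 linear
solve, then updates each tabulated nonlinearity through the clipped
variational expression, in which the coupling enters through the kernel
expectation $E_y[\tilde f_{other}(\sqrt{1-\rho_{eff}^2}\, y + \rho_{eff}
x)]$.  That change of variables moves all $\rho_{eff}$ dependence inside
the nonlinearity argument, which keeps the update stable as
$\rho_{eff} \to 1$; at exactly $\rho_{eff} = 1$ the kernel is a delta
function (the equations become functional and their solutions piecewise
linear), and at $\rho_{eff} = 0$ it integrates the other pathway out (the
equations decouple into two single-pathway copies).

Numerical settings (all overridable through `control`):

* **Grid**: 241 points on $[-6, 6]$ in rescaled units — beyond six standard
  deviations of any Gaussian input used here, matching the quadrature
  truncation.  Tabulated values are interpolated with natural cubic
  splines, clipped to $[0, 1]$, and extended by their boundary values.
* **Quadrature**: 200-node Gauss–Legendre on $[-6, 6]$ with the normal
  density in the integrand; double (cross) expectations by tensor-product
  quadrature.  Deterministic quadrature replaces Monte Carlo sampling of
  the double integrals for reproducibility; `mse(method = "monte_carlo")`
  provides the stochastic cross-check.
* **Convergence**: absolute tolerance $10^{-4}$ on the change of every
  weight and every grid value, with a cap of 2000 iterations.
* **Initialization**: weights drawn $N(\pm 1, 0.5^2)$ with the sign pattern
  of the requested class (ON-OFF: $D_1 > 0 > D_2$); nonlinearity values
  seeded per grid point by drawing the kernel-integral term uniformly
  (independently across grid points) and clipping the resulting update.
* **Stiff corners**: plain (undamped) iteration suffices almost everywhere,
  but near $\rho_{eff} = 1$ with strong anticorrelated downstream noise it
  can enter an exact period-2 cycle.  `multi_seed_solve()` retries a
  non-converged run once with a half-relaxed update
  ($f \leftarrow f + \tfrac12 \Delta f$), which breaks the cycle.

Because convergence of Picard iteration cannot be proven here, multiple
random initializations are used (`multi_seed_solve()`, 20 seeds per class
by default, matching the study conditions; the desk-scale presets use 2–3
since co-converged seeds agree to well below $10^{-2}$ sup-norm, and fine
threshold scans follow the original practice of using a single seed).
Converged solutions are classified by the signs of their weights (opposite:
ON-OFF; equal: ON-ON) and, for ON-ON, by a sup-norm identity test at
tolerance $10^{-2}$ on the rescaled grid — an order of magnitude above the
iteration tolerance and well below any genuine threshold split.  An
independent residual check (`solution_residual()`) re-evaluates the
optimality conditions with a 400-node rule; converged solutions sit within
ten times the iteration tolerance.

```{r dual}
p2 <- circuit_params(sigma_s = 1, sigma_up = 2, kappa = 0.25,
                     sigma_down = 0.25,
                     rho_up = rho_up_for_effective(0.5), rho_down = 0,
                     n_pathways = 2)
multi_seed_solve(p2, n_seeds = 3, seed = 1)
```

## Parametric sweeps

The simulation route mirrors the analytic one with a two-parameter family:
a logistic curve $f(z) = 1/(1 + e^{-\nu(z - \phi)})$ (smooth, as
physiological constraints might demand) or a clipped ramp of width $1/\nu$
centred at $\phi$ (the exact solution's shape).  For each grid point the
model is simulated, the optimal linear weights fitted, and the objective
scored; common random numbers across grid points sharpen the arg-optimum.
Defaults are 25 log-spaced slopes × 25 offsets (the study protocol states
only "a broad range"; the grid is recorded in the output), $10^7$ draws and
5 repetitions at study scale, reducible for interactive work, and a
closed-form scoring mode for deterministic comparisons.  The best logistic
is typically within a few percent of the analytic optimum but cannot reach
it (the logistic family's own floor at the comparison parameters is about
3% excess MSE); the piecewise family closes the gap to fractions of a
percent, which is what the regression tests assert.

## Entropy and mutual information

MI is estimated as $H(R) - \langle H(R \mid S) \rangle_S$ in bits.  The
default density-free estimator is the nearest-neighbour (binless) form

$$H \approx \log_2 \frac{S_d (M-1)}{d} + \frac{\gamma}{\ln 2}
  + \frac{d}{M} \sum_j \log_2 \lambda_j,$$

with exact nearest-neighbour distances ($S_1 = 2$, $S_2 = 2\pi$, $\gamma$
the Euler–Mascheroni constant).  It requires all samples distinct (checked
by exact floating-point equality); when the response support is discretized
— nonzero $\kappa$ with negligible downstream noise — the histogram
estimator with the bin-width correction takes over, using about 50 bins on
a data-driven range padded by $3\sigma_{down}$, with marginal and
conditional entropies sharing one bin width so their difference is
well-defined for discrete data.  Study-scale defaults are $10^4$ stimulus
draws for $H(R)$, $10^4$ responses per conditioning stimulus, and about 10
averaged repetitions; the test suite scales these down and validates both
estimators against Gaussian and uniform closed forms and against direct
numerical integration of the exactly-known response densities of
downstream-noise-only circuits (uniform–Gaussian convolution for the
CDF nonlinearity; atom-plus-ramp convolution for a clipped ramp).

## Strategy maps

`phase_map()` solves both polarity classes over a grid of
$(\rho_{eff}, \kappa, \sigma_{down}, \rho_{down})$ cells and records the
winner and the percent MSE decrease relative to the best other-class
solution.  The mechanism behind the polarity boundary is elementary: the
optimal ON-OFF readout is a *difference* of responses, which cancels
positively correlated downstream noise, while the ON-ON readout is a *sum*,
which cancels negatively correlated downstream noise.  As $\kappa \to 0$
(realized as $\kappa = 10^{-6}$ to stay off the all-noise-zero corner, and
with $\sigma_{down} \ge 0.1$ for the same reason) the equal-MSE crossover
sits at $\rho_{down} = 0$ exactly, by the mirror symmetry that maps an
ON-ON pair at $\rho_{down}$ onto an ON-OFF pair at $-\rho_{down}$ when
$\rho_{eff} = 0$; `boundary_rho_down()` locates it by bisection on the sign
of the class MSE difference.  `splitting_threshold()` scans $\rho_{eff}$
upward and reports the smallest value whose best ON-ON solution is split
rather than identical; splitting occupies a narrow window below
$\rho_{eff} = 1$ that shrinks as $\kappa$ or $\sigma_{down}$ grow.

## What the simulator does and does not emulate

`simulate_circuit()` is the package's synthetic-data generator: it draws
stimulus, correlated Gaussian noises, and stochastic stage outputs in a
fixed documented order from a single seed, so every fixture regenerates
bit-for-bit.  It emulates exactly the static, stationary encoding model
above — which is also all that the solvers assume — so agreement between
simulation and closed forms validates the algebra, not the biology.  Real
neural data would add temporal correlations, adaptation, spiking, stimulus
history, and non-Gaussian statistics, none of which are modelled; passing
tests say nothing about those.

## Problem sizes used by the tests and the acceptance analysis

The packaged regression suite runs the solvers at their full numerical
settings (241-point grids, 200-node quadrature) but reduces repetition
counts: 2–3 random initializations per class, Monte Carlo checks at
$10^5$–$10^6$ draws, MI estimates at $2\times 10^4$ stimuli × $2\times 10^4$
repeats over ~24 conditioning stimuli, and a 45-cell strategy-map subsample
($\rho_{eff} \in \{0, 0.5, 1\}$, $\sigma_{down} \in \{0.1, 0.5, 1\}$,
$\rho_{down} \in \{-1, -0.5, 0, 0.5, 1\}$ at $\kappa = 1$).  These sizes
were chosen so the dispersion across seeds (below $10^{-3}$ sup-norm at
benign parameters) and the Monte Carlo standard errors are far smaller than
every tolerance asserted.

## Known limitations

* Only monotonic nonlinearities emerge from the variational route with a
  linear decoder; non-monotonic transfer functions are not searched.
* Equal noise variances across the two pathways are assumed throughout.
* The binned entropy estimator is one-dimensional; discretized two-pathway
  responses (both $\kappa > 0$ and $\sigma_{down} \approx 0$) are not
  estimable and need a little downstream noise.
* The analytic boundary curves of the polarity phase diagram are not
  implemented (only the bisection-located numerical boundary).  Note that
  the percent MSE differences between classes peak at the
  $\rho_{down} = \pm 1$, large-$\sigma_{down}$ corners for a structural
  reason: the ON-OFF difference readout cancels perfectly correlated
  downstream noise exactly, so its error is independent of
  $\sigma_{down}$ there while the other class pays in full.
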