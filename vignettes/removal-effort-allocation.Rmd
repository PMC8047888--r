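---
title: "Spatial state-space modelling and optimal allocation of removal effort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial state-space modelling and optimal allocation of removal effort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`removalOpt` turns routine removal records from an invasive-species
control program — per-unit annual capture counts and trap-day effort —
into (i) a fitted spatially explicit population model, (ii) an optimized
spatial allocation of a fixed total capture effort, and (iii) a forecast
of how long the population needs to reach a management target density.
This vignette is the package's own account of the model, its assumptions,
and the numerical and design choices behind the implementation.

## The model

### Observation process

Let $C_{i,t}$ be the number of animals removed in spatial unit $i$
($i = 1,\dots,I$) and year $t$, and $E_{i,t}$ the capture effort in
trap-days. CPUE (catch per unit effort, $C_{i,t}/E_{i,t}$) is treated as
an index proportional to population density. With $\mu_{i,t}$ the latent
log relative density,
$$C_{i,t} \sim \mathrm{Poisson}\!\left(E_{i,t}\, e^{\mu_{i,t}}\right),$$
so $\mathbb{E}(C_{i,t}/E_{i,t}) = e^{\mu_{i,t}}$. Capture events are
assumed mutually independent; overdispersion beyond Poisson is absorbed
by the unit-year process noise, not by the observation model.

A unit-year with no trapping is a *missing observation*, not a zero: a
Poisson with mean $0$ carries no information, so absent records
contribute no likelihood term while the latent density keeps evolving
through them. Zero effort with a positive catch is impossible under this
model and is rejected at load time.

### State process

Log density follows a stochastic Gompertz (log-linear autoregressive)
model with environmental covariates, an effort effect, a spatial random
field, year effects and unit-year noise:
$$\mu_{i,t+1} = \alpha + \lambda\,\mu_{i,t} + \textstyle\sum_{k=1}^{5}
\beta_k H_{ki} + \beta_6\, E_{i,t}/100 + \rho_i + \omega_t + e_{i,t},$$
with $\omega_t \sim N(0, \sigma_\omega^2)$ shared by all units within a
transition and $e_{i,t} \sim N(0, \sigma_e^2)$ independent per unit-year.
Effort is stored in trap-days everywhere and divided by 100 only in this
term, so $\beta_6$ reads as the change in log growth rate per 100
trap-days. $\lambda$ measures density dependence: $\lambda = 1$ means
none, $|\lambda| < 1$ guarantees convergence to an equilibrium, and a
negative $\lambda$ gives oscillatory convergence. Covariates $H_{ki}$ are
standardized to mean 0, SD 1, so $\beta_k$ is the effect of +1 SD.
There is one year effect and one noise term per transition, i.e.
$\omega_1,\dots,\omega_{T-1}$ index the transitions $t \to t+1$.

The initial state is $\mu_{i,1} \sim N(0, \sigma_1^2)$, and the spatial
field $\rho$ follows a proper conditional autoregressive (CAR) prior on
the river-section graph,
$$\rho_i \mid \rho_{-i} \sim N\!\left(\gamma \sum_{j \in \delta_i}
\rho_j / k_i,\; \sigma_\rho^2 / k_i\right),$$
where $\delta_i$ are the units sharing an edge with $i$ and
$k_i = |\delta_i|$. These conditionals are mathematically identical to a
joint multivariate normal with precision $(D - \gamma W)/\sigma_\rho^2$
($D = \mathrm{diag}(k_i)$, $W$ the adjacency indicator), which is the
parameterization used both by the exact sampler
(`sampleCARField()`) and inside the MCMC model, because one joint node is
far cheaper than $I$ coupled conditionals. For a connected graph this
precision is positive definite for every $\gamma \in (0,1)$; units with
$k_i = 0$ are rejected at load time since the conditionals divide by
$k_i$.

### Priors and sampling

Posterior sampling is delegated to JAGS (via `rjags`), with four chains,
10,000 iterations, 5,000 warmup and thinning 4 by default, retaining
5,000 draws. Convergence is assessed with split-$\hat R$ computed by the
package (`computeRhat()`); any monitored scalar with $\hat R \ge 1.1$
raises a warning, never an error. Priors:

* $\alpha, \lambda, \beta_k, \beta_6$: Normal(0, SD 100) — effectively
  flat at the scale of the posterior. (True improper flat priors are not
  representable in JAGS.)
* $\sigma_\omega, \sigma_1$: half-Normal with scale 10. The choice to
  place the half-normal on the *standard deviation* rather than the
  variance is deliberate: it is the common weakly-informative
  parameterization and both readings are defensible; at scale 10 the
  data dominate either way.
* $\sigma_e, \sigma_\rho$: Uniform(0, 10) (flat positive, bounded to
  keep the posterior proper).
* $\gamma$: Uniform(0, 1), which exactly delimits the proper-CAR range.

$\lambda$ is *not* constrained to $(-1, 1)$ during fitting — that the
posterior concentrates inside the unit interval is a finding, not an
assumption. Draws with $|\lambda| \ge 1$ are excluded (and counted) by
every equilibrium computation rather than silently included.

`logJointDensity()` evaluates exactly the log target that the sampler
explores, term by term, and is verified in the tests against an
independently hand-summed oracle.

**A known identifiability ridge.** The intercept $\alpha$ and the mean
of the CAR field are only weakly separated (the proper CAR penalizes the
field mean through its smallest precision eigenvalue, which is small for
$\gamma$ near 1). Their *sum* — the quantity every equilibrium and
management output depends on — is well identified and mixes quickly,
but $\alpha$ alone can show large $\hat R$ in short runs while its wide
pooled interval remains honest. The acceptance workflow therefore
reports the convergence of the identified combination
$\alpha + \bar\rho$ alongside the raw parameter diagnostics. Under the
default (long) chain settings this ridge matters much less.

### Model diagnostics

`posteriorPredictiveCheck()` simulates replicate captures per retained
draw and compares annual observed totals with their posterior predictive
distributions: the per-year Bayesian P-value is
$P(\sum_i C^{rep}_{i,t} \ge \sum_i C^{obs}_{i,t})$ *with ties counted
half* — the half-tie rule keeps the statistic symmetric for discrete
counts (the alternative $>$/$\ge$ conventions differ by the tie mass).
Fitting data the model itself generated yields values concentrated near
0.5, which the acceptance suite verifies.

`fixedEffectContribution()` computes, per draw, the share
$\delta = V_1/(V_1+V_2)$ of across-unit variance in growth explained by
the measured covariates ($V_1$, variance of $\sum_k \beta_k H_{ki}$)
against the spatial random field ($V_2$, variance of $\rho_i$). Draws
with $V_1 + V_2 = 0$ are excluded with a reported count.

## The management objective

For a draw with $|\lambda| < 1$, setting $\omega = e = 0$ gives the
deterministic equilibrium
$$\mu^*_i = \frac{\alpha + \sum_k \beta_k H_{ki} + \beta_6 E_i / 100 +
\rho_i}{1 - \lambda},$$
the fixed point of the recursion (verified in tests against 50-step
iteration). No lognormal variance correction is applied — the objective
is defined on the deterministic equilibrium, and the forward simulator
quantifies the (Jensen) gap separately. The whole-area objective is the
posterior mean over retained draws
$$U(\mathbf{E}) = \frac{1}{N} \sum_{n=1}^{N} K_n(\mathbf{E}), \qquad
K_n(\mathbf{E}) = \sum_i 100\, e^{\mu^*_{i,n}},$$
reported on a per-100-trap-day scale; the companion "mean relative
density" $U/(100 I)$ is the expected whole-area mean CPUE per trap-day
and is the quantity compared against the management target (default
0.03, strict inequality). $U$ is a sum of exponentials of affine
functions of $\mathbf{E}$, hence convex in the allocation — the key
structural fact behind all three optimizers.

## Optimizing the allocation

The constraint set $\{E_i \ge 0, \sum_i E_i = E_{total}\}$ is handled by
a softmax reparameterization into $I-1$ unbounded auxiliary variables
($E_i = E_{total}\, e^{a_i} / (1 + \sum_j e^{a_j})$, last unit the
remainder). The implementation max-shifts the exponentials against
overflow and assigns the last component as the exact remainder, so the
budget holds to machine precision.

Three optimizers are provided and cross-checked against each other:

* **Simulated annealing** (`optimizeSA()`): Gaussian single-coordinate
  proposals (SD 0.5) on the auxiliary vector, exponential cooling
  (T0 = 1.0, factor 0.995 per sweep of $I-1$ proposals), default 200,000
  proposal steps, started from the greedy solution. Because the
  objective is convex, the annealer is effectively a polish step and the
  result is insensitive to the schedule; the returned solution is never
  worse than its start or the uniform split. The annealing loop and the
  $O(I \cdot N)$ objective kernel are implemented in C++ (Rcpp) and use
  R's RNG, so runs are bit-reproducible under a seed.
* **Greedy increments** (`optimizeGreedy()`): the budget is split into
  equal increments (default $E_{total}/1000$) assigned one at a time to
  the unit with the highest current posterior-mean equilibrium density.
  Ties break to the lowest unit index for determinism. For separable
  convex objectives this marginal rule is near-exact.
* **KKT water-filling** (`kktWaterfilling()`): the exact deterministic
  optimum, equalizing marginal derivatives on the active set by nested
  bisection (outer on the shared multiplier, inner vectorized per unit).
  It requires $\beta_6/(1-\lambda) < 0$ in every valid draw and refuses
  mixed-sign configurations with a diagnostic. It serves as the oracle
  bounding the other two: the test suite requires SA and greedy within
  1% relative of the KKT objective on random instances of 10-75 units.

`scenarioTable()` evaluates, for each multiplier $m$ of a base total
effort, the objective under uniform, actual ($m \times$ the base
pattern — the natural reading of scaling a reference allocation) and
annealed-optimal allocations, plus percent improvements
$100\,(1 - U_{opt}/U_{ref})$.

## Forecasting the response

`forwardSimulate()` propagates each retained draw from *its own*
final-year latent state — the estimated current state of the system,
which is the natural starting point for "what happens after the new
allocation is implemented" — iterating the full stochastic process model
(fresh $\omega_t$ shared across units, fresh $e_{i,t}$) under the fixed
allocation. Only the process is simulated; captures need not be
re-observed to report density trajectories. `timeToThreshold()` returns,
per draw, the first year whose whole-area mean relative density falls
strictly below the target, with the ensemble median (an order statistic,
so "not reached" tails cannot average in) and the fraction of draws
reaching the target. With noise off, the per-draw trajectory converges
to the deterministic equilibrium geometrically at rate $|\lambda|$
(tested to $10^{-6}$); with the weak density dependence typical of this
system ($|\lambda| \approx 0.16$), over 99% of any gap closes within
three years — the population equilibrates essentially immediately.

## Synthetic study conditions

`generateDataset()` reproduces the statistical structure the model
assumes, so the whole pipeline is testable without field data. Defaults
(the study conditions used throughout the tests):

* 75 river sections over 9 annual steps; the network is a random tree
  grown as a chain with side branches (probability 0.1), emulating
  consecutive 200-m river sections with occasional confluences. The real
  adjacency might or might not contain $k_i = 3$ junctions; the
  branching probability covers both.
* Generating parameters $\alpha = 1.9$, $\lambda = -0.16$,
  $\beta = (-0.05, -0.04, 0.18, 0.11, 0.01)$, $\beta_6 = -0.26$,
  $\gamma = 0.5$, $\sigma_\rho = 0.5$, $\sigma_\omega = 0.2$,
  $\sigma_e = 0.3$. $\sigma_1 = 1$ is the one value with no external
  anchor; it is a realistic spread of initial log densities across an
  established invaded river.
* Effort: trap lines persist, so each unit draws a Gamma base effort
  (mean 2000 trap-days/year, CV 0.4) with lognormal year-to-year jitter
  (SD 0.15). The mean is chosen so the controlled equilibrium CPUE is of
  order $10^{-2}$, matching the regime the model is meant for.
* Irregularity: 41 units are trapped from year 1, the rest enter in
  years 2-6 (program expansion), and 5% of the remaining unit-years are
  missing at random.
* One master seed drives three sub-streams (spatial field, process
  noise, observations), so each layer is reproducible independently.

Covariates are drawn standard-normal and re-standardized so tests can
assert exact mean-0/SD-1. What the generator does *not* emulate: real
spatial covariate autocorrelation (covariates are white noise across
units), observation-level overdispersion, within-season dynamics,
dispersal between units beyond what the CAR field absorbs, and
non-random missingness mechanisms. Passing recovery tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to their violation.

A behavior worth knowing when reading simulated CPUE: with
$|\lambda| \approx 0.16$ the unmanaged equilibrium is restored within
about one year, so a unit skipped for a single year rebounds to carrying
capacity and its next trapped year shows a large CPUE spike. Whole-area
mean CPUE is then dominated by rebound years; the stable controlled
regime is visible in continuously trapped unit-years.

## Problem sizes and numerical settings used by the checks

The test suite fits five replicate synthetic datasets at the full
75 x 9 size with 4 chains x 2,000 iterations (1,000 warmup, thin 4;
1,000 retained draws) — deliberately short chains whose 95% intervals
must cover the generating $\alpha$, $\lambda$, $\beta_6$ in at least
13 of 15 parameter-dataset pairs, and whose posterior predictive
P-values must lie in $[0.1, 0.9]$ for at least 80% of years. Optimizer
cross-checks use 20,000 annealing steps; the CAR sampling check uses
50,000 draws on a 5-unit graph with element-wise tolerance of ~4 Monte
Carlo standard errors. The acceptance script runs one such fit end to
end and 30,000 annealing steps per scenario. Reproducing the published
Kashima River analysis itself requires the original removal records,
which are not redistributed here; the corresponding check reports that
absence rather than substituting synthetic numbers.

## Known limitations

* The sampler is Gibbs/slice-based (JAGS), not Hamiltonian; the
  $\alpha$/$\bar\rho$ ridge mixes slowly in short runs (see above).
* The static allocation is optimized for the equilibrium state;
  time-varying (closed-loop) policies and dispersal dynamics are out of
  scope.
* Effort is the only cost currency; heterogeneous per-unit costs would
  change the water-filling condition but not the framework.
* The Poisson observation model has no overdispersion parameter; if
  real counts are overdispersed at the observation level, $\sigma_e$
  will absorb it into the process.
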