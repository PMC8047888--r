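# removalOpt

Invasive-species control programs accumulate removal records — how many
animals each trap line caught, and how many trap-days it took — but
rarely the dedicated surveys that spatial management optimization seems
to demand. `removalOpt` closes that gap for trap-based control of an
established invader (the motivating system is snapping-turtle removal on
a branching river network): it estimates the population dynamics
directly from the removal records, then uses the fitted model to decide
where a fixed budget of trap-days should go.

The package is aimed at quantitative ecologists and wildlife-management
analysts working with unit-by-year capture/effort data on a spatial
network of management units.

## The model and the objective

Captures are Poisson observations of a latent log relative density
(expected CPUE per trap-day), and the density follows a spatially
explicit stochastic Gompertz model:

    C[i,t] ~ Poisson(E[i,t] * exp(mu[i,t]))
    mu[i,t+1] = alpha + lambda * mu[i,t] + sum_k beta_k * H[k,i]
                + beta6 * E[i,t]/100 + rho_i + omega_t + e[i,t]

with a proper CAR prior on the spatial field `rho` over the river-graph
adjacency, shared year effects `omega`, unit-year noise `e`, and
`mu[i,1] ~ N(0, sigma1^2)`. Fitting is Bayesian (JAGS, four chains,
split-R-hat diagnostics, posterior predictive checks on annual totals).

For each posterior draw with `|lambda| < 1` the equilibrium log density
under a per-unit effort allocation `E` is
`mu*_i = (alpha + sum_k beta_k H[k,i] + beta6 E_i/100 + rho_i)/(1 - lambda)`,
and the management objective is the posterior mean of the whole-area
equilibrium density, `U(E) = mean_n sum_i 100 exp(mu*_{i,n})`.
`U` is convex in `E`, and three optimizers minimize it under
`sum(E) = E_total`: simulated annealing on a softmax reparameterization,
a greedy increment rule, and an exact KKT water-filling solver used as
the oracle for the other two. A forward simulator propagates the full
stochastic process model under the chosen allocation to estimate the
time until the whole-area mean CPUE falls below a management target
(default 0.03 per trap-day).

See `vignettes/removal-effort-allocation.Rmd` for the full account of
priors, parameterizations and numerical choices.

## Worked example

Everything below runs on synthetic data from the package's own
generator, which reproduces the statistical structure the model assumes
(75 river sections, 9 annual steps, staggered unit entry, missing
unit-years).

```r
library(removalOpt)

sim <- generateDataset(seed = 1)          # data + network + known truth
fit <- fitMCMC(sim$data, nChains = 4, nIter = 2000, nWarmup = 1000,
               thin = 4, seed = 1)        # scaled-down chains
fit
#> PosteriorSamples: 1000 retained draws ( 4 chains, warmup 1000 , thin 4 )
#>   max split-Rhat: 7.4673

round(colMeans(drawsMatrix(fit)[, c("lambda", "beta6", "sigma_e")]), 3)
#>  lambda   beta6 sigma_e
#>  -0.165  -0.261   0.286
```

The density dependence (`lambda`, truth -0.16), effort effect per 100
trap-days (`beta6`, truth -0.26) and process noise (`sigma_e`, truth
0.3) are recovered. The large split-R-hat belongs to `alpha` alone: the
intercept and the mean of the spatial field are only jointly identified,
and every management quantity depends on their well-mixed sum (see the
vignette). Posterior predictive P-values for annual capture totals stay
near 0.5, as they should on data the model generated:

```r
range(posteriorPredictiveCheck(fit, sim$data, seed = 1))
#> [1] 0.484 0.520
```

Optimizing the latest-year budget and forecasting the response:

```r
base <- actualAllocation(sim$data)        # latest-year effort pattern
objectiveU(fit, sim$network, base)
#> ObjectiveResult: U = 1515.4998, mean relative density = 0.2021 (0 invalid draws)

opt <- optimizeSA(fit, sim$network, totalEffort(base), steps = 3e4,
                  seed = 1)
opt$result
#> ObjectiveResult: U = 412.9212, mean relative density = 0.0551 (0 invalid draws)
```

`U` is the posterior-mean whole-area equilibrium density on the
per-100-trap-day reporting scale; the mean relative density `U/(100 I)`
is the expected whole-area CPUE per trap-day, the quantity compared
against the 0.03 management target. Reallocating the same budget cuts
the expected equilibrium density by 72.8% here, but 0.055 still misses
the target — the budget, not its placement, is the constraint. At four
times the budget the optimized allocation drives the equilibrium
essentially to zero, and the forward simulation says the system gets
there immediately:

```r
opt4 <- optimizeSA(fit, sim$network, 4 * totalEffort(base),
                   steps = 3e4, seed = 1)
ens <- forwardSimulate(fit, sim$network, opt4$allocation, seed = 1)
timeToThreshold(ens, 0.03)
#> $median
#> [1] 1        # with weak density dependence the system equilibrates
#>              # within a year; all 1000 draws reach the target
```

`scenarioTable()` repeats the uniform/actual/optimal comparison across
budget multipliers in one call.

A thin command-line workflow over the same functions is installed as
`inst/cli/removalopt` (subcommands `simulate-data`, `fit`, `diagnose`,
`optimize`, `scenarios`, `forecast`).

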